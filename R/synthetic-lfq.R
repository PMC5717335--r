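# Synthetic label-free quantification (LFQ) protein-group tables with a
# planted bait-enriched set, log-normal intensities, replicate noise and
# explicit missing values (never encoded as 0).

#' Parameters for a synthetic LFQ protein-group table
#'
#' Defaults emulate the published affinity-purification experiment: 3512
#' quantifiable protein groups, 4 biological replicates per group (bait
#' pull-down vs control), and a small bait-enriched set (42 proteins by
#' default, the size of the published significant set) shifted by +2 log2
#' units in the bait group.
#'
#' @param n_proteins number of protein groups.
#' @param n_replicates_per_group replicates per condition (>= 2).
#' @param log2_mean,log2_sd baseline per-protein log2-intensity distribution
#'   (MaxQuant-style LFQ intensities live around 2^25).
#' @param enriched_ids character protein ids planted as bait interactors, or
#'   an integer count n meaning the first n ids.
#' @param enrichment_log2fc log2 fold change added to bait replicates of
#'   enriched proteins.
#' @param replicate_noise_sd_log2 replicate-to-replicate noise SD (log2).
#' @param missing_rate probability that any single measurement is missing.
#' @param seed integer RNG seed.
#' @return a \code{SimLfqParams} list.
#' @export
sim_lfq_params <- function(n_proteins = 3512L, n_replicates_per_group = 4L,
                           log2_mean = 25, log2_sd = 2,
                           enriched_ids = 42L, enrichment_log2fc = 2,
                           replicate_noise_sd_log2 = 0.3,
                           missing_rate = 0.1, seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  n_replicates_per_group <- as.integer(n_replicates_per_group)
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  if (n_replicates_per_group < 2L) stop("n_replicates_per_group must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  ids <- sprintf("P%05d", seq_len(n_proteins))
  if (is.numeric(enriched_ids) && length(enriched_ids) == 1L)
    enriched_ids <- ids[seq_len(min(as.integer(enriched_ids), n_proteins))]
  enriched_ids <- as.character(enriched_ids)
  if (!all(enriched_ids %in% ids))
    stop("enriched_ids must be a subset of the generated protein ids (",
         "P00001..P", sprintf("%05d", n_proteins), ")")
  p <- list(n_proteins = n_proteins,
            n_replicates_per_group = n_replicates_per_group,
            log2_mean = log2_mean, log2_sd = log2_sd,
            protein_ids = ids, enriched_ids = enriched_ids,
            enrichment_log2fc = enrichment_log2fc,
            replicate_noise_sd_log2 = replicate_noise_sd_log2,
            missing_rate = missing_rate, seed = as.integer(seed))
  class(p) <- "SimLfqParams"
  p
}

#' Simulate an LFQ protein-group intensity table
#'
#' Per protein and replicate, log2 intensity = per-protein baseline
#' (+ enrichment for bait replicates of planted proteins) + Gaussian
#' replicate noise; intensities are reported on the raw (2^x) scale.
#' Measurements are removed completely at random at \code{missing_rate} and
#' encoded as \code{NA}, never as 0. Reproducible from \code{seed}.
#'
#' @param params a \code{SimLfqParams}.
#' @return data.frame with columns \code{protein_id}, \code{gene_name},
#'   \code{is_enriched} (ground truth), and
#'   \code{intensity.<group>.<replicate>} for groups \code{bait} and
#'   \code{control}; class \code{LFQTable}.
#' @export
simulate_lfq_table <- function(params) {
  stopifnot(inherits(params, "SimLfqParams"))
  set.seed(params$seed)
  n <- params$n_proteins
  nr <- params$n_replicates_per_group
  baseline <- stats::rnorm(n, params$log2_mean, params$log2_sd)
  enriched <- params$protein_ids %in% params$enriched_ids
  tab <- data.frame(protein_id = params$protein_ids,
                    gene_name = sprintf("GENE%05d", seq_len(n)),
                    is_enriched = enriched)
  for (grp in c("bait", "control")) {
    shift <- if (grp == "bait") params$enrichment_log2fc * enriched else 0
    for (r in seq_len(nr)) {
      l2 <- baseline + shift +
        stats::rnorm(n, 0, params$replicate_noise_sd_log2)
      v <- 2^l2
      v[stats::runif(n) < params$missing_rate] <- NA_real_
      tab[[sprintf("intensity.%s.%d", grp, r)]] <- v
    }
  }
  class(tab) <- c("LFQTable", "data.frame")
  tab
}

#' Write an LFQ table as tab-separated text
#'
#' Columns: \code{protein_id}, \code{gene_name},
#' \code{intensity.<group>.<replicate>}; missing values written as empty
#' fields. Ground-truth columns (\code{is_enriched}) are dropped on write.
#'
#' @param table an LFQ table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lfq_table <- function(table, path) {
  cols <- c("protein_id", "gene_name",
            grep("^intensity\\.", names(table), value = TRUE))
  missing <- setdiff(c("protein_id", "gene_name"), names(table))
  if (length(missing) > 0L)
    stop("table lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.table(table[, cols, drop = FALSE], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a tab-separated LFQ protein-group table
#'
#' Accepts the dialect written by \code{\link{write_lfq_table}} or any
#' tab-separated table whose intensity columns can be mapped to
#' \code{intensity.<group>.<replicate>} via \code{column_map}.
#'
#' @param path TSV path.
#' @param column_map optional named character vector mapping on-disk column
#'   names to canonical names (e.g.
#'   \code{c("LFQ intensity WT_1" = "intensity.bait.1")}).
#' @return an \code{LFQTable} data.frame; empty intensity fields become
#'   \code{NA}.
#' @export
read_lfq_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"))
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- column_map[names(df)[hit]]
  }
  need <- c("protein_id", "gene_name")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("LFQ table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  int_cols <- grep("^intensity\\.", names(df), value = TRUE)
  if (length(int_cols) == 0L)
    stop("LFQ table '", path, "' has no intensity.<group>.<replicate> ",
         "columns (supply column_map?)")
  for (cc in int_cols) df[[cc]] <- as.numeric(df[[cc]])
  class(df) <- c("LFQTable", "data.frame")
  df
}
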