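# Label-free bait-interactome analysis: filter protein-group tables, compute
# per-protein log2 fold changes and unpaired Student's t-tests between bait
# and control purifications on log2 intensities, classify enrichment at the
# per-protein p < 0.05 rule, and join static annotation sets.

.lfq_group_cols <- function(table, group) {
  grep(sprintf("^intensity\\.%s\\.", group), names(table), value = TRUE)
}

#' Filter an LFQ table to quantifiable rows
#'
#' Keeps protein groups with at least \code{min_valid_per_group} present
#' (non-missing) intensities in \emph{each} of the bait and control groups.
#' This is the only missing-value handling in the pipeline: no imputation is
#' performed. Removed rows are recorded in the \code{"removed"} attribute
#' with a reason.
#'
#' @param table an \code{LFQTable} data.frame.
#' @param min_valid_per_group minimum present values per group (default 2).
#' @return the filtered table (class preserved).
#' @export
filter_quantifiable <- function(table, min_valid_per_group = 2L) {
  bait_cols <- .lfq_group_cols(table, "bait")
  ctrl_cols <- .lfq_group_cols(table, "control")
  if (length(bait_cols) == 0L || length(ctrl_cols) == 0L)
    stop("table lacks intensity.bait.* / intensity.control.* columns")
  n_bait <- rowSums(!is.na(table[, bait_cols, drop = FALSE]))
  n_ctrl <- rowSums(!is.na(table[, ctrl_cols, drop = FALSE]))
  keep <- n_bait >= min_valid_per_group & n_ctrl >= min_valid_per_group
  removed <- data.frame(
    protein_id = table$protein_id[!keep],
    reason = sprintf("valid bait %d/%d, control %d/%d (need >= %d each)",
                     n_bait[!keep], length(bait_cols),
                     n_ctrl[!keep], length(ctrl_cols),
                     as.integer(min_valid_per_group)))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Volcano analysis of bait versus control purifications
#'
#' Intensities are log2-transformed; per protein,
#' \code{log2_fc = mean(log2 bait) - mean(log2 control)} and the p-value
#' comes from a two-sample unpaired pooled-variance Student's t-test on the
#' log2 values. A protein is \code{significant} when \code{p < alpha} and,
#' under the default sign-sensitive rule, \code{log2_fc > 0} (bait-enriched).
#' No multiple-testing correction drives the flag, matching the per-protein
#' p < 0.05 convention; a Benjamini-Hochberg FDR column is emitted for
#' reference only. Rows with zero pooled variance get p = 1 and are flagged.
#'
#' @param table a filtered \code{LFQTable}.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param require_positive_fc if TRUE (default), only bait-enriched
#'   (log2_fc > 0) proteins can be significant.
#' @return data.frame of volcano rows: protein_id, gene_name, log2_fc,
#'   p_value, neg_log10_p, fdr, significant, flagged, annotation_flags.
#' @export
volcano <- function(table, alpha = 0.05, require_positive_fc = TRUE) {
  bait <- log2(as.matrix(table[, .lfq_group_cols(table, "bait"),
                               drop = FALSE]))
  ctrl <- log2(as.matrix(table[, .lfq_group_cols(table, "control"),
                               drop = FALSE]))
  nb <- rowSums(!is.na(bait)); nc <- rowSums(!is.na(ctrl))
  if (any(nb < 2L | nc < 2L))
    stop("volcano needs >= 2 present values per group per row; ",
         "run filter_quantifiable() first")
  mb <- rowMeans(bait, na.rm = TRUE); mc <- rowMeans(ctrl, na.rm = TRUE)
  ssb <- rowSums((bait - mb)^2, na.rm = TRUE)
  ssc <- rowSums((ctrl - mc)^2, na.rm = TRUE)
  df <- nb + nc - 2L
  s2 <- (ssb + ssc) / df
  se <- sqrt(s2 * (1 / nb + 1 / nc))
  fc <- mb - mc
  tstat <- ifelse(se > 0, fc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df), 1)
  flagged <- se == 0
  sig <- p < alpha & (!require_positive_fc | fc > 0)
  out <- data.frame(
    protein_id = table$protein_id, gene_name = table$gene_name,
    log2_fc = fc, p_value = p, neg_log10_p = -log10(p),
    fdr = stats::p.adjust(p, method = "BH"),
    significant = sig & !flagged, flagged = flagged,
    annotation_flags = "", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach static annotation-set flags to volcano rows
#'
#' A plain set-membership join (e.g. a curated kinetochore protein list):
#' each label whose id set contains the protein is appended to that row's
#' \code{annotation_flags} (semicolon-separated). Ids in the map that match
#' no row are counted and reported via the \code{"unknown_ids"} attribute.
#'
#' @param rows volcano rows from \code{\link{volcano}}.
#' @param annotation_map named list: label -> character vector of
#'   protein_ids.
#' @return rows with \code{annotation_flags} filled; per-label counts in
#'   attribute \code{"flag_counts"}.
#' @export
annotate_volcano <- function(rows, annotation_map) {
  if (length(annotation_map) == 0L) {
    attr(rows, "flag_counts") <- integer(0)
    attr(rows, "unknown_ids") <- integer(0)
    return(rows)
  }
  if (is.null(names(annotation_map)))
    stop("annotation_map must be a named list of protein-id sets")
  flags <- rep("", nrow(rows))
  counts <- integer(length(annotation_map))
  names(counts) <- names(annotation_map)
  unknown <- integer(length(annotation_map))
  names(unknown) <- names(annotation_map)
  for (lab in names(annotation_map)) {
    ids <- as.character(annotation_map[[lab]])
    hit <- rows$protein_id %in% ids
    counts[lab] <- sum(hit)
    unknown[lab] <- length(setdiff(ids, rows$protein_id))
    flags[hit] <- ifelse(nzchar(flags[hit]), paste0(flags[hit], ";", lab), lab)
  }
  rows$annotation_flags <- flags
  attr(rows, "flag_counts") <- counts
  attr(rows, "unknown_ids") <- unknown
  rows
}

#' Read a label -> protein-id annotation map from a two-column TSV
#'
#' Expected columns: \code{label}, \code{protein_id}.
#'
#' @param path TSV path.
#' @return named list of character vectors.
#' @export
read_annotation_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "protein_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("annotation file lacks column(s): ", paste(missing, collapse = ", "))
  lapply(split(df$protein_id, df$label), unique)
}
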