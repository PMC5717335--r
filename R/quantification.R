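# Background-corrected per-kinetochore intensity measurement, line profiles
# across kinetochore pairs, and per-cell summaries.

#' Measure one kinetochore region in one channel
#'
#' Local background is the arithmetic mean over the region's annulus;
#' the corrected sum subtracts that mean from every voxel of the measurement
#' mask: \code{corrected_sum = raw_sum - background_mean * n_mask_voxels}.
#' Negative corrected sums are retained: clamping would bias dim-signal
#' conditions such as depleted cells.
#'
#' @param stack an \code{ImageStack}.
#' @param region a \code{KinetochoreRegion}.
#' @param channel channel name to measure.
#' @param mask which mask to measure in: \code{"expanded"} (default; the
#'   outer-kinetochore mask) or \code{"core"}.
#' @return one-row data.frame: label, channel, n_mask_voxels,
#'   n_annulus_voxels, background_mean, raw_sum, corrected_sum.
#' @export
measure_region <- function(stack, region, channel,
                           mask = c("expanded", "core")) {
  mask <- match.arg(mask)
  idx <- if (mask == "expanded") region$expanded else region$core
  if (length(idx) == 0L) stop("region ", region$label, ": empty mask")
  if (length(region$annulus) == 0L)
    stop("region ", region$label, ": empty background annulus")
  arr <- channel_array(stack, channel)
  bg <- mean(arr[region$annulus])
  raw <- sum(arr[idx])
  data.frame(label = region$label, channel = channel,
             n_mask_voxels = length(idx),
             n_annulus_voxels = length(region$annulus),
             background_mean = bg, raw_sum = raw,
             corrected_sum = raw - bg * length(idx))
}

#' Measure all regions of a cell across channels
#'
#' Flagged regions (empty annulus) are carried through with NA measurements
#' and \code{flagged = TRUE}; they are excluded from per-cell summaries.
#'
#' @param stack an \code{ImageStack}.
#' @param regions list of \code{KinetochoreRegion}.
#' @param channels channels to measure (default: all except DAPI).
#' @param mask measurement mask policy, as in \code{\link{measure_region}}.
#' @return data.frame, one row per region x channel, including centroid
#'   coordinates (0-based voxel and um).
#' @export
measure_cell <- function(stack, regions, channels = NULL,
                         mask = c("expanded", "core")) {
  mask <- match.arg(mask)
  if (is.null(channels))
    channels <- setdiff(stack$channel_names, "DAPI")
  vs <- stack$voxel_size
  rows <- list()
  for (r in regions) {
    for (ch in channels) {
      if (r$flagged) {
        m <- data.frame(label = r$label, channel = ch,
                        n_mask_voxels = length(
                          if (mask == "expanded") r$expanded else r$core),
                        n_annulus_voxels = 0L,
                        background_mean = NA_real_, raw_sum = NA_real_,
                        corrected_sum = NA_real_)
      } else {
        m <- measure_region(stack, r, ch, mask)
      }
      m$centroid_z <- r$centroid[1L] - 1   # exported 0-based
      m$centroid_y <- r$centroid[2L] - 1
      m$centroid_x <- r$centroid[3L] - 1
      m$centroid_z_um <- (r$centroid[1L] - 0.5) * vs[1L]
      m$centroid_y_um <- (r$centroid[2L] - 0.5) * vs[2L]
      m$centroid_x_um <- (r$centroid[3L] - 0.5) * vs[3L]
      m$flagged <- r$flagged
      rows[[length(rows) + 1L]] <- m
    }
  }
  if (length(rows) == 0L)
    return(data.frame(label = integer(0), channel = character(0),
                      n_mask_voxels = integer(0), n_annulus_voxels = integer(0),
                      background_mean = numeric(0), raw_sum = numeric(0),
                      corrected_sum = numeric(0), centroid_z = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0),
                      centroid_z_um = numeric(0), centroid_y_um = numeric(0),
                      centroid_x_um = numeric(0), flagged = logical(0)))
  do.call(rbind, rows)
}

#' Intensity line profile between two points
#'
#' Samples each requested channel at \code{n_samples} equidistant points on
#' the segment from \code{p0} to \code{p1} by trilinear interpolation (edge
#' voxels clamped), reporting distance along the segment in micrometres.
#' Used to display co-localization across a sister-kinetochore pair.
#'
#' @param stack an \code{ImageStack}.
#' @param p0,p1 numeric \code{(z, y, x)} continuous 1-based voxel
#'   coordinates; must lie inside the grid.
#' @param channels channels to sample (default all).
#' @param n_samples number of samples; default gives ~0.5-pixel spacing.
#' @param normalize if TRUE, min-max normalize each channel to [0, 1] for
#'   co-plotting.
#' @return data.frame: sample index, distance_um, one column per channel.
#' @export
line_profile <- function(stack, p0, p1, channels = NULL, n_samples = NULL,
                         normalize = FALSE) {
  d <- dim(stack$data)[2:4]
  for (p in list(p0, p1))
    if (length(p) != 3L || any(p < 0.5) || any(p > d + 0.5))
      stop("profile endpoints must be (z, y, x) inside the grid")
  if (is.null(channels)) channels <- stack$channel_names
  vs <- stack$voxel_size
  seg_px <- p1 - p0
  len_um <- sqrt(sum((seg_px * vs)^2))
  if (is.null(n_samples))
    n_samples <- max(2L, ceiling(2 * sqrt(sum(seg_px[2:3]^2))) + 1L)
  if (n_samples < 2L) stop("n_samples must be >= 2")
  t <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1L] + t * seg_px[1L], p0[2L] + t * seg_px[2L],
               p0[3L] + t * seg_px[3L])
  out <- data.frame(sample = seq_len(n_samples), distance_um = t * len_um)
  for (ch in channels) {
    arr <- channel_array(stack, ch)
    out[[ch]] <- .trilinear(arr, pts)
    if (normalize) {
      v <- out[[ch]]
      rng <- range(v)
      out[[ch]] <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0
    }
  }
  out
}

# Trilinear interpolation at continuous 1-based voxel-center coordinates;
# coordinates beyond the outermost voxel centers are clamped.
.trilinear <- function(arr, pts) {
  d <- dim(arr)
  out <- numeric(nrow(pts))
  cl <- function(v, n) pmin(pmax(v, 1), n)
  z <- cl(pts[, 1L], d[1L]); y <- cl(pts[, 2L], d[2L]); x <- cl(pts[, 3L], d[3L])
  z0 <- pmin(floor(z), d[1L] - 1L); z0 <- pmax(z0, 1L)
  y0 <- pmin(floor(y), d[2L] - 1L); y0 <- pmax(y0, 1L)
  x0 <- pmin(floor(x), d[3L] - 1L); x0 <- pmax(x0, 1L)
  if (d[1L] == 1L) z0 <- rep(1L, length(z))
  if (d[2L] == 1L) y0 <- rep(1L, length(y))
  if (d[3L] == 1L) x0 <- rep(1L, length(x))
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  z1 <- pmin(z0 + 1L, d[1L]); y1 <- pmin(y0 + 1L, d[2L]); x1 <- pmin(x0 + 1L, d[3L])
  g <- function(zi, yi, xi) arr[cbind(zi, yi, xi)]
  g(z0, y0, x0) * (1 - fz) * (1 - fy) * (1 - fx) +
    g(z1, y0, x0) * fz * (1 - fy) * (1 - fx) +
    g(z0, y1, x0) * (1 - fz) * fy * (1 - fx) +
    g(z0, y0, x1) * (1 - fz) * (1 - fy) * fx +
    g(z1, y1, x0) * fz * fy * (1 - fx) +
    g(z1, y0, x1) * fz * (1 - fy) * fx +
    g(z0, y1, x1) * (1 - fz) * fy * fx +
    g(z1, y1, x1) * fz * fy * fx
}

#' Summarize a cell's kinetochore measurements
#'
#' Aggregates the background-corrected sums of all non-flagged regions per
#' channel. The mean is the default central value (per-cell means feed the
#' n-cells-per-condition statistics); the median is available for
#' robustness to outlier regions.
#'
#' @param measurements output of \code{\link{measure_cell}}.
#' @param method \code{"mean"} (default) or \code{"median"}.
#' @param cell_id,condition,phase labels copied into the output.
#' @return data.frame: cell_id, condition, phase, channel, summary,
#'   n_regions. Zero valid regions yields zero rows (the cell is dropped
#'   with a warning).
#' @export
summarize_cell <- function(measurements, method = c("mean", "median"),
                           cell_id = "cell", condition = "unknown",
                           phase = NA_character_) {
  method <- match.arg(method)
  if (!is.na(phase)) phase <- match.arg(phase, PHASE_LEVELS)
  ok <- measurements[!measurements$flagged & !is.na(measurements$corrected_sum),
                     , drop = FALSE]
  if (nrow(ok) == 0L) {
    warning("cell '", cell_id, "': no valid regions; excluded from summaries")
    return(data.frame(cell_id = character(0), condition = character(0),
                      phase = character(0), channel = character(0),
                      summary = numeric(0), n_regions = integer(0)))
  }
  agg <- if (method == "mean") mean else stats::median
  sp <- split(ok$corrected_sum, ok$channel)
  data.frame(cell_id = cell_id, condition = condition, phase = phase,
             channel = names(sp),
             summary = vapply(sp, agg, numeric(1L)),
             n_regions = vapply(sp, length, integer(1L)),
             row.names = NULL)
}

#' Mitotic phase vocabulary
#' @export
PHASE_LEVELS <- c("interphase", "prophase", "prometaphase", "metaphase",
                  "anaphase", "cytokinesis")

#' Normalize per-cell summaries to a reference condition
#'
#' Divides every cell's per-channel summary by the mean summary of the
#' reference condition in that channel, so the reference group mean maps to
#' 1.0. This is the arbitrary-units convention used for plotting depletion
#' experiments; it is a presentation choice, not part of the measurement.
#'
#' @param cell_summaries data.frame in the per-cell schema (from
#'   \code{\link{summarize_cell}} rows bound together).
#' @param reference_condition condition label used as denominator.
#' @return the input with an added \code{normalized} column.
#' @export
normalize_to_reference <- function(cell_summaries, reference_condition) {
  ref <- cell_summaries[cell_summaries$condition == reference_condition, ,
                        drop = FALSE]
  if (nrow(ref) == 0L)
    stop("reference condition '", reference_condition, "' has no cells")
  out <- cell_summaries
  out$normalized <- NA_real_
  for (ch in unique(out$channel)) {
    m <- mean(ref$summary[ref$channel == ch])
    if (!is.finite(m) || m <= 0)
      stop("reference mean for channel '", ch, "' is not positive (", m, ")")
    sel <- out$channel == ch
    out$normalized[sel] <- out$summary[sel] / m
  }
  out
}
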