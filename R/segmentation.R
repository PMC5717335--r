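# Segmentation chain: DAPI-derived cuboid ROI -> Otsu threshold on the ACA
# channel in 3D -> connected components -> minimum-size filter -> in-plane
# mask expansion (outer kinetochore) -> background annulus.
#
# Voxel sets are held as sorted linear indices into the (nz, ny, nx) channel
# array (column-major, z fastest); coordinates are 1-based internally and
# exported 0-based in result tables.

#' Segmentation parameters
#'
#' Defaults follow the published volumetric analysis: minimum object size of
#' 70 voxels, 4-pixel (0.32 um at 0.08 um pitch) expansion of the ACA mask
#' perimeter to capture the outer kinetochore, and a 2-pixel background
#' annulus separated from the mask by a 1-pixel gap.
#'
#' @param min_object_voxels minimum 3D component size kept (voxels).
#' @param expand_radius_px Euclidean expansion radius of the core mask, in xy
#'   pixels.
#' @param annulus_gap_px gap between the measured mask and the annulus (px).
#' @param annulus_width_px annulus thickness (px).
#' @param connectivity component connectivity: 6, 18 or 26.
#' @param roi_padding_px padding added to the DAPI bounding cuboid (px).
#' @param dilate_3d if TRUE, expansion/annulus dilation uses a 3D ball in
#'   voxel units; default FALSE dilates in-plane only (z-spacing is typically
#'   2.5x the xy pitch, so an in-pixel 3D ball would be physically
#'   anisotropic).
#' @param annulus_around build the annulus around the \code{"expanded"}
#'   (default) or the \code{"core"} mask.
#' @param measure_mask measure intensities in the \code{"expanded"} (default)
#'   or the \code{"core"} mask.
#' @return a \code{SegmentationParams} list.
#' @export
seg_params <- function(min_object_voxels = 70L, expand_radius_px = 4L,
                       annulus_gap_px = 1L, annulus_width_px = 2L,
                       connectivity = 26L, roi_padding_px = 2L,
                       dilate_3d = FALSE,
                       annulus_around = c("expanded", "core"),
                       measure_mask = c("expanded", "core")) {
  p <- list(min_object_voxels = as.integer(min_object_voxels),
            expand_radius_px = as.integer(expand_radius_px),
            annulus_gap_px = as.integer(annulus_gap_px),
            annulus_width_px = as.integer(annulus_width_px),
            connectivity = as.integer(connectivity),
            roi_padding_px = as.integer(roi_padding_px),
            dilate_3d = isTRUE(dilate_3d),
            annulus_around = match.arg(annulus_around),
            measure_mask = match.arg(measure_mask))
  if (p$min_object_voxels < 1L) stop("min_object_voxels must be >= 1")
  if (p$expand_radius_px < 0L || p$annulus_gap_px < 0L ||
      p$annulus_width_px < 0L || p$roi_padding_px < 0L)
    stop("radii, gaps and padding must be >= 0")
  if (!p$connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  class(p) <- "SegmentationParams"
  p
}

.lin_encode <- function(z, y, x, dims) {
  as.integer(z + (y - 1L) * dims[1L] + (x - 1L) * dims[1L] * dims[2L])
}

.lin_decode <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1L] + 1L
  y <- (idx0 %/% dims[1L]) %% dims[2L] + 1L
  x <- idx0 %/% (dims[1L] * dims[2L]) + 1L
  cbind(z = z, y = y, x = x)
}

# Structuring-element offsets: Euclidean disk (in-plane) or ball (3D) of
# integer radius r, as an offset matrix (dz, dy, dx) including the origin.
.se_offsets <- function(radius, three_d = FALSE) {
  r <- as.integer(radius)
  s <- -r:r
  if (three_d) {
    g <- expand.grid(dz = s, dy = s, dx = s)
    keep <- g$dz^2 + g$dy^2 + g$dx^2 <= r^2
  } else {
    g <- expand.grid(dz = 0L, dy = s, dx = s)
    keep <- g$dy^2 + g$dx^2 <= r^2
  }
  as.matrix(g[keep, , drop = FALSE])
}

# Dilate a voxel set (linear indices) by a structuring element, clipping to
# bounds: list(z = c(lo, hi), y = ..., x = ...). Backed by C++ (hot path).
.dilate_lin <- function(idx, offsets, dims, bounds) {
  if (length(idx) == 0L) return(integer(0))
  .dilate_lin_cpp(as.integer(idx), as.integer(dims),
                  matrix(as.integer(offsets), ncol = 3L),
                  as.integer(c(bounds$z, bounds$y, bounds$x)))
}

#' Otsu threshold of an intensity sample
#'
#' Builds a 256-bin histogram over the sample range and returns the
#' threshold maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}. Ties are broken toward the
#' lowest qualifying threshold. The returned value is the largest sample
#' value assigned to the background class, so foreground is exactly
#' \code{values > threshold}.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold value (scalar).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  vmin <- min(values); vmax <- max(values)
  if (vmax <= vmin) stop("cannot threshold a constant sample")
  w <- (vmax - vmin) / n_bins
  bin <- pmin(as.integer(floor((values - vmin) / w)) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- vmin + (seq_len(n_bins) - 0.5) * w
  n <- length(values)
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * mids)
  tot_s <- cum_s[n_bins]
  k <- seq_len(n_bins - 1L)            # split after bin k
  w0 <- cum_n[k] / n
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- cum_s[k] / cum_n[k]
  mu1 <- (tot_s - cum_s[k]) / (n - cum_n[k])
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  kstar <- which.max(bcv)              # which.max takes the first (lowest) tie
  max(values[bin <= kstar])
}

#' Cuboid region of interest around the DAPI-stained nucleus
#'
#' Otsu-thresholds the DAPI channel over the whole stack and returns the
#' axis-aligned bounding cuboid of the foreground, padded by
#' \code{roi_padding_px} in every axis and clipped to the grid.
#'
#' @param stack an \code{ImageStack} containing a \code{"DAPI"} channel.
#' @param params a \code{SegmentationParams} object.
#' @param dapi_channel name of the DNA counterstain channel.
#' @return a list \code{(z = c(lo, hi), y = ..., x = ...)} of 1-based
#'   inclusive bounds, class \code{"ROI"}.
#' @export
crop_dapi_roi <- function(stack, params = seg_params(),
                          dapi_channel = "DAPI") {
  arr <- channel_array(stack, dapi_channel)
  if (max(arr) <= min(arr))
    stop("no nucleus detected: DAPI channel is constant")
  thr <- otsu_threshold(as.vector(arr))
  fg <- which(arr > thr, arr.ind = TRUE)   # columns: dim1=z, dim2=y, dim3=x
  if (nrow(fg) == 0L) stop("no nucleus detected: empty DAPI foreground")
  pad <- params$roi_padding_px
  d <- dim(arr)
  roi <- list(
    z = c(max(1L, min(fg[, 1L]) - pad), min(d[1L], max(fg[, 1L]) + pad)),
    y = c(max(1L, min(fg[, 2L]) - pad), min(d[2L], max(fg[, 2L]) + pad)),
    x = c(max(1L, min(fg[, 3L]) - pad), min(d[3L], max(fg[, 3L]) + pad)))
  class(roi) <- "ROI"
  roi
}

#' Whole-grid ROI (no DAPI cropping)
#'
#' @param stack an \code{ImageStack}.
#' @return an \code{ROI} spanning the full grid.
#' @export
full_roi <- function(stack) {
  d <- dim(stack$data)
  roi <- list(z = c(1L, d[2L]), y = c(1L, d[3L]), x = c(1L, d[4L]))
  class(roi) <- "ROI"
  roi
}

#' Expand a voxel mask by a Euclidean radius
#'
#' Morphological dilation by a disk of radius \code{expand_radius_px} applied
#' within each z-plane (default), or by a ball when \code{dilate_3d}; the
#' result is clipped to \code{bounds}.
#'
#' @param core_idx sorted linear voxel indices of the core mask.
#' @param expand_radius_px radius in pixels.
#' @param dims channel array dimensions \code{(nz, ny, nx)}.
#' @param bounds ROI bounds list.
#' @param dilate_3d logical.
#' @return sorted linear indices of the expanded mask (a superset of
#'   \code{core_idx}).
#' @export
expand_mask <- function(core_idx, expand_radius_px, dims, bounds,
                        dilate_3d = FALSE) {
  if (expand_radius_px == 0L) return(sort(unique(core_idx)))
  .dilate_lin(core_idx, .se_offsets(expand_radius_px, dilate_3d), dims, bounds)
}

#' Build a background annulus around a mask
#'
#' The annulus is the set difference of two dilations of the base mask, by
#' \code{gap_px + width_px} and by \code{gap_px}, minus the union of every
#' region's measured mask so neighbouring kinetochores never contaminate the
#' background sample.
#'
#' @param base_idx linear indices of the mask to ring (expanded mask by
#'   default policy).
#' @param exclude_idx linear indices excluded from the annulus (union of all
#'   regions' measured masks).
#' @param gap_px,width_px annulus geometry in pixels.
#' @param dims channel array dims.
#' @param bounds ROI bounds.
#' @param dilate_3d logical.
#' @return sorted linear indices of the annulus (possibly empty).
#' @export
build_annulus <- function(base_idx, exclude_idx, gap_px, width_px,
                          dims, bounds, dilate_3d = FALSE) {
  outer <- .dilate_lin(base_idx, .se_offsets(gap_px + width_px, dilate_3d),
                       dims, bounds)
  inner <- if (gap_px > 0L)
    .dilate_lin(base_idx, .se_offsets(gap_px, dilate_3d), dims, bounds)
  else sort(unique(base_idx))
  ring <- setdiff(outer, inner)
  sort(setdiff(ring, exclude_idx))
}

#' Segment kinetochores from the centromere reference channel
#'
#' Within the ROI, the reference (ACA) channel is Otsu-thresholded, connected
#' components are labeled at the configured connectivity, components below
#' \code{min_object_voxels} are discarded, remaining objects get expanded
#' measurement masks and background annuli, and labels are assigned in
#' deterministic scan order.
#'
#' @param stack an \code{ImageStack}.
#' @param roi an \code{ROI} (from \code{\link{crop_dapi_roi}} or
#'   \code{\link{full_roi}}).
#' @param params a \code{SegmentationParams}.
#' @param reference_channel channel defining kinetochore positions.
#' @return list of \code{KinetochoreRegion} objects; empty if no object
#'   survives the size filter. The Otsu threshold used is attached as
#'   attribute \code{"threshold"}.
#' @export
segment_kinetochores <- function(stack, roi, params = seg_params(),
                                 reference_channel = "ACA") {
  arr <- channel_array(stack, reference_channel)
  dims <- dim(arr)
  sub <- arr[roi$z[1L]:roi$z[2L], roi$y[1L]:roi$y[2L], roi$x[1L]:roi$x[2L],
             drop = FALSE]
  if (max(sub) <= min(sub)) {
    regions <- list()
    attr(regions, "threshold") <- NA_real_
    return(regions)
  }
  thr <- otsu_threshold(as.vector(sub))
  mask_sub <- sub > thr
  lab_sub <- .cc_label3d(as.integer(mask_sub), dim(sub), params$connectivity)
  nlab <- max(lab_sub, 0L)
  regions <- list()
  if (nlab > 0L) {
    sizes <- tabulate(lab_sub, nbins = nlab)
    keep <- which(sizes >= params$min_object_voxels)
    sub_dims <- dim(sub)
    off <- c(roi$z[1L] - 1L, roi$y[1L] - 1L, roi$x[1L] - 1L)
    new_label <- 0L
    for (lb in keep) {                 # keep is ascending = scan order
      new_label <- new_label + 1L
      sidx <- which(lab_sub == lb)
      zyx <- .lin_decode(sidx, sub_dims)
      zyx <- sweep(zyx, 2L, off, "+")
      core <- sort(.lin_encode(zyx[, 1L], zyx[, 2L], zyx[, 3L], dims))
      regions[[new_label]] <- structure(list(
        label = new_label,
        core = core,
        voxel_count = length(core),
        centroid = colMeans(zyx),
        expanded = NULL, annulus = NULL, flagged = FALSE),
        class = "KinetochoreRegion")
    }
  }
  bounds <- roi
  for (i in seq_along(regions)) {
    regions[[i]]$expanded <- expand_mask(
      regions[[i]]$core, params$expand_radius_px, dims, bounds,
      params$dilate_3d)
  }
  measure_union <- sort(unique(unlist(lapply(regions, function(r)
    if (params$measure_mask == "expanded") r$expanded else r$core))))
  for (i in seq_along(regions)) {
    base <- if (params$annulus_around == "expanded")
      regions[[i]]$expanded else regions[[i]]$core
    ann <- build_annulus(base, measure_union, params$annulus_gap_px,
                         params$annulus_width_px, dims, bounds,
                         params$dilate_3d)
    regions[[i]]$annulus <- ann
    if (length(ann) == 0L) regions[[i]]$flagged <- TRUE
  }
  attr(regions, "threshold") <- thr
  regions
}

#' @export
print.KinetochoreRegion <- function(x, ...) {
  cat(sprintf(
    "KinetochoreRegion %d: %d core voxels, %d expanded, %d annulus, centroid (z,y,x) = (%.1f, %.1f, %.1f)%s\n",
    x$label, x$voxel_count, length(x$expanded), length(x$annulus),
    x$centroid[1L], x$centroid[2L], x$centroid[3L],
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}
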