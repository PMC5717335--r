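# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: flood fill instead of the Rcpp labeler,
# exhaustive threshold search instead of the histogram recursion,
# Gauss-Legendre quadrature of the Gaussian density instead of pnorm
# differences, and brute-force lattice counts for the morphology.

# --- flood-fill connected components (frontier-vectorized BFS) -------------
oracle_label3d <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  s <- abs(off$dz) + abs(off$dy) + abs(off$dx)
  off <- off[s > 0 & s <= switch(as.character(connectivity),
                                 "6" = 1L, "18" = 2L, "26" = 3L), ]
  labels <- array(0L, dim = d)
  fg <- which(mask)
  lab <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    frontier <- seed
    labels[seed] <- lab
    while (length(frontier) > 0L) {
      i0 <- frontier - 1L
      z <- i0 %% d[1L] + 1L
      y <- (i0 %/% d[1L]) %% d[2L] + 1L
      x <- i0 %/% (d[1L] * d[2L]) + 1L
      n <- length(z); m <- nrow(off)
      zz <- rep(z, times = m) + rep(off$dz, each = n)
      yy <- rep(y, times = m) + rep(off$dy, each = n)
      xx <- rep(x, times = m) + rep(off$dx, each = n)
      ok <- zz >= 1L & zz <= d[1L] & yy >= 1L & yy <= d[2L] &
            xx >= 1L & xx <= d[3L]
      cand <- unique((xx[ok] - 1L) * d[1L] * d[2L] + (yy[ok] - 1L) * d[1L] +
                       zz[ok])
      cand <- cand[mask[cand] & labels[cand] == 0L]
      labels[cand] <- lab
      frontier <- cand
    }
  }
  labels
}

# Brute-force segmentation chain: threshold -> flood fill -> size filter.
# Returns list of sorted linear-index core sets, in first-voxel scan order.
oracle_segment <- function(arr, threshold, min_size, connectivity = 26L) {
  labels <- oracle_label3d(arr > threshold, connectivity)
  k <- max(labels)
  if (k == 0L) return(list())
  sets <- lapply(seq_len(k), function(l) which(labels == l))
  sets[vapply(sets, length, 0L) >= min_size]
}

# --- exhaustive Otsu over all 256-bin splits --------------------------------
oracle_otsu <- function(values, n_bins = 256L) {
  vmin <- min(values); vmax <- max(values)
  w <- (vmax - vmin) / n_bins
  bin <- pmin(floor((values - vmin) / w) + 1L, n_bins)
  best <- -Inf; best_k <- NA_integer_
  n <- length(values)
  for (k in seq_len(n_bins - 1L)) {
    in0 <- bin <= k
    n0 <- sum(in0)
    if (n0 == 0L || n0 == n) next
    # class means over bin midpoints, as in the histogram formulation
    mids <- vmin + (bin - 0.5) * w
    mu0 <- mean(mids[in0]); mu1 <- mean(mids[!in0])
    bcv <- (n0 / n) * (1 - n0 / n) * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; best_k <- k }
  }
  max(values[bin <= best_k])
}

# --- Gauss-Legendre quadrature of the anisotropic Gaussian ------------------
# 5-point nodes/weights on [-1, 1]
GL5 <- list(
  x = c(-0.906179845938664, -0.538469310105683, 0,
        0.538469310105683, 0.906179845938664),
  w = c(0.236926885056189, 0.478628670499366, 0.568888888888889,
        0.478628670499366, 0.236926885056189))

# integral of N(center, sigma) density over [a, b]
gl_norm_int <- function(a, b, center, sigma) {
  mid <- (a + b) / 2; half <- (b - a) / 2
  sum(GL5$w * stats::dnorm(mid + half * GL5$x, center, sigma)) * half
}

# mass of one spot (total amplitude over R^3) inside a set of voxels given as
# an (n x 3) matrix of 1-based (z, y, x) voxel indices
oracle_spot_mass <- function(voxels, center_vox, sigma_vox, amplitude) {
  per_axis <- function(i, c, s)
    vapply(i, function(j) gl_norm_int(j - 0.5, j + 0.5, c, s), numeric(1L))
  uz <- sort(unique(voxels[, 1L])); wz <- per_axis(uz, center_vox[1L], sigma_vox[1L])
  uy <- sort(unique(voxels[, 2L])); wy <- per_axis(uy, center_vox[2L], sigma_vox[2L])
  ux <- sort(unique(voxels[, 3L])); wx <- per_axis(ux, center_vox[3L], sigma_vox[3L])
  amplitude * sum(wz[match(voxels[, 1L], uz)] *
                  wy[match(voxels[, 2L], uy)] *
                  wx[match(voxels[, 3L], ux)])
}

# per-axis in-grid fraction by midpoint quadrature of the density (no pnorm)
oracle_axis_fraction <- function(n, center, sigma, n_sub = 2000L) {
  xs <- seq(0.5, n + 0.5, length.out = n_sub + 1L)
  mid <- (xs[-1L] + xs[-length(xs)]) / 2
  sum(stats::dnorm(mid, center, sigma) * diff(xs))
}

# fraction of one spot's mass inside the grid (product over axes)
oracle_in_grid_fraction <- function(dims, center_vox, sigma_vox) {
  prod(vapply(1:3, function(a)
    oracle_axis_fraction(dims[a], center_vox[a], sigma_vox[a]), numeric(1L)))
}

# --- lattice-point counts for disks/rings -----------------------------------
oracle_disk_count <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  sum(g$dy^2 + g$dx^2 <= r^2)
}

# --- tie-corrected Kruskal-Wallis H from first principles -------------------
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  ni <- tapply(rk, g, length)
  h <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# --- helpers for building tiny stacks ---------------------------------------
make_stack <- function(arrs, voxel_size = c(0.2, 0.08, 0.08)) {
  d <- dim(arrs[[1L]])
  data <- array(0, dim = c(length(arrs), d))
  for (i in seq_along(arrs)) data[i, , , ] <- arrs[[i]]
  image_stack(data, names(arrs), voxel_size)
}

# region linear-index decode matching the package convention (z fastest)
decode_zyx <- function(idx, dims) {
  i0 <- idx - 1L
  cbind(z = i0 %% dims[1L] + 1L,
        y = (i0 %/% dims[1L]) %% dims[2L] + 1L,
        x = i0 %/% (dims[1L] * dims[2L]) + 1L)
}

# pair-level detection matching: a pair counts as recalled if any detected
# centroid lies within tol_um of either sister; a detection is a true
# positive if it lies within tol_um of any sister.
match_detections <- function(regions, truth, voxel_size, tol_um = 0.5) {
  if (length(regions) == 0L)
    return(list(recall = 0, precision = NA_real_))
  cent <- t(vapply(regions, function(r) r$centroid, numeric(3L)))
  cent_um <- sweep(cent - 0.5, 2L, voxel_size, "*")
  truth_um <- cbind((truth$z - 0.5) * voxel_size[1L],
                    (truth$y - 0.5) * voxel_size[2L],
                    (truth$x - 0.5) * voxel_size[3L])
  dmat <- outer(seq_len(nrow(cent_um)), seq_len(nrow(truth_um)),
                Vectorize(function(i, j)
                  sqrt(sum((cent_um[i, ] - truth_um[j, ])^2))))
  hit_spot <- apply(dmat, 2L, min) <= tol_um
  pair_hit <- tapply(hit_spot, truth$pair_id, any)
  tp_det <- apply(dmat, 1L, min) <= tol_um
  list(recall = mean(pair_hit), precision = mean(tp_det))
}
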