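# Ground-truthed synthetic immunofluorescence stacks: kinetochore pairs as
# anisotropic-Gaussian spots inside a nuclear ellipsoid, constant background,
# Poisson shot noise plus Gaussian read noise. The generator's job is to
# exercise segmentation and quantification with known truth, not to be an
# optics simulation.

#' Parameters for one synthetic cell stack
#'
#' Defaults mirror the targeted acquisitions: 0.2 um z-steps and 0.08 um xy
#' pixel pitch (so the 4-pixel mask expansion is 0.32 um), and
#' sister-kinetochore pairs at 1.0 um separation inside a DAPI-stained
#' nuclear ellipsoid. Spot widths default to sigma_xy 0.15 um / sigma_z
#' 0.35 um: a point-spread function of ~0.10 um broadened by the ~0.25 um
#' physical extent of the centromeric ACA domain, so that spot footprints
#' clear the 70-voxel minimum object size the segmentation uses.
#'
#' @param grid_dims integer \code{(nz, ny, nx)} voxels.
#' @param voxel_size numeric \code{(dz, dy, dx)} in um.
#' @param n_pairs number of sister-kinetochore pairs.
#' @param channel_amplitudes named numeric: mean total integrated signal
#'   (counts) per spot for each non-DAPI channel; must include \code{"ACA"}.
#' @param amplitude_cv lognormal coefficient of variation of per-spot
#'   amplitudes (biological spot-to-spot variability).
#' @param pair_separation_um distance between sister kinetochores.
#' @param min_pair_distance_um minimum distance between distinct pair
#'   centers, so the ground-truth object count is unambiguous.
#' @param sigma_xy_um,sigma_z_um Gaussian PSF widths.
#' @param background_level counts/voxel added to every channel; scalar or
#'   named per channel.
#' @param dapi_level peak DAPI counts inside the nucleus (above background).
#' @param read_noise_sd additive Gaussian read noise SD (counts).
#' @param shot_noise logical; Poisson noise on background + signal.
#' @param nuclear_center_um,nuclear_semiaxes_um ellipsoid geometry; defaults
#'   center the nucleus and scale semi-axes to 40\% of each physical extent.
#' @param seed integer RNG seed.
#' @return a \code{SimImageParams} list.
#' @export
sim_image_params <- function(grid_dims = c(30L, 128L, 128L),
                             voxel_size = c(0.2, 0.08, 0.08),
                             n_pairs = 20L,
                             channel_amplitudes = c(ACA = 30000, Bod1 = 30000),
                             amplitude_cv = 0.2,
                             pair_separation_um = 1.0,
                             min_pair_distance_um = 1.5,
                             sigma_xy_um = 0.15, sigma_z_um = 0.35,
                             background_level = 50,
                             dapi_level = 500,
                             read_noise_sd = 3,
                             shot_noise = TRUE,
                             nuclear_center_um = NULL,
                             nuclear_semiaxes_um = NULL,
                             seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1L))
    stop("grid_dims must be 3 positive integers (nz, ny, nx)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers")
  if (is.null(names(channel_amplitudes)) || !"ACA" %in% names(channel_amplitudes))
    stop("channel_amplitudes must be named and include 'ACA'")
  if (any(channel_amplitudes < 0)) stop("amplitudes must be >= 0")
  if (sigma_xy_um <= 0 || sigma_z_um <= 0) stop("PSF sigmas must be > 0")
  extent <- grid_dims * voxel_size         # (z, y, x) in um
  if (is.null(nuclear_center_um)) nuclear_center_um <- extent / 2
  if (is.null(nuclear_semiaxes_um)) nuclear_semiaxes_um <- 0.4 * extent
  if (any(nuclear_center_um - nuclear_semiaxes_um < 0) ||
      any(nuclear_center_um + nuclear_semiaxes_um > extent))
    stop("nuclear ellipsoid does not fit inside the grid")
  channels <- c("DAPI", names(channel_amplitudes))
  bg <- background_level
  if (is.null(names(bg))) bg <- stats::setNames(rep(bg[1L], length(channels)),
                                                channels)
  if (any(bg < 0)) stop("background_level must be >= 0")
  p <- list(grid_dims = grid_dims, voxel_size = voxel_size,
            n_pairs = as.integer(n_pairs),
            channel_amplitudes = channel_amplitudes,
            amplitude_cv = amplitude_cv,
            pair_separation_um = pair_separation_um,
            min_pair_distance_um = min_pair_distance_um,
            sigma_xy_um = sigma_xy_um, sigma_z_um = sigma_z_um,
            background_level = bg, dapi_level = dapi_level,
            read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
            nuclear_center_um = nuclear_center_um,
            nuclear_semiaxes_um = nuclear_semiaxes_um,
            channels = channels,
            seed = as.integer(seed))
  class(p) <- "SimImageParams"
  p
}

# Per-axis voxel-integrated Gaussian weights: voxel i (1-based, centred at i)
# spans [i - 0.5, i + 0.5] in voxel units.
.gauss_axis_weights <- function(idx, center, sigma_vox) {
  stats::pnorm((idx + 0.5 - center) / sigma_vox) -
    stats::pnorm((idx - 0.5 - center) / sigma_vox)
}

# Add one spot's voxel-integrated Gaussian mass (total = amplitude over the
# infinite domain) into a (nz, ny, nx) array; truncated at +/- 6 sigma.
.render_spot <- function(arr, center_vox, amplitude, sigma_vox) {
  d <- dim(arr)
  rng <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(1L, floor(center_vox[a] - 6 * sigma_vox[a]))
    hi <- min(d[a], ceiling(center_vox[a] + 6 * sigma_vox[a]))
    if (lo > hi) return(arr)
    rng[[a]] <- lo:hi
  }
  wz <- .gauss_axis_weights(rng[[1L]], center_vox[1L], sigma_vox[1L])
  wy <- .gauss_axis_weights(rng[[2L]], center_vox[2L], sigma_vox[2L])
  wx <- .gauss_axis_weights(rng[[3L]], center_vox[3L], sigma_vox[3L])
  block <- amplitude * outer(outer(wz, wy), wx)
  arr[rng[[1L]], rng[[2L]], rng[[3L]]] <-
    arr[rng[[1L]], rng[[2L]], rng[[3L]]] + block
  arr
}

# Uniform sample inside an ellipsoid (um coordinates), by rejection.
.sample_in_ellipsoid <- function(center, semiaxes, scale = 1) {
  repeat {
    u <- stats::runif(3L, -1, 1)
    if (sum(u^2) <= 1) return(center + scale * semiaxes * u)
  }
}

# Sequential rejection placement; if one pair cannot be placed within the
# per-pair retry budget the whole layout is restarted (still deterministic
# under the seed), and only after repeated whole-layout failures do we error.
.place_pairs <- function(params) {
  ctr <- params$nuclear_center_um
  ax <- params$nuclear_semiaxes_um
  half <- params$pair_separation_um / 2
  inside <- function(p) sum(((p - ctr) / ax)^2) <= 1
  for (attempt in seq_len(25L)) {
    centers <- list()
    spots <- list()
    failed <- FALSE
    for (j in seq_len(params$n_pairs)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        c_um <- .sample_in_ellipsoid(ctr, ax, scale = 0.85)
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u^2))
        a_um <- c_um + half * u
        b_um <- c_um - half * u
        if (!inside(a_um) || !inside(b_um)) next
        ok <- TRUE
        for (cc in centers)
          if (sqrt(sum((c_um - cc)^2)) < params$min_pair_distance_um) {
            ok <- FALSE; break
          }
        if (!ok) next
        centers[[length(centers) + 1L]] <- c_um
        spots[[length(spots) + 1L]] <- list(pair_id = j, center_um = a_um)
        spots[[length(spots) + 1L]] <- list(pair_id = j, center_um = b_um)
        placed <- TRUE
        break
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) return(spots)
  }
  stop("could not place ", params$n_pairs, " pairs",
       ": nuclear region too crowded at min_pair_distance_um = ",
       params$min_pair_distance_um)
}

.apply_noise <- function(noiseless, params) {
  v <- noiseless
  if (params$shot_noise) v[] <- stats::rpois(length(v), lambda = as.vector(v))
  if (params$read_noise_sd > 0)
    v[] <- v + stats::rnorm(length(v), sd = params$read_noise_sd)
  v[v < 0] <- 0
  v
}

#' Simulate one cell's multi-channel z-stack with ground truth
#'
#' Spot channels are rendered as background plus per-voxel-integrated
#' anisotropic 3D Gaussians (the infinite-domain integral of each spot equals
#' its amplitude); the DAPI channel is a smoothed nuclear-ellipsoid indicator
#' used only to exercise ROI cropping. Noise is Poisson shot noise on
#' background + signal followed by additive Gaussian read noise, clamped at
#' zero. Fully reproducible from \code{params$seed}.
#'
#' @param params a \code{SimImageParams}.
#' @return list with \code{stack} (an \code{ImageStack}), \code{truth} (a
#'   data.frame: spot_id, pair_id, continuous 1-based voxel-center
#'   coordinates z/y/x, sigma_xy_um, sigma_z_um, and one \code{amp.<channel>}
#'   column per spot channel) and \code{noiseless} (the noise-free 4-D
#'   array, for oracle checks).
#' @export
simulate_cell_stack <- function(params) {
  stopifnot(inherits(params, "SimImageParams"))
  set.seed(params$seed)
  d <- params$grid_dims
  vs <- params$voxel_size
  spots <- .place_pairs(params)
  n_spots <- length(spots)
  spot_chans <- names(params$channel_amplitudes)
  sdlog <- sqrt(log(1 + params$amplitude_cv^2))
  amp <- matrix(0, nrow = n_spots, ncol = length(spot_chans),
                dimnames = list(NULL, spot_chans))
  for (ch in spot_chans) {
    base <- params$channel_amplitudes[[ch]]
    amp[, ch] <- if (n_spots > 0L)
      base * exp(stats::rnorm(n_spots, -sdlog^2 / 2, sdlog)) else numeric(0)
  }
  sigma_vox <- c(params$sigma_z_um / vs[1L], params$sigma_xy_um / vs[2L],
                 params$sigma_xy_um / vs[3L])
  # um -> continuous 1-based voxel-center coordinates
  to_vox <- function(p_um) p_um / vs + 0.5

  nchan <- length(params$channels)
  noiseless <- array(0, dim = c(nchan, d))
  # DAPI: logistic shoulder of the ellipsoid's normalized radius
  zc <- ((seq_len(d[1L]) - 0.5) * vs[1L] - params$nuclear_center_um[1L]) /
    params$nuclear_semiaxes_um[1L]
  yc <- ((seq_len(d[2L]) - 0.5) * vs[2L] - params$nuclear_center_um[2L]) /
    params$nuclear_semiaxes_um[2L]
  xc <- ((seq_len(d[3L]) - 0.5) * vs[3L] - params$nuclear_center_um[3L]) /
    params$nuclear_semiaxes_um[3L]
  r <- sqrt(outer(outer(zc^2, yc^2, "+"), xc^2, "+"))
  dapi <- params$dapi_level / (1 + exp((r - 1) / 0.05)) +
    params$background_level[["DAPI"]]
  noiseless[match("DAPI", params$channels), , , ] <- dapi

  centers_vox <- if (n_spots > 0L)
    t(vapply(spots, function(s) to_vox(s$center_um), numeric(3L)))
  else matrix(0, 0L, 3L)
  for (ch in spot_chans) {
    arr <- array(params$background_level[[ch]], dim = d)
    for (i in seq_len(n_spots))
      arr <- .render_spot(arr, centers_vox[i, ], amp[i, ch], sigma_vox)
    noiseless[match(ch, params$channels), , , ] <- arr
  }

  data <- noiseless
  for (ci in seq_len(nchan))
    data[ci, , , ] <- .apply_noise(array(noiseless[ci, , , ], dim = d), params)

  truth <- data.frame(
    spot_id = seq_len(n_spots),
    pair_id = vapply(spots, function(s) s$pair_id, integer(1L)),
    z = centers_vox[, 1L], y = centers_vox[, 2L], x = centers_vox[, 3L],
    sigma_xy_um = rep(params$sigma_xy_um, n_spots),
    sigma_z_um = rep(params$sigma_z_um, n_spots))
  for (ch in spot_chans) truth[[paste0("amp.", ch)]] <- amp[, ch]

  list(stack = image_stack(data, params$channels, vs),
       truth = truth, noiseless = noiseless)
}

#' Simulate a control vs depletion experiment
#'
#' Control cells are drawn from \code{ctrl}; depleted cells are drawn from
#' the same parameters except that every measurement-channel amplitude (all
#' spot channels except the ACA reference) is multiplied by
#' \code{1 - depleted_fraction}. Per-cell seeds are derived deterministically
#' from \code{seed}.
#'
#' @param ctrl a \code{SimImageParams} for the control condition.
#' @param depleted_fraction fraction of measurement signal removed, in
#'   \code{[0, 1]} (e.g. 0.65 for a 65\% knockdown).
#' @param n_cells_per_group cells per condition (the published experiments
#'   use 10).
#' @param seed master seed.
#' @return list of cells, each \code{list(cell_id, condition, stack, truth,
#'   noiseless, seed)}; conditions are \code{"control"} and
#'   \code{"depleted"}.
#' @export
simulate_depletion_experiment <- function(ctrl, depleted_fraction,
                                          n_cells_per_group = 10L,
                                          seed = 1L) {
  stopifnot(inherits(ctrl, "SimImageParams"))
  if (depleted_fraction < 0 || depleted_fraction > 1)
    stop("depleted_fraction must be in [0, 1]")
  n_cells_per_group <- as.integer(n_cells_per_group)
  if (n_cells_per_group < 1L) stop("n_cells_per_group must be >= 1")
  depl <- ctrl
  meas <- setdiff(names(ctrl$channel_amplitudes), "ACA")
  depl$channel_amplitudes[meas] <-
    depl$channel_amplitudes[meas] * (1 - depleted_fraction)
  cells <- list()
  k <- 0L
  for (grp in c("control", "depleted")) {
    par0 <- if (grp == "control") ctrl else depl
    for (i in seq_len(n_cells_per_group)) {
      k <- k + 1L
      par <- par0
      par$seed <- as.integer((as.numeric(seed) * 7919 + k * 104729) %%
                               2147483647)
      sim <- simulate_cell_stack(par)
      cells[[k]] <- list(cell_id = sprintf("cell_%03d", k), condition = grp,
                         stack = sim$stack, truth = sim$truth,
                         noiseless = sim$noiseless, seed = par$seed)
    }
  }
  cells
}

#' Write a simulated experiment to disk
#'
#' One TIFF per cell plus a long-format ground-truth CSV and a manifest CSV
#' (the same manifest format \code{\link{cmd_quantify}} consumes).
#'
#' @param cells output of \code{\link{simulate_depletion_experiment}} (or a
#'   list of cells shaped the same way).
#' @param dir output directory (created if needed).
#' @param phase phase label recorded in the manifest (default
#'   \code{"metaphase"}).
#' @return the manifest data.frame, invisibly.
#' @export
write_simulated_experiment <- function(cells, dir, phase = "metaphase") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(cell_id = character(0), path = character(0),
                         condition = character(0), phase = character(0),
                         seed = integer(0))
  truth_rows <- list()
  for (cell in cells) {
    fn <- file.path(dir, paste0(cell$cell_id, ".tif"))
    write_stack(cell$stack, fn)
    manifest <- rbind(manifest, data.frame(
      cell_id = cell$cell_id, path = fn, condition = cell$condition,
      phase = phase, seed = cell$seed))
    tr <- cell$truth
    amp_cols <- grep("^amp\\.", names(tr), value = TRUE)
    vs <- cell$stack$voxel_size
    for (ac in amp_cols) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        cell_id = cell$cell_id, spot_id = tr$spot_id, pair_id = tr$pair_id,
        z = tr$z - 1, y = tr$y - 1, x = tr$x - 1,     # exported 0-based
        z_um = (tr$z - 0.5) * vs[1L], y_um = (tr$y - 0.5) * vs[2L],
        x_um = (tr$x - 0.5) * vs[3L],
        channel = sub("^amp\\.", "", ac), amplitude = tr[[ac]])
    }
  }
  truth <- do.call(rbind, truth_rows)
  write_results_table(truth, file.path(dir, "ground_truth.csv"),
                      schema = "ground_truth")
  write_results_table(manifest, file.path(dir, "manifest.csv"),
                      schema = "manifest")
  invisible(manifest)
}
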