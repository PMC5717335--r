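# helper: one hand-built region in a small grid
fixed_region <- function(dims, core_zyx, expand = 0L, gap = 1L, width = 2L) {
  bounds <- list(z = c(1L, dims[1]), y = c(1L, dims[2]), x = c(1L, dims[3]))
  core <- sort(kinetoquant:::.lin_encode(core_zyx[, 1], core_zyx[, 2],
                                         core_zyx[, 3], dims))
  exp_idx <- expand_mask(core, expand, dims, bounds)
  ann <- build_annulus(exp_idx, exp_idx, gap, width, dims, bounds)
  structure(list(label = 1L, core = core, voxel_count = length(core),
                 centroid = colMeans(core_zyx), expanded = exp_idx,
                 annulus = ann, flagged = FALSE), class = "KinetochoreRegion")
}

test_that("corrected sum is the exact identity raw - bg * n", {
  set.seed(41)
  d <- c(6L, 20L, 20L)
  for (i in 1:5) {
    arr <- array(rexp(prod(d), 1 / 50), dim = d)
    st <- make_stack(list(ACA = arr))
    reg <- fixed_region(d, cbind(3, sample(5:15, 4), sample(5:15, 4)),
                        expand = 2L)
    m <- measure_region(st, reg, "ACA")
    expect_identical(m$corrected_sum,
                     m$raw_sum - m$background_mean * m$n_mask_voxels)
    # offset invariance, exactly
    st2 <- make_stack(list(ACA = arr + 123.456))
    m2 <- measure_region(st2, reg, "ACA")
    expect_equal(m2$corrected_sum, m$corrected_sum, tolerance = 1e-9)
    # linearity, exactly up to round-off
    st3 <- make_stack(list(ACA = arr * 7))
    m3 <- measure_region(st3, reg, "ACA")
    expect_equal(m3$corrected_sum, 7 * m$corrected_sum, tolerance = 1e-9)
  }
})

test_that("uniform fields give zero; simple arithmetic case gives 800", {
  d <- c(5L, 15L, 15L)
  st <- make_stack(list(ACA = array(37.5, dim = d)))
  reg <- fixed_region(d, cbind(3, 7:9, 7:9), expand = 1L)
  expect_equal(measure_region(st, reg, "ACA")$corrected_sum, 0)
  # 10-voxel mask at 100, annulus at 20 -> 1000 - 20*10 = 800
  arr <- array(20, dim = d)
  core <- cbind(3, rep(6:10, 2), rep(7:8, each = 5))
  for (i in seq_len(nrow(core))) arr[core[i, 1], core[i, 2], core[i, 3]] <- 100
  st2 <- make_stack(list(ACA = arr))
  reg2 <- fixed_region(d, core, expand = 0L)
  m <- measure_region(st2, reg2, "ACA")
  expect_identical(m$n_mask_voxels, 10L)
  expect_equal(m$background_mean, 20)
  expect_equal(m$corrected_sum, 800)
})

test_that("noiseless spot measurement matches the quadrature oracle", {
  p <- sim_image_params(grid_dims = c(16, 48, 48), n_pairs = 1, seed = 6,
                        shot_noise = FALSE, read_noise_sd = 0,
                        amplitude_cv = 0, background_level = 40)
  sim <- simulate_cell_stack(p)
  regs <- segment_kinetochores(sim$stack, full_roi(sim$stack), seg_params())
  expect_gte(length(regs), 1L)
  d <- dim(channel_array(sim$stack, "ACA"))
  sig_vox <- c(p$sigma_z_um / p$voxel_size[1], p$sigma_xy_um / p$voxel_size[2],
               p$sigma_xy_um / p$voxel_size[3])
  for (reg in regs) {
    m <- measure_region(sim$stack, reg, "ACA", mask = "expanded")
    mask_zyx <- decode_zyx(reg$expanded, d)
    ann_zyx <- decode_zyx(reg$annulus, d)
    expected <- 0
    for (i in seq_len(nrow(sim$truth))) {
      ctr <- unlist(sim$truth[i, c("z", "y", "x")])
      amp <- sim$truth$amp.ACA[i]
      in_mask <- oracle_spot_mass(mask_zyx, ctr, sig_vox, amp)
      in_ann <- oracle_spot_mass(ann_zyx, ctr, sig_vox, amp)
      expected <- expected + in_mask -
        in_ann / nrow(ann_zyx) * nrow(mask_zyx)
    }
    expect_equal(m$corrected_sum, expected, tolerance = 1e-6)
  }
})

test_that("the estimator is unbiased under the noise model", {
  p <- sim_image_params(grid_dims = c(16, 48, 48), n_pairs = 1, seed = 6,
                        shot_noise = FALSE, read_noise_sd = 0,
                        amplitude_cv = 0, background_level = 40)
  sim <- simulate_cell_stack(p)
  regs <- segment_kinetochores(sim$stack, full_roi(sim$stack), seg_params())
  reg <- regs[[1]]
  noiseless_val <- measure_region(sim$stack, reg, "ACA")$corrected_sum
  d <- dim(channel_array(sim$stack, "ACA"))
  base <- channel_array(sim$stack, "ACA")
  set.seed(99)
  reps <- replicate(100, {
    noisy <- array(rpois(length(base), as.vector(base)) +
                     rnorm(length(base), 0, 3), dim = d)
    noisy[noisy < 0] <- 0
    measure_region(make_stack(list(ACA = noisy)), reg, "ACA")$corrected_sum
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - noiseless_val), 2 * se + 1e-9)
})

test_that("line profiles interpolate exactly and resolve a spot pair", {
  d <- c(7L, 30L, 30L)
  arr <- array(13, dim = d)
  st <- make_stack(list(ACA = arr))
  pr <- line_profile(st, c(2, 3, 3), c(6, 25, 20), n_samples = 17)
  expect_true(all(pr$ACA == 13))
  expect_equal(pr$distance_um[1], 0)
  # voxel-center identity
  set.seed(44)
  arr2 <- array(runif(prod(d)) * 100, dim = d)
  st2 <- make_stack(list(ACA = arr2))
  pr2 <- line_profile(st2, c(4, 5, 8), c(4, 5, 20), n_samples = 13)
  expect_equal(pr2$ACA, arr2[4, 5, 8:20], tolerance = 1e-12)
  # a synthetic sister pair gives two maxima at the centers
  blob <- function(a, c0) {
    for (y in 1:d[2]) for (x in 1:d[3])
      a[c0[1], y, x] <- a[c0[1], y, x] +
        200 * exp(-((y - c0[2])^2 + (x - c0[3])^2) / (2 * 2^2))
    a
  }
  arr3 <- blob(blob(array(5, d), c(4, 15, 10)), c(4, 15, 22))
  st3 <- make_stack(list(ACA = arr3))
  pr3 <- line_profile(st3, c(4, 15, 6), c(4, 15, 26), n_samples = 41)
  v <- pr3$ACA
  locmax <- which(diff(sign(diff(v))) == -2) + 1
  x_at <- 6 + (pr3$sample[locmax] - 1) / 40 * 20
  expect_length(locmax, 2L)
  spacing <- 20 / 40
  expect_lt(abs(x_at[1] - 10), 1 + spacing)
  expect_lt(abs(x_at[2] - 22), 1 + spacing)
  # normalization puts each channel on [0, 1]
  pn <- line_profile(st3, c(4, 15, 6), c(4, 15, 26), n_samples = 21,
                     normalize = TRUE)
  expect_equal(range(pn$ACA), c(0, 1))
  expect_error(line_profile(st3, c(0, 1, 1), c(4, 15, 26)), "inside the grid")
})

test_that("per-cell summaries aggregate as documented", {
  meas <- data.frame(label = 1:2, channel = "ACA",
                     corrected_sum = c(100, 300), flagged = FALSE)
  s <- summarize_cell(meas, cell_id = "c1", condition = "control",
                      phase = "metaphase")
  expect_equal(s$summary, 200)
  expect_identical(s$n_regions, 2L)
  expect_equal(summarize_cell(meas, method = "median")$summary, 200)
  one <- summarize_cell(meas[1, ], cell_id = "c1")
  expect_equal(one$summary, 100)
  # median robustness to a planted 100x outlier
  vals <- c(90, 95, 100, 105, 110)
  meas2 <- data.frame(label = 1:5, channel = "ACA", corrected_sum = vals,
                      flagged = FALSE)
  meas3 <- meas2; meas3$corrected_sum[5] <- vals[5] * 100
  med_shift <- abs(summarize_cell(meas3, method = "median")$summary /
                     summarize_cell(meas2, method = "median")$summary - 1)
  mean_shift <- abs(summarize_cell(meas3, method = "mean")$summary /
                      summarize_cell(meas2, method = "mean")$summary - 1)
  expect_lt(med_shift, 0.05)
  expect_gt(mean_shift, 1)
  # flagged regions are excluded; all-flagged cells are dropped with warning
  meas4 <- meas; meas4$flagged <- TRUE
  expect_warning(out <- summarize_cell(meas4, cell_id = "cX"), "no valid")
  expect_identical(nrow(out), 0L)
  expect_error(summarize_cell(meas, phase = "mitosis"), "arg")
})

test_that("normalization to the reference condition behaves", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:6),
    condition = rep(c("control", "treated"), each = 3),
    phase = "metaphase", channel = "Bod1",
    summary = c(200, 200, 200, 60, 70, 50), n_regions = 10)
  out <- normalize_to_reference(cells, "control")
  expect_equal(out$normalized[1:3], rep(1, 3))
  expect_equal(out$normalized[4], 0.3)
  expect_error(normalize_to_reference(cells, "missing"), "no cells")
  bad <- cells; bad$summary[1:3] <- 0
  expect_error(normalize_to_reference(bad, "control"), "not positive")
})
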