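small_params <- function(...) {
  do.call(sim_image_params,
          utils::modifyList(list(grid_dims = c(16, 48, 48), n_pairs = 2L,
                                 seed = 42L), list(...)))
}

test_that("defaults encode the acquisition geometry", {
  p <- sim_image_params()
  expect_equal(p$voxel_size, c(0.2, 0.08, 0.08))
  # 4 px at the xy pitch is the 0.32 um outer-kinetochore expansion
  expect_equal(4 * p$voxel_size[2], 0.32)
  expect_equal(seg_params()$expand_radius_px, 4L)
})

test_that("no-signal, noiseless stack is exactly the stated background", {
  p <- small_params(n_pairs = 0, shot_noise = FALSE, read_noise_sd = 0,
                    background_level = 50)
  sim <- simulate_cell_stack(p)
  aca <- channel_array(sim$stack, "ACA")
  expect_true(all(aca == 50))
  expect_identical(nrow(sim$truth), 0L)
})

test_that("noiseless spot mass matches amplitude minus truncation (oracle)", {
  p <- sim_image_params(grid_dims = c(16, 48, 48), n_pairs = 1, seed = 5,
                        shot_noise = FALSE, read_noise_sd = 0,
                        amplitude_cv = 0, background_level = 10)
  sim <- simulate_cell_stack(p)
  aca <- channel_array(sim$stack, "ACA")
  sig_vox <- c(p$sigma_z_um / p$voxel_size[1], p$sigma_xy_um / p$voxel_size[2],
               p$sigma_xy_um / p$voxel_size[3])
  expected <- 0
  for (i in seq_len(nrow(sim$truth))) {
    ctr <- unlist(sim$truth[i, c("z", "y", "x")])
    expected <- expected + sim$truth[[paste0("amp.", "ACA")]][i] *
      oracle_in_grid_fraction(dim(aca), ctr, sig_vox)
  }
  expect_equal(sum(aca - 10), expected, tolerance = 1e-6)
})

test_that("same seed gives bit-identical output, different seed differs", {
  a <- simulate_cell_stack(small_params())
  b <- simulate_cell_stack(small_params())
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_cell_stack(small_params(seed = 43))
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("shot noise is Poisson-calibrated on a constant background", {
  p <- sim_image_params(grid_dims = c(12, 128, 128), n_pairs = 0,
                        background_level = 80, read_noise_sd = 0,
                        shot_noise = TRUE, seed = 9)
  aca <- channel_array(simulate_cell_stack(p)$stack, "ACA")
  n <- length(aca)                     # 196608 >= 1e5 voxels
  expect_gte(n, 1e5)
  # var/mean ~ 1 with SE ~ sqrt(2/n); clamping at 0 is negligible at 80
  expect_lt(abs(var(as.vector(aca)) / mean(aca) - 1), 4 * sqrt(2 / n))
})

test_that("spot placement respects pair geometry or fails loudly", {
  p <- small_params(n_pairs = 3, seed = 2)
  sim <- simulate_cell_stack(p)
  tr <- sim$truth
  vs <- p$voxel_size
  um <- cbind((tr$z - 0.5) * vs[1], (tr$y - 0.5) * vs[2], (tr$x - 0.5) * vs[3])
  for (pid in unique(tr$pair_id)) {
    pr <- um[tr$pair_id == pid, ]
    expect_equal(sqrt(sum((pr[1, ] - pr[2, ])^2)), p$pair_separation_um,
                 tolerance = 1e-9)
  }
  centers <- do.call(rbind, lapply(unique(tr$pair_id), function(pid)
    colMeans(um[tr$pair_id == pid, ])))
  if (nrow(centers) > 1) {
    dd <- as.matrix(dist(centers))
    expect_gte(min(dd[upper.tri(dd)]), p$min_pair_distance_um)
  }
  # an impossible packing errors
  expect_error(simulate_cell_stack(
    sim_image_params(grid_dims = c(10, 24, 24), n_pairs = 50, seed = 1)),
    "too crowded")
})

test_that("depletion experiment scales only the measurement channels", {
  ctrl <- small_params(amplitude_cv = 0)
  cells <- simulate_depletion_experiment(ctrl, depleted_fraction = 1,
                                         n_cells_per_group = 1, seed = 3)
  expect_identical(vapply(cells, `[[`, "", "condition"),
                   c("control", "depleted"))
  depl <- cells[[2]]
  # full ablation: measurement channel truth amplitude is 0, ACA untouched
  expect_true(all(depl$truth$amp.Bod1 == 0))
  expect_true(all(depl$truth$amp.ACA > 0))
  bod1 <- depl$noiseless[match("Bod1", depl$stack$channel_names), , , ]
  expect_true(all(bod1 == ctrl$background_level[["Bod1"]]))

  # null case: both groups drawn from the same parameters
  cells0 <- simulate_depletion_experiment(ctrl, depleted_fraction = 0,
                                          n_cells_per_group = 2, seed = 3)
  amp_by_grp <- tapply(
    unlist(lapply(cells0, function(cc) cc$truth$amp.Bod1)),
    rep(vapply(cells0, `[[`, "", "condition"),
        vapply(cells0, function(cc) nrow(cc$truth), 0L)), mean)
  expect_equal(unname(amp_by_grp["control"]), unname(amp_by_grp["depleted"]),
               tolerance = 0.05)
  expect_error(simulate_depletion_experiment(ctrl, 0.5, 0), ">= 1")
  expect_error(simulate_depletion_experiment(ctrl, 1.2, 2), "\\[0, 1\\]")
})

test_that("simulated experiments round-trip through disk", {
  cells <- simulate_depletion_experiment(small_params(), 0.5,
                                         n_cells_per_group = 1, seed = 8)
  dir <- withr::local_tempdir()
  manifest <- write_simulated_experiment(cells, dir)
  expect_identical(nrow(manifest), 2L)
  st <- read_stack(manifest$path[1])
  expect_identical(st$data, cells[[1]]$stack$data)
  truth <- read_results_table(file.path(dir, "ground_truth.csv"),
                              schema = "ground_truth")
  expect_identical(nrow(truth),
                   sum(vapply(cells, function(cc) nrow(cc$truth), 0L)) * 2L)
  expect_true(all(truth$channel %in% c("ACA", "Bod1")))
})

# ---- LFQ generator ---------------------------------------------------------

test_that("null noiseless LFQ table has identical groups; defaults match", {
  p <- sim_lfq_params(n_proteins = 50, enriched_ids = character(0),
                      replicate_noise_sd_log2 = 0, missing_rate = 0, seed = 1)
  expect_identical(p$n_replicates_per_group, 4L)   # n = 4 biological replicates
  tab <- simulate_lfq_table(p)
  # no noise, no enrichment: every replicate equals the per-protein baseline
  for (r in 1:4)
    expect_equal(tab[[paste0("intensity.bait.", r)]],
                 tab[[paste0("intensity.control.", r)]], tolerance = 1e-12)
})

test_that("missingness count falls inside binomial 99% bounds", {
  p <- sim_lfq_params(n_proteins = 1000, enriched_ids = character(0),
                      missing_rate = 0.2, seed = 21)
  tab <- simulate_lfq_table(p)
  n_missing <- sum(is.na(as.matrix(
    tab[, grep("^intensity\\.", names(tab))])))
  n_slots <- 1000 * 8
  bounds <- qbinom(c(0.005, 0.995), n_slots, 0.2)
  expect_gte(n_missing, bounds[1])
  expect_lte(n_missing, bounds[2])
})

test_that("enrichment is planted on the log2 scale and reproducible", {
  p <- sim_lfq_params(n_proteins = 400, enriched_ids = 40,
                      enrichment_log2fc = 2, replicate_noise_sd_log2 = 0,
                      missing_rate = 0, seed = 5)
  tab <- simulate_lfq_table(p)
  enr <- tab$is_enriched
  fc <- log2(tab$intensity.bait.1) - log2(tab$intensity.control.1)
  expect_equal(fc[enr], rep(2, 40), tolerance = 1e-9)
  expect_equal(fc[!enr], rep(0, 360), tolerance = 1e-9)
  expect_identical(simulate_lfq_table(p), tab)
  expect_error(sim_lfq_params(missing_rate = 1), "missing_rate")
  expect_error(sim_lfq_params(n_replicates_per_group = 1), ">= 2")
})

test_that("LFQ tables round-trip through TSV with explicit missing values", {
  p <- sim_lfq_params(n_proteins = 30, missing_rate = 0.3, seed = 2)
  tab <- simulate_lfq_table(p)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lfq_table(tab, path)
  back <- read_lfq_table(path)
  int_cols <- grep("^intensity\\.", names(tab), value = TRUE)
  for (cc in int_cols)
    expect_equal(back[[cc]], tab[[cc]], tolerance = 1e-9)
  expect_identical(back$protein_id, tab$protein_id)
  # missing is NA, never zero
  expect_false(any(back$intensity.bait.1 == 0, na.rm = TRUE))
})
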