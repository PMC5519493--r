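test_that("correlation matrix agrees with the two-pass Pearson oracle", {
  data <- with_seed(11, matrix(rnorm(50 * 100), 50, 100))
  cm <- corr_matrix(manual_session(data))
  expect_false(any(cm$mask))
  expect_equal(max(abs(cm$r - t(cm$r))), 0)
  worst <- 0
  for (i in 1:50) {
    for (j in i:50) {
      worst <- max(worst, abs(cm$r[i, j] -
                                pearson_oracle(data[i, ], data[j, ])))
    }
  }
  expect_lt(worst, 1e-10)
  expect_true(all(diag(cm$r) == 1))
})

test_that("identical and sign-flipped series give r of 1 and -1", {
  x <- rnorm(80)
  cm <- corr_matrix(manual_session(rbind(x, x, -x)))
  expect_equal(cm$r[1, 2], 1)
  expect_equal(cm$r[1, 3], -1)
})

test_that("zero-variance vertices are masked, not propagated", {
  data <- rbind(rnorm(50), rep(2, 50), rnorm(50))
  cm <- corr_matrix(manual_session(data))
  expect_equal(cm$mask, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(cm$r[2, ])))
  expect_false(is.na(cm$r[1, 3]))
})

test_that("fisher transform matches the closed form and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(1.9 / 0.1), tolerance = 1e-6)
  expect_equal(fisher_z(0.9), 1.47222, tolerance = 1e-5)
  r <- seq(-0.99, 0.99, by = 0.11)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.2), "outside")
})

test_that("mean z matrix averages runs and is invariant to run order", {
  runs <- lapply(1:3, function(i)
    manual_session(matrix(rnorm(10 * 60), 10, 60), run_id = i))
  m123 <- mean_z_matrix(runs)
  m321 <- mean_z_matrix(rev(runs))
  expect_identical(m123$z, m321$z)
  expect_equal(m123$n_runs_averaged, 3)
  # identical runs: mean equals the single-run matrix
  same <- mean_z_matrix(list(runs[[1]], runs[[1]]))
  single <- mean_z_matrix(runs[1])
  expect_equal(same$z, single$z, tolerance = 1e-12)
  # two runs: elementwise arithmetic mean (spot check off-diagonal)
  two <- mean_z_matrix(runs[1:2])
  z1 <- fisher_z(corr_matrix(runs[[1]])$r[1, 2])
  z2 <- fisher_z(corr_matrix(runs[[2]])$r[1, 2])
  expect_equal(two$z[1, 2], (z1 + z2) / 2, tolerance = 1e-12)
  # diagonal sentinel
  expect_true(all(diag(m123$z) == atanh(1 - 1e-7)))
  expect_error(mean_z_matrix(list(runs[[1]],
                                  manual_session(matrix(0, 3, 60)))),
               "mismatch")
})

test_that("seed maps are row extractions with the display convention", {
  runs <- lapply(1:2, function(i)
    manual_session(matrix(rnorm(8 * 50), 8, 50), run_id = i))
  z <- mean_z_matrix(runs)
  m <- seed_map(z, 5)
  expect_identical(m$values, z$z[5, ])
  expect_equal(m$values[5], atanh(1 - 1e-7))
  expect_equal(m$display_range, c(0.2, 0.6))
  expect_error(seed_map(z, 9), "out of range")
})

test_that("test-retest is 1 for identical matrices and near 0 under the null", {
  runs <- lapply(1:2, function(i)
    manual_session(matrix(rnorm(20 * 50), 20, 50), run_id = i))
  z <- mean_z_matrix(runs)
  expect_equal(test_retest(z, z), 1)
  za <- manual_zconn(with_seed(1, {
    m <- matrix(rnorm(300^2, sd = 0.1), 300, 300); (m + t(m)) / 2
  }))
  zb <- manual_zconn(with_seed(2, {
    m <- matrix(rnorm(300^2, sd = 0.1), 300, 300); (m + t(m)) / 2
  }))
  expect_lt(abs(test_retest(za, zb)), 0.05)
})

test_that("discovery and replication halves of a planted study are consistent", {
  p <- tiny_params(n_sessions = 24, frames_per_run = 300,
                   vertex_noise_sd = 1.0)
  study <- preprocess_study(simulate_study(p),
                            preproc_params(n_discard = 4))
  zd <- mean_z_matrix(study_sessions(study, 1, "discovery"), "discovery")
  zr <- mean_z_matrix(study_sessions(study, 1, "replication"), "replication")
  expect_gt(test_retest(zd, zr), 0.85)
})

test_that("reliability is 1 for identical maps and low for pure noise", {
  mesh <- tiny_mesh()
  nv <- mesh$n_vertices
  mk_map <- function(values) structure(
    list(seed_vertex = 1L, values = values, dataset_label = "full",
         display_range = c(0.2, 0.6)), class = "fc_map")
  base <- with_seed(4, rnorm(nv))
  rel <- reliability_map(lapply(1:4, function(i) mk_map(base)), mesh)
  expect_true(all(rel$values >= 1 - 1e-10))
  noise_maps <- lapply(1:4, function(i)
    mk_map(with_seed(i, rnorm(nv))))
  rel_noise <- reliability_map(noise_maps, mesh)
  expect_lt(mean(rel_noise$values), 0.1)
  expect_true(all(rel_noise$values >= 0 & rel_noise$values <= 1))
  expect_error(reliability_map(noise_maps[1:2], mesh), ">= 3")
})

test_that("dropout lowers reliability and disattenuation restores the seed map", {
  tpl <- tiny_template()
  mesh <- tiny_mesh()
  seedv <- which(tpl$assignment == 1)[1]
  run_maps <- function(p) {
    lapply(1:6, function(i) {
      sess <- simulate_session(tpl, p, seed = 500 + i, run_id = i)
      z <- mean_z_matrix(list(sess))
      seed_map(z, seedv)
    })
  }
  p_clean <- tiny_params(frames_per_run = 200, global_signal_sd = 0)
  p_drop <- tiny_params(frames_per_run = 200, global_signal_sd = 0,
                        dropout_zone = 3, dropout_attenuation = 0.3)
  maps_clean <- run_maps(p_clean)
  maps_drop <- run_maps(p_drop)
  rel_drop <- reliability_map(maps_drop, mesh)
  dz_net <- intersect(tpl$zones$members[[3]], which(tpl$assignment == 1))
  other_net <- setdiff(which(tpl$assignment == 1),
                       unlist(tpl$zones$members[c(1, 3)]))
  expect_lt(mean(rel_drop$values[dz_net]), mean(rel_drop$values[other_net]))

  mean_map <- function(maps) Reduce(`+`, lapply(maps, `[[`, "values")) /
    length(maps)
  z_no_drop <- mean_map(maps_clean)
  z_drop <- mean_map(maps_drop)
  map_obj <- maps_drop[[1]]
  map_obj$values <- z_drop
  z_corr <- disattenuate(map_obj, rel_drop)$values
  improved <- abs(z_corr[dz_net] - z_no_drop[dz_net]) <
    abs(z_drop[dz_net] - z_no_drop[dz_net])
  expect_gte(mean(improved), 0.8)
})

test_that("disattenuation scales by inverse square-root reliability with a floor", {
  map <- structure(list(seed_vertex = 1L, values = c(0.4, 0.4, 0.4),
                        dataset_label = "full",
                        display_range = c(0.2, 0.6)), class = "fc_map")
  rel <- structure(list(values = c(1, 0.25, 0.01), n_runs = 4),
                   class = "reliability_map")
  out <- disattenuate(map, rel, floor = 0.04)
  expect_equal(out$values, c(0.4, 0.8, 0.4 / 0.2), tolerance = 1e-12)
})
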