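test_that("noise-free limit reproduces the latent time course exactly", {
  tpl <- tiny_template()
  p <- tiny_params(vertex_noise_sd = 0, global_signal_sd = 0,
                   network_loading = 1.5, baseline_mean = 0)
  sess <- simulate_session(tpl, p, seed = 3)
  s1 <- which(tpl$assignment == 1)
  # every vertex of a network carries loading * s_k(t): all rows equal
  ref <- sess$data[s1[1], ]
  for (v in s1[-1]) expect_equal(sess$data[v, ], ref, tolerance = 1e-12)
  expect_equal(stats::sd(ref) / 1.5, 1, tolerance = 1e-10)
  # background vertices are exactly zero
  bg <- which(tpl$assignment == 0)
  expect_true(all(sess$data[bg, ] == 0))
})

test_that("same-network correlation matches the shared-signal closed form", {
  # r = loading^2 / (loading^2 + sigma^2) = 0.5 at loading 1, sigma 1
  tpl <- tiny_template()
  p <- tiny_params(frames_per_run = 1000, global_signal_sd = 0)
  s1 <- which(tpl$assignment == 1)
  rs <- c()
  for (seed in 1:4) {
    sess <- simulate_session(tpl, p, seed = seed)
    prs <- with_seed(seed + 100,
      t(replicate(50, sample(s1, 2))))
    rs <- c(rs, mapply(function(a, b) cor(sess$data[a, ], sess$data[b, ]),
                       prs[, 1], prs[, 2]))
  }
  expect_equal(mean(rs), 0.5, tolerance = 0.03)
})

test_that("different-network vertices are uncorrelated on average", {
  tpl <- tiny_template()
  p <- tiny_params(frames_per_run = 1000, global_signal_sd = 0)
  s1 <- which(tpl$assignment == 1)
  s2 <- which(tpl$assignment == 2)
  rs <- c()
  for (seed in 1:4) {
    sess <- simulate_session(tpl, p, seed = seed)
    a <- with_seed(seed + 200, sample(s1, 50, replace = TRUE))
    b <- with_seed(seed + 300, sample(s2, 50, replace = TRUE))
    rs <- c(rs, mapply(function(x, y) cor(sess$data[x, ], sess$data[y, ]),
                       a, b))
  }
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("same-network correlation exceeds different-network at every SNR", {
  tpl <- tiny_template()
  s1 <- which(tpl$assignment == 1)
  s2 <- which(tpl$assignment == 2)
  for (loading in c(0.25, 0.5, 1.0)) {
    p <- tiny_params(frames_per_run = 500, network_loading = loading,
                     global_signal_sd = 0)
    sess <- simulate_session(tpl, p, seed = 7)
    within <- with_seed(1, t(replicate(100, sample(s1, 2))))
    between <- cbind(with_seed(2, sample(s1, 100, TRUE)),
                     with_seed(3, sample(s2, 100, TRUE)))
    r_within <- mean(mapply(function(a, b) cor(sess$data[a, ], sess$data[b, ]),
                            within[, 1], within[, 2]))
    r_between <- mean(mapply(function(a, b) cor(sess$data[a, ], sess$data[b, ]),
                             between[, 1], between[, 2]))
    expect_gt(r_within, r_between)
  }
})

test_that("latent time courses are band-limited below the cutoff", {
  x <- with_seed(5, interdigitate:::band_limited_noise(1000, 0.08, 1))
  amp <- abs(stats::fft(x))[2:500]
  freq <- (1:499) / 1000
  expect_lt(sum(amp[freq > 0.08]) / sum(amp), 0.01)
  expect_equal(stats::sd(x), 1, tolerance = 1e-12)
})

test_that("generator is a pure function of params and seed", {
  p <- tiny_params(n_subjects = 2, n_sessions = 4, frames_per_run = 100)
  a <- simulate_study(p)
  b <- simulate_study(p)
  expect_identical(a$subjects[[2]]$sessions[[3]]$data,
                   b$subjects[[2]]$sessions[[3]]$data)
  expect_identical(a$subjects[[1]]$template$assignment,
                   b$subjects[[1]]$template$assignment)
})

test_that("study structure: sessions, split labels, shared template without jitter", {
  p <- tiny_params(n_subjects = 2, n_sessions = 6, frames_per_run = 100,
                   jitter_steps = 0)
  study <- simulate_study(p)
  expect_length(study$subjects, 2)
  expect_length(study$subjects[[1]]$sessions, 6)
  labels <- vapply(study$subjects[[1]]$sessions, `[[`, character(1),
                   "dataset_label")
  expect_equal(labels, rep(c("discovery", "replication"), 3))
  expect_identical(study$subjects[[1]]$template$assignment,
                   study$subjects[[2]]$template$assignment)
  # nuisance table holds the global signal and motion regressors
  nuis <- study$subjects[[1]]$sessions[[1]]$nuisance
  expect_named(nuis, c("global", paste0("motion", 1:6)))
})

test_that("dropout attenuates signal but not noise", {
  tpl <- tiny_template()
  p0 <- tiny_params(frames_per_run = 400, global_signal_sd = 0,
                    vertex_noise_sd = 0)
  pd <- tiny_params(frames_per_run = 400, global_signal_sd = 0,
                    vertex_noise_sd = 0, dropout_zone = 2,
                    dropout_attenuation = 0.3)
  s0 <- simulate_session(tpl, p0, seed = 9)
  sd_ <- simulate_session(tpl, pd, seed = 9)
  dz <- tpl$zones$members[[2]]
  in_dz <- intersect(which(tpl$assignment == 1), dz)
  out_dz <- setdiff(which(tpl$assignment == 1), dz)
  expect_equal(sd_$data[in_dz, ], 0.3 * s0$data[in_dz, ] + 0.7 * 100,
               tolerance = 1e-10)
  expect_identical(sd_$data[out_dz, ], s0$data[out_dz, ])
})

test_that("too-short runs are refused for spectral analyses", {
  tpl <- tiny_template()
  p <- tiny_params(frames_per_run = 50)
  expect_error(simulate_session(tpl, p, seed = 1), "insufficient")
})
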