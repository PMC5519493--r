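test_that("initial-frame discard truncates data and nuisance identically", {
  data <- matrix(rnorm(5 * 422), 5, 422)
  nuis <- data.frame(g = rnorm(422))
  sess <- manual_session(data, nuisance = nuis)
  out <- discard_initial(sess, 12)
  expect_equal(ncol(out$data), 410)
  expect_equal(nrow(out$nuisance), 410)
  expect_identical(out$data, data[, 13:422])
  expect_identical(discard_initial(sess, 0), sess)
  expect_error(discard_initial(sess, 422), "no frames")
})

test_that("low-pass filter preserves DC, passes 0.05 Hz, stops 0.20 Hz", {
  t <- 0:1023
  const <- manual_session(matrix(7, 1, 1024))
  expect_equal(lowpass_filter(const)$data[1, ], rep(7, 1024),
               tolerance = 1e-8)

  for (freq in c(0.05, 0.20)) {
    x <- sin(2 * pi * freq * t)
    out <- lowpass_filter(manual_session(rbind(x)))$data[1, ]
    amp_ratio <- max(abs(stats::fft(out))) / max(abs(stats::fft(x)))
    if (freq == 0.05) expect_gt(amp_ratio, 0.98)
    else expect_lt(amp_ratio, 0.02)
  }
  # mean preserved to high relative accuracy
  y <- 100 + rnorm(512)
  outm <- lowpass_filter(manual_session(rbind(y)))$data[1, ]
  expect_equal(mean(outm), mean(y), tolerance = 1e-8 * abs(mean(y)))
  expect_error(lowpass_filter(manual_session(rbind(y)), cutoff_hz = 0.6),
               "Nyquist")
})

test_that("vectorized zero-phase filtering equals the per-series reference", {
  bf <- interdigitate:::.butter_lowpass(0.08, 1)
  X <- matrix(rnorm(200 * 20), 200, 20)
  fast <- interdigitate:::.filtfilt_cols(bf, X)
  ref <- apply(X, 2, function(x) signal::filtfilt(bf, x))
  expect_lt(max(abs(fast - ref)), 1e-10)
})

test_that("nuisance regression leaves residuals orthogonal to regressors", {
  set.seed(42)
  nuis <- data.frame(matrix(rnorm(200 * 9), 200, 9))
  names(nuis) <- c(paste0("mot", 1:6), "wb", "vent", "wm")
  data <- matrix(rnorm(30 * 200), 30, 200)
  sess <- manual_session(data, nuisance = nuis)
  out <- regress_nuisance(sess, add_derivatives = TRUE)
  X <- interdigitate:::.nuisance_design(nuis, TRUE)
  expect_equal(ncol(X), 19)  # intercept + 9 + 9 derivatives
  cors <- abs(crossprod(X[, -1], t(out$data)))
  expect_lt(max(cors) / 200, 1e-8)
  # a series equal to a regressor is annihilated
  sess2 <- manual_session(rbind(nuis$wb), nuisance = nuis)
  out2 <- regress_nuisance(sess2, add_derivatives = FALSE)
  expect_lt(max(abs(out2$data)), 1e-8)
})

test_that("empty nuisance table means intercept-only regression", {
  data <- matrix(rnorm(5 * 100), 5, 100)
  sess <- manual_session(data)
  out <- regress_nuisance(sess, add_derivatives = FALSE)
  expect_equal(out$data, data - rowMeans(data), tolerance = 1e-12)
})

test_that("collinear nuisance columns are reported by name", {
  g <- rnorm(100)
  nuis <- data.frame(g = g, g2 = 2 * g)
  sess <- manual_session(matrix(rnorm(300), 3, 100), nuisance = nuis)
  expect_error(regress_nuisance(sess, add_derivatives = FALSE),
               "collinear columns: g")
})

test_that("surface smoothing preserves sums, keeps impulse peak, stays within hemisphere", {
  mesh <- tiny_mesh()
  const <- rep(3.5, mesh$n_vertices)
  expect_equal(smooth_surface(const, mesh, fwhm_mm = 2, mesh_edge_mm = 1),
               const, tolerance = 1e-10)
  impulse <- numeric(mesh$n_vertices)
  impulse[10] <- 1
  sm <- smooth_surface(impulse, mesh, fwhm_mm = 3, mesh_edge_mm = 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(which.max(sm), 10)
  left <- mesh$hemisphere == "L"
  expect_true(all(sm[!left] == 0))
  # white-noise variance strictly decreases
  noise <- with_seed(1, rnorm(mesh$n_vertices))
  expect_lt(var(smooth_surface(noise, mesh, 2, mesh_edge_mm = 1)),
            var(noise))
  # fwhm 0 is the identity; negative fwhm errors
  expect_identical(smooth_surface(noise, mesh, 0), noise)
  expect_error(smooth_surface(noise, mesh, -1), ">= 0")
})

test_that("sub-resolution kernels leave the data untouched", {
  mesh <- tiny_mesh()   # level 2: fsaverage6-equivalent edge 16 mm
  x <- rnorm(mesh$n_vertices)
  expect_identical(smooth_surface(x, mesh, fwhm_mm = 2), x)
})

test_that("a signal built from nuisance columns is removed by the pipeline", {
  set.seed(3)
  tfr <- 200
  nuis <- data.frame(g = rnorm(tfr), m = rnorm(tfr))
  beta <- matrix(rnorm(10 * 2), 10, 2)
  data <- beta %*% t(as.matrix(nuis)) + 50
  sess <- manual_session(data, nuisance = nuis)
  out <- regress_nuisance(lowpass_filter(sess), add_derivatives = FALSE)
  rms_in <- sqrt(mean((data - rowMeans(data))^2))
  expect_lt(sqrt(mean(out$data^2)), 1e-6 * rms_in)
})

test_that("temporal operations act on each vertex independently", {
  base <- matrix(rnorm(8 * 128), 8, 128)
  pert <- base
  pert[3, ] <- pert[3, ] + 5 * sin(2 * pi * 0.03 * seq_len(128))
  f_base <- lowpass_filter(manual_session(base))$data
  f_pert <- lowpass_filter(manual_session(pert))$data
  expect_identical(f_base[-3, ], f_pert[-3, ])
})
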