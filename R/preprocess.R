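#' Preprocessing parameters
#'
#' @param n_discard Initial frames to discard (T1-equilibration
#'   convention; default 12).
#' @param lowpass_hz Temporal low-pass cutoff in Hz (default 0.08).
#' @param add_derivatives Augment nuisance regressors with their
#'   backward-difference temporal derivatives (default TRUE).
#' @param smooth_fwhm_mm Surface smoothing kernel FWHM in mm
#'   (default 2).
#' @param mesh_edge_mm Nominal mesh edge length in mm used to convert
#'   FWHM to geodesic hops. `NULL` (default) means the
#'   fsaverage6-equivalent spacing scaled to the mesh in use,
#'   `2^(6 - level)` mm, under which a 2 mm kernel is sub-resolution
#'   (identity) on meshes coarser than level 5.
#' @return A validated `preproc_params` list.
#' @export
preproc_params <- function(n_discard = 12, lowpass_hz = 0.08,
                           add_derivatives = TRUE, smooth_fwhm_mm = 2,
                           mesh_edge_mm = NULL) {
  stopifnot(n_discard >= 0, lowpass_hz > 0, smooth_fwhm_mm >= 0,
            is.null(mesh_edge_mm) || mesh_edge_mm > 0)
  structure(as.list(environment()), class = "preproc_params")
}

#' Discard initial frames of a session
#'
#' Drops the first `n_discard` frames from the data and, identically,
#' from the nuisance table (scanner signal has not reached T1
#' equilibrium during the first frames of a run).
#'
#' @param ts A `session_ts`.
#' @param n_discard Number of leading frames to drop; must be smaller
#'   than the frame count.
#' @return The truncated `session_ts`.
#' @export
discard_initial <- function(ts, n_discard) {
  tfr <- ncol(ts$data)
  if (n_discard >= tfr) {
    stop("n_discard = ", n_discard, " leaves no frames (run has ",
         tfr, ")", call. = FALSE)
  }
  if (n_discard == 0) return(ts)
  keep <- (n_discard + 1):tfr
  ts$data <- ts$data[, keep, drop = FALSE]
  ts$nuisance <- ts$nuisance[keep, , drop = FALSE]
  rownames(ts$nuisance) <- NULL
  ts
}

# zero-phase low-pass Butterworth, designed once per (cutoff, fs, T)
# order 4 run forward-backward; the cutoff is pre-corrected by
# (sqrt(2)-1)^(-1/8) so the -3 dB point of the two-pass response sits at
# the nominal cutoff
.butter_lowpass <- function(cutoff_hz, tr_seconds) {
  correction <- (sqrt(2) - 1)^(-1 / 8)
  wn <- 2 * cutoff_hz * correction * tr_seconds
  signal::butter(4, min(wn, 0.999))
}

# apply IIR filter (b, a) with zero initial conditions to every column
# of X: moving-average part by convolution, autoregressive part by
# recursion, both via stats::filter so the whole matrix goes in one call
.filter_ba_cols <- function(b, a, X) {
  nb <- length(b)
  if (nb > 1) {
    Xp <- rbind(matrix(0, nb - 1, ncol(X)), X)   # zero past, as filter(zi=0)
    Y <- stats::filter(Xp, b, method = "convolution", sides = 1)
    Y <- Y[nb:nrow(Xp), , drop = FALSE]
  } else {
    Y <- b * X
  }
  if (length(a) > 1) {
    Y <- stats::filter(Y, -a[-1], method = "recursive")
  }
  matrix(as.numeric(Y), nrow(X), ncol(X))
}

# zero-phase forward-backward filtering of every column (same scheme as
# signal::filtfilt: zero-pad the tail, filter, reverse, filter, truncate)
.filtfilt_cols <- function(bf, X) {
  b <- bf$b
  a <- bf$a
  npad <- 2 * max(length(a), length(b))
  Xp <- rbind(X, matrix(0, npad, ncol(X)))
  Y <- .filter_ba_cols(b, a, Xp)
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y <- .filter_ba_cols(b, a, Y)
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y[seq_len(nrow(X)), , drop = FALSE]
}

#' Temporally low-pass filter a session
#'
#' Zero-phase (forward-backward) 4th-order Butterworth low-pass filter
#' applied per vertex. Each series is demeaned before filtering and its
#' mean restored afterwards, so the DC level is preserved exactly and
#' in-band components incur no temporal shift.
#'
#' @param ts A `session_ts`.
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @return The filtered `session_ts`.
#' @export
lowpass_filter <- function(ts, cutoff_hz = 0.08) {
  nyq <- 1 / (2 * ts$tr_seconds)
  if (cutoff_hz >= nyq) {
    stop("cutoff ", cutoff_hz, " Hz is at or above Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  bf <- .butter_lowpass(cutoff_hz, ts$tr_seconds)
  mu <- rowMeans(ts$data)
  filtered <- t(.filtfilt_cols(bf, t(ts$data - mu)))
  # re-center: edge transients can leak a tiny DC term; the series mean
  # must come back exactly
  ts$data <- filtered - rowMeans(filtered) + mu
  # the nuisance table is filtered identically so later regression works
  # in the same frequency band as the data
  if (!is.null(ts$nuisance) && ncol(ts$nuisance) > 0) {
    N <- as.matrix(ts$nuisance)
    nmu <- colMeans(N)
    Nf <- .filtfilt_cols(bf, sweep(N, 2, nmu))
    Nf <- sweep(sweep(Nf, 2, colMeans(Nf)), 2, nmu, `+`)
    ts$nuisance <- as.data.frame(Nf)
    names(ts$nuisance) <- colnames(N)
  }
  ts
}

# design matrix with intercept and optional backward-difference derivatives
.nuisance_design <- function(nuisance, add_derivatives) {
  X <- as.matrix(nuisance)
  if (is.null(X) || ncol(X) == 0) {
    X <- matrix(numeric(0), nrow = nrow(nuisance), ncol = 0)
  }
  if (add_derivatives && ncol(X) > 0) {
    D <- apply(X, 2, function(x) c(0, diff(x)))
    colnames(D) <- paste0(colnames(X), "_deriv")
    X <- cbind(X, D)
  }
  cbind(intercept = 1, X)
}

#' Regress nuisance signals out of a session
#'
#' Ordinary least-squares projection of every vertex series onto the
#' orthogonal complement of the nuisance design (regressors from the
#' session's nuisance table, optionally augmented with their
#' backward-difference temporal derivatives, plus an intercept).
#' Residuals are exactly orthogonal to every regressor.
#'
#' @param ts A `session_ts`.
#' @param add_derivatives Add derivative columns (default TRUE).
#' @return The residualized `session_ts` (mean removed via the
#'   intercept).
#' @export
regress_nuisance <- function(ts, add_derivatives = TRUE) {
  X <- .nuisance_design(ts$nuisance, add_derivatives)
  if (ncol(ts$data) < 2 * ncol(X)) {
    stop("run too short for ", ncol(X), " regressors", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # residuals of data' ~ X, vectorized across vertices
  fitted <- X %*% qr.coef(qrX, t(ts$data))
  ts$data <- ts$data - t(fitted)
  ts
}

# sparse symmetric diffusion operator I - (step/d_max) * (D - A);
# column sums are 1, so per-frame vertex sums are preserved, and the
# hemispheres stay decoupled because A has no cross-hemisphere edges
.diffusion_operator <- function(mesh, step = 0.5) {
  nv <- mesh$n_vertices
  el <- cbind(rep(seq_along(mesh$adjacency), lengths(mesh$adjacency)),
              unlist(mesh$adjacency, use.names = FALSE))
  A <- Matrix::sparseMatrix(i = el[, 1], j = el[, 2], x = 1,
                            dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  dmax <- max(deg)
  Matrix::Diagonal(nv, 1 - step * deg / dmax) + (step / dmax) * A
}

#' Smooth a map or time series on the surface
#'
#' Iterated graph heat diffusion approximating a geodesic Gaussian
#' kernel of the requested FWHM. The diffusion operator is symmetric
#' with unit column sums, so the per-frame sum over vertices is
#' preserved and smoothing never mixes hemispheres. The iteration count
#' derives from `sigma = FWHM / sqrt(8 ln 2)` expressed in mesh-edge
#' hops (each diffusion step with weight 0.5 adds about half a squared
#' hop of kernel variance).
#'
#' @param x A `session_ts`, a vertex x time matrix, or a per-vertex
#'   numeric vector.
#' @param mesh The `surface_mesh` the vertex dimension refers to.
#' @param fwhm_mm Kernel FWHM in mm; 0 is the identity.
#' @param mesh_edge_mm Nominal edge length in mm; `NULL` uses the
#'   fsaverage6-equivalent spacing `2^(6 - level)` mm.
#' @return Same type as `x`, smoothed.
#' @export
smooth_surface <- function(x, mesh, fwhm_mm, mesh_edge_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (inherits(x, "session_ts")) {
    x$data <- smooth_surface(x$data, mesh, fwhm_mm, mesh_edge_mm)
    return(x)
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  stopifnot(nrow(m) == mesh$n_vertices)
  if (fwhm_mm == 0) return(x)
  if (is.null(mesh_edge_mm)) mesh_edge_mm <- 2^(6 - mesh$level)
  step <- 0.5
  sigma_hops <- (fwhm_mm / mesh_edge_mm) / sqrt(8 * log(2))
  n_iter <- as.integer(round(sigma_hops^2 / step))
  if (n_iter == 0) return(x)     # kernel narrower than the mesh spacing
  W <- .diffusion_operator(mesh, step)
  for (i in seq_len(n_iter)) m <- as.matrix(W %*% m)
  if (vec) drop(m) else m
}

#' Run the full preprocessing chain on one session
#'
#' Applies, in order: initial-frame discard, zero-phase low-pass
#' filtering, nuisance regression, and surface smoothing. The order is
#' fixed by default and mirrors the conventional resting-state surface
#' pipeline; `smooth_before_regression` swaps the last two steps.
#'
#' @param ts A `session_ts`.
#' @param mesh The study `surface_mesh`.
#' @param params A `preproc_params`.
#' @param smooth_before_regression Swap smoothing ahead of nuisance
#'   regression (default FALSE).
#' @return The preprocessed `session_ts`.
#' @export
preprocess_session <- function(ts, mesh, params = preproc_params(),
                               smooth_before_regression = FALSE) {
  ts <- discard_initial(ts, params$n_discard)
  ts <- lowpass_filter(ts, params$lowpass_hz)
  if (smooth_before_regression) {
    ts <- smooth_surface(ts, mesh, params$smooth_fwhm_mm,
                         params$mesh_edge_mm)
    ts <- regress_nuisance(ts, params$add_derivatives)
  } else {
    ts <- regress_nuisance(ts, params$add_derivatives)
    ts <- smooth_surface(ts, mesh, params$smooth_fwhm_mm,
                         params$mesh_edge_mm)
  }
  ts
}

#' Preprocess every session of a study
#'
#' @param study A `study_dataset`.
#' @param params A `preproc_params`.
#' @param ... Passed to [preprocess_session()].
#' @return The study with all sessions preprocessed.
#' @export
preprocess_study <- function(study, params = preproc_params(), ...) {
  for (s in seq_along(study$subjects)) {
    study$subjects[[s]]$sessions <-
      lapply(study$subjects[[s]]$sessions, preprocess_session,
             mesh = study$mesh, params = params, ...)
  }
  study
}
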