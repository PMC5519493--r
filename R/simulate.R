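#' Generator parameters for a synthetic surface-fMRI study
#'
#' Bundles and validates every knob of the synthetic study generator.
#' Defaults encode the study design being emulated: 4 subjects scanned
#' in 24 sessions each, one 7 m 2 s resting run per session at TR = 1 s
#' (422 frames), two distributed networks interdigitated across six
#' cortical zones, unit network loading against unit-variance vertex
#' noise, and latent network fluctuations band-limited below 0.08 Hz so
#' the planted signal survives the preprocessing low-pass filter.
#'
#' @param subdivision_level Icosphere subdivision level (desk-scale
#'   default 4, i.e. 2,562 vertices per hemisphere; 6 reproduces the
#'   40,962-vertex fsaverage6 resolution).
#' @param n_subjects,n_sessions Study dimensions.
#' @param frames_per_run Frames per session at `tr_seconds` spacing
#'   (>= 64 so fALFF has usable frequency resolution).
#' @param n_networks,n_zones,parcel_radius,zone_radius,jitter_steps
#'   Template layout, see [plant_networks()].
#' @param network_loading Unitless weight of a network's latent time
#'   course at its member vertices.
#' @param vertex_noise_sd SD of i.i.d. vertex noise.
#' @param global_signal_sd SD of the shared global signal (also written
#'   into the nuisance table).
#' @param latent_lowpass_cutoff Band limit (Hz) of latent and global
#'   time courses.
#' @param dropout_zone Zone id whose vertices get signal attenuation
#'   (`NULL` = none); emulates susceptibility dropout.
#' @param dropout_attenuation Multiplier in `[0, 1]` applied to the
#'   network signal (not the noise) inside `dropout_zone`.
#' @param baseline_mean Constant BOLD-like offset added to every vertex
#'   so temporal SNR is well defined.
#' @param tr_seconds Repetition time (s).
#' @param n_motion_regressors Number of synthetic motion-like nuisance
#'   columns written into the session nuisance table.
#' @param master_seed Master RNG seed; all template and session seeds
#'   derive from it deterministically.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(subdivision_level = 4,
                             n_subjects = 4,
                             n_sessions = 24,
                             frames_per_run = 422,
                             n_networks = 2,
                             n_zones = 6,
                             parcel_radius = 2,
                             zone_radius = 2 * parcel_radius,
                             jitter_steps = 2,
                             network_loading = 1.0,
                             vertex_noise_sd = 1.0,
                             global_signal_sd = 0.5,
                             latent_lowpass_cutoff = 0.08,
                             dropout_zone = NULL,
                             dropout_attenuation = 1.0,
                             baseline_mean = 100,
                             tr_seconds = 1.0,
                             n_motion_regressors = 6,
                             master_seed = 1) {
  p <- as.list(environment())
  errs <- character()
  if (p$vertex_noise_sd < 0) errs <- c(errs, "vertex_noise_sd must be >= 0")
  if (p$global_signal_sd < 0) errs <- c(errs, "global_signal_sd must be >= 0")
  if (p$dropout_attenuation < 0 || p$dropout_attenuation > 1)
    errs <- c(errs, "dropout_attenuation must be in [0, 1]")
  if (p$tr_seconds <= 0) errs <- c(errs, "tr_seconds must be > 0")
  if (p$latent_lowpass_cutoff >= 1 / (2 * p$tr_seconds))
    errs <- c(errs, "latent_lowpass_cutoff must be below Nyquist")
  if (p$latent_lowpass_cutoff <= 0)
    errs <- c(errs, "latent_lowpass_cutoff must be > 0")
  if (p$n_subjects < 1 || p$n_sessions < 1)
    errs <- c(errs, "n_subjects and n_sessions must be >= 1")
  if (p$network_loading < 0) errs <- c(errs, "network_loading must be >= 0")
  if (length(errs) > 0) {
    stop("invalid generator params:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  class(p) <- "generator_params"
  p
}

# unit-variance band-limited noise: white noise with FFT coefficients above
# the cutoff zeroed (and DC removed), then scaled to unit sample sd
band_limited_noise <- function(n_frames, cutoff_hz, tr_seconds, sd = 1) {
  x <- stats::rnorm(n_frames)
  co <- stats::fft(x)
  freq <- seq(0, n_frames - 1) / (n_frames * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)     # fold to [0, Nyquist]
  co[freq > cutoff_hz | freq == 0] <- 0
  y <- Re(stats::fft(co, inverse = TRUE)) / n_frames
  s <- stats::sd(y)
  if (s == 0) return(rep(0, n_frames))
  y / s * sd
}

#' Simulate one session of vertex time series
#'
#' Signal model per vertex v and frame t:
#' `x_v(t) = baseline + a_v * loading * s_k(v)(t) + g(t) + e_v(t)`,
#' where `s_k` is the unit-variance band-limited latent time course of
#' the network containing v (zero off-network), `g` a shared global
#' signal, `e` i.i.d. Gaussian vertex noise, and `a_v` the dropout
#' attenuation (1 outside the dropout zone). Latents of distinct
#' networks are generated independently. The nuisance table carries the
#' realized global signal and smooth synthetic motion-like regressors.
#'
#' @param template A `network_template`.
#' @param params A `generator_params`.
#' @param seed Session RNG seed; output is reproducible given
#'   `(template, params, seed)`.
#' @param run_id,subject_id Identifiers stored on the session.
#' @return A `session_ts`: `data` (vertex x time), `tr_seconds`,
#'   `nuisance` (time x regressor data.frame), `run_id`, `subject_id`,
#'   `rng_seed`, `dataset_label`.
#' @export
simulate_session <- function(template, params, seed, run_id = 1L,
                             subject_id = 1L) {
  tfr <- params$frames_per_run
  if (tfr < 64) {
    stop("frames_per_run = ", tfr, " gives insufficient frequency ",
         "resolution for spectral QC (need >= 64)", call. = FALSE)
  }
  stopifnot(inherits(template, "network_template"))
  nv <- template$n_vertices
  with_seed(seed, {
    latents <- vapply(seq_len(template$n_networks), function(k)
      band_limited_noise(tfr, params$latent_lowpass_cutoff,
                         params$tr_seconds),
      numeric(tfr))                               # tfr x n_networks
    g <- if (params$global_signal_sd > 0)
      band_limited_noise(tfr, params$latent_lowpass_cutoff,
                         params$tr_seconds, sd = params$global_signal_sd)
    else rep(0, tfr)
    motion <- vapply(seq_len(params$n_motion_regressors), function(j) {
      m <- as.numeric(stats::filter(stats::rnorm(tfr, sd = 0.1), 0.95,
                                    method = "recursive"))
      m - mean(m)
    }, numeric(tfr))
    noise <- if (params$vertex_noise_sd > 0)
      matrix(stats::rnorm(nv * tfr, sd = params$vertex_noise_sd), nv, tfr)
    else matrix(0, nv, tfr)
    atten <- rep(1, nv)
    if (!is.null(params$dropout_zone) && params$dropout_attenuation < 1) {
      dz <- template$zones$members[[params$dropout_zone]]
      atten[dz] <- params$dropout_attenuation
    }
    signal <- matrix(0, nv, tfr)
    for (k in seq_len(template$n_networks)) {
      supp <- which(template$assignment == k)
      if (length(supp) > 0) {
        signal[supp, ] <- params$network_loading *
          matrix(latents[, k], length(supp), tfr, byrow = TRUE)
      }
    }
    data <- params$baseline_mean + atten * signal +
      matrix(g, nv, tfr, byrow = TRUE) + noise
    # no all-zero regressor when the global signal is disabled
    nuis <- if (params$global_signal_sd > 0) data.frame(global = g)
    else data.frame(row.names = seq_len(tfr))
    for (j in seq_len(params$n_motion_regressors)) {
      nuis[[paste0("motion", j)]] <- motion[, j]
    }
    structure(
      list(data = data,
           tr_seconds = params$tr_seconds,
           nuisance = nuis,
           run_id = as.integer(run_id),
           subject_id = as.integer(subject_id),
           rng_seed = as.integer(seed),
           dataset_label = if (run_id %% 2 == 1) "discovery" else "replication"),
      class = "session_ts")
  })
}

#' @export
print.session_ts <- function(x, ...) {
  cat("session_ts: subject", x$subject_id, "run", x$run_id,
      sprintf("(%s),", x$dataset_label),
      nrow(x$data), "vertices x", ncol(x$data), "frames, TR",
      x$tr_seconds, "s\n")
  invisible(x)
}

#' Simulate a complete multi-subject, multi-session study
#'
#' Builds the mesh once, plants a per-subject network template (jittered
#' with a subject-specific seed derived from the master seed), and
#' simulates every session with a deterministically derived session
#' seed. Odd-numbered sessions are labeled `discovery`, even-numbered
#' sessions `replication`, so hypotheses formed on one half of the data
#' can be tested on the held-out half.
#'
#' @param params A `generator_params`.
#' @return A `study_dataset`: `mesh`, `params`, and `subjects`, a list
#'   with per-subject `template` and `sessions`.
#' @export
simulate_study <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  mesh <- build_icosphere(params$subdivision_level)
  subjects <- lapply(seq_len(params$n_subjects), function(s) {
    template <- plant_networks(
      mesh,
      n_networks = params$n_networks,
      n_zones = params$n_zones,
      parcel_radius = params$parcel_radius,
      zone_radius = params$zone_radius,
      jitter_steps = params$jitter_steps,
      subject_seed = derive_seed(params$master_seed, 101L, s))
    sessions <- lapply(seq_len(params$n_sessions), function(r)
      simulate_session(template, params,
                       seed = derive_seed(params$master_seed, 202L, s, r),
                       run_id = r, subject_id = s))
    list(subject_id = s, template = template, sessions = sessions)
  })
  structure(list(mesh = mesh, params = params, subjects = subjects),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:", length(x$subjects), "subjects x",
      x$params$n_sessions, "sessions,",
      x$mesh$n_vertices, "vertices,",
      x$params$frames_per_run, "frames/run\n")
  invisible(x)
}

#' Sessions of one subject filtered by dataset label
#'
#' @param study A `study_dataset`.
#' @param subject Subject index.
#' @param label `"all"`, `"discovery"` (odd runs) or `"replication"`
#'   (even runs).
#' @return List of `session_ts`.
#' @export
study_sessions <- function(study, subject, label = c("all", "discovery",
                                                     "replication")) {
  label <- match.arg(label)
  sess <- study$subjects[[subject]]$sessions
  if (label == "all") return(sess)
  sess[vapply(sess, function(s) s$dataset_label == label, logical(1))]
}
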