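#' Temporal signal-to-noise ratio map
#'
#' tSNR per vertex: mean of the series over time divided by its
#' standard deviation over time (denominator T - 1). Vertices with zero
#' temporal variance are flagged undefined (`NA`), never infinite.
#'
#' @param ts A `session_ts` (or vertex x time matrix) with >= 2 frames.
#' @return A `qc_map`: `values` per vertex (NA where undefined),
#'   `metric_name = "tsnr"`.
#' @export
tsnr <- function(ts) {
  data <- if (inherits(ts, "session_ts")) ts$data else ts
  if (ncol(data) < 2) stop("tSNR needs at least 2 frames", call. = FALSE)
  mu <- rowMeans(data)
  sdv <- apply(data, 1, stats::sd)
  values <- unname(ifelse(sdv == 0, NA_real_, mu / sdv))
  structure(list(values = values, metric_name = "tsnr", band_hz = NULL),
            class = "qc_map")
}

# one-sided amplitude spectrum of a demeaned series (DC excluded);
# returns frequencies and amplitudes up to Nyquist
.amplitude_spectrum <- function(x, tr_seconds) {
  n <- length(x)
  x <- x - mean(x)
  amp <- abs(stats::fft(x))[seq_len(floor(n / 2)) + 1]
  freq <- seq_len(floor(n / 2)) / (n * tr_seconds)
  list(freq = freq, amp = amp)
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Per vertex: spectral amplitude summed over the low-frequency band
#' divided by the amplitude summed over the whole spectrum
#' (0, Nyquist], both from the one-sided periodogram of the demeaned
#' series. "Power" is operationalized as amplitude (square root of the
#' periodogram); set `use_power = TRUE` for raw power.
#'
#' @param ts A `session_ts` (or vertex x time matrix) with >= 64
#'   frames.
#' @param band_hz Length-2 band, default `c(0.01, 0.08)` Hz.
#' @param tr_seconds Repetition time; taken from `ts` when it is a
#'   `session_ts`.
#' @param use_power Sum squared amplitudes instead (default FALSE).
#' @return A `qc_map` with values in `[0, 1]`.
#' @export
falff <- function(ts, band_hz = c(0.01, 0.08), tr_seconds = NULL,
                  use_power = FALSE) {
  data <- if (inherits(ts, "session_ts")) ts$data else ts
  tr <- if (inherits(ts, "session_ts")) ts$tr_seconds else tr_seconds
  stopifnot(!is.null(tr))
  if (ncol(data) < 64) {
    stop("fALFF needs >= 64 frames for usable frequency resolution",
         call. = FALSE)
  }
  nyq <- 1 / (2 * tr)
  if (band_hz[1] < 0 || band_hz[2] <= band_hz[1] || band_hz[2] > nyq) {
    stop("band [", band_hz[1], ", ", band_hz[2],
         "] Hz lies outside the spectrum (0, ", nyq, "]", call. = FALSE)
  }
  values <- apply(data, 1, function(x) {
    sp <- .amplitude_spectrum(x, tr)
    a <- if (use_power) sp$amp^2 else sp$amp
    tot <- sum(a)
    if (tot == 0) return(NA_real_)
    sum(a[sp$freq >= band_hz[1] & sp$freq <= band_hz[2]]) / tot
  })
  structure(list(values = unname(values), metric_name = "falff",
                 band_hz = band_hz),
            class = "qc_map")
}

#' @export
print.qc_map <- function(x, ...) {
  cat("qc_map:", x$metric_name, "over", length(x$values), "vertices;",
      "mean", round(mean(x$values, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Per-run QC summary table for a study
#'
#' @param study A `study_dataset` (QC is meant to run on data before
#'   temporal filtering).
#' @return data.frame with one row per (subject, run): mean tSNR and
#'   mean fALFF over vertices.
#' @export
qc_summary <- function(study) {
  rows <- list()
  for (sub in study$subjects) {
    for (sess in sub$sessions) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = sess$subject_id,
        run = sess$run_id,
        dataset = sess$dataset_label,
        mean_tsnr = mean(tsnr(sess)$values, na.rm = TRUE),
        mean_falff = mean(falff(sess)$values, na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}
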