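# Fisher-z sentinel used on matrix diagonals in place of atanh(1) = Inf
Z_SENTINEL <- atanh(1 - 1e-7)

#' Vertex-wise Pearson correlation matrix of one session
#'
#' Pearson product-moment correlations between the time series of every
#' vertex pair. Zero-variance vertices are recorded in a mask and their
#' rows/columns set to `NA` rather than propagating NaN.
#'
#' @param ts A `session_ts` or vertex x time matrix.
#' @return List with `r` (vertex x vertex correlation matrix) and
#'   `mask` (logical, TRUE where the vertex had zero variance).
#' @export
corr_matrix <- function(ts) {
  data <- if (inherits(ts, "session_ts")) ts$data else ts
  sdv <- apply(data, 1, stats::sd)
  mask <- sdv == 0
  r <- matrix(NA_real_, nrow(data), nrow(data))
  if (any(!mask)) {
    r[!mask, !mask] <- stats::cor(t(data[!mask, , drop = FALSE]))
  }
  list(r = r, mask = mask)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)` with `|r|` clipped to `1 - 1e-7` so unit correlations
#' map to a large finite sentinel instead of infinity. Odd in `r`.
#'
#' @param r Correlations in `[-1, 1]` (vector or matrix).
#' @return Same shape, Fisher z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("correlations outside [-1, 1]", call. = FALSE)
  }
  atanh(pmin(abs(r), 1 - 1e-7) * sign(r))
}

#' Run-averaged Fisher-z connectivity matrix
#'
#' Computes the vertex-wise correlation matrix of every run, r-to-z
#' transforms each, and averages elementwise, yielding a mean matrix
#' with much higher stability than any single run. Runs are summed in
#' `run_id` order regardless of input order, so the result is
#' bit-identical under permutation of the run list. The diagonal is set
#' to the documented sentinel `atanh(1 - 1e-7)` and must be excluded
#' from statistics.
#'
#' @param runs List of `session_ts` with identical vertex dimension.
#' @param dataset_label Label stored on the result (`"discovery"`,
#'   `"replication"`, or `"full"`).
#' @return A `z_connectivity`: `z` matrix, `n_runs_averaged`,
#'   `dataset_label`, `mask` (vertices with zero variance in any run).
#' @export
mean_z_matrix <- function(runs, dataset_label = "full") {
  stopifnot(length(runs) >= 1)
  nv <- nrow(runs[[1]]$data)
  if (!all(vapply(runs, function(r) nrow(r$data) == nv, logical(1)))) {
    stop("runs have mismatched vertex dimensions", call. = FALSE)
  }
  ord <- order(vapply(runs, function(r) r$run_id, numeric(1)))
  acc <- matrix(0, nv, nv)
  mask <- rep(FALSE, nv)
  for (i in ord) {
    cm <- corr_matrix(runs[[i]])
    mask <- mask | cm$mask
    z <- fisher_z(cm$r)
    z[is.na(z)] <- 0
    acc <- acc + z
  }
  zbar <- acc / length(runs)
  zbar[mask, ] <- NA_real_
  zbar[, mask] <- NA_real_
  diag(zbar) <- Z_SENTINEL
  structure(
    list(z = zbar, n_runs_averaged = length(runs),
         dataset_label = dataset_label, mask = mask),
    class = "z_connectivity")
}

#' @export
print.z_connectivity <- function(x, ...) {
  cat("z_connectivity:", nrow(x$z), "x", ncol(x$z), "Fisher-z matrix,",
      x$n_runs_averaged, "runs averaged (", x$dataset_label, ")\n")
  invisible(x)
}

#' Seed functional-connectivity map
#'
#' Extracts the Fisher-z connectivity of one seed vertex with every
#' vertex (a row of the mean z matrix). The value at the seed itself is
#' the diagonal sentinel. Maps carry the conventional display range
#' `[0.2, 0.6]` used to visualize these networks.
#'
#' @param z A `z_connectivity`.
#' @param seed_vertex Valid vertex index.
#' @return An `fc_map`: `seed_vertex`, `values`, `dataset_label`,
#'   `display_range`.
#' @export
seed_map <- function(z, seed_vertex) {
  nv <- nrow(z$z)
  if (seed_vertex < 1 || seed_vertex > nv) {
    stop("seed vertex ", seed_vertex, " out of range 1..", nv,
         call. = FALSE)
  }
  structure(
    list(seed_vertex = as.integer(seed_vertex),
         values = z$z[seed_vertex, ],
         dataset_label = z$dataset_label,
         display_range = c(0.2, 0.6)),
    class = "fc_map")
}

#' Test-retest correlation of two connectivity matrices
#'
#' Pearson correlation of the vectorized upper triangles (diagonal and
#' masked vertices excluded) of two mean z matrices, e.g. discovery vs
#' replication, quantifying within-subject consistency of the
#' connectivity pattern.
#'
#' @param zA,zB `z_connectivity` objects of identical dimension.
#' @return Scalar Pearson r.
#' @export
test_retest <- function(zA, zB) {
  stopifnot(all(dim(zA$z) == dim(zB$z)))
  keep <- !(zA$mask | zB$mask)
  if (!any(keep)) stop("all vertices masked", call. = FALSE)
  ut <- upper.tri(zA$z)
  ut[!keep, ] <- FALSE
  ut[, !keep] <- FALSE
  stats::cor(zA$z[ut], zB$z[ut])
}

#' Across-run reliability map of seed connectivity
#'
#' Per-vertex reliability of a seed's connectivity estimate across
#' runs, operationalized as ICC(1,1) computed over the vertex's 1-hop
#' geodesic neighborhood (neighborhood vertices as items, runs as
#' raters), clipped to `[0, 1]`. Low reliability marks vertices whose
#' connectivity is dominated by run-to-run noise, e.g. under signal
#' dropout. This is a declared operationalization: the classical
#' literature cites reliability-based dropout estimation without a
#' printed formula.
#'
#' @param per_run_maps List of >= 3 `fc_map`s with a common seed.
#' @param mesh The `surface_mesh` (for 1-hop neighborhoods).
#' @return A `reliability_map`: `values` in `[0, 1]`, `n_runs`.
#' @export
reliability_map <- function(per_run_maps, mesh) {
  k <- length(per_run_maps)
  if (k < 3) stop("reliability needs >= 3 runs", call. = FALSE)
  seeds <- vapply(per_run_maps, function(m) m$seed_vertex, integer(1))
  if (length(unique(seeds)) != 1) {
    stop("per-run maps must share a seed", call. = FALSE)
  }
  M <- vapply(per_run_maps, function(m) m$values,
              numeric(length(per_run_maps[[1]]$values)))  # vertex x run
  nv <- nrow(M)
  values <- vapply(seq_len(nv), function(v) {
    items <- c(v, mesh$adjacency[[v]])
    Y <- M[items, , drop = FALSE]                 # items x runs
    n <- nrow(Y)
    grand <- mean(Y)
    msb <- k * sum((rowMeans(Y) - grand)^2) / (n - 1)
    msw <- sum((Y - rowMeans(Y))^2) / (n * (k - 1))
    if (msb + (k - 1) * msw == 0) return(0)
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    min(max(icc, 0), 1)
  }, numeric(1))
  structure(list(values = values, n_runs = k), class = "reliability_map")
}

#' Disattenuate a seed map by its reliability
#'
#' Classical correction for attenuation with one unreliable side:
#' `z'(v) = z(v) / sqrt(max(rel(v), floor))`. The floor keeps the
#' correction bounded where reliability is estimated near zero.
#'
#' @param map An `fc_map`.
#' @param rel A `reliability_map` on the same vertex space.
#' @param floor Reliability floor in `(0, 1]` (default 0.04, i.e. a
#'   maximum 5-fold boost).
#' @return The disattenuated `fc_map`.
#' @export
disattenuate <- function(map, rel, floor = 0.04) {
  stopifnot(length(map$values) == length(rel$values),
            floor > 0, floor <= 1)
  map$values <- map$values / sqrt(pmax(rel$values, floor))
  map
}
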