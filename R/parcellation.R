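#' k-means parcellation of concatenated vertex time series
#'
#' Concatenates the given sessions in time (each vertex series
#' variance-normalized per session first, so every run contributes on
#' the same scale), then clusters vertices with k-means on Euclidean
#' distance (equivalent to correlation distance for standardized
#' series, up to scale). Best of `n_restarts` k-means++-style starts by
#' within-cluster sum of squares; deterministic for a fixed seed.
#'
#' @param sessions List of preprocessed `session_ts` (e.g. the
#'   discovery half).
#' @param k Number of clusters (default 12, a deliberately
#'   low-dimensional fractionation).
#' @param n_restarts Random restarts (default 10).
#' @param seed RNG seed.
#' @return A `parcellation_result`: `labels` (per vertex, in `1..k`),
#'   `k`, `n_restarts`, `seed`, `inertia`.
#' @export
kmeans_parcellate <- function(sessions, k = 12, n_restarts = 10, seed = 1) {
  stopifnot(length(sessions) >= 1)
  nv <- nrow(sessions[[1]]$data)
  if (k > nv) stop("k = ", k, " exceeds vertex count ", nv, call. = FALSE)
  blocks <- lapply(sessions, function(sess) {
    m <- sess$data - rowMeans(sess$data)
    sdv <- apply(m, 1, stats::sd)
    sdv[sdv == 0] <- 1
    m / sdv
  })
  X <- do.call(cbind, blocks)
  fit <- with_seed(seed, {
    for (attempt in 1:5) {
      res <- tryCatch(
        stats::kmeans(X, centers = k, nstart = n_restarts, iter.max = 100),
        error = function(e) e)
      if (!inherits(res, "error")) break   # empty-cluster starts: re-seed
    }
    if (inherits(res, "error")) stop(res)
    res
  })
  structure(
    list(labels = unname(fit$cluster), k = as.integer(k),
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         inertia = fit$tot.withinss),
    class = "parcellation_result")
}

# adjusted Rand index between two labelings (chance-corrected agreement)
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(0)
  (nij - expected) / denom
}

#' Match clusters to planted networks and score recovery
#'
#' Finds the one-to-one assignment of planted networks to clusters that
#' maximizes total vertex overlap (solved exactly by enumeration over
#' injective assignments; the network count is small), then scores
#' recovery with the adjusted Rand index over all vertices (background
#' included) and a per-network Dice coefficient over the matched
#' clusters.
#'
#' @param parcellation A `parcellation_result` (or integer label
#'   vector).
#' @param template A `network_template` on the same vertex space.
#' @return List with `matched_mapping` (named integer: network ->
#'   cluster), `ari`, `dice` (per network).
#' @export
match_and_score <- function(parcellation, template) {
  labels <- if (inherits(parcellation, "parcellation_result"))
    parcellation$labels else parcellation
  stopifnot(length(labels) == template$n_vertices)
  truth <- template$assignment
  m <- template$n_networks
  ks <- sort(unique(labels))
  if (m > 5) stop("exact matching supports up to 5 networks", call. = FALSE)
  overlap <- outer(seq_len(m), ks, Vectorize(function(net, cl)
    sum(truth == net & labels == cl)))
  # enumerate injective maps network -> cluster
  best <- NULL
  best_total <- -1
  assign_rec <- function(net, used, current, total) {
    if (net > m) {
      if (total > best_total) {
        best_total <<- total
        best <<- current
      }
      return()
    }
    for (j in seq_along(ks)) {
      if (!used[j]) {
        used[j] <- TRUE
        current[net] <- ks[j]
        assign_rec(net + 1, used, current, total + overlap[net, j])
        used[j] <- FALSE
      }
    }
  }
  assign_rec(1L, logical(length(ks)), integer(m), 0)
  dice <- vapply(seq_len(m), function(net) {
    pred <- labels == best[net]
    act <- truth == net
    2 * sum(pred & act) / (sum(pred) + sum(act))
  }, numeric(1))
  names(best) <- paste0("network", seq_len(m))
  names(dice) <- names(best)
  list(matched_mapping = best,
       ari = adjusted_rand_index(labels, truth),
       dice = dice)
}
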