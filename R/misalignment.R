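#' Individually tailored region list from a subject's template
#'
#' The misalignment analysis uses each subject's parcel anchor vertices
#' as that subject's "individually tailored" regions: one region per
#' network per zone over the first `n_region_zones` zones (2 networks x
#' 5 zones = 10 regions by default).
#'
#' @param template A `network_template`.
#' @param n_region_zones Zones contributing regions (default 5).
#' @return List with `vertices` (length 2 x zones), `network`
#'   (`"a"`/`"b"`), `zone`.
#' @export
template_regions <- function(template, n_region_zones = 5) {
  stopifnot(template$n_networks == 2,
            n_region_zones <= template$zones$n_zones)
  zones <- seq_len(n_region_zones)
  list(vertices = c(template$anchors[zones, 1], template$anchors[zones, 2]),
       network = rep(c("a", "b"), each = n_region_zones),
       zone = rep(zones, 2))
}

#' Region-by-region connectivity matrix
#'
#' Mean-over-sessions Fisher-z correlation matrix between the time
#' series at a set of region vertices (typically 10: two networks in
#' five zones), optionally applying one subject's region definitions to
#' another subject's data to emulate between-subject misalignment.
#' Meshes are registered by construction, so cross-subject application
#' reuses the same vertex indices.
#'
#' @param sessions Data sessions (e.g. one subject's replication half).
#' @param regions Region list from [template_regions()] (fields
#'   `vertices`, `network`, `zone`).
#' @param data_subject,region_subject Bookkeeping labels.
#' @return A `region_matrix`: `z` (region x region, diagonal sentinel),
#'   `network`, `zone`, subject labels.
#' @export
region_matrix <- function(sessions, regions, data_subject = NA,
                          region_subject = NA) {
  verts <- regions$vertices
  nv_data <- nrow(sessions[[1]]$data)
  if (any(verts < 1 | verts > nv_data)) {
    stop("region vertex out of range", call. = FALSE)
  }
  acc <- matrix(0, length(verts), length(verts))
  for (sess in sessions) {
    r <- stats::cor(t(sess$data[verts, , drop = FALSE]))
    acc <- acc + fisher_z(r)
  }
  z <- acc / length(sessions)
  diag(z) <- Z_SENTINEL
  structure(
    list(z = z, network = regions$network, zone = regions$zone,
         data_subject = data_subject, region_subject = region_subject),
    class = "region_matrix")
}

#' Within- vs between-network block contrast of a region matrix
#'
#' Mean within-network off-diagonal Fisher z minus mean between-network
#' Fisher z. Large values mean the two-network block structure is
#' intact; values near zero mean it has broken down (as happens when
#' another subject's region locations are imposed).
#'
#' @param m A `region_matrix`.
#' @return Scalar contrast.
#' @export
block_contrast <- function(m) {
  same <- outer(m$network, m$network, "==")
  off <- !diag(nrow(m$z))
  mean(m$z[same & off]) - mean(m$z[!same])
}

# 2-cluster assignment accuracy of the region matrix: sign split of the
# leading eigenvector of the double-centered off-diagonal matrix
region_cluster_accuracy <- function(m) {
  z <- m$z
  diag(z) <- 0
  z <- sweep(z, 1, rowMeans(z))
  z <- sweep(z, 2, colMeans(z))
  v <- eigen(z, symmetric = TRUE)$vectors[, 1]
  pred <- v >= 0
  act <- m$network == m$network[1]
  max(mean(pred == act), mean(pred != act))
}

#' Full own- vs cross-subject misalignment grid
#'
#' Computes the region matrix for every (region-source subject, data
#' subject) pair and summarizes the block contrast, separating
#' own-subject (i = j) from cross-subject (i != j) applications.
#'
#' @param study A `study_dataset`.
#' @param regions_per_subject List of region lists (one per subject),
#'   e.g. from [template_regions()] on each subject's template.
#' @param session_label Which sessions to evaluate on (default
#'   `"replication"`).
#' @return List with `matrices` (list of `region_matrix`), `summary`
#'   data.frame (region_subject, data_subject, contrast, accuracy,
#'   own), `mean_own_contrast`, `mean_cross_contrast`.
#' @export
misalignment_grid <- function(study, regions_per_subject,
                              session_label = "replication") {
  ns <- length(study$subjects)
  stopifnot(length(regions_per_subject) == ns)
  mats <- list()
  rows <- list()
  for (j in seq_len(ns)) {
    sessions <- study_sessions(study, j, session_label)
    for (i in seq_len(ns)) {
      m <- region_matrix(sessions, regions_per_subject[[i]],
                         data_subject = j, region_subject = i)
      mats[[length(mats) + 1]] <- m
      rows[[length(rows) + 1]] <- data.frame(
        region_subject = i, data_subject = j,
        contrast = block_contrast(m),
        accuracy = region_cluster_accuracy(m),
        own = i == j)
    }
  }
  summary <- do.call(rbind, rows)
  list(matrices = mats, summary = summary,
       mean_own_contrast = mean(summary$contrast[summary$own]),
       mean_cross_contrast = mean(summary$contrast[!summary$own]))
}
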