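#' Seed-selection criteria
#'
#' Thresholds that turn the interactive seed-exploration procedure into
#' an automated search. A candidate seed is *robust* when its
#' connectivity map shows suprathreshold peaks (`z >= z_robust`,
#' default 0.6) in at least `min_zones` distinct cortical zones;
#' *diffuse* when its best peak only reaches the intermediate range
#' (around `z_diffuse`, default 0.4, read as a mixture of signals); and
#' *dropout* when no peak reaches even that (low-SNR territory). A
#' dissociated second seed must additionally show `z < z_separation`
#' (default 0.3) with the first seed's map.
#'
#' @param z_robust Robust-network peak threshold (default 0.6).
#' @param z_diffuse Diffuse-map threshold (default 0.4).
#' @param z_separation Maximum allowed correlation between paired
#'   seeds' networks (default 0.3).
#' @param min_zones Distinct distributed zones required for a robust
#'   verdict (default 4, the canonical distributed-network motif).
#' @param vicinity_hops Maximum graph distance between paired seeds
#'   (`NULL` = the zone diameter).
#' @return A validated `seed_criteria` list.
#' @export
seed_criteria <- function(z_robust = 0.6, z_diffuse = 0.4,
                          z_separation = 0.3, min_zones = 4,
                          vicinity_hops = NULL) {
  if (!(z_separation < z_diffuse && z_diffuse < z_robust)) {
    stop("criteria must be ordered z_separation < z_diffuse < z_robust",
         call. = FALSE)
  }
  if (min_zones < 2) stop("min_zones must be >= 2", call. = FALSE)
  structure(as.list(environment()), class = "seed_criteria")
}

#' Score one candidate seed against the distribution criteria
#'
#' Computes the peak Fisher-z connectivity of the seed within every
#' zone (the seed vertex itself is excluded from its own zone's peak)
#' and classifies the seed: `robust` when at least `min_zones` zones
#' peak at or above `z_robust`; otherwise `diffuse` when the global
#' peak reaches `z_diffuse`; otherwise `dropout`.
#'
#' @param z A `z_connectivity`.
#' @param seed_vertex Candidate vertex.
#' @param zones Zone layout from [plant_networks()]'s template
#'   (`template$zones`) or [place_zones()].
#' @param criteria A `seed_criteria`.
#' @return A `seed_quality`: `seed_vertex`, `peak_z_per_zone`,
#'   `n_robust_zones`, `verdict`.
#' @export
evaluate_seed <- function(z, seed_vertex, zones, criteria = seed_criteria()) {
  if (z$mask[seed_vertex]) {
    stop("seed vertex ", seed_vertex, " is masked (zero variance)",
         call. = FALSE)
  }
  row <- z$z[seed_vertex, ]
  peaks <- vapply(seq_len(zones$n_zones), function(zn) {
    memb <- setdiff(zones$members[[zn]], seed_vertex)
    memb <- memb[!z$mask[memb]]
    if (length(memb) == 0) return(-Inf)
    max(row[memb])
  }, numeric(1))
  n_robust <- sum(peaks >= criteria$z_robust)
  verdict <- if (n_robust >= criteria$min_zones) "robust"
  else if (max(peaks) >= criteria$z_diffuse) "diffuse"
  else "dropout"
  structure(
    list(seed_vertex = as.integer(seed_vertex),
         peak_z_per_zone = peaks,
         n_robust_zones = n_robust,
         verdict = verdict),
    class = "seed_quality")
}

#' Find a dissociated seed pair within a search zone
#'
#' Automates the two-stage seed selection. Stage one scans the search
#' zone in ascending vertex order and keeps the robust-verdict vertex
#' with the most robust zones (ties broken toward the lowest index).
#' Stage two searches the same zone for a second seed that (i) lies in
#' the search zone, (ii) is within `vicinity_hops` of the first seed,
#' (iii) shows `z < z_separation` with the first seed's map, and
#' (iv) itself earns a robust verdict; among qualifiers the one with
#' most robust zones wins (ties toward the lowest index). The whole
#' search is deterministic for fixed inputs.
#'
#' @param z A `z_connectivity` (discovery data).
#' @param search_zone Zone id to search (the lateral-PFC analog).
#' @param zones Zone layout (see [evaluate_seed()]).
#' @param criteria A `seed_criteria`.
#' @param mesh The `surface_mesh` (for the vicinity hop distances).
#' @return A `seed_pair`: `seed_a`, `seed_b`, `quality_a`, `quality_b`,
#'   `dataset_label`.
#' @export
find_seed_pair <- function(z, search_zone, zones,
                           criteria = seed_criteria(), mesh) {
  cand <- sort(zones$members[[search_zone]])
  cand <- cand[!z$mask[cand]]
  if (length(cand) == 0) stop("search zone is empty", call. = FALSE)
  quals <- lapply(cand, evaluate_seed, z = z, zones = zones,
                  criteria = criteria)
  robust <- vapply(quals, function(q) q$verdict == "robust", logical(1))
  if (!any(robust)) {
    stop("seed search failed: no robust seed in zone ", search_zone,
         call. = FALSE)
  }
  nrz <- vapply(quals, function(q) q$n_robust_zones, numeric(1))
  first_i <- which(robust)[which.max(nrz[robust])]
  seed_a <- cand[first_i]
  qual_a <- quals[[first_i]]

  vicinity <- criteria$vicinity_hops
  if (is.null(vicinity)) vicinity <- 2 * zones$radius
  hops <- mesh_hop_distance(mesh, seed_a)[1, ]
  map_a <- z$z[seed_a, ]

  pool <- setdiff(cand, seed_a)
  in_vicinity <- pool[hops[pool] <= vicinity]
  separated <- in_vicinity[map_a[in_vicinity] < criteria$z_separation]
  second_robust <- separated[vapply(
    match(separated, cand), function(i) quals[[i]]$verdict == "robust",
    logical(1))]
  if (length(second_robust) == 0) {
    failed_at <- if (length(in_vicinity) == 0) {
      "vicinity (criterion ii)"
    } else if (length(separated) == 0) {
      "separation z < z_separation (criterion iii)"
    } else {
      "robust distributed map (criterion iv)"
    }
    stop("seed pairing failed: last candidates eliminated by ",
         failed_at, call. = FALSE)
  }
  idx <- match(second_robust, cand)
  second_i <- idx[which.max(nrz[idx])]
  seed_b <- cand[second_i]
  structure(
    list(seed_a = seed_a, seed_b = seed_b,
         quality_a = qual_a, quality_b = quals[[second_i]],
         dataset_label = z$dataset_label),
    class = "seed_pair")
}

#' @export
print.seed_pair <- function(x, ...) {
  cat("seed_pair: A =", x$seed_a, "(", x$quality_a$n_robust_zones,
      "robust zones ), B =", x$seed_b, "(",
      x$quality_b$n_robust_zones, "robust zones ), from",
      x$dataset_label, "data\n")
  invisible(x)
}
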