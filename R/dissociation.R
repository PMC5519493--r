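#' Select a priori test regions from discovery data
#'
#' For every target zone, picks the vertex most correlated (Fisher z)
#' with seed A and the vertex most correlated with seed B, yielding one
#' region pair per zone; the two targets must be distinct (the B target
#' falls back to its next-best vertex on collision). Selection uses
#' discovery data only and the result carries that provenance label so
#' the battery can enforce the discovery/replication firewall. An
#' optional lone region (a zone where only one network is
#' represented, like parahippocampal cortex) can be declared with a
#' partner zone whose opposite-network target completes its 2x2 cell.
#'
#' @param z_disc A `z_connectivity` with `dataset_label = "discovery"`.
#' @param seed_pair A `seed_pair` from [find_seed_pair()].
#' @param zones Zone layout.
#' @param target_zones Zone ids to select region pairs in.
#' @param subject_id Stored on the result.
#' @param lone_zone Optional zone id carrying only a network-A region.
#' @param lone_partner Zone id whose B target is paired with the lone
#'   region (required with `lone_zone`).
#' @return A `region_set`: seeds, per-zone targets, provenance.
#' @export
select_regions <- function(z_disc, seed_pair, zones, target_zones,
                           subject_id = 1L, lone_zone = NULL,
                           lone_partner = NULL) {
  map_a <- z_disc$z[seed_pair$seed_a, ]
  map_b <- z_disc$z[seed_pair$seed_b, ]
  pick <- function(zone_id) {
    memb <- sort(zones$members[[zone_id]])
    memb <- memb[!z_disc$mask[memb]]
    memb <- setdiff(memb, c(seed_pair$seed_a, seed_pair$seed_b))
    ta <- memb[which.max(map_a[memb])]
    rest <- setdiff(memb, ta)
    tb <- rest[which.max(map_b[rest])]
    c(a = ta, b = tb)
  }
  targets <- vapply(target_zones, pick, integer(2))
  colnames(targets) <- as.character(target_zones)
  lone <- NULL
  if (!is.null(lone_zone)) {
    stopifnot(!is.null(lone_partner), lone_partner %in% target_zones)
    memb <- sort(zones$members[[lone_zone]])
    memb <- memb[!z_disc$mask[memb]]
    lone <- list(zone = lone_zone,
                 vertex = memb[which.max(map_a[memb])],
                 network = "a",
                 partner_zone = lone_partner)
  }
  structure(
    list(subject_id = as.integer(subject_id),
         seed_a = seed_pair$seed_a, seed_b = seed_pair$seed_b,
         target_zones = target_zones,
         targets = targets,
         lone = lone,
         provenance = z_disc$dataset_label),
    class = "region_set")
}

#' Per-session cell values for one 2x2 dissociation test
#'
#' For each session, the Fisher-z correlation of each seed's time
#' series with each target's time series: four cells per session,
#' giving a balanced 2x2 design with one value per cell per session.
#'
#' @param sessions List of (replication) `session_ts`.
#' @param seed_a,seed_b Seed vertices.
#' @param target_a,target_b Target vertices; a target equal to a seed
#'   is rejected (self-correlation guard).
#' @return data.frame with columns `session`, `seed` (a/b), `target`
#'   (a/b), `z`.
#' @export
extract_cell_values <- function(sessions, seed_a, seed_b,
                                target_a, target_b) {
  verts <- c(seed_a, seed_b, target_a, target_b)
  if (anyDuplicated(verts) > 0) {
    stop("seed and target vertices must be distinct (self-correlation)",
         call. = FALSE)
  }
  rows <- lapply(sessions, function(sess) {
    X <- sess$data[verts, , drop = FALSE]
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance region vertex in subject ", sess$subject_id,
           " run ", sess$run_id, call. = FALSE)
    }
    r <- stats::cor(t(X))
    data.frame(
      session = sess$run_id,
      seed = c("a", "a", "b", "b"),
      target = c("a", "b", "a", "b"),
      z = fisher_z(c(r[1, 3], r[1, 4], r[2, 3], r[2, 4])))
  })
  do.call(rbind, rows)
}

#' Balanced 2x2 ANOVA on seed x target cell values
#'
#' Classical two-way ANOVA with seed (A/B) and target (A/B) as fixed
#' factors and the per-session Fisher-z correlation as the dependent
#' variable; fitted with [stats::aov()]. The design must be balanced
#' with n >= 2 per cell; the interaction is tested on (1, 4(n-1))
#' degrees of freedom against the exact F distribution.
#'
#' @param cells data.frame from [extract_cell_values()] (columns
#'   `seed`, `target`, `z`).
#' @param zone Zone label stored on the result.
#' @return An `anova_result`: cell means, F and p for both main
#'   effects and the interaction, df, `crossover_class`, `n_per_cell`.
#' @export
anova_2x2 <- function(cells, zone = NA) {
  counts <- table(cells$seed, cells$target)
  if (length(counts) != 4 || length(unique(as.vector(counts))) != 1) {
    stop("design is unbalanced: equal n per cell required", call. = FALSE)
  }
  n <- counts[1, 1]
  if (n < 2) stop("need n >= 2 per cell", call. = FALSE)
  d <- data.frame(seed = factor(cells$seed), target = factor(cells$target),
                  z = cells$z)
  cm <- tapply(d$z, list(d$seed, d$target), mean)
  df2 <- 4L * (as.integer(n) - 1L)
  if (stats::var(d$z) == 0) {      # degenerate constant input: no effect
    return(structure(
      list(zone = zone, cell_means = cm, F_seed = 0, F_target = 0,
           F_interaction = 0, df = c(1L, df2), p_interaction = 1,
           crossover_class = classify_crossover(cm),
           n_per_cell = as.integer(n)),
      class = "anova_result"))
  }
  fit <- stats::aov(z ~ seed * target, data = d)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  structure(
    list(zone = zone,
         cell_means = cm,
         F_seed = tab["seed", "F value"],
         F_target = tab["target", "F value"],
         F_interaction = tab["seed:target", "F value"],
         df = c(1L, df2),
         p_interaction = tab["seed:target", "Pr(>F)"],
         crossover_class = classify_crossover(cm),
         n_per_cell = as.integer(n)),
    class = "anova_result")
}

#' Classify a 2x2 interaction pattern
#'
#' `crossover` when each seed correlates more strongly with its own
#' network's target than with the other network's target in both
#' directions (`AA > AB` and `BB > BA`); `ordinal` when the interaction
#' contrast `AA - AB - BA + BB` is positive but one direction fails;
#' `none` otherwise (ties count as failures).
#'
#' @param cell_means 2x2 matrix of cell means, rows = seed (a, b),
#'   columns = target (a, b).
#' @return One of `"crossover"`, `"ordinal"`, `"none"`.
#' @export
classify_crossover <- function(cell_means) {
  aa <- cell_means["a", "a"]; ab <- cell_means["a", "b"]
  ba <- cell_means["b", "a"]; bb <- cell_means["b", "b"]
  if (aa > ab && bb > ba) return("crossover")
  if ((aa - ab - ba + bb) > 0) return("ordinal")
  "none"
}

#' Run the full dissociation battery
#'
#' One balanced 2x2 ANOVA per subject and target zone, on replication
#' sessions only, with regions that were selected from discovery data
#' (the provenance label is enforced — a region set not derived from
#' discovery data is refused). The lone-region pairing, when present,
#' contributes one extra test per subject in which the lone network-A
#' region is paired with the partner zone's network-B region. No
#' multiple-testing correction is applied across tests — the design
#' argues by convergence of repeated significant results — but the
#' expected number of false positives under the global null is
#' reported for transparency.
#'
#' @param study A preprocessed `study_dataset`.
#' @param regions_per_subject List of `region_set`, one per subject.
#' @param alpha Significance level (default 0.01).
#' @return A `dissociation_report`: `results` data.frame (one row per
#'   test), `n_tests`, `n_significant`, `n_crossover`, `alpha`,
#'   `expected_null_significant`.
#' @export
run_battery <- function(study, regions_per_subject, alpha = 0.01) {
  if (length(regions_per_subject) != length(study$subjects)) {
    stop("need one region set per subject", call. = FALSE)
  }
  rows <- list()
  details <- list()
  for (s in seq_along(study$subjects)) {
    regions <- regions_per_subject[[s]]
    if (is.null(regions)) {
      stop("missing regions for subject ", s, call. = FALSE)
    }
    if (!identical(regions$provenance, "discovery")) {
      stop("firewall: regions for subject ", s,
           " were not derived from discovery data (provenance: ",
           regions$provenance, ")", call. = FALSE)
    }
    repl <- study_sessions(study, s, "replication")
    test_one <- function(zone_label, ta, tb) {
      cells <- extract_cell_values(repl, regions$seed_a, regions$seed_b,
                                   ta, tb)
      res <- anova_2x2(cells, zone = zone_label)
      details[[length(details) + 1]] <<- res
      data.frame(
        subject = s, zone = as.character(zone_label),
        mean_aa = res$cell_means["a", "a"],
        mean_ab = res$cell_means["a", "b"],
        mean_ba = res$cell_means["b", "a"],
        mean_bb = res$cell_means["b", "b"],
        F_interaction = res$F_interaction,
        df1 = res$df[1], df2 = res$df[2],
        p_interaction = res$p_interaction,
        crossover_class = res$crossover_class,
        significant = res$p_interaction < alpha)
    }
    for (zi in seq_along(regions$target_zones)) {
      zid <- regions$target_zones[zi]
      rows[[length(rows) + 1]] <-
        test_one(zid, regions$targets["a", zi], regions$targets["b", zi])
    }
    if (!is.null(regions$lone)) {
      partner_col <- match(regions$lone$partner_zone, regions$target_zones)
      rows[[length(rows) + 1]] <- test_one(
        paste0("lone", regions$lone$zone),
        regions$lone$vertex,
        regions$targets["b", partner_col])
    }
  }
  results <- do.call(rbind, rows)
  structure(
    list(results = results,
         details = details,
         n_tests = nrow(results),
         n_significant = sum(results$significant),
         n_crossover = sum(results$crossover_class == "crossover"),
         alpha = alpha,
         expected_null_significant = alpha * nrow(results)),
    class = "dissociation_report")
}

#' @export
print.dissociation_report <- function(x, ...) {
  cat("dissociation_report:", x$n_tests, "2x2 ANOVAs;",
      x$n_significant, "significant at p <", x$alpha,
      "(", x$n_crossover, "crossover );",
      "null expectation", x$expected_null_significant, "\n")
  invisible(x)
}
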