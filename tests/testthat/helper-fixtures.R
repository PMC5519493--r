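# shared fixture builders; everything is generated in code at test time

# small planted study: level-2 mesh (162 vertices/hemisphere), 6 zones,
# parcels of radius 1, two networks
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(subdivision_level = 2, n_subjects = 1, n_sessions = 4,
         frames_per_run = 150, n_networks = 2, n_zones = 6,
         parcel_radius = 1, zone_radius = 2, jitter_steps = 0,
         network_loading = 1.0, vertex_noise_sd = 1.0,
         global_signal_sd = 0.5, master_seed = 1),
    list(...))
  do.call(generator_params, args)
}

tiny_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_icosphere(2)
    cache
  }
})

tiny_template <- function(jitter_steps = 0, subject_seed = 1) {
  plant_networks(tiny_mesh(), n_networks = 2, n_zones = 6,
                 parcel_radius = 1, zone_radius = 2,
                 jitter_steps = jitter_steps, subject_seed = subject_seed)
}

# session with hand-made data matrix on an arbitrary vertex space
manual_session <- function(data, tr = 1, nuisance = NULL, run_id = 1L,
                           subject_id = 1L) {
  if (is.null(nuisance)) {
    nuisance <- data.frame(matrix(numeric(0), nrow = ncol(data), ncol = 0))
  }
  structure(
    list(data = data, tr_seconds = tr, nuisance = nuisance,
         run_id = as.integer(run_id), subject_id = as.integer(subject_id),
         rng_seed = NA_integer_,
         dataset_label = if (run_id %% 2 == 1) "discovery" else "replication"),
    class = "session_ts")
}

# z_connectivity built directly from a hand-made z matrix
manual_zconn <- function(z, label = "discovery") {
  diag(z) <- atanh(1 - 1e-7)
  structure(list(z = z, n_runs_averaged = 1L, dataset_label = label,
                 mask = rep(FALSE, nrow(z))),
            class = "z_connectivity")
}

# independent two-pass Pearson correlation oracle (per pair, no shortcuts)
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force balanced two-way ANOVA oracle from explicit sums of squares
anova_ss_oracle <- function(cells) {
  # cells: data.frame seed, target, z; balanced 2x2
  n <- nrow(cells) / 4
  grand <- mean(cells$z)
  m_seed <- tapply(cells$z, cells$seed, mean)
  m_target <- tapply(cells$z, cells$target, mean)
  m_cell <- tapply(cells$z, list(cells$seed, cells$target), mean)
  ss_seed <- 2 * n * sum((m_seed - grand)^2)
  ss_target <- 2 * n * sum((m_target - grand)^2)
  ss_cells <- n * sum((m_cell - grand)^2)
  ss_int <- ss_cells - ss_seed - ss_target
  ss_tot <- sum((cells$z - grand)^2)
  ss_within <- ss_tot - ss_cells
  df_within <- 4 * (n - 1)
  list(F_seed = ss_seed / (ss_within / df_within),
       F_target = ss_target / (ss_within / df_within),
       F_interaction = ss_int / (ss_within / df_within),
       p_interaction = stats::pf(ss_int / (ss_within / df_within),
                                 1, df_within, lower.tail = FALSE))
}

# null battery ingredients: a no-network study on a level-1 mesh with
# arbitrary distinct region vertices; returns a dissociation_report
null_battery <- function(master_seed, n_subjects = 4, n_zones = 5,
                         frames = 128, n_sessions = 8) {
  p <- generator_params(subdivision_level = 1, n_subjects = n_subjects,
                        n_sessions = n_sessions, frames_per_run = frames,
                        n_networks = 1, n_zones = 2, parcel_radius = 1,
                        zone_radius = 2, jitter_steps = 0,
                        network_loading = 0, vertex_noise_sd = 1,
                        global_signal_sd = 0.5, master_seed = master_seed)
  study <- simulate_study(p)
  study <- preprocess_study(study, preproc_params(n_discard = 4,
                                                  smooth_fwhm_mm = 0))
  nv <- study$mesh$n_vertices
  regions <- lapply(seq_len(n_subjects), function(s) {
    verts <- seq(1, nv, length.out = 2 + 2 * n_zones)
    verts <- as.integer(round(verts))
    structure(
      list(subject_id = s, seed_a = verts[1], seed_b = verts[2],
           target_zones = seq_len(n_zones),
           targets = matrix(verts[-(1:2)], nrow = 2,
                            dimnames = list(c("a", "b"), NULL)),
           lone = NULL, provenance = "discovery"),
      class = "region_set")
  })
  run_battery(study, regions, alpha = 0.01)
}
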