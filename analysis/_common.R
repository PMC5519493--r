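# Shared setup for the numbered analysis drivers.
#
# Desk-scale study conditions used throughout the analyses: a level-2
# two-hemisphere icosphere (162 vertices per hemisphere), 4 subjects,
# 24 sessions of 300 frames at TR = 1 s, two networks interdigitated
# across 6 zones (parcels of radius 1, subject jitter 1 hop), network
# loading 1.0 against unit-variance vertex noise. The simulated and
# preprocessed studies are cached under scratch/ so the drivers can be
# run in any order without recomputation.

library(interdigitate)

STUDY_SEED <- 20
RESULTS <- "results"
CACHE <- "scratch/analysis_cache"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
dir.create(CACHE, showWarnings = FALSE, recursive = TRUE)

study_params <- function() {
  generator_params(
    subdivision_level = 2, n_subjects = 4, n_sessions = 24,
    frames_per_run = 300, n_networks = 2, n_zones = 6,
    parcel_radius = 1, zone_radius = 2, jitter_steps = 1,
    network_loading = 1.0, vertex_noise_sd = 1.0, global_signal_sd = 0.5,
    master_seed = STUDY_SEED)
}

cached <- function(name, compute) {
  path <- file.path(CACHE, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- compute()
  saveRDS(value, path)
  value
}

get_raw_study <- function() {
  cached("raw_study", function() simulate_study(study_params()))
}

get_study <- function() {
  cached("preprocessed_study", function()
    preprocess_study(get_raw_study(), preproc_params()))
}

get_fc <- function() {
  cached("fc", function() {
    study <- get_study()
    lapply(seq_along(study$subjects), function(s) list(
      discovery = mean_z_matrix(study_sessions(study, s, "discovery"),
                                "discovery"),
      replication = mean_z_matrix(study_sessions(study, s, "replication"),
                                  "replication")))
  })
}

get_regions <- function() {
  cached("regions", function() {
    study <- get_study()
    fc <- get_fc()
    lapply(seq_along(study$subjects), function(s) {
      tpl <- study$subjects[[s]]$template
      pair <- find_seed_pair(fc[[s]]$discovery, 1, tpl$zones,
                             seed_criteria(), study$mesh)
      select_regions(fc[[s]]$discovery, pair, tpl$zones,
                     target_zones = 2:6, subject_id = s)
    })
  })
}
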