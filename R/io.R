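#' Write a study dataset as a plain-text container
#'
#' Directory layout: `meta.json` (generator parameters and study
#' shape), `mesh_vertices.csv` / `mesh_faces.csv` / `mesh_hemisphere.csv`,
#' and per subject `subjects/<id>/template.csv` (vertex, network) plus
#' `subjects/<id>/sessions/<run>/data.csv` (vertex x time) and
#' `nuisance.tsv` (one column per regressor, header row).
#'
#' @param study A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_container <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    params = unclass(study$params),
    n_subjects = length(study$subjects),
    n_vertices = study$mesh$n_vertices,
    level = study$mesh$level)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  data.table::fwrite(data.table::as.data.table(study$mesh$vertices),
                     file.path(dir, "mesh_vertices.csv"))
  data.table::fwrite(data.table::as.data.table(study$mesh$faces),
                     file.path(dir, "mesh_faces.csv"))
  data.table::fwrite(
    data.table::data.table(vertex = seq_len(study$mesh$n_vertices),
                           hemisphere = as.character(study$mesh$hemisphere)),
    file.path(dir, "mesh_hemisphere.csv"))
  for (sub in study$subjects) {
    sdir <- file.path(dir, "subjects", sub$subject_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(
      data.table::data.table(vertex = seq_along(sub$template$assignment),
                             network = sub$template$assignment),
      file.path(sdir, "template.csv"))
    for (sess in sub$sessions) {
      rdir <- file.path(sdir, "sessions", sess$run_id)
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      data.table::fwrite(data.table::as.data.table(sess$data),
                         file.path(rdir, "data.csv"))
      data.table::fwrite(data.table::as.data.table(sess$nuisance),
                         file.path(rdir, "nuisance.tsv"), sep = "\t")
    }
  }
  invisible(dir)
}

#' Read a study dataset written by [write_study_container()]
#'
#' @param dir Container directory.
#' @return A `study_dataset` (the mesh is rebuilt from its subdivision
#'   level so adjacency is available; templates reload as assignment
#'   vectors with layout metadata from `meta.json`).
#' @export
read_study_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  params <- do.call(generator_params,
                    meta$params[names(meta$params) %in%
                                  names(formals(generator_params))])
  mesh <- build_icosphere(meta$level)
  subject_ids <- sort(as.integer(
    list.files(file.path(dir, "subjects"))))
  subjects <- lapply(subject_ids, function(s) {
    sdir <- file.path(dir, "subjects", s)
    tmpl_df <- data.table::fread(file.path(sdir, "template.csv"))
    template <- plant_networks(
      mesh, n_networks = params$n_networks, n_zones = params$n_zones,
      parcel_radius = params$parcel_radius,
      zone_radius = params$zone_radius,
      jitter_steps = params$jitter_steps,
      subject_seed = derive_seed(params$master_seed, 101L, s))
    template$assignment <- tmpl_df$network   # stored assignment wins
    run_ids <- sort(as.integer(list.files(file.path(sdir, "sessions"))))
    sessions <- lapply(run_ids, function(r) {
      rdir <- file.path(sdir, "sessions", r)
      data <- as.matrix(data.table::fread(file.path(rdir, "data.csv")))
      dimnames(data) <- NULL
      nuis <- as.data.frame(data.table::fread(file.path(rdir,
                                                        "nuisance.tsv")))
      structure(
        list(data = data, tr_seconds = params$tr_seconds, nuisance = nuis,
             run_id = r, subject_id = s, rng_seed = NA_integer_,
             dataset_label = if (r %% 2 == 1) "discovery" else "replication"),
        class = "session_ts")
    })
    list(subject_id = s, template = template, sessions = sessions)
  })
  structure(list(mesh = mesh, params = params, subjects = subjects),
            class = "study_dataset")
}

#' Write a QC map, FC map, or template as CSV
#'
#' @param x A `qc_map`, `fc_map`, or per-vertex numeric vector.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vertex_map <- function(x, path) {
  values <- if (is.list(x)) x$values else x
  data.table::fwrite(
    data.table::data.table(vertex = seq_along(values), value = values),
    path)
  invisible(path)
}
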