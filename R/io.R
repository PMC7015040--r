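#' Write a simulation run to disk
#'
#' The sampled trajectory goes to CSV (one row per log step), the event
#' times and summary to JSON; re-reading reproduces the numeric arrays to
#' full double precision.
#'
#' @param run result of [run_walking()]
#' @param dir output directory (created if missing)
#' @param prefix file name prefix
#' @param cfg configuration to record in the manifest (optional)
#' @return invisibly, the paths written
#' @export
write_run <- function(run, dir, prefix = "run", cfg = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj_path <- file.path(dir, paste0(prefix, "_trajectory.csv"))
  ev_path <- file.path(dir, paste0(prefix, "_events.json"))
  utils::write.csv(as.data.frame(run$traj), traj_path, row.names = FALSE)
  summary <- list(status = run$status, t_end = run$t_end,
                  fall_time = run$fall_time, events = run$events)
  jsonlite::write_json(summary, ev_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(trajectory = traj_path, events = ev_path)
  if (!is.null(cfg)) {
    mf <- file.path(dir, paste0(prefix, "_manifest.json"))
    write_manifest(mf, cfg, files = paths)
    paths <- c(paths, manifest = mf)
  }
  invisible(paths)
}

#' Read a trajectory written by [write_run()]
#' @param path CSV path
#' @return numeric matrix with the original column names
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df)
}

#' Write a PRC estimate table
#'
#' Tidy CSV with one row per (phase, direction) trial plus a JSON feature
#' summary.
#'
#' @param est data.frame from [run_prc_experiment()]
#' @param dir output directory
#' @param prefix file name prefix
#' @param double_stance optional double-stance intervals (% cycle) for the
#'   feature annotation
#' @return invisibly, the paths written
#' @export
write_prc <- function(est, dir, prefix = "prc", double_stance = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- file.path(dir, paste0(prefix, "_table.csv"))
  utils::write.csv(est, tab, row.names = FALSE)
  feat_path <- file.path(dir, paste0(prefix, "_features.json"))
  feats <- lapply(split(est[est$ok, ], est$direction[est$ok]), function(d) {
    if (sum(is.finite(d$Z)) >= 3) extract_features(d, double_stance)
    else NULL
  })
  jsonlite::write_json(feats, feat_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(table = tab, features = feat_path))
}

#' Write a run manifest
#'
#' Records the configuration hash, schema version, package version, start
#' time and output file inventory so a run can be reproduced from its
#' manifest and config alone.
#'
#' @param path output JSON path
#' @param cfg configuration list
#' @param files named character vector of produced files
#' @param seed optional RNG seed used
#' @export
write_manifest <- function(path, cfg, files = character(0), seed = NULL) {
  mf <- list(
    config_hash = config_hash(cfg),
    preset = cfg$preset,
    schema_version = cfg$schema_version,
    package_version = as.character(utils::packageVersion("prcgait")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    files = as.list(files))
  jsonlite::write_json(mf, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
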