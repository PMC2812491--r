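# Plain-text serialization: protocol YAML, observations CSV, trajectory
# CSV, clone table CSV, ensemble archive directory, JSON run manifests.

#' Read / write a simulation protocol (YAML)
#'
#' YAML layout: `t_end_hr`, optional `output_times_hr`, optional `events`
#' (list of maps with `time_hr`, `kind`, `target`, `value`).
#'
#' @param path file path.
#' @return a [kin_protocol()].
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  events <- NULL
  if (!is.null(y$events)) {
    events <- dplyr::bind_rows(lapply(y$events, tibble::as_tibble))
  }
  kin_protocol(events = events, t_end_hr = y$t_end_hr,
               output_times_hr = unlist(y$output_times_hr))
}

#' @rdname read_protocol
#' @param protocol a [kin_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  y <- list(t_end_hr = protocol$t_end_hr,
            output_times_hr = as.numeric(protocol$output_times_hr))
  if (nrow(protocol$events)) {
    y$events <- lapply(seq_len(nrow(protocol$events)), function(i)
      as.list(protocol$events[i, ]))
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read / write observations (CSV)
#'
#' Columns: `dataset_id`, `species_id`, `condition`, `value`, `std`.
#'
#' @param path file path.
#' @return a tibble of observations.
#' @export
read_observations <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(condition = "character")))
}

#' @rdname read_observations
#' @param observations observation tibble.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a trajectory as CSV (time plus one column per species)
#'
#' @param trajectory a `kin_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Write / read an ensemble archive
#'
#' A plain-text directory: `members.csv` (one row per member, one column
#' per parameter), `errors.csv`, and `meta.json` (chain configuration,
#' thinning interval, provenance, template label).
#'
#' @param ensemble a `kin_ensemble`.
#' @param dir archive directory (created if missing).
#' @return `write_ensemble()` the directory path; `read_ensemble()` a
#'   `kin_ensemble`.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(ensemble$members),
                   file.path(dir, "members.csv"), row.names = FALSE)
  utils::write.csv(data.frame(error = ensemble$errors),
                   file.path(dir, "errors.csv"), row.names = FALSE)
  meta <- list(interval = ensemble$interval,
               provenance = as.data.frame(ensemble$provenance),
               config = unclass(ensemble$config),
               label = ensemble$template$label,
               template = as.list(as_theta(ensemble$template)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  members <- as.matrix(utils::read.csv(file.path(dir, "members.csv"),
                                       check.names = FALSE))
  errors <- utils::read.csv(file.path(dir, "errors.csv"))$error
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- meta$config
  config <- kin_chain_config(sigma = cfg$sigma, E0 = cfg$E0,
                             n_steps = cfg$n_steps, seed = cfg$seed,
                             block_size = cfg$block_size)
  template <- theta_to_params(unlist(meta$template), list(label = meta$label))
  structure(list(members = members, errors = errors,
                 interval = as.integer(meta$interval),
                 provenance = tibble::as_tibble(meta$provenance),
                 config = config, template = template),
            class = "kin_ensemble")
}

#' Write a JSON run manifest next to an artifact
#'
#' Every pipeline artifact records the configuration, seed and package
#' version that produced it, so it can be reproduced from the manifest
#' alone.
#'
#' @param path manifest path (`*.json`).
#' @param stage pipeline stage name.
#' @param config named list of stage settings (must include any seed used).
#' @export
write_manifest <- function(path, stage, config) {
  manifest <- list(stage = stage, config = config,
                   package_version = as.character(utils::packageVersion("enkin")),
                   written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
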