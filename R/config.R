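# YAML config plumbing for the command-line entry points.

#' Build a scene specification from a YAML config
#'
#' The config mirrors the [scene_spec()] arguments: scalar fields plus
#' `guvs` (list of records) and `puncta` (map channel role -> list of
#' records).
#'
#' @param config path to a YAML file, or an already-parsed list.
#' @param seed optional seed overriding the config's.
#' @return a [scene_spec()].
#' @export
scene_spec_from_config <- function(config, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- seed
  config$guvs <- do.call(rbind, lapply(config$guvs, as.data.frame))
  config$puncta <- lapply(config$puncta,
                          function(p) do.call(rbind, lapply(p, as.data.frame)))
  do.call(scene_spec, config)
}

#' Build a trajectory specification from a YAML config
#'
#' The config mirrors the [traj_spec()] arguments; `contact_schedule` and
#' `ion_schedule` are lists of records.
#'
#' @param config path to a YAML file, or an already-parsed list.
#' @param seed optional seed overriding the config's.
#' @return a [traj_spec()].
#' @export
traj_spec_from_config <- function(config, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- seed
  for (f in c("contact_schedule", "ion_schedule"))
    if (!is.null(config[[f]]))
      config[[f]] <- do.call(rbind, lapply(config[[f]], as.data.frame))
  if (!is.null(config$residues)) config$residues <- unlist(config$residues)
  if (!is.null(config$box)) config$box <- unlist(config$box)
  do.call(traj_spec, config)
}

#' Build pipeline parameters from a YAML config
#'
#' @param config path to a YAML file, or an already-parsed list; missing
#'   fields keep their defaults.
#' @return a [pipeline_params()].
#' @export
pipeline_params_from_config <- function(config) {
  if (is.null(config)) return(pipeline_params())
  if (is.character(config)) config <- yaml::read_yaml(config)
  do.call(pipeline_params, config)
}
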