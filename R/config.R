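#' Load a simulator configuration from YAML
#'
#' The YAML keys mirror the arguments of [tap_sim_config()]; nested blocks
#' `hesitation:` and `camera:` are passed through.
#'
#' @param path YAML file.
#' @return A [tap_sim_config()].
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(tap_sim_config, cfg)
}

#' Load an augmentation policy from YAML
#'
#' The YAML keys mirror the arguments of [augment_policy()]; the `stages`
#' entry names the training / model-picking / inference stages at which 3D
#' rotation applies, matching the named ablation variants (t, tp, ti, tpi).
#'
#' @param path YAML file, or a list already parsed from one (e.g. the
#'   `augment:` block of a training config).
#' @return An [augment_policy()].
#' @export
read_augment_policy <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  do.call(augment_policy, cfg)
}
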