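#' Build a synthetic-data spec from a structured config file
#'
#' Reads a YAML file whose top-level `type` selects the generator
#' (`"two_mode"`, `"phase_oscillator"` or `"cohort"`) and whose remaining
#' keys are passed to the matching spec constructor ([two_mode_spec()],
#' [phase_oscillator_spec()], [cohort_spec()]). Frequency trajectories
#' cannot be expressed in YAML and keep their defaults; `coupled_pairs`
#' is given as a list of two-element label lists.
#'
#' @param path Path to the YAML config.
#' @return The constructed spec object.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("type: phase_oscillator", "E: 5", "duration: 60",
#'              "seed: 1"), cfg)
#' spec_from_config(cfg)
#' @export
spec_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  type <- cfg$type %||% stop("config needs a top-level `type`", call. = FALSE)
  cfg$type <- NULL
  switch(
    type,
    two_mode = do.call(two_mode_spec, cfg),
    phase_oscillator = do.call(phase_oscillator_spec, cfg),
    cohort = {
      if (!is.null(cfg$coupled_pairs)) {
        cfg$coupled_pairs <- lapply(cfg$coupled_pairs, unlist)
      }
      if (!is.null(cfg$n_per_group)) cfg$n_per_group <- unlist(cfg$n_per_group)
      if (!is.null(cfg$channel_labels)) {
        cfg$channel_labels <- unlist(cfg$channel_labels)
      }
      if (!is.null(cfg$amplitudes)) cfg$amplitudes <- unlist(cfg$amplitudes)
      do.call(cohort_spec, cfg)
    },
    stop(sprintf("unknown config type '%s'", type), call. = FALSE)
  )
}
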