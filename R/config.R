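# Run configuration: a versioned schema carrying every analysis threshold,
# serialisable to YAML.  Unknown keys are rejected so a misspelt threshold
# can never silently fall back to a default.

.DEFAULT_CONFIG <- function() list(
  version = 1L,
  seed = 1L,
  output_dir = NULL,
  input = NULL,       # list(topology, trajectory, psf, frame_interval)
  scenario = NULL,    # list(<scenario_spec fields>, events = list(...))
  stages = list(binding = TRUE, membrane = TRUE, interactions = TRUE,
                lipids = TRUE, gate = TRUE),
  residues = list(tilt = c(565L, 591L), gate_pair1 = c(564L, 473L),
                  gate_pair2 = c(562L, 476L),
                  gate_footprint = c(473L, 476L, 562L, 564L)),
  thresholds = list(
    hydrophobic_cutoff = 3.0,   # A
    min_consecutive = 2L,       # frames
    hbond_distance = 2.4,       # A, H...acceptor
    hbond_angle = 130,          # degrees, donor-H-acceptor minimum
    cation_pi_cutoff = 7.0,     # A, every ring atom to choline N
    snorkel_offset = -5,        # A below the phosphorus plane
    snorkel_fraction = 0.01,    # strict fraction-of-frames threshold
    contact_window = 20,        # ns, windowed contact series
    density_window = 500,       # ns, trailing window for density profiles
    binding_cutoff = 4.0,       # A
    binding_dwell = 10,         # ns
    gate_open_threshold = NULL, # A; NULL = KDE minimum between modes
    gate_min_dwell = 0,         # ns
    inserted_max = 45,          # degrees
    bilayer_min = 150,          # degrees
    footprint_radius = 15))     # A

.merge_config <- function(defaults, user, path = "") {
  .assert(is.list(user), "mi_config_error", "config%s must be a mapping", path)
  extra <- setdiff(names(user), names(defaults))
  .assert(!length(extra), "mi_config_error", "unknown config key%s: %s",
          path, paste(extra, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k %in% c("stages", "thresholds", "residues")) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, "$", k))
    } else {
      defaults[k] <- list(user[[k]])
    }
  }
  defaults
}

#' Build a run configuration
#'
#' Starts from the package defaults (every criterion at its standard
#' printed value: 3 A hydrophobic cutoff over 2 consecutive frames, 2.4 A /
#' 130 degree hydrogen bonds, 7 A cation-pi, snorkeling above -5 A for more
#' than 1 percent of frames, 20 ns contact windows, trailing 500 ns density
#' window) and overrides them with the supplied values.  Unknown keys are
#' an error.
#'
#' @param ... top-level overrides (`seed`, `scenario`, `input`, `stages`,
#'   `residues`, `thresholds`, `output_dir`).
#' @return class `mi_run_config`.
#' @export
run_config <- function(...) {
  cfg <- .merge_config(.DEFAULT_CONFIG(), list(...))
  th <- cfg$thresholds
  for (k in c("hydrophobic_cutoff", "hbond_distance", "cation_pi_cutoff",
              "binding_cutoff", "footprint_radius", "contact_window"))
    .assert(th[[k]] > 0, "mi_config_error", "threshold %s must be positive", k)
  .assert(th$min_consecutive >= 1, "mi_config_error",
          "min_consecutive must be >= 1")
  structure(cfg, class = "mi_run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML round-trip is lossless: reading a written config reproduces the
#' configuration, and unknown keys in a file are rejected.
#'
#' @param path YAML file.
#' @param config an `mi_run_config`.
#' @return `read_run_config`: an `mi_run_config`; `write_run_config`: the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$version))
    .assert(raw$version == 1, "mi_config_error",
            "unsupported config schema version %s", raw$version)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical YAML serialisation of the analysis-relevant fields
#' (`output_dir` is excluded: where results land does not change what they
#' are); stamped into every CSV the pipeline writes so outputs are traceable
#' to the exact thresholds used.
#'
#' @param config an `mi_run_config`.
#' @return character hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}
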