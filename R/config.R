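# Configuration: YAML or JSON, sections world / cohort / protocol / stats.
# Every section is optional; omitted fields fall back to the package
# defaults, and the resolved configuration is echoed into reports for
# provenance.

#' Default configuration
#'
#' @return Nested list with sections `world`, `cohort`, `protocol`,
#'   `stats`, mirroring the constructor defaults of [world_config()],
#'   [cohort_spec()] and [protocol_spec()].
#' @export
default_config <- function() {
  list(
    world = list(
      viewing_distance_m = 6,
      balloon_diameter_m = 0.5,
      lateral_offsets_m = c(0, 0.5, 1),
      eye_height_m = 1.6
    ),
    cohort = list(
      n_subjects = 19L,
      pfv_mean = 18, pfv_sd = 3,
      nfv_mean = 10, nfv_sd = 2,
      baseline_bias_mean = 0.65,
      motor_noise_sd = 0.25,
      prop_glasses = 0.684
    ),
    protocol = list(
      shots_per_condition = 40L,
      conditions = CONDITION_LEVELS,
      control_first = TRUE
    ),
    stats = list(
      alpha = 0.05,
      adjust = "none"
    )
  )
}

#' Read a configuration file (YAML or JSON)
#'
#' Unknown sections or fields raise an error; known fields override the
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   defaults.
#' @return Resolved configuration list (see [default_config()]).
#' @export
read_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(base, user)
}

merge_config <- function(base, user, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base)) stop("unknown config field: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) stop("config field must be a mapping: ", full)
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(full, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

# Constructors from a resolved configuration.
config_world <- function(cfg) {
  w <- cfg$world
  world_config(w$viewing_distance_m, w$balloon_diameter_m,
               w$lateral_offsets_m, w$eye_height_m)
}

config_cohort_spec <- function(cfg) {
  cspec <- cfg$cohort
  cohort_spec(
    n_subjects = cspec$n_subjects,
    pfv_mean = cspec$pfv_mean, pfv_sd = cspec$pfv_sd,
    nfv_mean = cspec$nfv_mean, nfv_sd = cspec$nfv_sd,
    baseline_bias_mean = cspec$baseline_bias_mean,
    motor_noise_sd = cspec$motor_noise_sd,
    prop_glasses = cspec$prop_glasses
  )
}

config_protocol_spec <- function(cfg) {
  protocol_spec(cfg$protocol$shots_per_condition, cfg$protocol$conditions)
}
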