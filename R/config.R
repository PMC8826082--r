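# Pipeline configuration: defaults, YAML loading, validation.

#' Default pipeline configuration
#'
#' Nested list of every tunable of the end-to-end pipeline, with the
#' documented defaults: the gradient design (4 levels per compound, step
#' x10), the ground-truth landscape, acquisition and noise settings,
#' kinetics (window 5, OD floor 0.003), niche-space options, and the
#' serial-transfer evolution model.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    design = list(levels_per_compound = 4L, log_step = 10,
                  pseudo_floor_decades = 1),
    landscape = list(mu0 = 0.7, deficit_per_mb = 0.25,
                     recovery_per_mb = 0.35, width = 1.2,
                     narrow_per_mb = 0.35,
                     narrowed_constituents = c("glucose", "SO4", "NH4"),
                     floor_mu = 0.02),
    study = list(replicates = 6L, t_end = 48, dt = 0.5, od0 = 0.001,
                 k_cap = 1.0, noise_sd_additive = 0.003,
                 noise_sd_multiplicative = 0.02, lag_h = 0),
    kinetics = list(window = 5L, od_floor = 0.003, blank_od = 0),
    niche = list(clip_negative = FALSE),
    evolution = list(total_days = 50, init_od = 0.05, k_cap = 1.0,
                     selection_od = c(0.01, 0.1),
                     rate_per_gen = 0.002, supply_per_mb = 1.5,
                     effect_mean = 0.5, diminishing_returns = 4,
                     effect_shape = 3,
                     f0 = 1e-4, fix_threshold = 0.999),
    seed = 1L,
    out_dir = "results"
  )
}

# Recursively overlay user values onto defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop("config section '", paste(path, collapse = "."),
         "' must be a mapping")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     c(path, nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

check_that <- function(ok, key, msg) {
  if (!ok) stop("invalid config at '", key, "': ", msg, call. = FALSE)
}

validate_config <- function(cfg) {
  check_that(cfg$design$log_step > 1, "design.log_step", "must be > 1")
  check_that(cfg$design$pseudo_floor_decades > 0,
             "design.pseudo_floor_decades", "must be positive")
  lv <- cfg$design$levels_per_compound
  check_that(all(lv >= 0) && (length(lv) == 1 || !is.null(names(lv))),
             "design.levels_per_compound",
             "must be a single count or a named vector")
  check_that(cfg$study$replicates >= 1, "study.replicates", "must be >= 1")
  check_that(cfg$study$dt > 0 && cfg$study$t_end >= cfg$study$dt,
             "study.t_end", "need dt > 0 and t_end >= dt")
  check_that(cfg$kinetics$window >= 2, "kinetics.window", "must be >= 2")
  check_that(cfg$kinetics$od_floor > 0, "kinetics.od_floor",
             "must be positive")
  sel <- cfg$evolution$selection_od
  check_that(length(sel) == 2 && sel[1] < sel[2],
             "evolution.selection_od", "upper bound must exceed lower")
  check_that(cfg$evolution$f0 > 0 && cfg$evolution$f0 < 1,
             "evolution.f0", "must be in (0, 1)")
  check_that(is.numeric(cfg$seed) && length(cfg$seed) == 1,
             "seed", "must be a single integer")
  cfg
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, overlays it on [default_config()], rejects unknown
#' keys (naming the offending key path) and validates the constraints. An
#' empty file yields the full defaults.
#'
#' @param path Path to a YAML config file, or NULL for pure defaults.
#' @return Validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  validate_config(merge_config(default_config(), user))
}
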