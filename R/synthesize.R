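# Synthetic growth-curve generator with known ground truth.

# Evaluate an expression with a temporary RNG state; restores the caller's.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stable 31-bit string hash for deriving per-curve RNG substreams from a
# master seed plus metadata; arithmetic stays below 2^53 so it is exact.
stable_hash <- function(...) {
  s <- paste(..., sep = "\r")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Growth-model parameters for the synthetic generator
#'
#' Lagged exponential growth to a sharp carrying-capacity ceiling, with
#' plate-reader-like noise: after a lag of `lag_h` hours the deterministic
#' curve grows exponentially from `od0` at rate `mu_true` until it hits
#' `k_cap` (the substrate-exhaustion limit: in minimal media the Monod
#' half-saturation constant is far below the initial substrate level, so
#' the rate holds near its maximum until the ceiling). Observed OD adds
#' multiplicative Gaussian noise (fractional SD `noise_sd_multiplicative`)
#' and additive Gaussian noise (`noise_sd_additive`, OD units), floored at
#' zero.
#'
#' @param mu_true Intrinsic maximal growth rate, 1/h; must be in (0, 2].
#' @param od0 Initial OD600 (> 0).
#' @param k_cap Carrying-capacity OD600 (> od0); may be `Inf` for pure
#'   exponential growth.
#' @param noise_sd_additive Additive OD noise SD (default 0.003, a typical
#'   plate-reader noise floor).
#' @param noise_sd_multiplicative Multiplicative noise SD as a fraction
#'   (default 0.02).
#' @param lag_h Lag before growth starts, hours.
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(mu_true, od0 = 0.001, k_cap = 1.0,
                          noise_sd_additive = 0.003,
                          noise_sd_multiplicative = 0.02,
                          lag_h = 0) {
  if (!is.finite(mu_true) || mu_true <= 0 || mu_true > 2) {
    stop("mu_true must be in (0, 2] 1/h")
  }
  if (!is.finite(od0) || od0 <= 0) stop("od0 must be positive")
  if (k_cap <= od0) stop("k_cap must exceed od0")
  if (noise_sd_additive < 0 || noise_sd_multiplicative < 0 || lag_h < 0) {
    stop("noise SDs and lag must be non-negative")
  }
  structure(list(mu_true = mu_true, od0 = od0, k_cap = k_cap,
                 noise_sd_additive = noise_sd_additive,
                 noise_sd_multiplicative = noise_sd_multiplicative,
                 lag_h = lag_h),
            class = "growth_params")
}

# Deterministic OD at times t: exponential growth after the lag, capped
# sharply at carrying capacity (the substrate-exhaustion limit of Monod
# kinetics: half-saturation constants are orders of magnitude below the
# initial substrate level, so the rate stays near-constant until the
# ceiling). Vectorised over t.
growth_od <- function(t, mu, od0, k_cap, lag = 0) {
  pmin(od0 * exp(mu * pmax(t - lag, 0)), k_cap)
}

#' Simulate one plate-reader growth curve
#'
#' Emulates OD600 acquisition at fixed intervals (default every 30 min for
#' 48 h) from the capped-exponential model of [growth_params()]. The same
#' `seed` and parameters give a bitwise-identical curve; the caller's RNG
#' state is untouched.
#'
#' @param params A `growth_params` object.
#' @param t_end Total duration, h.
#' @param dt Sampling interval, h (> 0); the curve has `floor(t_end/dt)+1`
#'   reads.
#' @param seed Integer seed for the noise draws.
#' @param genome,population,combination_id,replicate Metadata carried on
#'   the curve.
#' @return A `growth_curve` object (see [growth_curve()]).
#' @export
simulate_growth_curve <- function(params, t_end = 48, dt = 0.5, seed = 1,
                                  genome = NA_character_,
                                  population = NA_character_,
                                  combination_id = NA_character_,
                                  replicate = NA_integer_) {
  stopifnot(inherits(params, "growth_params"))
  if (dt <= 0 || t_end < dt) stop("need dt > 0 and t_end >= dt")
  times <- seq(0, by = dt, length.out = floor(t_end / dt) + 1L)
  od <- growth_od(times, params$mu_true, params$od0, params$k_cap,
                    params$lag_h)
  if (params$noise_sd_additive > 0 || params$noise_sd_multiplicative > 0) {
    od <- with_seed(seed, {
      n <- length(od)
      obs <- od * (1 + stats::rnorm(n, 0, params$noise_sd_multiplicative)) +
        stats::rnorm(n, 0, params$noise_sd_additive)
      pmax(obs, 0)
    })
  }
  growth_curve(times, od, genome = genome, population = population,
               combination_id = combination_id, replicate = replicate)
}

#' Synthetic fitness landscape with built-in, recoverable effects
#'
#' Ground truth for the study simulator: for each (genome, population,
#' constituent) the intrinsic maximal growth rate responds unimodally
#' (Gaussian in log10 concentration) to the constituent's concentration,
#' peaking at the reference-medium concentration. Genome reduction lowers
#' the peak rate (`deficit_per_mb` fractional loss per Mb deleted) and, for
#' the constituents in `narrowed_constituents`, narrows the response width;
#' evolution recovers the peak by a deletion-dependent factor
#' (1 + `recovery_per_mb` per Mb) and restores the full width.
#'
#' @param design A `nichespan_design`; response peaks are placed at its
#'   reference (C0) constituent concentrations.
#' @param genomes Data frame with columns `genome` and `deletion_kb`.
#'   Default: the five-strain panel N0/N7/N14/N20/N28 with synthetic
#'   cumulative deletion sizes 0, 210, 610, 900 and 1230 kb.
#' @param mu0 Wild-type peak growth rate, 1/h.
#' @param deficit_per_mb Fractional loss of ancestral peak rate per Mb of
#'   deletion.
#' @param recovery_per_mb Evolved-over-ancestral peak ratio exceeds 1 by
#'   this amount per Mb of deletion.
#' @param width Response width (SD of the Gaussian, log10 units).
#' @param narrow_per_mb Fractional width narrowing per Mb, applied to
#'   `narrowed_constituents` in ancestral populations.
#' @param narrowed_constituents Constituents whose ancestral breadth
#'   shrinks with genome reduction (default glucose, SO4, NH4).
#' @param floor_mu Baseline growth rate far from the peak, 1/h.
#' @return A list of class `nichespan_landscape` with a long `responses`
#'   data frame and the `genomes` table.
#' @export
fitness_landscape <- function(design,
                              genomes = default_genomes(),
                              mu0 = 0.7,
                              deficit_per_mb = 0.25,
                              recovery_per_mb = 0.35,
                              width = 1.2,
                              narrow_per_mb = 0.35,
                              narrowed_constituents = c("glucose", "SO4",
                                                        "NH4"),
                              floor_mu = 0.02) {
  stopifnot(inherits(design, "nichespan_design"))
  stopifnot(all(c("genome", "deletion_kb") %in% names(genomes)))
  ref <- design_combo(design, design$reference_id)
  peaks <- log10(ref$ions[constituent_names()])
  rows <- list()
  for (i in seq_len(nrow(genomes))) {
    g <- genomes$genome[i]
    mb <- genomes$deletion_kb[i] / 1000
    mu_anc <- mu0 * (1 - deficit_per_mb * mb)
    if (mu_anc <= floor_mu) {
      stop("deficit_per_mb drives ancestral peak rate of ", g,
           " to or below floor_mu")
    }
    rec <- 1 + recovery_per_mb * mb
    for (k in constituent_names()) {
      w_anc <- if (k %in% narrowed_constituents) {
        width * max(1 - narrow_per_mb * mb, 0.1)
      } else width
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g,
        population = c("Anc", "Evo"),
        constituent = k,
        peak_log10_conc = unname(peaks[k]),
        width = c(w_anc, width),
        mu_at_peak = c(mu_anc, min(mu_anc * rec, 2)),
        floor = floor_mu)
    }
  }
  structure(list(responses = do.call(rbind, rows), genomes = genomes),
            class = "nichespan_landscape")
}

#' @rdname fitness_landscape
#' @export
default_genomes <- function() {
  data.frame(genome = c("N0", "N7", "N14", "N20", "N28"),
             deletion_kb = c(0, 210, 610, 900, 1230))
}

landscape_row <- function(landscape, genome, population, constituent) {
  r <- landscape$responses
  i <- which(r$genome == genome & r$population == population &
               r$constituent == constituent)
  if (length(i) != 1) {
    stop("landscape has no response for (", genome, ", ", population, ", ",
         constituent, ")")
  }
  r[i, ]
}

# Unimodal response: floor + (peak - floor) * Gaussian in log10 conc.
response_mu <- function(row, conc) {
  x <- log10(pmax(conc, 1e-300))
  row$floor + (row$mu_at_peak - row$floor) *
    exp(-((x - row$peak_log10_conc)^2) / (2 * row$width^2))
}

#' Ground-truth growth rate of a genome in a medium combination
#'
#' Evaluates the landscape's unimodal response for the constituent(s) the
#' combination's varied compound contributes to, taking the minimum across
#' them (limiting-nutrient rule); the reference combination takes the
#' minimum over all eight constituents. Deterministic.
#'
#' @param landscape A `nichespan_landscape`.
#' @param genome,population Identifiers present in the landscape.
#' @param combo One element of a design's `combinations`, or a combination
#'   id resolved against `design`.
#' @param design Optional `nichespan_design` used to resolve a character
#'   `combo`.
#' @return Growth rate, 1/h.
#' @export
true_mu <- function(landscape, genome, population, combo, design = NULL) {
  stopifnot(inherits(landscape, "nichespan_landscape"))
  if (is.character(combo)) {
    if (is.null(design)) stop("design required to resolve combination id")
    combo <- design_combo(design, combo)
  }
  ks <- varied_constituents(combo)
  if (length(ks) == 0) ks <- constituent_names()
  mus <- vapply(ks, function(k) {
    row <- landscape_row(landscape, genome, population, k)
    response_mu(row, combo$ions[[k]])
  }, numeric(1))
  min(mus)
}

#' Simulate a full fitness-assay study
#'
#' Generates one growth curve per (genome, population, combination,
#' replicate) cell of the design, with the intrinsic rate taken from the
#' ground-truth landscape via [true_mu()]. Each curve's noise stream is
#' derived from the master seed and the cell's metadata by a stable hash,
#' so any subset regenerates identically.
#'
#' @param design A `nichespan_design`.
#' @param landscape A `nichespan_landscape`.
#' @param replicates Replicate wells per cell (default 6).
#' @param seed Master integer seed.
#' @param t_end,dt Acquisition window and interval, h.
#' @param od0,k_cap,noise_sd_additive,noise_sd_multiplicative,lag_h Passed
#'   to [growth_params()].
#' @param populations Populations to simulate (default Anc and Evo).
#' @return Long data frame: genome, population, combination_id, replicate,
#'   time_h, od600.
#' @export
simulate_study <- function(design, landscape, replicates = 6, seed = 1,
                           t_end = 48, dt = 0.5,
                           od0 = 0.001, k_cap = 1.0,
                           noise_sd_additive = 0.003,
                           noise_sd_multiplicative = 0.02,
                           lag_h = 0,
                           populations = c("Anc", "Evo")) {
  stopifnot(inherits(design, "nichespan_design"),
            inherits(landscape, "nichespan_landscape"))
  if (replicates < 1) stop("replicates must be >= 1")
  genomes <- landscape$genomes$genome
  out <- vector("list",
                length(genomes) * length(populations) *
                  length(design$combinations) * replicates)
  i <- 0L
  for (g in genomes) {
    for (p in populations) {
      for (cb in design$combinations) {
        mu <- true_mu(landscape, g, p, cb)
        for (r in seq_len(replicates)) {
          i <- i + 1L
          pars <- growth_params(
            mu_true = mu, od0 = od0, k_cap = k_cap,
            noise_sd_additive = noise_sd_additive,
            noise_sd_multiplicative = noise_sd_multiplicative,
            lag_h = lag_h)
          cv <- simulate_growth_curve(
            pars, t_end = t_end, dt = dt,
            seed = stable_hash(seed, g, p, cb$id, r),
            genome = g, population = p, combination_id = cb$id,
            replicate = r)
          out[[i]] <- data.frame(
            genome = g, population = p, combination_id = cb$id,
            replicate = r, time_h = cv$time_h, od600 = cv$od600)
        }
      }
    }
  }
  do.call(rbind, out)
}
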