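# Serial-transfer evolution simulator with stepwise mutation fixation.

#' Serial-transfer protocol constants
#'
#' Each day the culture is split into eight 10-fold serial dilutions
#' (10^1..10^8) and regrown; only the well caught in early exponential
#' phase (OD600 0.01-0.1) is carried forward. Transfers happen at 12- or
#' 24-h intervals depending on the growth rate.
#'
#' @param dilution_exponents Integer dilution exponents of the wells.
#' @param selection_od Two-element OD600 range defining early exponential
#'   phase.
#' @param total_days Length of the experiment, days.
#' @param k_cap Carrying-capacity OD600 of a well.
#' @param init_od Starting OD600 of the founding culture.
#' @return List of class `transfer_protocol`.
#' @export
transfer_protocol <- function(dilution_exponents = 1:8,
                              selection_od = c(0.01, 0.1),
                              total_days = 50,
                              k_cap = 1.0,
                              init_od = 0.05) {
  if (length(selection_od) != 2 || selection_od[1] >= selection_od[2]) {
    stop("selection_od must be an increasing range")
  }
  if (any(dilution_exponents < 1)) stop("dilution exponents must be >= 1")
  structure(list(dilution_exponents = as.integer(dilution_exponents),
                 selection_od = selection_od,
                 total_days = total_days, k_cap = k_cap,
                 init_od = init_od),
            class = "transfer_protocol")
}

#' Mutation-supply and sweep model
#'
#' Mutations arise as a Poisson process per generation at rate
#' `rate_per_gen * (1 + supply_per_mb * deletion_Mb)`, mirroring the
#' observation that reduced genomes accumulate mutations faster. Each
#' beneficial mutation sweeps deterministically (logistic allele-frequency
#' dynamics) one at a time; queued arrivals wait for the current sweep.
#' Effects on the growth rate are Gamma-distributed (shape
#' `effect_shape`) with mean
#' `effect_mean * exp(-diminishing_returns * mu_before)`, a
#' diminishing-returns epistasis in the current growth rate (slower
#' backgrounds gain more per mutation, within and between genomes), and
#' combine additively once fixed.
#'
#' @param rate_per_gen Baseline beneficial-mutation supply per generation.
#' @param supply_per_mb Supply scaling per Mb of genome deletion.
#' @param effect_mean Mean growth-rate effect of a mutation extrapolated
#'   to a non-growing background, 1/h.
#' @param diminishing_returns Exponential discount rate of the effect
#'   size with the pre-fixation growth rate, h.
#' @param effect_shape Gamma shape of the effect distribution (>= 1;
#'   larger means less dispersed effects).
#' @param f0 Initial allele frequency of a new mutation.
#' @param fix_threshold Frequency at which a sweep is recorded as fixed.
#' @return List of class `mutation_model`.
#' @export
mutation_model <- function(rate_per_gen = 0.002,
                           supply_per_mb = 1.5,
                           effect_mean = 0.5,
                           diminishing_returns = 4,
                           effect_shape = 3,
                           f0 = 1e-4,
                           fix_threshold = 0.999) {
  if (f0 <= 0 || f0 >= 1) stop("f0 must be in (0, 1)")
  if (fix_threshold <= f0 || fix_threshold > 1) {
    stop("fix_threshold must be in (f0, 1]")
  }
  if (effect_shape < 1) stop("effect_shape must be >= 1")
  structure(list(rate_per_gen = rate_per_gen, supply_per_mb = supply_per_mb,
                 effect_mean = effect_mean,
                 diminishing_returns = diminishing_returns,
                 effect_shape = effect_shape,
                 f0 = f0, fix_threshold = fix_threshold),
            class = "mutation_model")
}

#' One serial-transfer step
#'
#' Dilutes the current culture into the protocol's wells, grows each well
#' exponentially (capped at the well's carrying capacity) for
#' `interval_h` hours at rate `mu_now`, and selects the
#' well whose final OD lies in the early-exponential selection range; if
#' several qualify the largest dilution wins (fewest generations of
#' crowding). If no well qualifies, the well closest to the range on the
#' log-OD scale is chosen and flagged.
#'
#' @param current_od OD600 of the culture being transferred (> 0).
#' @param mu_now Current growth rate, 1/h (> 0).
#' @param protocol A `transfer_protocol`.
#' @param interval_h Incubation time, h.
#' @return List: `dilution_exponent`, `od_start` (theoretical post-dilution
#'   OD), `od_final`, `mu_estimate` (per the whole-transfer log-ratio),
#'   `generations_added`, `in_range`.
#' @export
step_transfer <- function(current_od, mu_now, protocol = transfer_protocol(),
                          interval_h = 24) {
  if (current_od <= 0) stop("current_od must be positive")
  if (mu_now <= 0) stop("mu_now must be positive")
  ks <- protocol$dilution_exponents
  starts <- current_od / 10^ks
  finals <- growth_od(interval_h, mu_now, starts, protocol$k_cap)
  lo <- protocol$selection_od[1]
  hi <- protocol$selection_od[2]
  ok <- finals >= lo & finals <= hi
  if (any(ok)) {
    sel <- max(which(ok))  # largest dilution among qualifiers
    in_range <- TRUE
  } else {
    dist <- pmax(log10(lo / finals), log10(finals / hi), 0)
    sel <- max(which(dist == min(dist)))
    in_range <- FALSE
    warning("no well in the selection OD range; choosing nearest (10^-",
            ks[sel], ")", call. = FALSE)
  }
  list(dilution_exponent = ks[sel],
       od_start = starts[sel],
       od_final = finals[sel],
       mu_estimate = transfer_rate(finals[sel], starts[sel], interval_h, 0),
       generations_added = generations(finals[sel], starts[sel]),
       in_range = in_range)
}

# Interval rule: transfer after 12 h if some well is predicted to reach
# the selection range's lower bound by then, else after 24 h.
choose_interval <- function(current_od, mu_now, protocol) {
  starts <- current_od / 10^protocol$dilution_exponents
  finals <- growth_od(12, mu_now, starts, protocol$k_cap)
  if (any(finals >= protocol$selection_od[1])) 12 else 24
}

#' Deterministic logistic selective sweep
#'
#' Allele frequency of a mutant with per-generation selection coefficient
#' `s` starting at frequency `f0`:
#' f(g) = f0 e^(s g) / (1 - f0 + f0 e^(s g)). Monotone increasing for
#' s > 0, approaching one.
#'
#' @param s Selection coefficient per generation.
#' @param f0 Initial frequency in (0, 1).
#' @param g Vector of generations (>= 0).
#' @return Frequencies in (0, 1).
#' @export
allele_frequency_series <- function(s, f0, g) {
  if (f0 <= 0 || f0 >= 1) stop("f0 must be in (0, 1)")
  # algebraically identical to f0 e^{sg} / (1 - f0 + f0 e^{sg}) but
  # stable when s*g overflows exp()
  f0 / (f0 + (1 - f0) * exp(-s * g))
}

#' Fitness ladder of sequentially fixed mutants
#'
#' Growth rates of the ancestor and of each successive mutant under the
#' additive model: mu_k = base_mu + sum of the first k effects. Effects
#' may be negative.
#'
#' @param base_mu Ancestral growth rate, 1/h.
#' @param effects Mutation effects in order of appearance.
#' @return Numeric vector of length `length(effects) + 1`.
#' @export
mutant_ladder_fitness <- function(base_mu, effects = numeric(0)) {
  c(base_mu, base_mu + cumsum(effects))
}

#' Simulate one serial-transfer evolution experiment
#'
#' Runs the transfer protocol for `protocol$total_days` days. Between
#' transfers the population grows at its current mean rate; mutation
#' arrivals follow the supply model, sweep one at a time with
#' deterministic logistic dynamics (selection coefficient per generation
#' ln(2) * effect / mu), and add their effect to the growth rate once past
#' the fixation threshold. The population mean rate during a sweep is
#' base + f * effect.
#'
#' @param base_mu Ancestral growth rate in the evolution medium, 1/h.
#' @param deletion_kb Genome deletion size, kb (scales mutation supply).
#' @param protocol A `transfer_protocol`.
#' @param model A `mutation_model`.
#' @param seed Integer seed.
#' @param genome Genome label carried into the outputs.
#' @return Object of class `evolution_trajectory`: data frame
#'   `transfers` (day, interval_h, dilution_exponent, od_transfer,
#'   mu_estimate, mu_true, cum_generations, n_fixed, active_mutation,
#'   allele_freq, in_range) and data frame `mutations` (label, effect,
#'   appearance_generation, fixation_generation, mu_before), plus
#'   `base_mu` and `genome`.
#' @export
run_evolution <- function(base_mu, deletion_kb = 0,
                          protocol = transfer_protocol(),
                          model = mutation_model(),
                          seed = 1,
                          genome = NA_character_) {
  stopifnot(inherits(protocol, "transfer_protocol"),
            inherits(model, "mutation_model"))
  if (base_mu <= 0) stop("base_mu must be positive")
  lambda <- model$rate_per_gen * (1 + model$supply_per_mb * deletion_kb / 1000)
  with_seed(seed, {
    od <- protocol$init_od
    mu_base <- base_mu
    cum_gen <- 0
    t_h <- 0
    queue <- 0L          # mutations waiting for the current sweep to end
    active <- NULL       # list(label, effect, s, f, appearance, mu_before)
    n_fixed <- 0L
    n_arisen <- 0L
    mut_rows <- list()
    rows <- list()
    while (t_h < protocol$total_days * 24) {
      f <- if (is.null(active)) 0 else active$f
      eff <- if (is.null(active)) 0 else active$effect
      mu_now <- mu_base + f * eff
      interval <- choose_interval(od, mu_now, protocol)
      st <- suppressWarnings(step_transfer(od, mu_now, protocol, interval))
      t_h <- t_h + interval
      cum_gen <- cum_gen + st$generations_added
      od <- st$od_final
      # advance the active sweep over the generations just elapsed
      if (!is.null(active)) {
        active$f <- allele_frequency_series(
          active$s, active$f, st$generations_added)
        if (active$f >= model$fix_threshold) {
          n_fixed <- n_fixed + 1L
          mu_base <- mu_base + active$effect
          mut_rows[[n_fixed]] <- data.frame(
            label = active$label, effect = active$effect,
            appearance_generation = active$appearance,
            fixation_generation = cum_gen,
            mu_before = active$mu_before)
          active <- NULL
        }
      }
      # new arrivals this transfer
      queue <- queue + stats::rpois(1, lambda * max(st$generations_added, 0))
      if (is.null(active) && queue > 0L) {
        queue <- queue - 1L
        eff_mean <- model$effect_mean *
          exp(-model$diminishing_returns * mu_base)
        effect <- stats::rgamma(1, shape = model$effect_shape,
                                scale = eff_mean / model$effect_shape)
        n_arisen <- n_arisen + 1L
        active <- list(label = sprintf("mut%02d", n_arisen),
                       effect = effect,
                       s = log(2) * effect / mu_base,
                       f = model$f0,
                       appearance = cum_gen,
                       mu_before = mu_base)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        day = ceiling(t_h / 24),
        interval_h = interval,
        dilution_exponent = st$dilution_exponent,
        od_transfer = st$od_final,
        mu_estimate = st$mu_estimate,
        mu_true = mu_now,
        cum_generations = cum_gen,
        n_fixed = n_fixed,
        active_mutation = if (is.null(active)) NA_character_ else
          active$label,
        allele_freq = if (is.null(active)) NA_real_ else active$f,
        in_range = st$in_range)
    }
    mutations <- if (n_fixed > 0) do.call(rbind, mut_rows) else
      data.frame(label = character(0), effect = numeric(0),
                 appearance_generation = numeric(0),
                 fixation_generation = numeric(0),
                 mu_before = numeric(0))
    structure(list(transfers = do.call(rbind, rows),
                   mutations = mutations,
                   base_mu = base_mu, deletion_kb = deletion_kb,
                   genome = genome),
              class = "evolution_trajectory")
  })
}

#' @export
print.evolution_trajectory <- function(x, ...) {
  tr <- x$transfers
  cat(sprintf(
    "evolution_trajectory [%s]: %d transfers, %.0f generations, %d fixed mutation(s), mu %.3f -> %.3f 1/h\n",
    x$genome, nrow(tr), max(tr$cum_generations), max(tr$n_fixed),
    x$base_mu, tr$mu_true[nrow(tr)]))
  invisible(x)
}
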