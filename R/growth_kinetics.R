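# From OD600 time series to growth rates and fitness estimates.

#' Construct a growth curve
#'
#' One well's OD600 time series with its metadata. Times must be strictly
#' increasing with at least two reads; ODs must be non-negative.
#'
#' @param time_h Numeric vector of read times, h.
#' @param od600 Numeric vector of OD600 readings, same length.
#' @param genome,population,combination_id,replicate Metadata.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(time_h, od600, genome = NA_character_,
                         population = NA_character_,
                         combination_id = NA_character_,
                         replicate = NA_integer_) {
  time_h <- as.numeric(time_h)
  od600 <- as.numeric(od600)
  if (length(time_h) < 2) stop("a growth curve needs at least 2 reads")
  if (length(od600) != length(time_h)) stop("time and OD lengths differ")
  if (any(!is.finite(time_h)) || any(diff(time_h) <= 0)) {
    stop("times must be finite and strictly increasing")
  }
  if (any(!is.finite(od600)) || any(od600 < 0)) {
    stop("OD600 must be finite and non-negative")
  }
  structure(list(time_h = time_h, od600 = od600, genome = genome,
                 population = population, combination_id = combination_id,
                 replicate = replicate),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth_curve: %d reads over %.1f h [%s %s %s rep %s]\n",
              length(x$time_h), max(x$time_h) - min(x$time_h),
              x$genome, x$population, x$combination_id,
              as.character(x$replicate)))
  invisible(x)
}

#' Interval-wise specific growth rates
#'
#' For each pair of consecutive reads computes
#' mu_i = ln(C_(i+1)/C_i) / (t_(i+1) - t_i). Intervals where either OD is
#' at or below `od_floor` are excluded (log of noise-floor reads produces
#' spurious rates) and counted in the `n_excluded` attribute. Rates may be
#' negative. Scaling all ODs by a positive constant leaves every rate
#' unchanged.
#'
#' @param curve A `growth_curve`.
#' @param od_floor OD600 detection floor (> 0), default 0.003.
#' @return Data frame of class `growth_rate_series` with columns
#'   `interval` (index of the read pair), `t_mid` (midpoint time, h) and
#'   `rate` (1/h); attribute `n_excluded`.
#' @export
interval_rates <- function(curve, od_floor = 0.003) {
  stopifnot(inherits(curve, "growth_curve"))
  if (od_floor <= 0) stop("od_floor must be positive")
  n <- length(curve$od600)
  use <- curve$od600[-n] > od_floor & curve$od600[-1] > od_floor
  if (!any(use)) {
    stop("insufficient data: no consecutive read pair above od_floor")
  }
  rate <- log(curve$od600[-1] / curve$od600[-n]) / diff(curve$time_h)
  out <- data.frame(interval = which(use),
                    t_mid = ((curve$time_h[-n] + curve$time_h[-1]) / 2)[use],
                    rate = rate[use])
  attr(out, "n_excluded") <- sum(!use)
  attr(out, "curve_meta") <- curve[c("genome", "population",
                                     "combination_id", "replicate")]
  class(out) <- c("growth_rate_series", "data.frame")
  out
}

#' Maximal growth rate by the best contiguous window
#'
#' The fitness estimate is the mean of the best window of `window`
#' (default five) consecutive interval rates; windows are only formed
#' over strictly consecutive intervals (exclusions break them). The
#' selection criterion wants the window that is simultaneously fastest
#' and most stable ("largest mean and smallest standard deviation") —
#' two objectives that need a total order. Windows are therefore ranked
#' by the conservative score mean - `sd_penalty` * SD: for the
#' near-constant rates of a true exponential phase the SD term vanishes
#' and the rule reduces to the maximal mean, while windows whose large
#' mean is an artifact of read noise (log-ratios of near-noise-floor
#' ODs swing wildly) are heavily penalized. Plain maximal-mean selection
#' (`sd_penalty = 0`) is an order statistic over noise and overestimates
#' the rate badly on realistic curves. Near-ties in the score (relative
#' tolerance `rel_tol`) are broken by the smaller SD, remaining ties by
#' the earliest window. The returned `mu_max` is the selected window's
#' mean.
#'
#' @param series A `growth_rate_series` from [interval_rates()], or a bare
#'   numeric vector of rates (treated as consecutive).
#' @param window Window length (>= 2), default 5.
#' @param sd_penalty Weight of the window SD in the selection score
#'   (default 2, a lower-confidence-bound style penalty).
#' @param rel_tol Relative tolerance for near-ties in the score.
#' @return A list of class `fitness_estimate`: `mu_max`,
#'   `window_start_index` (interval index of the window's first rate),
#'   `window_mean`, `window_sd`, `n_rates_in_window`.
#' @export
max_growth_rate <- function(series, window = 5, sd_penalty = 2,
                            rel_tol = 1e-6) {
  if (is.numeric(series) && is.null(dim(series))) {
    series <- data.frame(interval = seq_along(series), t_mid = NA_real_,
                         rate = as.numeric(series))
  }
  if (window < 2) stop("window must be >= 2")
  w <- as.integer(window)
  # split into runs of consecutive interval indices
  runs <- split(seq_len(nrow(series)),
                cumsum(c(1L, diff(series$interval) != 1L)))
  best <- NULL
  for (run in runs) {
    r <- series$rate[run]
    nr <- length(r)
    if (nr < w) next
    cs <- cumsum(c(0, r))
    cs2 <- cumsum(c(0, r^2))
    starts <- seq_len(nr - w + 1L)
    means <- (cs[starts + w] - cs[starts]) / w
    vars <- pmax((cs2[starts + w] - cs2[starts]) - w * means^2, 0) / (w - 1)
    sds <- sqrt(vars)
    for (j in seq_along(starts)) {
      cand <- list(mean = means[j], sd = sds[j],
                   score = means[j] - sd_penalty * sds[j],
                   start = series$interval[run[starts[j]]])
      if (is.null(best) || window_beats(cand, best, rel_tol)) best <- cand
    }
  }
  if (is.null(best)) {
    stop("insufficient data: no run of ", w, " consecutive rates")
  }
  structure(list(mu_max = best$mean,
                 window_start_index = best$start,
                 window_mean = best$mean,
                 window_sd = best$sd,
                 n_rates_in_window = w),
            class = "fitness_estimate")
}

# Decision rule: larger score; near-ties by smaller SD; then earlier
# start.
window_beats <- function(cand, best, rel_tol) {
  scale <- max(abs(cand$score), abs(best$score), 1e-12)
  if (abs(cand$score - best$score) > rel_tol * scale) {
    return(cand$score > best$score)
  }
  if (cand$sd != best$sd) return(cand$sd < best$sd)
  cand$start < best$start
}

#' Evolutionary generations from a serial transfer
#'
#' gen = log2(C_i / C_j), where C_i is the OD600 at transfer and C_j the
#' theoretical starting OD600 (previous transfer OD divided by the
#' dilution). Additive over consecutive transfers. Vectorised.
#'
#' @param c_i,c_j Positive OD600 values.
#' @return Generations (dimensionless).
#' @export
generations <- function(c_i, c_j) {
  if (any(c_i <= 0) || any(c_j <= 0)) stop("ODs must be positive")
  log2(c_i / c_j)
}

#' Growth rate across one serial transfer
#'
#' mu = ln(C_i / C_j) / (t_i - t_j) over a whole transfer interval; the
#' two-point version of [interval_rates()]. Vectorised.
#'
#' @param c_i,c_j Positive OD600 values at transfer and at start.
#' @param t_i,t_j Times, h, with `t_i > t_j`.
#' @return Rate, 1/h.
#' @export
transfer_rate <- function(c_i, c_j, t_i, t_j) {
  if (any(c_i <= 0) || any(c_j <= 0)) stop("ODs must be positive")
  if (any(t_i <= t_j)) stop("t_i must exceed t_j")
  log(c_i / c_j) / (t_i - t_j)
}

#' Aggregate replicate fitness estimates
#'
#' Arithmetic mean and standard error (SD/sqrt(n)) over biological
#' replicates.
#'
#' @param mu Numeric vector of replicate growth rates, or a list of
#'   `fitness_estimate` objects.
#' @return List: `mean`, `se` (NA for n = 1), `n`.
#' @export
mean_fitness <- function(mu) {
  if (is.list(mu) && length(mu) && inherits(mu[[1]], "fitness_estimate")) {
    mu <- vapply(mu, `[[`, numeric(1), "mu_max")
  }
  mu <- as.numeric(mu)
  if (length(mu) == 0) stop("insufficient data: no replicates")
  n <- length(mu)
  list(mean = mean(mu),
       se = if (n > 1) stats::sd(mu) / sqrt(n) else NA_real_,
       n = n)
}

#' Redox activity from OD490 reduction kinetics
#'
#' The reduction rate of each measurement series is the ordinary
#' least-squares slope of OD490 against time (minutes); activity is that
#' slope divided by the culture's OD600. With several measurement series
#' (typically N = 5) the mean and SD of the per-series activities are
#' reported.
#'
#' @param od490 Numeric vector (one series) or a list/matrix of series
#'   (matrix columns are series).
#' @param time_min Measurement times in minutes (shared across series).
#' @param od600_of_culture OD600 of the assayed culture (> 0).
#' @return List: `activity` (mean, 1/(min * OD600)), `sd`, `n`,
#'   `per_series`.
#' @export
redox_activity <- function(od490, time_min, od600_of_culture) {
  if (od600_of_culture <= 0) stop("od600_of_culture must be positive")
  if (length(unique(time_min)) < 2) {
    stop("time vector must contain at least two distinct times")
  }
  series <- if (is.matrix(od490)) {
    lapply(seq_len(ncol(od490)), function(j) od490[, j])
  } else if (is.list(od490)) od490 else list(od490)
  acts <- vapply(series, function(y) {
    if (length(y) != length(time_min)) stop("series length mismatch")
    unname(stats::coef(stats::lm(y ~ time_min))[2]) / od600_of_culture
  }, numeric(1))
  list(activity = mean(acts),
       sd = if (length(acts) > 1) stats::sd(acts) else NA_real_,
       n = length(acts),
       per_series = acts)
}

#' Per-replicate and aggregated fitness tables from a curve collection
#'
#' `fitness_replicates()` computes one maximal growth rate per curve in a
#' long-format collection; `fitness_table()` aggregates the replicates to
#' mean, standard error and n per (genome, population, combination).
#'
#' @param curves Long data frame with columns genome, population,
#'   combination_id, replicate, time_h, od600 (as written by
#'   [simulate_study()] or read by [read_curves()]).
#' @param window,od_floor Passed to [max_growth_rate()] and
#'   [interval_rates()].
#' @param blank_od Per-plate blank OD600 subtracted from every read
#'   before rate computation (default 0: no blank subtraction).
#' @return `fitness_replicates()`: data frame (genome, population,
#'   combination_id, replicate, mu, below_detection). `fitness_table()`:
#'   data frame (genome, population, combination_id, mu_mean, mu_se, n).
#' @details Wells that never rise above the detection floor have no
#'   measurable exponential phase; their growth rate is recorded as zero
#'   with `below_detection = TRUE` rather than erroring, so non-permissive
#'   conditions stay in the fitness table.
#' @export
fitness_replicates <- function(curves, window = 5, od_floor = 0.003,
                               blank_od = 0) {
  need <- c("genome", "population", "combination_id", "replicate",
            "time_h", "od600")
  if (!all(need %in% names(curves))) {
    stop("curves must have columns: ", paste(need, collapse = ", "))
  }
  if (blank_od > 0) curves$od600 <- pmax(curves$od600 - blank_od, 0)
  key <- interaction(curves$genome, curves$population,
                     curves$combination_id, curves$replicate, drop = TRUE)
  rows <- lapply(split(curves, key), function(d) {
    d <- d[order(d$time_h), ]
    cv <- growth_curve(d$time_h, d$od600, genome = d$genome[1],
                       population = d$population[1],
                       combination_id = d$combination_id[1],
                       replicate = d$replicate[1])
    mu <- tryCatch(
      max_growth_rate(interval_rates(cv, od_floor = od_floor),
                      window = window)$mu_max,
      error = function(e) {
        if (grepl("insufficient data", conditionMessage(e))) NA_real_
        else stop(e)
      })
    data.frame(genome = d$genome[1], population = d$population[1],
               combination_id = d$combination_id[1],
               replicate = d$replicate[1],
               mu = if (is.na(mu)) 0 else mu,
               below_detection = is.na(mu))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$genome, out$population, out$combination_id,
            out$replicate), , drop = FALSE]
}

#' @rdname fitness_replicates
#' @export
fitness_table <- function(curves, window = 5, od_floor = 0.003,
                          blank_od = 0) {
  reps <- if (all(c("mu", "replicate") %in% names(curves)) &&
                !"od600" %in% names(curves)) {
    curves  # already per-replicate rates
  } else {
    fitness_replicates(curves, window = window, od_floor = od_floor,
                       blank_od = blank_od)
  }
  key <- interaction(reps$genome, reps$population, reps$combination_id,
                     drop = TRUE)
  rows <- lapply(split(reps, key), function(d) {
    mf <- mean_fitness(d$mu)
    data.frame(genome = d$genome[1], population = d$population[1],
               combination_id = d$combination_id[1],
               mu_mean = mf$mean, mu_se = mf$se, n = mf$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$genome, out$population, out$combination_id), , drop = FALSE]
}

#' Read and write long-format curve collections
#'
#' CSV with columns genome, population, combination_id, replicate, time_h,
#' od600. `read_curves()` also accepts a wide plate-reader export (first
#' column time, one column per well) together with a well map CSV
#' (columns well, genome, population, combination_id, replicate).
#'
#' @param path CSV file path.
#' @param well_map Optional path to a well-map CSV for wide input.
#' @param curves Long data frame to write.
#' @return `read_curves()`: long data frame; `write_curves()`: the path,
#'   invisibly.
#' @export
read_curves <- function(path, well_map = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  long_cols <- c("genome", "population", "combination_id", "replicate",
                 "time_h", "od600")
  if (all(long_cols %in% names(d))) return(d[long_cols])
  if (is.null(well_map)) {
    stop("input is not long-format; supply well_map for a wide export")
  }
  wm <- utils::read.csv(well_map)
  need <- c("well", "genome", "population", "combination_id", "replicate")
  if (!all(need %in% names(wm))) {
    stop("well map must have columns: ", paste(need, collapse = ", "))
  }
  tcol <- names(d)[1]
  wells <- setdiff(names(d), tcol)
  miss <- setdiff(wells, wm$well)
  if (length(miss)) stop("wells missing from well map: ",
                         paste(miss, collapse = ", "))
  out <- lapply(wells, function(w) {
    m <- wm[wm$well == w, ][1, ]
    data.frame(genome = m$genome, population = m$population,
               combination_id = m$combination_id, replicate = m$replicate,
               time_h = d[[tcol]], od600 = d[[w]])
  })
  do.call(rbind, out)
}

#' @rdname read_curves
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
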