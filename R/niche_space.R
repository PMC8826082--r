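# The niche-space statistic S: cubic fit of fitness along a log-scaled
# concentration gradient, analytic area, dual normalization, and the
# niche-broadness total S_T.

#' Construct a niche profile
#'
#' Fitness of one (genome, population) along the concentration gradient of
#' one constituent: pairs of x = log10(concentration) and mean growth
#' rate. A cubic has four coefficients, so at least four distinct x values
#' are required.
#'
#' @param constituent Constituent name.
#' @param x Numeric vector of log10 concentrations (any affine mapping of
#'   the log axis is acceptable; the statistic is invariant to it).
#' @param mu_mean Mean growth rates, 1/h, same length.
#' @param mu_se Optional standard errors.
#' @param combination_id Optional combination labels.
#' @param genome,population Identifiers.
#' @return Object of class `niche_profile`.
#' @export
niche_profile <- function(constituent, x, mu_mean, mu_se = NULL,
                          combination_id = NULL, genome = NA_character_,
                          population = NA_character_) {
  x <- as.numeric(x)
  mu_mean <- as.numeric(mu_mean)
  if (length(x) != length(mu_mean)) stop("x and mu_mean lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(mu_mean))) {
    stop("x and mu_mean must be finite")
  }
  if (length(unique(x)) < 4) {
    stop("niche profile for '", constituent,
         "' needs >= 4 distinct x values (got ", length(unique(x)), ")")
  }
  structure(list(constituent = constituent, x = x, mu_mean = mu_mean,
                 mu_se = mu_se, combination_id = combination_id,
                 genome = genome, population = population),
            class = "niche_profile")
}

#' Cubic polynomial fit of a niche profile
#'
#' Ordinary least squares of mu(x) = a x^3 + b x^2 + c x + d, with x first
#' rescaled so the profile spans [0, 1] (the dual normalization of the
#' statistic makes the result invariant to this affine choice). With
#' exactly four distinct x values the fit interpolates.
#'
#' @param profile A `niche_profile`.
#' @return Object of class `cubic_fit`: coefficients `a`, `b`, `c`, `d`
#'   (in rescaled-x units), `rss`, `n`, and the original-axis `x_min`,
#'   `x_max`.
#' @export
fit_cubic <- function(profile) {
  stopifnot(inherits(profile, "niche_profile"))
  x_min <- min(profile$x)
  x_max <- max(profile$x)
  x01 <- (profile$x - x_min) / (x_max - x_min)
  fit <- stats::lm(profile$mu_mean ~ x01 + I(x01^2) + I(x01^3))
  cf <- unname(stats::coef(fit))
  if (any(!is.finite(cf))) {
    stop("degenerate cubic fit: rank-deficient design for '",
         profile$constituent, "'")
  }
  structure(list(a = cf[4], b = cf[3], c = cf[2], d = cf[1],
                 rss = sum(stats::residuals(fit)^2),
                 n = length(profile$x),
                 x_min = x_min, x_max = x_max),
            class = "cubic_fit")
}

# Evaluate a cubic fit at rescaled coordinates in [0, 1].
predict_cubic <- function(fit, x01) {
  fit$a * x01^3 + fit$b * x01^2 + fit$c * x01 + fit$d
}

#' Analytic area under a cubic fit
#'
#' The integral of a x^3 + b x^2 + c x + d over [x_min, x_max], evaluated
#' from the antiderivative a/4 x^4 + b/3 x^3 + c/2 x^2 + d x. No numerical
#' quadrature is involved.
#'
#' @param fit A `cubic_fit` (or any list with elements a, b, c, d).
#' @param x_min,x_max Integration bounds in the fit's x units (for fits
#'   from [fit_cubic()], rescaled units, default [0, 1]).
#' @return The signed area.
#' @export
area_under_fit <- function(fit, x_min = 0, x_max = 1) {
  if (x_max <= x_min) stop("x_max must exceed x_min")
  anti <- function(x) {
    fit$a / 4 * x^4 + fit$b / 3 * x^3 + fit$c / 2 * x^2 + fit$d * x
  }
  anti(x_max) - anti(x_min)
}

#' Niche space S of one profile
#'
#' The breadth-of-adaptation statistic: the area under the cubic fit,
#' normalized by both the gradient width and the maximal growth rate, so
#' that S = Area / (mu_max * (x_max - x_min)). On the rescaled axis the
#' width is one; mu_max is the maximal observed mean growth rate of the
#' profile. S = 1 means full fitness across the whole gradient; the fitted
#' polynomial may slightly overshoot the observed maximum between points,
#' so S can marginally exceed 1.
#'
#' @param profile A `niche_profile` with a positive maximal mean rate.
#' @param clip_negative If TRUE, negative excursions of the fitted cubic
#'   are clipped to zero before integration (numerically, on a fine grid);
#'   by default the polynomial is integrated as-is.
#' @return Object of class `niche_result`: `S`, `area`, `mu_max`, `x_min`,
#'   `x_max`, `fit`, plus the profile's identifiers.
#' @export
niche_space_S <- function(profile, clip_negative = FALSE) {
  stopifnot(inherits(profile, "niche_profile"))
  mu_max <- max(profile$mu_mean)
  if (mu_max <= 0) {
    stop("degenerate profile for '", profile$constituent,
         "': maximal observed growth rate is not positive")
  }
  fit <- fit_cubic(profile)
  area <- if (clip_negative) {
    xs <- seq(0, 1, length.out = 2001)
    mean(pmax(predict_cubic(fit, xs), 0))  # width 1
  } else {
    area_under_fit(fit, 0, 1)
  }
  structure(list(S = area / mu_max, area = area, mu_max = mu_max,
                 x_min = fit$x_min, x_max = fit$x_max, fit = fit,
                 constituent = profile$constituent,
                 genome = profile$genome, population = profile$population),
            class = "niche_result")
}

#' Niche broadness S_T over the eight constituents
#'
#' Sums the per-constituent S values of one (genome, population) into the
#' niche broadness S_T, and reports the population standard deviation of
#' the eight values as a measure of their evenness.
#'
#' @param results List of eight `niche_result` objects, one per
#'   constituent.
#' @return Object of class `niche_broadness`: `S_T`, named `S` vector,
#'   `sd_across_niches`, `n`, `genome`, `population`.
#' @export
total_S <- function(results) {
  ks <- vapply(results, `[[`, character(1), "constituent")
  if (anyDuplicated(ks)) stop("duplicate constituent in S results")
  if (!setequal(ks, constituent_names())) {
    stop("S results must cover all 8 constituents; missing: ",
         paste(setdiff(constituent_names(), ks), collapse = ", "))
  }
  s <- vapply(results, `[[`, numeric(1), "S")
  names(s) <- ks
  s <- s[constituent_names()]
  structure(list(S_T = sum(s), S = s,
                 sd_across_niches = stats::sd(s) * sqrt(7 / 8),
                 n = length(s),
                 genome = results[[1]]$genome,
                 population = results[[1]]$population),
            class = "niche_broadness")
}

#' Evolutionary change in niche space
#'
#' Elementwise S(Evo) - S(Anc) per constituent and the change in the total
#' S_T, for one genome.
#'
#' @param anc,evo `niche_broadness` objects covering the same
#'   constituents.
#' @return List: `delta_S` (named vector), `delta_S_T`, `genome`.
#' @export
delta_S <- function(anc, evo) {
  stopifnot(inherits(anc, "niche_broadness"),
            inherits(evo, "niche_broadness"))
  if (!identical(names(anc$S), names(evo$S))) {
    stop("constituent sets differ between the two sides")
  }
  list(delta_S = evo$S - anc$S, delta_S_T = evo$S_T - anc$S_T,
       genome = anc$genome)
}

# Assemble the niche profile of one constituent from a fitness table:
# C0 plus every combination whose varied compound contributes to the
# constituent (so shared ions, e.g. SO4 from three sulfate salts, pool
# points across compounds). Zero concentrations sit at a pseudo-floor on
# the log axis.
constituent_profile <- function(fitness, design, constituent, genome,
                                population, pseudo_floor_decades = 1) {
  ids <- vapply(design$combinations, `[[`, character(1), "id")
  keep <- vapply(design$combinations, function(cb) {
    identical(cb$id, design$reference_id) ||
      constituent %in% varied_constituents(cb)
  }, logical(1))
  sub <- fitness[fitness$genome == genome &
                   fitness$population == population &
                   fitness$combination_id %in% ids[keep], ]
  if (nrow(sub) == 0) {
    stop("fitness table has no rows for (", genome, ", ", population,
         ", ", constituent, ")")
  }
  conc <- vapply(sub$combination_id, function(id) {
    design_combo(design, id)$ions[[constituent]]
  }, numeric(1))
  x <- rep(NA_real_, length(conc))
  pos <- conc > 0
  x[pos] <- log10(conc[pos])
  if (any(!pos)) {
    if (!any(pos)) stop("all concentrations zero for '", constituent, "'")
    x[!pos] <- min(x[pos]) - pseudo_floor_decades
  }
  niche_profile(constituent, x, sub$mu_mean,
                mu_se = if ("mu_se" %in% names(sub)) sub$mu_se else NULL,
                combination_id = sub$combination_id,
                genome = genome, population = population)
}

#' Batch niche-space computation over a whole study
#'
#' Builds one niche profile per (genome, population, constituent) from an
#' aggregated fitness table and the medium design, computes every S, the
#' per-(genome, population) niche broadness S_T, and — where both Anc and
#' Evo populations are present — the evolutionary changes in S. A full
#' five-genome, two-population design yields 80 S values and 40 changes.
#'
#' @param fitness Aggregated fitness table from [fitness_table()]
#'   (columns genome, population, combination_id, mu_mean, ...).
#' @param design The `nichespan_design` the fitness refers to.
#' @param pseudo_floor_decades Log-decades below the smallest nonzero
#'   concentration at which zero concentrations are placed.
#' @param clip_negative Passed to [niche_space_S()].
#' @return Object of class `nichespan_S`: data frames `S_values` (genome,
#'   population, constituent, S, area, mu_max, a, b, c, d, n_points),
#'   `broadness` (genome, population, S_T, sd_across_niches) and `delta`
#'   (genome, constituent, delta_S) with `delta_totals` (genome,
#'   delta_S_T).
#' @export
batch_S <- function(fitness, design, pseudo_floor_decades = 1,
                    clip_negative = FALSE) {
  stopifnot(inherits(design, "nichespan_design"))
  cells <- unique(fitness[c("genome", "population")])
  s_rows <- list()
  broad_rows <- list()
  results_by_cell <- list()
  for (i in seq_len(nrow(cells))) {
    g <- cells$genome[i]
    p <- cells$population[i]
    res <- lapply(constituent_names(), function(k) {
      prof <- constituent_profile(fitness, design, k, g, p,
                                  pseudo_floor_decades)
      niche_space_S(prof, clip_negative = clip_negative)
    })
    for (r in res) {
      s_rows[[length(s_rows) + 1L]] <- data.frame(
        genome = g, population = p, constituent = r$constituent,
        S = r$S, area = r$area, mu_max = r$mu_max,
        a = r$fit$a, b = r$fit$b, c = r$fit$c, d = r$fit$d,
        n_points = r$fit$n)
    }
    nb <- total_S(res)
    broad_rows[[length(broad_rows) + 1L]] <- data.frame(
      genome = g, population = p, S_T = nb$S_T,
      sd_across_niches = nb$sd_across_niches)
    results_by_cell[[paste(g, p, sep = "|")]] <- nb
  }
  delta_rows <- list()
  delta_tot <- list()
  for (g in unique(cells$genome)) {
    a <- results_by_cell[[paste(g, "Anc", sep = "|")]]
    e <- results_by_cell[[paste(g, "Evo", sep = "|")]]
    if (is.null(a) || is.null(e)) next
    d <- delta_S(a, e)
    delta_rows[[length(delta_rows) + 1L]] <- data.frame(
      genome = g, constituent = names(d$delta_S),
      delta_S = unname(d$delta_S))
    delta_tot[[length(delta_tot) + 1L]] <- data.frame(
      genome = g, delta_S_T = d$delta_S_T)
  }
  structure(list(
    S_values = do.call(rbind, s_rows),
    broadness = do.call(rbind, broad_rows),
    delta = if (length(delta_rows)) do.call(rbind, delta_rows) else
      data.frame(genome = character(0), constituent = character(0),
                 delta_S = numeric(0)),
    delta_totals = if (length(delta_tot)) do.call(rbind, delta_tot) else
      data.frame(genome = character(0), delta_S_T = numeric(0))),
    class = "nichespan_S")
}

#' @export
print.nichespan_S <- function(x, ...) {
  cat("nichespan_S:", nrow(x$S_values), "S values,",
      nrow(x$delta), "changes in S across",
      nrow(x$broadness), "(genome, population) cells\n")
  invisible(x)
}
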