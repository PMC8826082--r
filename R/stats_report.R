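# Statistical comparisons and figure-level summary tables.

# All permutations of 1..n as an (n!) x n integer matrix. Only used for
# small n (exact Spearman p needs n <= 9, i.e. at most 362,880 rows).
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- perm_matrix(n - 1L)
  np <- nrow(p)
  out <- matrix(0L, nrow = n * np, ncol = n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * np + 1L):(i * np)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[p], np, n - 1L)
  }
  out
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Rho is the Pearson correlation of midranks (average ranks for ties).
#' For n <= `exact_max` (default 9) the two-sided p-value is computed by
#' full enumeration of all n! permutations of one rank vector — at the
#' n = 5 typical of genome-panel comparisons the null has only 120
#' permutations and asymptotics are unreliable. For larger n the usual
#' t-approximation with n - 2 degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @param exact_max Largest n for which the exact permutation null is
#'   enumerated.
#' @return List of class `correlation_result`: `rho`, `p_value`, `n`,
#'   `method` ("exact-permutation" or "asymptotic").
#' @export
spearman <- function(x, y, exact_max = 9) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- perm_matrix(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    rxc <- rx - mean(rx)
    ryc2 <- sum((ry - mean(ry))^2)
    rho_perm <- (ry_perm %*% rxc) / sqrt(sum(rxc^2) * ryc2)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "asymptotic"
  }
  structure(list(rho = rho, p_value = min(p, 1), n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' Evolved-vs-ancestral significance over the whole design
#'
#' Two-tailed two-sample t-test of the replicate growth rates of Evo
#' against Anc for every (combination, genome) cell. Welch's
#' unequal-variance form is the default (`var_equal = TRUE` gives the
#' pooled-variance Student form). Raw p-values are reported as in the
#' source heatmaps; a Benjamini-Hochberg column is added alongside for
#' transparency, without replacing them. Cells where both sides are
#' essentially constant get p = 1 when the means agree and p ~ 0
#' otherwise.
#'
#' @param reps Per-replicate fitness table from [fitness_replicates()]:
#'   columns genome, population ("Anc"/"Evo"), combination_id, mu.
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return List of class `significance_matrix`: `table` (long: genome,
#'   combination_id, p_value, log10_p, p_bh, n_anc, n_evo) and `matrix`
#'   (combinations x genomes, p-values).
#' @export
anc_evo_tests <- function(reps, var_equal = FALSE) {
  need <- c("genome", "population", "combination_id", "mu")
  if (!all(need %in% names(reps))) {
    stop("reps must have columns: ", paste(need, collapse = ", "))
  }
  genomes <- sort(unique(reps$genome))
  combos <- unique(reps$combination_id)
  rows <- list()
  for (g in genomes) {
    for (cb in combos) {
      a <- reps$mu[reps$genome == g & reps$combination_id == cb &
                     reps$population == "Anc"]
      e <- reps$mu[reps$genome == g & reps$combination_id == cb &
                     reps$population == "Evo"]
      p <- if (length(a) < 2 || length(e) < 2) {
        NA_real_  # absent cell, reported as missing, never imputed
      } else {
        tryCatch(
          stats::t.test(a, e, var.equal = var_equal)$p.value,
          error = function(err) {
            if (isTRUE(all.equal(mean(a), mean(e)))) 1 else 0
          })
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, combination_id = cb, p_value = p,
        n_anc = length(a), n_evo = length(e))
    }
  }
  tab <- do.call(rbind, rows)
  tab$log10_p <- log10(tab$p_value)
  tab$p_bh <- stats::p.adjust(tab$p_value, method = "BH")
  m <- matrix(NA_real_, nrow = length(combos), ncol = length(genomes),
              dimnames = list(combos, genomes))
  for (i in seq_len(nrow(tab))) {
    m[tab$combination_id[i], tab$genome[i]] <- tab$p_value[i]
  }
  structure(list(table = tab, matrix = m), class = "significance_matrix")
}

#' Figure-level summary tables
#'
#' Collects the study's headline panels as tidy data frames: the
#' radar-chart table of the eight per-constituent S values per (genome,
#' population), the S_T bar and across-niche SD tables, the change in S_T
#' against genome deletion size, per-transfer evolution trajectory
#' summaries, and the mutant fitness ladder. Missing inputs yield empty
#' tables with a warning, so partial pipelines still export.
#'
#' @param S A `nichespan_S` from [batch_S()], or NULL.
#' @param genomes Optional data frame (genome, deletion_kb) to join onto
#'   the delta-S_T table.
#' @param trajectories Optional named list of `evolution_trajectory`
#'   objects.
#' @param out_dir Optional directory; when given, each table is written
#'   as `<name>.csv`.
#' @return Named list of data frames (radar, s_t, sd_niches,
#'   delta_s_t_vs_deletion, trajectory, mutant_ladder), invisibly when
#'   `out_dir` is given.
#' @export
figure_tables <- function(S = NULL, genomes = NULL, trajectories = NULL,
                          out_dir = NULL) {
  empty <- function(...) data.frame(...)
  if (is.null(S) || nrow(S$S_values) == 0) {
    warning("no S values supplied; radar and S_T tables are empty")
    radar <- empty(genome = character(0), population = character(0),
                   constituent = character(0), S = numeric(0))
    s_t <- empty(genome = character(0), population = character(0),
                 S_T = numeric(0))
    sd_niches <- empty(genome = character(0), population = character(0),
                       sd_across_niches = numeric(0))
    dvd <- empty(genome = character(0), delta_S_T = numeric(0))
  } else {
    radar <- S$S_values[c("genome", "population", "constituent", "S")]
    s_t <- S$broadness[c("genome", "population", "S_T")]
    sd_niches <- S$broadness[c("genome", "population", "sd_across_niches")]
    dvd <- S$delta_totals
    if (!is.null(genomes)) {
      dvd <- merge(dvd, genomes[c("genome", "deletion_kb")], by = "genome",
                   all.x = TRUE)
    }
  }
  if (is.null(trajectories) || length(trajectories) == 0) {
    traj <- empty(genome = character(0), day = numeric(0),
                  mu_estimate = numeric(0), cum_generations = numeric(0),
                  n_fixed = integer(0))
    ladder <- empty(genome = character(0), step = integer(0),
                    label = character(0), mu = numeric(0))
  } else {
    traj <- do.call(rbind, lapply(trajectories, function(tr) {
      data.frame(genome = tr$genome, tr$transfers[
        c("day", "mu_estimate", "cum_generations", "n_fixed")])
    }))
    ladder <- do.call(rbind, lapply(trajectories, function(tr) {
      mus <- mutant_ladder_fitness(tr$base_mu, tr$mutations$effect)
      data.frame(genome = tr$genome,
                 step = seq_along(mus) - 1L,
                 label = c("ancestor", tr$mutations$label),
                 mu = mus)
    }))
    rownames(traj) <- rownames(ladder) <- NULL
  }
  tabs <- list(radar = radar, s_t = s_t, sd_niches = sd_niches,
               delta_s_t_vs_deletion = dvd, trajectory = traj,
               mutant_ladder = ladder)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tabs)) {
      utils::write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    return(invisible(tabs))
  }
  tabs
}
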