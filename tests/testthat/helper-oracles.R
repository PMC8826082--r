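# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: plain loops and direct formulas only.

# Exhaustive window enumeration under the mean - penalty*SD score with
# tie-by-min-SD / earliest, computed with naive mean() and sd() over
# every contiguous window.
oracle_best_window <- function(rates, window, sd_penalty = 2,
                               rel_tol = 1e-6) {
  best <- NULL
  for (start in seq_len(length(rates) - window + 1)) {
    w <- rates[start:(start + window - 1)]
    cand <- list(mean = mean(w), sd = stats::sd(w),
                 score = mean(w) - sd_penalty * stats::sd(w),
                 start = start)
    if (is.null(best)) { best <- cand; next }
    scale <- max(abs(cand$score), abs(best$score), 1e-12)
    if (abs(cand$score - best$score) > rel_tol * scale) {
      if (cand$score > best$score) best <- cand
    } else if (cand$sd < best$sd) {
      best <- cand
    }
  }
  best
}

# All permutations of 1..n, built by insertion (distinct from the
# package's block construction).
oracle_perms <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in out) {
      for (pos in 0:(k - 1)) {
        nxt[[length(nxt) + 1L]] <- append(p, k, after = pos)
      }
    }
    out <- nxt
  }
  out
}

# Exact two-sided permutation p-value for Spearman's rho by full
# enumeration, rho computed from scratch each time.
oracle_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  n <- length(x)
  hits <- 0L
  perms <- oracle_perms(n)
  for (p in perms) {
    if (abs(stats::cor(rx, ry[p])) >= abs(rho_obs) - 1e-12) hits <- hits + 1L
  }
  hits / length(perms)
}

# Deterministic haploid selection recursion, one generation at a time:
# mutant/resident fitness ratio w per generation.
oracle_sweep_recursion <- function(w, f0, n_gen) {
  f <- numeric(n_gen + 1)
  f[1] <- f0
  for (g in seq_len(n_gen)) {
    f[g + 1] <- w * f[g] / (1 + (w - 1) * f[g])
  }
  f
}

# Deterministic per-case seeds for parameterised simulation tests.
stable_seed_for_test <- function(...) {
  s <- paste(..., collapse = "|")
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

# A small fitness table with mu taken straight from the ground-truth
# landscape (no curves, no noise): one row per (genome, population,
# combination).
truth_fitness_table <- function(design, landscape,
                                populations = c("Anc", "Evo")) {
  rows <- list()
  for (g in landscape$genomes$genome) {
    for (p in populations) {
      for (cb in design$combinations) {
        rows[[length(rows) + 1L]] <- data.frame(
          genome = g, population = p, combination_id = cb$id,
          mu_mean = true_mu(landscape, g, p, cb), mu_se = 0, n = 1)
      }
    }
  }
  do.call(rbind, rows)
}
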