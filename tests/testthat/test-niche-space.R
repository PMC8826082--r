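# Cubic fitness profiles, analytic areas, the S statistic and S_T.

test_that("cubic fit interpolates four points and handles constants", {
  x <- c(0, 1 / 3, 2 / 3, 1)
  f <- niche_profile("glucose", x, x^3)
  fit <- fit_cubic(f)
  expect_equal(fit$a, 1, tolerance = 1e-8)
  expect_equal(abs(fit$b) + abs(fit$c) + abs(fit$d), 0, tolerance = 1e-8)

  flat <- fit_cubic(niche_profile("glucose", c(-3, -2, -1, 0, 1),
                                  rep(0.7, 5)))
  expect_equal(flat$d, 0.7, tolerance = 1e-10)
  expect_equal(abs(flat$a) + abs(flat$b) + abs(flat$c), 0,
               tolerance = 1e-8)

  expect_error(niche_profile("glucose", c(1, 1, 2, 2), c(1, 2, 3, 4)),
               "distinct")
})

test_that("cubic coefficients match a normal-equations solve", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    x <- sort(stats::runif(n, -4, 0))
    mu <- stats::runif(n, 0, 0.8)
    fit <- fit_cubic(niche_profile("K", x, mu))
    x01 <- (x - min(x)) / (max(x) - min(x))
    X <- cbind(1, x01, x01^2, x01^3)
    beta <- solve(t(X) %*% X, t(X) %*% mu)
    expect_equal(c(fit$d, fit$c, fit$b, fit$a), drop(beta),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("analytic area equals adaptive quadrature on random cubics", {
  set.seed(41)
  for (i in 1:100) {
    cf <- list(a = stats::rnorm(1, 0, 2), b = stats::rnorm(1, 0, 2),
               c = stats::rnorm(1, 0, 2), d = stats::rnorm(1, 0, 2))
    lo <- stats::runif(1, -3, 0)
    hi <- lo + stats::runif(1, 0.5, 4)
    got <- area_under_fit(cf, lo, hi)
    want <- stats::integrate(function(x) {
      cf$a * x^3 + cf$b * x^2 + cf$c * x + cf$d
    }, lo, hi, rel.tol = 1e-12, abs.tol = 1e-13)$value
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_equal(area_under_fit(list(a = 0, b = 0, c = 0, d = 2), 0, 1), 2)
  expect_equal(area_under_fit(list(a = 1, b = 0, c = 0, d = 0), 0, 1),
               0.25)
  expect_error(area_under_fit(list(a = 1, b = 0, c = 0, d = 0), 1, 1),
               "exceed")
})

test_that("S is 1 for flat profiles and 0.5 for a linear ramp", {
  flat <- niche_profile("SO4", seq(-4, 0, length.out = 6), rep(0.55, 6))
  expect_equal(niche_space_S(flat)$S, 1, tolerance = 1e-8)

  x <- seq(-5, -1, length.out = 7)
  ramp <- niche_profile("SO4", x, 0.6 * (x - min(x)) / diff(range(x)))
  expect_equal(niche_space_S(ramp)$S, 0.5, tolerance = 1e-8)

  expect_error(niche_space_S(niche_profile("SO4", x, rep(0, 7))),
               "degenerate")
})

test_that("S is invariant to affine x maps, mu scaling and point order", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    x <- sort(stats::runif(n, -6, -1))
    mu <- stats::runif(n, 0.05, 0.8)
    s0 <- niche_space_S(niche_profile("NH4", x, mu))$S
    a <- stats::runif(1, 0.2, 5)
    b <- stats::runif(1, -10, 10)
    g <- stats::runif(1, 0.1, 10)
    s1 <- niche_space_S(niche_profile("NH4", a * x + b, g * mu))$S
    expect_equal(s1, s0, tolerance = 1e-10)
    ord <- rev(seq_len(n))
    s2 <- niche_space_S(niche_profile("NH4", x[ord], mu[ord]))$S
    expect_equal(s2, s0, tolerance = 1e-10)
  }
})

test_that("niche broadness sums the eight constituent S values", {
  mk <- function(s, k) {
    structure(list(S = s, constituent = k, genome = "N0",
                   population = "Anc"), class = "niche_result")
  }
  ks <- constituent_names()
  all_one <- total_S(Map(mk, rep(1, 8), ks))
  expect_equal(all_one$S_T, 8)
  expect_equal(all_one$sd_across_niches, 0)

  one_hot <- total_S(Map(mk, c(1, rep(0, 7)), ks))
  expect_equal(one_hot$S_T, 1)

  set.seed(61)
  for (i in 1:20) {
    s <- stats::runif(8)
    nb <- total_S(Map(mk, s, ks))
    expect_equal(nb$sd_across_niches, sqrt(mean((s - mean(s))^2)),
                 tolerance = 1e-12)
  }
  expect_error(total_S(Map(mk, rep(1, 8), c(ks[1], ks[1], ks[3:8]))),
               "duplicate")
  expect_error(total_S(Map(mk, rep(1, 7), ks[-1])), "missing")
})

test_that("delta-S is elementwise and additive across stages", {
  mk_broad <- function(s) {
    structure(list(S_T = sum(s),
                   S = stats::setNames(s, constituent_names()),
                   sd_across_niches = 0, n = 8, genome = "N7",
                   population = "x"), class = "niche_broadness")
  }
  a <- mk_broad(rep(0.5, 8))
  b <- mk_broad(rep(0.6, 8))
  d <- delta_S(a, b)
  expect_equal(unname(d$delta_S), rep(0.1, 8))
  expect_equal(d$delta_S_T, 0.8, tolerance = 1e-12)
  expect_equal(delta_S(a, a)$delta_S_T, 0)

  set.seed(71)
  ca <- mk_broad(stats::runif(8)); cb <- mk_broad(stats::runif(8))
  cc <- mk_broad(stats::runif(8))
  expect_equal(delta_S(ca, cc)$delta_S,
               delta_S(ca, cb)$delta_S + delta_S(cb, cc)$delta_S)
})

test_that("batch_S emits the full structural complement of S values", {
  d <- build_design_matrix()
  ls <- fitness_landscape(d)
  ft <- truth_fitness_table(d, ls)
  S <- batch_S(ft, d)
  expect_equal(nrow(S$S_values), 80)
  expect_equal(nrow(S$delta), 40)
  expect_equal(nrow(S$broadness), 10)
  expect_equal(nrow(S$delta_totals), 5)

  # shared-ion constituents pool points across compounds
  np <- S$S_values[S$S_values$genome == "N0" &
                     S$S_values$population == "Anc", ]
  n_pts <- stats::setNames(np$n_points, np$constituent)
  expect_equal(unname(n_pts["glucose"]), 5)   # own compound + C0
  expect_equal(unname(n_pts["K"]), 9)         # K2HPO4 + KH2PO4 + C0
  expect_equal(unname(n_pts["SO4"]), 13)      # three sulfate salts + C0

  # one genome, one population: 8 S values, no deltas
  one <- batch_S(ft[ft$genome == "N0" & ft$population == "Anc", ], d)
  expect_equal(nrow(one$S_values), 8)
  expect_equal(nrow(one$delta), 0)
})

test_that("S increases with the landscape response width at zero noise", {
  d <- build_design_matrix()
  widths <- c(0.5, 0.8, 1.1, 1.4)
  s_gl <- vapply(widths, function(w) {
    ls <- fitness_landscape(d, genomes = data.frame(genome = "N0",
                                                    deletion_kb = 0),
                            width = w, narrow_per_mb = 0)
    ft <- truth_fitness_table(d, ls, populations = "Anc")
    S <- batch_S(ft, d)
    S$S_values$S[S$S_values$constituent == "glucose"]
  }, numeric(1))
  expect_true(all(diff(s_gl) > 0))
})
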