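test_that("uncertainty assignment applies the censoring rules", {
  v <- matrix(c(100, 4, 0, 50,
                20, 30, 40, NA), 4, 2)
  colnames(v) <- c("sp1", "sp2")
  cm <- toy_matrix(v, mdl = 10)
  prep <- assign_uncertainties(cm)
  # quantified: u = sqrt((0.1 c)^2 + MDL^2)
  expect_equal(unname(prep$X[1, 1]), 100)
  expect_equal(unname(prep$U[1, 1]), sqrt(100 + 100), tolerance = 1e-12)
  # below MDL (4 and exact 0): value MDL/2, u = 5/6 MDL
  expect_equal(unname(prep$X[2, 1]), 5)
  expect_equal(unname(prep$U[2, 1]), 25 / 3, tolerance = 1e-12)
  expect_equal(unname(prep$X[3, 1]), 5)
  expect_equal(unname(prep$provenance[3, 1]), "below_mdl")
  # missing: species median, u = 4x median
  expect_equal(unname(prep$X[4, 2]), 30)
  expect_equal(unname(prep$U[4, 2]), 120)
  expect_equal(unname(prep$provenance[4, 2]), "imputed")
  expect_true(all(prep$U > 0))
})

test_that("Q decreases monotonically and respects scale invariance", {
  tc <- generate_pmf_testcase(25, 8, 3, noise_fraction = 0.15, seed = 4)
  fit <- fit_pmf(tc$X, tc$U, 3, n_starts = 3, seed = 2)
  dq <- diff(fit$q_trace)
  expect_true(all(dq <= 1e-8 * fit$q_trace[-length(fit$q_trace)]))
  expect_true(all(fit$G >= 0) && all(fit$F >= 0))
  expect_gte(fit$Q, 0)
  # scaling X and U together leaves Q unchanged
  fit2 <- fit_pmf(1000 * tc$X, 1000 * tc$U, 3, n_starts = 3, seed = 2)
  expect_equal(fit2$Q, fit$Q, tolerance = 1e-8)
})

test_that("noiseless planted factors are recovered near-exactly", {
  tc <- generate_pmf_testcase(30, 6, 2, noise_fraction = 0, seed = 1)
  U <- matrix(1, 30, 6)
  fit <- fit_pmf(tc$X, U, 2, n_starts = 10, seed = 1)
  expect_lt(fit$Q / fit$Q_expected, 0.01)
  mt <- match_factors(fit$F, tc$F_true)
  expect_true(all(mt$similarity > 0.99))
  # rank-1 identity
  g <- matrix(c(1, 2, 3), 3, 1); f <- matrix(c(4, 5), 1, 2)
  X1 <- g %*% f
  fit1 <- fit_pmf(X1, matrix(1, 3, 2), 1, n_starts = 5, seed = 1)
  expect_equal(unname(fit1$G %*% fit1$F), X1, tolerance = 1e-4)
})

test_that("single-factor fits match the SVD brute-force optimum", {
  # with constant U the problem is unweighted rank-1 approximation, whose
  # optimum is the truncated SVD (independent oracle)
  set.seed(9)
  for (k in 1:3) {
    X <- matrix(runif(12, 1, 10), 4, 3)
    sv <- svd(X)
    q_opt <- sum(sv$d[-1]^2)             # residual of the best rank-1 fit
    fit <- fit_pmf(X, matrix(1, 4, 3), 1, n_starts = 10, seed = k,
                   tol = 1e-12, max_iter = 20000)
    expect_equal(fit$Q, q_opt, tolerance = 1e-4)
  }
})

test_that("Q/Q_expected is near 1 for well-specified synthetic data", {
  tc <- generate_pmf_testcase(40, 8, 3, noise_fraction = 0.1, seed = 6)
  fit <- fit_pmf(tc$X, tc$U, 3, n_starts = 5, seed = 1)
  expect_gt(fit$Q / fit$Q_expected, 0.5)
  expect_lt(fit$Q / fit$Q_expected, 2)
})

test_that("contribution and profile percentages are proper shares", {
  tc <- generate_pmf_testcase(30, 7, 3, noise_fraction = 0.1, seed = 2)
  fit <- fit_pmf(tc$X, tc$U, 3, n_starts = 5, seed = 3)
  co <- factor_contributions(fit)
  expect_equal(sum(co), 100, tolerance = 0.1)
  expect_true(all(co >= 0))
  prof <- species_profile_percentages(fit)
  expect_equal(unname(rowSums(prof)), rep(100, 7), tolerance = 0.1)
  # a single factor takes all mass
  fit1 <- fit_pmf(tc$X, tc$U, 1, n_starts = 3, seed = 1)
  expect_equal(unname(factor_contributions(fit1)), 100, tolerance = 1e-9)
  expect_equal(unname(species_profile_percentages(fit1)[, 1]), rep(100, 7))
})

test_that("factor matching recovers permutations and is scale invariant", {
  set.seed(13)
  Ft <- matrix(rgamma(4 * 14, 0.8), 4, 14); Ft <- Ft / rowSums(Ft)
  perm <- c(3, 1, 4, 2)
  mt <- match_factors(Ft[perm, ], Ft)
  # reference factor k should map to the row where it was placed
  expect_equal(mt$perm, order(perm))
  expect_equal(mt$similarity, rep(1, 4), tolerance = 1e-12)
  mt2 <- match_factors(Ft * 10, Ft)
  expect_equal(mt2$similarity, rep(1, 4), tolerance = 1e-12)
  expect_error(match_factors(Ft[, 1:5], Ft), "shape")
})

test_that("random profiles do not spuriously match planted ones", {
  set.seed(17)
  sims <- vapply(1:100, function(s) {
    Ft <- matrix(rgamma(4 * 14, 0.8), 4, 14); Ft <- Ft / rowSums(Ft)
    Fe <- matrix(rgamma(4 * 14, 0.8), 4, 14); Fe <- Fe / rowSums(Fe)
    match_factors(Fe, Ft)$mean_similarity
  }, numeric(1))
  expect_gt(mean(sims < 0.9), 0.95)
})

test_that("fit_pmf validates inputs", {
  X <- matrix(1, 4, 3); U <- matrix(1, 4, 3)
  expect_error(fit_pmf(X, U[1:3, ], 2), "shape")
  expect_error(fit_pmf(X, U, 0), "n_factors")
  expect_error(fit_pmf(X, U, 5), "exceeds")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_pmf(Xna, U, 2), "NA")
  U0 <- U; U0[2, 2] <- 0
  expect_error(fit_pmf(X, U0, 2), "positive")
})
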