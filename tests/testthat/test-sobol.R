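norm01 <- function() dist_spec("normal", mean = 0, sd = 1)

test_that("Saltelli blocks have the required structure", {
  specs <- list(a = norm01(), b = norm01())
  bl <- saltelli_matrices(specs, 64, seed = 1)
  expect_equal(dim(bl$A), c(64L, 2L))
  expect_equal(dim(bl$B), c(64L, 2L))
  expect_length(bl$AB, 2)
  # swapped column comes from B, the rest from A
  expect_identical(bl$AB[["a"]][, "a"], bl$B[, "a"])
  expect_identical(bl$AB[["a"]][, "b"], bl$A[, "b"])
  expect_identical(bl$AB[["b"]][, "b"], bl$B[, "b"])
  bl2 <- saltelli_matrices(specs, 64, seed = 1)
  expect_identical(bl, bl2)
  expect_error(saltelli_matrices(specs["a"], 64), "at least 2")
  expect_error(saltelli_matrices(specs, 32), "N must be")
})

test_that("block marginals match the declared distributions", {
  specs <- list(x = dist_spec("lognormal", meanlog = 1, sdlog = 0.5),
                y = dist_spec("uniform", min = 2, max = 5))
  bl <- saltelli_matrices(specs, 2^13, seed = 2)
  ks_x <- suppressWarnings(stats::ks.test(bl$A[, "x"], function(q) {
    pdist(specs$x, q)
  })$statistic)
  ks_y <- suppressWarnings(stats::ks.test(bl$A[, "y"], function(q) {
    pdist(specs$y, q)
  })$statistic)
  expect_lt(ks_x, 0.05)
  expect_lt(ks_y, 0.05)
})

test_that("additive equal-variance model splits indices evenly", {
  specs <- list(x1 = norm01(), x2 = norm01())
  bl <- saltelli_matrices(specs, 2^14, seed = 1)
  res <- total_order_indices(function(m) m[, 1] + m[, 2], bl)
  expect_equal(res$indices$S_T, c(0.5, 0.5), tolerance = 0.03)
  expect_gt(sum(res$indices$S_T), 0.95)
  expect_lt(sum(res$indices$S_T), 1.05)
})

test_that("inert inputs receive a near-zero total-order index", {
  specs <- list(x1 = norm01(), x2 = norm01())
  bl <- saltelli_matrices(specs, 2^14, seed = 3)
  res <- total_order_indices(function(m) m[, 1], bl)
  st <- stats::setNames(res$indices$S_T, res$indices$input)
  expect_equal(unname(st["x1"]), 1, tolerance = 0.02)
  expect_equal(unname(st["x2"]), 0, tolerance = 0.02)
})

test_that("Ishigami indices match the analytic values", {
  a <- 7; b <- 0.1
  # closed-form variance decomposition, derived from the sine expansion
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  D <- V1 + V2 + V13
  st_true <- c((V1 + V13) / D, V2 / D, V13 / D)
  upi <- dist_spec("uniform", min = -pi, max = pi)
  bl <- saltelli_matrices(list(x1 = upi, x2 = upi, x3 = upi), 2^15, seed = 1)
  res <- total_order_indices(function(m) {
    sin(m[, 1]) + a * sin(m[, 2])^2 + b * m[, 3]^4 * sin(m[, 1])
  }, bl)
  expect_equal(res$indices$S_T, st_true, tolerance = 0.02)
})

test_that("estimates tighten as N doubles", {
  specs <- list(x1 = norm01(), x2 = norm01())
  spread <- function(N) {
    st <- vapply(1:8, function(s) {
      bl <- saltelli_matrices(specs, N, seed = s)
      total_order_indices(function(m) m[, 1] + m[, 2], bl,
                          n_boot = 10)$indices$S_T[1]
    }, numeric(1))
    stats::sd(st)
  }
  expect_lt(spread(2048), spread(256))
})

test_that("ranking sorts by index with alphabetical tie-break", {
  res <- structure(list(indices = data.frame(
    input = c("EF", "CA"), S_T = c(0.1, 0.8), stderr = c(0, 0),
    negative = c(FALSE, FALSE)), N = 64, degenerate = FALSE),
    class = "sobol_result")
  expect_equal(rank_inputs(res), c("CA", "EF"))
  tie <- structure(list(indices = data.frame(
    input = c("b", "a"), S_T = c(0.5, 0.5), stderr = c(0, 0),
    negative = c(FALSE, FALSE)), N = 64, degenerate = FALSE),
    class = "sobol_result")
  expect_equal(rank_inputs(tie), c("a", "b"))
})

test_that("degenerate (zero-variance) models are reported as such", {
  specs <- list(x1 = norm01(), x2 = norm01())
  bl <- saltelli_matrices(specs, 64, seed = 4)
  res <- total_order_indices(function(m) rep(1, nrow(m)), bl)
  expect_true(res$degenerate)
  expect_error(rank_inputs(res), "degenerate")
})

test_that("concentration dominates the cancer-risk ranking when its variance is wide", {
  reg <- fixture_registry()
  # wide-CV species: concentration CV 0.9 vs 10% CV time parameters
  res <- risk_sobol("1,2-Dichloroethane", reg,
                    ca_spec = lognormal_from_moments(265, 239),
                    et_spec = dist_spec("normal", mean = 24, sd = 2.4,
                                        lower = 0, upper = 24),
                    ef_spec = dist_spec("normal", mean = 365, sd = 36.5,
                                        lower = 0, upper = 365),
                    N = 2^13, seed = 1)
  expect_equal(rank_inputs(res)[1], "CA")
})

test_that("time parameters take over when concentration variance is narrow", {
  reg <- fixture_registry()
  # narrow concentration, wide exposure frequency/duration; AT held fixed so
  # ED acts as a free input
  res <- risk_sobol("Carbon tetrachloride", reg,
                    ca_spec = lognormal_from_moments(92, 9),
                    ef_spec = dist_spec("normal", mean = 300, sd = 90,
                                        lower = 0, upper = 365),
                    ed_spec = dist_spec("normal", mean = 74.8, sd = 22,
                                        lower = 0, upper = 100),
                    at_rule = "independent",
                    at_spec = dist_spec("point", value = 74.8 * 365 * 24),
                    N = 2^13, seed = 1)
  expect_true(rank_inputs(res)[1] %in% c("EF", "ED"))
  st <- stats::setNames(res$indices$S_T, res$indices$input)
  expect_lt(unname(st["CA"]), max(st[c("EF", "ED")]))
})
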