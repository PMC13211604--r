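test_that("default campaign has the expected shape and structure", {
  camp <- generate_campaign(campaign_config(seed = 1))
  v <- camp$concentrations$values
  expect_equal(dim(v), c(49L, 14L))
  expect_true(all(v > 0))
  expect_equal(dim(camp$true_contributions), c(49L, 4L))
  expect_equal(dim(camp$true_profiles), c(4L, 14L))
  expect_equal(unname(rowSums(camp$true_profiles)), rep(1, 4), tolerance = 1e-12)
  # regulated CFC columns are near-constant
  reg_cols <- camp$concentrations$registry$category == "regulated_CFC"
  cvs <- apply(v[, reg_cols], 2, stats::sd) / colMeans(v[, reg_cols])
  expect_true(all(cvs < 0.05))
})

test_that("campaign generation is reproducible and noise-controlled", {
  c1 <- generate_campaign(campaign_config(seed = 42))
  c2 <- generate_campaign(campaign_config(seed = 42))
  expect_identical(c1$concentrations$values, c2$concentrations$values)
  expect_identical(c1$tracer, c2$tracer)
  c3 <- generate_campaign(campaign_config(seed = 43))
  expect_false(identical(c1$concentrations$values, c3$concentrations$values))
  # zero noise reproduces the planted product exactly
  c0 <- generate_campaign(campaign_config(seed = 5, noise_fraction = 0))
  expect_equal(unname(c0$concentrations$values),
               unname(c0$true_contributions %*% c0$true_profiles),
               tolerance = 1e-12)
})

test_that("unregulated species show an afternoon diurnal minimum", {
  camp <- generate_campaign(campaign_config(seed = 1))
  dp <- diurnal_profile(camp$concentrations)
  vsls <- camp$concentrations$registry$category == "unregulated_VSLS"
  argmin <- dp$argmin_window[vsls]
  # planted minimum at the 16 h window; accept the adjacent afternoon windows
  expect_true(all(argmin %in% c("14", "16", "18")))
  # the pooled VSLS series bottoms out in the afternoon too
  tot <- rowSums(camp$concentrations$values[, vsls])
  wm <- tapply(tot, camp$concentrations$windows, mean)
  expect_true(names(which.min(wm)) %in% c("14", "16", "18"))
  # and the planted minimum window sits below the morning/evening peaks
  expect_lt(wm[["16"]], wm[["10"]])
  expect_lt(wm[["16"]], wm[["20"]])
})

test_that("CO tracer couples to the solvent-carried species across seeds", {
  cors <- vapply(1:10, function(s) {
    camp <- generate_campaign(campaign_config(seed = s))
    stats::cor(camp$tracer, camp$concentrations$values[, "Chloromethane"])
  }, numeric(1))
  expect_true(all(cors > 0.5))
})

test_that("campaign config validates its invariants", {
  bad_prof <- matrix(1, 4, 14)  # rows do not sum to 1
  expect_error(campaign_config(source_profiles = bad_prof), "sum to 1")
  expect_error(campaign_config(noise_fraction = -0.1), "noise_fraction")
  expect_error(campaign_config(windows = "08"), "2 daily windows")
})

test_that("pmf testcase generator honours its contracts", {
  tc <- generate_pmf_testcase(30, 6, 2, noise_fraction = 0, seed = 1)
  expect_true(all(tc$X >= 0))
  expect_equal(qr(tc$X)$rank, 2)
  expect_equal(tc$X, (tc$G_true %*% tc$F_true), tolerance = 1e-12)
  # U follows the quadrature error rule
  expect_equal(tc$U, sqrt((0.1 * tc$X)^2 +
                            matrix(tc$mdl, 30, 6, byrow = TRUE)^2),
               tolerance = 1e-12)
  # determinism
  tc2 <- generate_pmf_testcase(30, 6, 2, noise_fraction = 0, seed = 1)
  expect_identical(tc$X, tc2$X)
  expect_error(generate_pmf_testcase(5, 3, 4), "exceed")
})

test_that("testcase noise level matches the requested fraction", {
  rel <- vapply(1:10, function(s) {
    tc <- generate_pmf_testcase(60, 10, 3, noise_fraction = 0.1, seed = s)
    M <- tc$G_true %*% tc$F_true
    sqrt(sum((tc$X - M)^2)) / sqrt(sum(tc$X^2))
  }, numeric(1))
  expect_true(all(abs(rel - 0.1) < 0.03))
})

test_that("lognormal series are moment-matched", {
  # methylene chloride scale: mean 563, sd 505
  x <- generate_lognormal_series(563, 505, 1e5, seed = 1)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 563) / 563, 0.02)
  expect_lt(abs(stats::sd(x) - 505) / 505, 0.05)
  # chloromethane scale: positivity at moderate CV
  y <- generate_lognormal_series(785, 261, 1e5, seed = 2)
  expect_true(all(y > 0))
  expect_identical(generate_lognormal_series(100, 0, 5), rep(100, 5))
  expect_error(generate_lognormal_series(0, 1, 10), "mean")
})
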