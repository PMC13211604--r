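test_that("detection filter applies the strict >threshold rule", {
  # 100 samples; detection counts 100, 61, 30
  set.seed(1)
  v <- matrix(10, 100, 3)
  v[1:39, 2] <- 0.1   # below MDL 1 -> detected in 61
  v[1:70, 3] <- 0.1   # detected in 30
  cm <- toy_matrix(v)
  out <- detection_filter(cm, 0.60)
  expect_equal(colnames(out$values), c("sp1", "sp2"))
  expect_equal(attr(out, "dropped")$species, "sp3")
  # 29/49 detected (59.2%) is dropped under >0.60
  v2 <- matrix(10, 49, 2); v2[1:20, 2] <- 0.1
  out2 <- detection_filter(toy_matrix(v2), 0.60)
  expect_equal(colnames(out2$values), "sp1")
  expect_error(detection_filter(cm, 1.2), "threshold")
})

test_that("composition shares are computed on means and sum to 100", {
  set.seed(7)
  v <- matrix(rlnorm(40 * 5, 3, 0.5), 40, 5)
  cm <- toy_matrix(v)
  cs <- composition_summary(cm)
  expect_equal(sum(cs$species$share_pct), 100, tolerance = 0.1)
  expect_equal(sum(cs$groups$total), cs$grand_total, tolerance = 1e-9)
  expect_equal(cs$species$mean, unname(colMeans(v)))
  # single species -> 100%
  cs1 <- composition_summary(toy_matrix(v[, 1, drop = FALSE]))
  expect_equal(cs1$species$share_pct, 100)
  expect_error(composition_summary(toy_matrix(v[0, , drop = FALSE])), "mpty")
})

test_that("diurnal profile reduces to window means and their spread", {
  # one day, seven windows: window means equal the planted values
  vals <- c(270, 265, 260, 255, 260, 265, 270)
  cm <- toy_matrix(matrix(vals, 7, 1), windows = sprintf("w%d", 1:7))
  dp <- diurnal_profile(cm)
  expect_equal(unname(dp$mean[, 1]), vals)
  # sd over the 7 window means, computed independently:
  # sqrt(sum((x - mean(x))^2) / 6) = 5.563486
  expect_equal(unname(dp$sd_of_window_means[1]), 5.563486, tolerance = 1e-5)
  expect_equal(unname(dp$argmin_window[1]), "w4")
  # constant series: zero spread
  cmc <- toy_matrix(matrix(5, 14, 1), windows = rep(sprintf("w%d", 1:7), 2))
  expect_equal(unname(diurnal_profile(cmc)$sd_of_window_means[1]), 0)
})

test_that("correlation matrix matches brute-force Pearson on toy data", {
  set.seed(11)
  v <- matrix(rnorm(5 * 4, 10, 2), 5, 4)
  colnames(v) <- paste0("sp", 1:4)
  cm <- correlation_matrix(v)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    xi <- v[, i]; xj <- v[, j]
    r_bf <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(cm$r[i, j], r_bf, tolerance = 1e-12)
    expect_equal(cm$p[i, j], stats::cor.test(xi, xj)$p.value, tolerance = 1e-10)
  }
  expect_equal(unname(diag(cm$r)), rep(1, 4))
})

test_that("correlation handles exact dependence and degenerate columns", {
  x <- 1:10
  v <- cbind(a = x, b = 2 * x, c = -x + 30)
  cm <- correlation_matrix(v)
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_lt(cm$p["a", "b"], 1e-12)
  vz <- cbind(a = x, z = rep(3, 10))
  expect_warning(cz <- correlation_matrix(vz), "zero-variance")
  expect_true(is.na(cz$r["a", "z"]))
  # independent standard normals stay near zero
  set.seed(3)
  vi <- cbind(a = rnorm(1e4), b = rnorm(1e4))
  expect_lt(abs(correlation_matrix(vi)$r["a", "b"]), 0.05)
})

test_that("tracer regression recovers slopes with OLS properties", {
  x <- seq(1, 20)
  fit <- suppressWarnings(tracer_regression(2 * x, x))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$slope_se, 0, tolerance = 1e-10)
  fit0 <- suppressWarnings(tracer_regression(rep(3, 10), 1:10))
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  # emission-ratio recovery at the campaign scale (slope 1.4)
  set.seed(21)
  co <- rnorm(49, 600, 80)
  y <- 1.4 * co + rnorm(49, 0, 40)
  fr <- tracer_regression(y, co)
  expect_lt(abs(fr$slope - 1.4), 2 * fr$slope_se)
  # invariances: shifts leave the slope alone; scaling the response scales it
  expect_equal(tracer_regression(y + 100, co)$slope, fr$slope, tolerance = 1e-10)
  expect_equal(tracer_regression(y, co + 50)$slope, fr$slope, tolerance = 1e-10)
  expect_equal(tracer_regression(3 * y, co)$slope, 3 * fr$slope, tolerance = 1e-10)
  expect_error(tracer_regression(y, rep(1, 49)), "variance")
})

test_that("background enhancement follows its defining identities", {
  e <- background_enhancement(563, 501)
  expect_equal(e$absolute_enhancement, 62)
  expect_equal(e$percent_enhancement, 100 * 62 / 501)
  expect_equal(background_enhancement(50, 50)$percent_enhancement, 0)
  expect_error(background_enhancement(10, 0), "background")
  # registry-driven table covers exactly the species with backgrounds
  tab <- enhancement_table(fixture_means(), fixture_registry())
  expect_equal(nrow(tab), 11)  # three species lack background values
  expect_true(all(tab$absolute_enhancement ==
                    tab$observed_mean - tab$background))
})
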