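#' Detection-frequency filter
#'
#' Retains species detected (value at or above the species MDL, i.e. flag
#' `FALSE`) in strictly more than `threshold` of the samples; missing values
#' count as non-detections. This mirrors the usual QA rule of keeping only
#' compounds detected in >60% of canister samples.
#'
#' @param matrix `concentration_matrix`.
#' @param threshold detection fraction in (0, 1); strict inequality applies.
#' @return filtered `concentration_matrix` with attribute `"dropped"`
#'   (data frame of removed species and their detection fractions).
#' @export
detection_filter <- function(matrix, threshold = 0.60) {
  stopifnot(inherits(matrix, "concentration_matrix"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  frac <- colMeans(!matrix$below_mdl)
  keep <- frac > threshold
  dropped <- data.frame(species = colnames(matrix$values)[!keep],
                        detection_fraction = unname(frac[!keep]))
  out <- concentration_matrix(matrix$values[, keep, drop = FALSE],
                              matrix$dates, matrix$windows, matrix$registry,
                              below_mdl = matrix$below_mdl[, keep, drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Campaign composition summary
#'
#' Per-species means and SDs over samples (pptv), per-species shares of the
#' grand total of means (%), and regulatory-group totals and shares. Shares
#' are computed on means of samples, not on per-sample shares.
#'
#' @param matrix `concentration_matrix`, or a data frame with columns
#'   `name`, `mean` (and optionally `sd`) of per-species campaign means.
#' @param registry `species_registry`; defaults to the one embedded in
#'   `matrix` when it is a `concentration_matrix`.
#' @return list of class `composition_summary`: `species` (data frame with
#'   `name`, `category`, `mean`, `sd`, `share_pct`), `grand_total` (pptv),
#'   and `groups` (per-category `total` and `share_pct`).
#' @export
composition_summary <- function(matrix, registry = NULL) {
  if (inherits(matrix, "concentration_matrix")) {
    if (nrow(matrix$values) < 1L) stop("empty concentration matrix")
    registry <- registry %||% matrix$registry
    mu <- colMeans(matrix$values, na.rm = TRUE)
    sdv <- apply(matrix$values, 2, stats::sd, na.rm = TRUE)
    nm <- colnames(matrix$values)
  } else {
    tab <- as.data.frame(matrix)
    if (is.null(registry)) stop("a registry is required with a summary table input")
    if (nrow(tab) < 1L) stop("empty species table")
    mu <- tab$mean
    sdv <- tab$sd %||% rep(NA_real_, nrow(tab))
    nm <- tab$name
  }
  cat_of <- registry$category[match(nm, registry$name)]
  if (anyNA(cat_of)) stop("species not in registry: ",
                          paste(nm[is.na(cat_of)], collapse = ", "))
  grand <- sum(mu)
  species <- data.frame(name = nm, category = cat_of, mean = unname(mu),
                        sd = unname(sdv), share_pct = unname(100 * mu / grand),
                        stringsAsFactors = FALSE)
  grp_tot <- tapply(species$mean, species$category, sum)
  groups <- data.frame(category = names(grp_tot), total = as.numeric(grp_tot),
                       share_pct = 100 * as.numeric(grp_tot) / grand,
                       stringsAsFactors = FALSE)
  structure(list(species = species, grand_total = grand, groups = groups),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("<composition_summary> grand total", round(x$grand_total, 1), "pptv\n")
  print(transform(x$species, share_pct = round(share_pct, 1),
                  mean = round(mean, 1), sd = round(sd, 1)))
  print(transform(x$groups, share_pct = round(share_pct, 1),
                  total = round(total, 1)))
  invisible(x)
}

#' Diurnal window profile
#'
#' Per-window mean and SD of each species across sampling days, plus the SD
#' across window means (the magnitude of the diurnal cycle, pptv).
#'
#' @param matrix `concentration_matrix` with window labels on every sample.
#' @return list of class `diurnal_profile`: `windows` (ordered labels),
#'   `mean` and `sd` (windows x species matrices), `sd_of_window_means`
#'   (per species), `argmin_window` (label of the window with the lowest
#'   mean, per species).
#' @export
diurnal_profile <- function(matrix) {
  stopifnot(inherits(matrix, "concentration_matrix"))
  w <- matrix$windows
  if (anyNA(w) || any(w == "")) stop("every sample needs a window label")
  levels_w <- unique(w)
  m <- ncol(matrix$values)
  mean_m <- matrix(NA_real_, length(levels_w), m,
                   dimnames = list(levels_w, colnames(matrix$values)))
  sd_m <- mean_m
  for (lv in levels_w) {
    block <- matrix$values[w == lv, , drop = FALSE]
    mean_m[lv, ] <- colMeans(block, na.rm = TRUE)
    sd_m[lv, ] <- apply(block, 2, stats::sd, na.rm = TRUE)
  }
  sdwm <- apply(mean_m, 2, stats::sd)
  argmin <- levels_w[apply(mean_m, 2, which.min)]
  names(argmin) <- colnames(matrix$values)
  structure(list(windows = levels_w, mean = mean_m, sd = sd_m,
                 sd_of_window_means = sdwm, argmin_window = argmin),
            class = "diurnal_profile")
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson correlations among species columns (and an optional tracer
#' series), with two-sided p-values from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Zero-variance columns yield `NA`
#' (undefined pairs) with a warning.
#'
#' @param matrix `concentration_matrix` or a numeric matrix.
#' @param tracer optional per-sample tracer vector, added as column `CO`.
#' @return list with `r` (correlations, unit diagonal), `p` (two-sided
#'   p-values, `NA` on the diagonal), and `n` (samples used).
#' @export
correlation_matrix <- function(matrix, tracer = NULL) {
  vals <- if (inherits(matrix, "concentration_matrix")) matrix$values else as.matrix(matrix)
  if (!is.null(tracer)) {
    if (length(tracer) != nrow(vals)) stop("tracer length must match sample count")
    vals <- cbind(vals, CO = tracer)
  }
  n <- nrow(vals)
  if (n < 3L) stop("need at least 3 samples")
  zero_var <- apply(vals, 2, function(col) stats::sd(col, na.rm = TRUE) == 0)
  if (any(zero_var)) {
    warning("zero-variance column(s), correlations undefined: ",
            paste(colnames(vals)[zero_var], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r)[!zero_var] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Tracer regression
#'
#' Ordinary least-squares regression (with intercept) of a species series on
#' a tracer series; the slope is the emission-ratio estimate.
#'
#' @param species numeric response series (pptv).
#' @param tracer numeric predictor series (e.g. CO, ppbv); nonzero variance.
#' @return list with `slope`, `slope_se`, `intercept`, `r` (Pearson), `n`.
#' @export
tracer_regression <- function(species, tracer) {
  if (length(species) != length(tracer)) stop("series must have equal length")
  ok <- stats::complete.cases(species, tracer)
  species <- species[ok]; tracer <- tracer[ok]
  if (length(species) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(tracer) == 0) stop("tracer series has zero variance")
  fit <- stats::lm(species ~ tracer)
  co <- summary(fit)$coefficients
  list(slope = unname(co["tracer", "Estimate"]),
       slope_se = unname(co["tracer", "Std. Error"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r = unname(stats::cor(species, tracer)),
       n = length(species))
}

#' Background enhancement
#'
#' Excess of an observed campaign mean over the concurrent hemispheric
#' background level, absolute (pptv) and as a percentage of the background.
#'
#' @param observed_mean observed campaign mean, pptv.
#' @param background background mixing ratio, pptv; must be > 0.
#' @param name optional species name carried into the result.
#' @return data frame (one row) with `name`, `observed_mean`, `background`,
#'   `absolute_enhancement` (pptv) and `percent_enhancement` (%).
#' @examples
#' background_enhancement(563, 501)   # +62 pptv, 12.4%
#' @export
background_enhancement <- function(observed_mean, background, name = NA_character_) {
  if (any(background <= 0)) stop("background must be > 0")
  abs_enh <- observed_mean - background
  data.frame(name = name,
             observed_mean = observed_mean,
             background = background,
             absolute_enhancement = abs_enh,
             percent_enhancement = 100 * abs_enh / background,
             stringsAsFactors = FALSE)
}

#' Enhancement table for a registry
#'
#' Applies [background_enhancement()] to every species with a background
#' value in the registry.
#'
#' @param means data frame with `name` and `mean` columns (pptv).
#' @param registry `species_registry` supplying backgrounds.
#' @return data frame, one row per species with a background.
#' @export
enhancement_table <- function(means, registry) {
  idx <- match(means$name, registry$name)
  bg <- registry$background[idx]
  keep <- !is.na(bg)
  do.call(rbind, Map(background_enhancement,
                     means$mean[keep], bg[keep], means$name[keep]))
}
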