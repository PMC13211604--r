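#' Parametric distribution specification
#'
#' Lightweight description of one uncertain model input. Supported families
#' and parameters:
#' \itemize{
#'   \item `point`: `value`
#'   \item `uniform`: `min`, `max`
#'   \item `triangular`: `min`, `mode`, `max`
#'   \item `normal`: `mean`, `sd`
#'   \item `lognormal`: `meanlog`, `sdlog`
#' }
#' Optional truncation bounds restrict the support; sampling then uses the
#' inverse-CDF of the conditional distribution.
#'
#' @param family one of the five family names.
#' @param ... family parameters as named arguments.
#' @param lower,upper optional truncation bounds (`lower < upper`).
#' @return object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", meanlog = 0, sdlog = 1)
#' dist_spec("normal", mean = 74.8, sd = 7.48, lower = 0, upper = 100)
#' @export
dist_spec <- function(family = c("point", "uniform", "triangular",
                                 "normal", "lognormal"),
                      ..., lower = NULL, upper = NULL) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
    point = "value", uniform = c("min", "max"),
    triangular = c("min", "mode", "max"),
    normal = c("mean", "sd"), lognormal = c("meanlog", "sdlog"))
  if (!all(need %in% names(params))) {
    stop(family, " spec needs parameters: ", paste(need, collapse = ", "))
  }
  params <- params[need]
  if (family == "uniform" && params$min >= params$max) stop("need min < max")
  if (family == "triangular" &&
      !(params$min <= params$mode && params$mode <= params$max &&
        params$min < params$max)) {
    stop("need min <= mode <= max with min < max")
  }
  if (family == "normal" && params$sd < 0) stop("sd must be >= 0")
  if (family == "lognormal" && params$sdlog < 0) stop("sdlog must be >= 0")
  if (!is.null(lower) && !is.null(upper) && lower >= upper) {
    stop("truncation bounds must satisfy lower < upper")
  }
  structure(list(family = family, params = params,
                 lower = lower, upper = upper),
            class = "dist_spec")
}

#' Moment-matched lognormal specification
#'
#' Builds a lognormal `dist_spec` whose arithmetic mean and SD equal the
#' supplied values (`sd = 0` gives a point mass).
#'
#' @param mean arithmetic mean, > 0.
#' @param sd arithmetic standard deviation, >= 0.
#' @return `dist_spec`.
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (sd == 0) return(dist_spec("point", value = mean))
  par <- lognormal_moments(mean, sd)
  dist_spec("lognormal", meanlog = unname(par["meanlog"]),
            sdlog = unname(par["sdlog"]))
}

ptri <- function(q, min, mode, max) {
  out <- numeric(length(q))
  out[q <= min] <- 0
  out[q >= max] <- 1
  i <- q > min & q <= mode
  out[i] <- (q[i] - min)^2 / ((max - min) * (mode - min))
  i <- q > mode & q < max
  out[i] <- 1 - (max - q[i])^2 / ((max - min) * (max - mode))
  out
}

qtri <- function(p, min, mode, max) {
  pc <- (mode - min) / (max - min)
  ifelse(p <= pc,
         min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}

cdf_raw <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    point = as.numeric(q >= p$value),
    uniform = stats::punif(q, p$min, p$max),
    triangular = ptri(q, p$min, p$mode, p$max),
    normal = stats::pnorm(q, p$mean, p$sd),
    lognormal = stats::plnorm(q, p$meanlog, p$sdlog))
}

quantile_raw <- function(spec, pr) {
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, length(pr)),
    uniform = stats::qunif(pr, p$min, p$max),
    triangular = qtri(pr, p$min, p$mode, p$max),
    normal = stats::qnorm(pr, p$mean, p$sd),
    lognormal = stats::qlnorm(pr, p$meanlog, p$sdlog))
}

#' Cumulative distribution function of a spec
#'
#' @param spec `dist_spec`.
#' @param q quantiles.
#' @return F(q), accounting for truncation bounds if present.
#' @export
pdist <- function(spec, q) {
  stopifnot(inherits(spec, "dist_spec"))
  if (is.null(spec$lower) && is.null(spec$upper)) return(cdf_raw(spec, q))
  lo <- if (is.null(spec$lower)) 0 else cdf_raw(spec, spec$lower)
  hi <- if (is.null(spec$upper)) 1 else cdf_raw(spec, spec$upper)
  pmin(pmax((cdf_raw(spec, q) - lo) / (hi - lo), 0), 1)
}

#' Quantile function of a spec
#'
#' @param spec `dist_spec`.
#' @param pr probabilities in `[0, 1]`.
#' @return quantiles, accounting for truncation bounds if present.
#' @export
qdist <- function(spec, pr) {
  stopifnot(inherits(spec, "dist_spec"))
  if (is.null(spec$lower) && is.null(spec$upper)) return(quantile_raw(spec, pr))
  lo <- if (is.null(spec$lower)) 0 else cdf_raw(spec, spec$lower)
  hi <- if (is.null(spec$upper)) 1 else cdf_raw(spec, spec$upper)
  quantile_raw(spec, lo + pr * (hi - lo))
}

#' Random draws from a spec
#'
#' Inverse-CDF sampling (uses the current RNG state; callers set seeds).
#'
#' @param spec `dist_spec`.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
rdist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$family == "point" && is.null(spec$lower) && is.null(spec$upper)) {
    return(rep(spec$params$value, n))
  }
  qdist(spec, stats::runif(n))
}

#' Fit a lognormal distribution
#'
#' Parameters are the mean and SD of the log values (the lognormal MLE up
#' to the SD denominator convention; `stats::sd` with `n - 1` is used).
#' Constant samples return `sdlog = 0` with a degeneracy warning.
#'
#' @param samples at least 5 strictly positive values.
#' @return `dist_spec` of family `lognormal`.
#' @export
fit_lognormal <- function(samples) {
  if (length(samples) < 5L) stop("need at least 5 samples")
  if (any(samples <= 0)) stop("lognormal support requires strictly positive samples")
  lx <- log(samples)
  s <- stats::sd(lx)
  if (s == 0) warning("constant samples: degenerate lognormal (sdlog = 0)")
  dist_spec("lognormal", meanlog = mean(lx), sdlog = s)
}

# Per-family moment/ML fits used by select_distribution().
fit_distribution <- function(samples, family) {
  switch(family,
    point = dist_spec("point", value = mean(samples)),
    uniform = dist_spec("uniform", min = min(samples), max = max(samples)),
    triangular = {
      a <- min(samples); b <- max(samples)
      mode <- min(max(3 * mean(samples) - a - b, a), b)
      dist_spec("triangular", min = a, mode = mode, max = b)
    },
    normal = dist_spec("normal", mean = mean(samples), sd = stats::sd(samples)),
    lognormal = fit_lognormal(samples),
    stop("unknown family: ", family))
}

#' Anderson-Darling statistic
#'
#' `A^2 = -n - (1/n) * sum((2i - 1) * (log F(x_(i)) + log(1 - F(x_(n+1-i)))))`
#' on the order statistics, scoring `samples` against the CDF of `spec`.
#' CDF values numerically at 0 or 1 are clamped (with a warning) to keep
#' the logs finite.
#'
#' @param samples at least 5 numeric values.
#' @param spec `dist_spec` with a computable CDF.
#' @return the A-squared statistic (invariant to input ordering).
#' @export
anderson_darling <- function(samples, spec) {
  n <- length(samples)
  if (n < 5L) stop("need at least 5 samples")
  x <- sort(samples)
  Fx <- pdist(spec, x)
  eps <- .Machine$double.eps
  if (any(Fx <= 0) || any(Fx >= 1)) {
    warning("CDF numerically 0 or 1 at a sample point; clamped")
    Fx <- pmin(pmax(Fx, eps), 1 - eps)
  }
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(Fx) + log(1 - rev(Fx))))
}

#' Select the best-fitting distribution family
#'
#' Fits each candidate family to the samples and ranks them by the
#' Anderson-Darling statistic against the fitted CDF (smaller is better).
#' Selection is by the statistic, not a p-value: composite-test critical
#' values differ by family, while the statistic gives a consistent ranking.
#'
#' @param samples numeric sample vector.
#' @param candidates character vector of at least 2 family names
#'   (default `c("normal", "lognormal")`).
#' @return list with `best` (family name), `spec` (its fitted `dist_spec`)
#'   and `table` (data frame `family`, `A2`, `selected`; unfittable
#'   candidates get `NA`).
#' @export
select_distribution <- function(samples, candidates = c("normal", "lognormal")) {
  if (length(candidates) < 2L) {
    if (length(candidates) == 1L) {
      spec <- fit_distribution(samples, candidates)
      return(list(best = candidates, spec = spec,
                  table = data.frame(family = candidates,
                                     A2 = suppressWarnings(anderson_darling(samples, spec)),
                                     selected = TRUE)))
    }
    stop("need at least one candidate family")
  }
  fits <- lapply(candidates, function(f) {
    tryCatch(fit_distribution(samples, f), error = function(e) NULL)
  })
  a2 <- vapply(seq_along(fits), function(k) {
    if (is.null(fits[[k]])) return(NA_real_)
    tryCatch(suppressWarnings(anderson_darling(samples, fits[[k]])),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(a2))) stop("no candidate family could be fitted")
  best_k <- which.min(a2)
  list(best = candidates[best_k], spec = fits[[best_k]],
       table = data.frame(family = candidates, A2 = a2,
                          selected = seq_along(candidates) == best_k))
}
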