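#' Saltelli sample blocks for total-order Sobol estimation
#'
#' Draws two independent base blocks `A` and `B` of `N` rows from the
#' joint distribution of the (independent) inputs, plus one block
#' `AB[[i]]` per input equal to `A` with its i-th column replaced by the
#' corresponding column of `B`. These are the evaluation designs required
#' by the Jansen total-order estimator. Each block uses Latin-hypercube
#' stratified uniforms per column (mapped through the inverse CDF), which
#' keeps the marginals exact in distribution while reducing estimator
#' variance relative to plain random sampling.
#'
#' @param specs named list of `dist_spec`, one per input (>= 2 inputs).
#' @param N base sample size (>= 64).
#' @param seed integer RNG seed.
#' @return list with `A`, `B` (N x d matrices with input names) and `AB`
#'   (named list of N x d matrices).
#' @export
saltelli_matrices <- function(specs, N, seed = 1L) {
  d <- length(specs)
  if (d < 2L) stop("total-order analysis needs at least 2 inputs (a single input has S_T = 1)")
  if (N < 64) stop("N must be >= 64")
  if (is.null(names(specs)) || any(names(specs) == "")) {
    stop("specs must be a named list")
  }
  set.seed(as.integer(seed))
  draw_block <- function() {
    m <- vapply(specs, function(sp) {
      u <- (sample.int(N) - stats::runif(N)) / N   # Latin-hypercube column
      qdist(sp, u)
    }, numeric(N))
    colnames(m) <- names(specs)
    m
  }
  A <- draw_block()
  B <- draw_block()
  AB <- lapply(seq_len(d), function(i) { M <- A; M[, i] <- B[, i]; M })
  names(AB) <- names(specs)
  list(A = A, B = B, AB = AB)
}

#' Total-order Sobol indices (Jansen estimator)
#'
#' Estimates the total-order index of each input,
#' `S_Ti = mean((f(A) - f(AB_i))^2) / (2 * Var(f))`, with the output
#' variance taken over the combined `A` and `B` evaluations. The
#' total-order index measures the fraction of output variance an input
#' drives alone or through interactions. Small negative estimates can
#' occur within Monte-Carlo noise and are reported raw (flagged), never
#' clipped. Bootstrap standard errors are computed by resampling rows.
#'
#' @param model function mapping a matrix of input rows to a numeric
#'   output vector (one value per row).
#' @param blocks output of [saltelli_matrices()].
#' @param n_boot bootstrap resamples for standard errors (default 200).
#' @return object of class `sobol_result`: data frame `indices` with
#'   `input`, `S_T`, `stderr`, `negative` flag; plus `N`, `variance`,
#'   `degenerate` (TRUE when the output variance is zero, making indices
#'   undefined).
#' @export
total_order_indices <- function(model, blocks, n_boot = 200) {
  A <- blocks$A; B <- blocks$B
  N <- nrow(A)
  fA <- model(A)
  fB <- model(B)
  if (length(fA) != N || length(fB) != N) {
    stop("model must return one output per input row")
  }
  v <- stats::var(c(fA, fB))
  inputs <- colnames(A)
  fAB <- vapply(blocks$AB, model, numeric(N))
  if (!is.finite(v) || v == 0) {
    return(structure(list(indices = data.frame(input = inputs, S_T = NA_real_,
                                               stderr = NA_real_,
                                               negative = NA),
                          N = N, variance = v, degenerate = TRUE),
                     class = "sobol_result"))
  }
  d2 <- (fA - fAB)^2                      # N x d squared differences
  st <- colMeans(d2) / (2 * v)
  se <- vapply(seq_along(inputs), function(i) {
    idx <- matrix(sample.int(N, N * n_boot, replace = TRUE), N, n_boot)
    boot <- colMeans(matrix(d2[idx, i], N, n_boot)) / (2 * v)
    stats::sd(boot)
  }, numeric(1))
  structure(list(indices = data.frame(input = inputs, S_T = unname(st),
                                      stderr = unname(se),
                                      negative = unname(st < 0),
                                      stringsAsFactors = FALSE),
                 N = N, variance = v, degenerate = FALSE),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result> N =", x$N,
      if (x$degenerate) "(degenerate: zero output variance)", "\n")
  df <- x$indices
  df$S_T <- round(df$S_T, 4); df$stderr <- round(df$stderr, 4)
  print(df[order(-df$S_T), ], row.names = FALSE)
  invisible(x)
}

#' Rank inputs by total-order index
#'
#' Descending `S_T` order; exact ties are broken alphabetically by input
#' name.
#'
#' @param result `sobol_result`.
#' @return character vector of input names, most influential first.
#' @export
rank_inputs <- function(result) {
  stopifnot(inherits(result, "sobol_result"))
  if (isTRUE(result$degenerate)) stop("degenerate result: indices undefined")
  df <- result$indices
  df$input[order(-df$S_T, df$input)]
}

#' Sobol sensitivity of the risk chain for one species
#'
#' Convenience wrapper building the LCR (or HQ) model for a single species
#' as a function of the uncertain inputs CA (pptv), ET, EF, ED, AT and IUR
#' or RfC, then estimating total-order indices. With the default
#' `at_rule = "derived"`, AT is `ED * 365 * 24` inside every evaluation and
#' ED cancels out of the exposure factor, so only ET and EF remain as time
#' inputs; with `at_rule = "independent"` an `at_spec` is sampled and ED
#' acts as a free input. Point-mass inputs are held fixed and excluded
#' from the sampled design (their index is 0 by construction).
#'
#' @param species species name (must be in `registry`).
#' @param registry `species_registry`.
#' @param ca_spec `dist_spec` for the mixing ratio (pptv).
#' @param et_spec,ef_spec,ed_spec exposure input specs.
#' @param at_rule `"derived"` or `"independent"`.
#' @param at_spec `dist_spec` for AT (hours) when independent.
#' @param iur_spec,rfc_spec optional toxicity specs (default: registry
#'   point values, held fixed).
#' @param type `"LCR"` or `"HQ"`.
#' @param N base sample size (default 2^14).
#' @param seed integer RNG seed.
#' @param molar_volume L mol^-1.
#' @return `sobol_result`.
#' @export
risk_sobol <- function(species, registry, ca_spec,
                       et_spec = dist_spec("point", value = 24),
                       ef_spec = dist_spec("point", value = 365),
                       ed_spec = dist_spec("normal", mean = 74.8, sd = 7.48,
                                           lower = 0, upper = 100),
                       at_rule = c("derived", "independent"),
                       at_spec = NULL,
                       iur_spec = NULL, rfc_spec = NULL,
                       type = c("LCR", "HQ"), N = 2^14, seed = 1L,
                       molar_volume = 24.45) {
  type <- match.arg(type)
  at_rule <- match.arg(at_rule)
  if (at_rule == "independent" && is.null(at_spec)) {
    stop("independent AT rule requires at_spec")
  }
  row <- registry[registry$name == species, , drop = FALSE]
  if (nrow(row) != 1L) stop("species not in registry: ", species)
  tox_spec <- if (type == "LCR") {
    iur_spec %||% dist_spec("point", value = row$iur)
  } else {
    rfc_spec %||% dist_spec("point", value = row$rfc)
  }
  specs <- list(CA = ca_spec, ET = et_spec, EF = ef_spec, ED = ed_spec)
  if (at_rule == "independent") specs$AT <- at_spec
  specs[[if (type == "LCR") "IUR" else "RfC"]] <- tox_spec
  fixed <- vapply(specs, function(s) s$family == "point", logical(1))
  fixed_vals <- vapply(specs[fixed], function(s) s$params$value, numeric(1))
  free <- specs[!fixed]
  if (length(free) < 2L) stop("need at least 2 non-point inputs")

  mw <- row$mw
  model <- function(mat) {
    get_in <- function(nm) {
      if (nm %in% colnames(mat)) mat[, nm] else fixed_vals[[nm]]
    }
    ca_ug <- pptv_to_ugm3(get_in("CA"), mw, molar_volume)
    efac <- if (at_rule == "derived") {
      get_in("ET") * get_in("EF") / (365 * 24)   # ED/AT cancels
    } else {
      get_in("ET") * get_in("EF") * get_in("ED") / get_in("AT")
    }
    ec <- ca_ug * efac
    if (type == "LCR") ec * get_in("IUR") else ec / (get_in("RfC") * 1000)
  }
  blocks <- saltelli_matrices(free, N, seed)
  total_order_indices(model, blocks)
}
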