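#' Assign measurement uncertainties for receptor modelling
#'
#' Prepares a concentration matrix for uncertainty-weighted factorization
#' using the standard receptor-model censoring rules:
#' \itemize{
#'   \item missing values are imputed with the species median, with a large
#'     uncertainty of `missing_unc_factor` times the median (downweighting);
#'   \item values below the MDL are replaced by `MDL/2` with uncertainty
#'     `5/6 * MDL`;
#'   \item quantified values get `u = sqrt((error_fraction * conc)^2 + MDL^2)`.
#' }
#'
#' @param matrix `concentration_matrix` with below-MDL flags.
#' @param registry `species_registry` supplying MDLs; defaults to the one
#'   embedded in `matrix`.
#' @param error_fraction proportional error term (default 0.1).
#' @param missing_unc_factor uncertainty multiplier for imputed cells
#'   (default 4).
#' @return list with `X` (prepared concentrations), `U` (uncertainties,
#'   strictly positive) and `provenance` (character matrix:
#'   `"quantified"`, `"below_mdl"`, `"imputed"`).
#' @export
assign_uncertainties <- function(matrix, registry = NULL,
                                 error_fraction = 0.1,
                                 missing_unc_factor = 4) {
  stopifnot(inherits(matrix, "concentration_matrix"))
  registry <- registry %||% matrix$registry
  mdl <- registry$mdl[match(colnames(matrix$values), registry$name)]
  if (anyNA(mdl)) stop("every species needs an MDL in the registry")
  X <- matrix$values
  n <- nrow(X); m <- ncol(X)
  U <- matrix(NA_real_, n, m, dimnames = dimnames(X))
  prov <- matrix("quantified", n, m, dimnames = dimnames(X))
  for (j in seq_len(m)) {
    xj <- X[, j]
    miss <- is.na(xj)
    med <- stats::median(xj[!miss])
    below <- !miss & matrix$below_mdl[, j]
    quant <- !miss & !below
    xj[miss] <- med
    xj[below] <- mdl[j] / 2
    uj <- numeric(n)
    uj[miss] <- missing_unc_factor * med
    uj[below] <- 5 / 6 * mdl[j]
    uj[quant] <- sqrt((error_fraction * xj[quant])^2 + mdl[j]^2)
    X[, j] <- xj
    U[, j] <- uj
    prov[miss, j] <- "imputed"
    prov[below, j] <- "below_mdl"
  }
  if (any(!is.finite(U)) || any(U <= 0)) {
    stop("uncertainties must be finite and > 0 (check MDLs and medians)")
  }
  list(X = X, U = U, provenance = prov)
}

#' Uncertainty-weighted positive matrix factorization
#'
#' Factorizes a nonnegative samples x species matrix `X` into nonnegative
#' contributions `G` (samples x factors) and profiles `F` (factors x
#' species) by minimizing the weighted objective
#' `Q = sum(((X - G F) / U)^2)` with multiplicative updates, which keep all
#' entries nonnegative and make `Q` nonincreasing at every iteration. The
#' best (lowest-Q) solution over `n_starts` random initializations is
#' returned; ties go to the earliest start.
#'
#' @param X nonnegative numeric matrix (samples x species).
#' @param U positive uncertainty matrix, same shape as `X`.
#' @param n_factors number of factors, `>= 1` and at most `min(dim(X))`.
#' @param n_starts random restarts (default 20).
#' @param seed master seed; per-start seeds are derived deterministically.
#' @param tol relative Q change declaring convergence (default 1e-8).
#' @param max_iter iteration cap per start (default 5000).
#' @return object of class `pmf_result`: `G`, `F`, `Q`, `Q_expected`
#'   (`n*m - p*(n+m)`), `q_trace` (per-iteration Q of the winning start),
#'   `n_starts`, `best_start`, `best_seed`, `converged`, `iteration_count`.
#' @export
fit_pmf <- function(X, U, n_factors, n_starts = 20, seed = 1L,
                    tol = 1e-8, max_iter = 5000) {
  X <- as.matrix(X); U <- as.matrix(U)
  if (!identical(dim(X), dim(U))) stop("X and U must have the same shape")
  if (anyNA(X)) stop("X contains NA after preparation")
  if (any(X < 0)) stop("X must be nonnegative")
  if (any(U <= 0)) stop("U must be strictly positive")
  if (n_factors < 1L) stop("n_factors must be >= 1")
  if (n_factors > min(dim(X))) stop("n_factors exceeds matrix dimensions")
  n <- nrow(X); m <- ncol(X); p <- as.integer(n_factors)

  W <- 1 / U^2
  XW <- X * W
  eps <- 1e-12
  start_seeds <- derive_seeds(seed, n_starts)
  scale0 <- sqrt(mean(X) / p)

  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(start_seeds[s])
    G <- matrix(stats::runif(n * p, 0.1, 1), n, p) * scale0
    Fm <- matrix(stats::runif(p * m, 0.1, 1), p, m) * scale0
    q_trace <- numeric(0)
    q_prev <- Inf
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      GF <- G %*% Fm
      Fm <- pmax(Fm * (crossprod(G, XW) / pmax(crossprod(G, GF * W), eps)), eps)
      GF <- G %*% Fm
      G <- pmax(G * (XW %*% t(Fm)) / pmax((GF * W) %*% t(Fm), eps), eps)
      GF <- G %*% Fm
      q <- sum(W * (X - GF)^2)
      q_trace <- c(q_trace, q)
      if (is.finite(q_prev) && q_prev > 0 &&
          (q_prev - q) / q_prev < tol) { converged <- TRUE; break }
      if (q == 0) { converged <- TRUE; break }
      q_prev <- q
    }
    if (is.null(best) || q < best$Q) {
      best <- list(G = G, F = Fm, Q = q, q_trace = q_trace,
                   best_start = s, best_seed = start_seeds[s],
                   converged = converged, iteration_count = iter)
    }
  }
  colnames(best$G) <- rownames(best$F) <- paste0("factor", seq_len(p))
  if (!is.null(colnames(X))) colnames(best$F) <- colnames(X)
  structure(c(best,
              list(Q_expected = n * m - p * (n + m),
                   n_starts = n_starts, n_factors = p)),
            class = "pmf_result")
}

#' @export
print.pmf_result <- function(x, ...) {
  cat("<pmf_result> ", nrow(x$G), " samples, ", x$n_factors, " factors; Q = ",
      signif(x$Q, 6), " (Q_expected = ", x$Q_expected, "), ",
      if (x$converged) "converged" else "not converged",
      " in ", x$iteration_count, " iterations (best of ", x$n_starts,
      " starts)\n", sep = "")
  invisible(x)
}

#' Factor contribution percentages
#'
#' Share of the total reconstructed mass `sum(G F)` attributed to each
#' factor; percentages are nonnegative and sum to 100.
#'
#' @param result `pmf_result`.
#' @return named numeric vector of percentages.
#' @export
factor_contributions <- function(result) {
  stopifnot(inherits(result, "pmf_result"))
  mass <- colSums(result$G) * rowSums(result$F)
  tot <- sum(mass)
  if (tot <= 0) stop("all-zero factorization: contributions undefined")
  stats::setNames(100 * mass / tot, colnames(result$G))
}

#' Per-species profile percentages
#'
#' Percentage of each species' reconstructed mass carried by each factor
#' (rows are species and sum to 100); the quantity usually plotted in
#' receptor-model profile figures.
#'
#' @param result `pmf_result`.
#' @return species x factors matrix of percentages.
#' @export
species_profile_percentages <- function(result) {
  stopifnot(inherits(result, "pmf_result"))
  csG <- colSums(result$G)
  M <- t(result$F * csG)                 # species x factors mass
  tot <- rowSums(M)
  if (any(tot <= 0)) {
    stop("species with zero total mass: ",
         paste(rownames(M)[tot <= 0], collapse = ", "))
  }
  out <- 100 * M / tot
  colnames(out) <- colnames(result$G)
  out
}

#' Match estimated factors to reference factors
#'
#' PMF is identifiable only up to permutation and scale, so recovered
#' factors are aligned to a reference by the one-to-one assignment that
#' maximizes the total cosine similarity of the (row-normalized) profiles.
#' The assignment is found by exact enumeration over permutations.
#'
#' @param F_est estimated factors x species profile matrix.
#' @param F_true reference profile matrix, same shape.
#' @return list with `perm` (`perm[k]` = estimated factor matched to
#'   reference factor `k`), `similarity` (cosine per matched pair) and
#'   `mean_similarity`.
#' @export
match_factors <- function(F_est, F_true) {
  F_est <- as.matrix(F_est); F_true <- as.matrix(F_true)
  if (!identical(dim(F_est), dim(F_true))) stop("profile matrices must match in shape")
  p <- nrow(F_est)
  norm_rows <- function(A) A / pmax(sqrt(rowSums(A^2)), .Machine$double.eps)
  C <- norm_rows(F_est) %*% t(norm_rows(F_true))   # est x true cosine
  perms <- all_permutations(p)
  scores <- vapply(perms, function(pr) sum(C[cbind(pr, seq_len(p))]), numeric(1))
  best <- perms[[which.max(scores)]]
  sim <- C[cbind(best, seq_len(p))]
  list(perm = best, similarity = sim, mean_similarity = mean(sim))
}
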