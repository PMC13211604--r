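#' Campaign generator configuration
#'
#' Describes the latent structure of a synthetic monitoring campaign:
#' `n_sources` emission sources with fixed fractional species profiles
#' (rows of `source_profiles`, each summing to 1), per-source lognormal
#' activity with mean per-sample contribution `source_means` (pptv) and
#' coefficient of variation `source_cv`, a per-source diurnal multiplier
#' over the daily sampling windows (`diurnal`, rows normalized to mean 1),
#' per-species multiplicative measurement noise (`noise_fraction`, CV of a
#' mean-1 lognormal), and a combustion tracer (CO) linearly coupled to
#' source activity.
#'
#' The defaults emulate a 7-day, 7-windows-per-day summer canister campaign
#' over 14 halocarbons (49 samples): a near-constant regulated-CFC "bank
#' leakage" source (CV 3%), and three diurnally U-shaped industrial sources
#' carrying the unregulated VSLSs, with planted mass-contribution shares of
#' 19.9/27.8/23.7/28.6% (CFC banks / industrial process / solvent use /
#' electronics cleaning) and an afternoon concentration minimum. Regulated
#' species get measurement noise of 3% and unregulated species 10%.
#'
#' @param registry `species_registry` (default: packaged 14-species table).
#' @param n_days number of sampling days (default 7).
#' @param windows daily window start labels (default 7 windows, 08-20 h).
#' @param source_profiles sources x species nonnegative matrix, rows sum to 1.
#' @param source_means per-source mean contribution per sample, pptv.
#' @param source_cv per-source lognormal CV of the activity.
#' @param diurnal sources x windows positive multiplier matrix.
#' @param noise_fraction per-species (or scalar) multiplicative noise CV.
#' @param tracer_coupling per-source coefficient mapping activity (pptv) to
#'   tracer units (ppbv CO).
#' @param tracer_base,tracer_noise_sd baseline and Gaussian noise of the
#'   tracer series (ppbv).
#' @param seed integer RNG seed.
#' @return list of class `campaign_config`.
#' @export
campaign_config <- function(registry = load_registry(vhh_species()),
                            n_days = 7,
                            windows = c("08", "10", "12", "14", "16", "18", "20"),
                            source_profiles = NULL,
                            source_means = NULL,
                            source_cv = NULL,
                            diurnal = NULL,
                            noise_fraction = NULL,
                            tracer_coupling = NULL,
                            tracer_base = 600,
                            tracer_noise_sd = 20,
                            seed = 1L) {
  if (length(windows) < 2L) stop("need at least 2 daily windows")
  m <- nrow(registry)

  if (is.null(source_profiles)) {
    if (m != 14L) stop("default source profiles require the 14-species registry")
    f <- matrix(0, 4, 14, dimnames = list(
      c("cfc_banks", "industrial_process", "solvent_use", "electronics_cleaning"),
      registry$name))
    f[1, 1:6] <- c(563, 17, 21, 264, 81, 92)          # regulated CFCs
    f[2, c(9, 11, 12)] <- c(73, 265, 67)              # chlorinated feedstocks
    f[3, c(7, 8, 10)] <- c(785, 563, 34)              # solvent species
    f[4, c(13, 14, 10)] <- c(42, 27, 30)              # degreasing agents
    source_profiles <- f / rowSums(f)
  }
  source_profiles <- as.matrix(source_profiles)
  if (ncol(source_profiles) != m) stop("source_profiles must have one column per species")
  if (any(source_profiles < 0)) stop("source profiles must be nonnegative")
  if (any(abs(rowSums(source_profiles) - 1) > 1e-8)) {
    stop("each source profile row must sum to 1")
  }
  p <- nrow(source_profiles)

  if (is.null(source_means)) {
    shares <- c(19.9, 27.8, 23.7, 28.6) / 100
    if (p != 4L) shares <- rep(1 / p, p)
    source_means <- shares * 2924
  }
  if (is.null(source_cv)) source_cv <- c(0.03, rep(0.40, p - 1L))
  if (length(source_means) != p || length(source_cv) != p) {
    stop("source_means and source_cv must have one entry per source")
  }

  if (is.null(diurnal)) {
    u_shape <- c(1.20, 1.30, 1.00, 0.75, 0.60, 0.80, 1.35)
    if (length(windows) != 7L) u_shape <- rep(1, length(windows))
    diurnal <- rbind(rep(1, length(windows)),
                     matrix(rep(u_shape, p - 1L), nrow = p - 1L, byrow = TRUE))
  }
  diurnal <- as.matrix(diurnal)
  if (any(diurnal <= 0)) stop("diurnal multipliers must be > 0")
  if (!identical(dim(diurnal), c(p, length(windows)))) {
    stop("diurnal must be sources x windows")
  }
  diurnal <- diurnal / rowMeans(diurnal)  # mean 1 per source

  if (is.null(noise_fraction)) {
    noise_fraction <- ifelse(registry$category == "regulated_CFC", 0.03, 0.10)
  }
  if (length(noise_fraction) == 1L) noise_fraction <- rep(noise_fraction, m)
  if (any(noise_fraction < 0)) stop("noise_fraction must be >= 0")

  if (is.null(tracer_coupling)) tracer_coupling <- c(0, 0, 0.25, 0)[seq_len(p)]

  structure(list(registry = registry, n_days = n_days, windows = windows,
                 source_profiles = source_profiles, source_means = source_means,
                 source_cv = source_cv, diurnal = diurnal,
                 noise_fraction = noise_fraction,
                 tracer_coupling = tracer_coupling, tracer_base = tracer_base,
                 tracer_noise_sd = tracer_noise_sd, seed = as.integer(seed)),
            class = "campaign_config")
}

# lognormal multiplier with mean 1 and given CV
rlnorm_mean1 <- function(n, cv) {
  if (length(cv) == 1L && cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic campaign
#'
#' Draws a campaign from a [campaign_config()]: per-sample source activities
#' `G_true` (lognormal, diurnally modulated), fixed profiles `F_true`, and
#' observed concentrations `X = (G_true %*% F_true) * noise` with
#' multiplicative lognormal noise, so the planted factor structure holds
#' exactly up to the noise term and all entries stay positive. Values below
#' a species MDL are retained but flagged. A CO tracer series coupled to
#' the configured source is returned alongside.
#'
#' @param config `campaign_config`.
#' @return list of class `synthetic_campaign` with elements
#'   `concentrations` ([concentration_matrix]), `true_contributions`
#'   (samples x sources), `true_profiles` (sources x species), `tracer`
#'   (per-sample CO, ppbv), and `config`.
#' @examples
#' camp <- generate_campaign(campaign_config(seed = 1))
#' dim(camp$concentrations)          # 49 x 14
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(config$seed)
  reg <- config$registry
  nw <- length(config$windows)
  n <- config$n_days * nw
  p <- nrow(config$source_profiles)
  m <- nrow(reg)

  window_idx <- rep(seq_len(nw), times = config$n_days)
  dates <- rep(sprintf("day%02d", seq_len(config$n_days)), each = nw)

  G <- matrix(0, n, p)
  for (k in seq_len(p)) {
    G[, k] <- config$source_means[k] * config$diurnal[k, window_idx] *
      rlnorm_mean1(n, config$source_cv[k])
  }
  colnames(G) <- rownames(config$source_profiles)

  noise <- matrix(1, n, m)
  for (j in seq_len(m)) noise[, j] <- rlnorm_mean1(n, config$noise_fraction[j])

  X <- (G %*% config$source_profiles) * noise
  colnames(X) <- reg$name

  tracer <- config$tracer_base + as.vector(G %*% config$tracer_coupling) +
    stats::rnorm(n, 0, config$tracer_noise_sd)

  conc <- concentration_matrix(X, dates, config$windows[window_idx], reg)
  structure(list(concentrations = conc,
                 true_contributions = G,
                 true_profiles = config$source_profiles,
                 tracer = tracer,
                 config = config),
            class = "synthetic_campaign")
}

#' @export
print.synthetic_campaign <- function(x, ...) {
  cat("<synthetic_campaign> ", nrow(x$true_contributions), " samples, ",
      ncol(x$true_contributions), " planted sources\n", sep = "")
  shares <- 100 * colSums(x$true_contributions) / sum(x$true_contributions)
  cat("realized source shares (%):",
      paste(sprintf("%s %.1f", colnames(x$true_contributions), shares),
            collapse = ", "), "\n")
  invisible(x)
}

#' Planted factorization test case
#'
#' Generates a generic nonnegative factorization problem with known ground
#' truth for validating the PMF solver: lognormal contributions `G_true`,
#' Dirichlet-style profiles `F_true` (rows sum to 1), observations
#' `X = (G_true %*% F_true) * noise`, and an uncertainty matrix built by the
#' standard receptor-model rule `u = sqrt((0.1 x)^2 + MDL^2)`.
#'
#' The planted truth is made identifiable by two-sided anchoring: species
#' `k` loads only on source `k` (a marker species), and sample `k` receives
#' activity only from source `k` (a pure-plume sample). With zeros on both
#' sides, the exact (noiseless) nonnegative factorization is unique up to
#' permutation and scale, so planted-recovery oracles are well defined;
#' with strictly positive factors an exact fit could be a valid rotation of
#' the truth.
#'
#' @param n_samples,n_species,n_sources problem dimensions;
#'   `n_sources <= min(n_samples, n_species)`.
#' @param noise_fraction CV of the multiplicative lognormal noise (default 0.1).
#' @param seed integer RNG seed.
#' @param mdl per-species MDL vector (default: 1% of each species' median).
#' @return list with `X`, `U`, `G_true`, `F_true`, `mdl`.
#' @export
generate_pmf_testcase <- function(n_samples, n_species, n_sources,
                                  noise_fraction = 0.1, seed = 1L,
                                  mdl = NULL) {
  if (n_sources > min(n_samples, n_species)) {
    stop("n_sources must not exceed min(n_samples, n_species)")
  }
  if (n_sources < 1L) stop("n_sources must be >= 1")
  set.seed(as.integer(seed))
  G <- matrix(stats::rlnorm(n_samples * n_sources, meanlog = 3, sdlog = 0.6),
              n_samples, n_sources)
  F_raw <- matrix(stats::rgamma(n_sources * n_species, shape = 0.8),
                  n_sources, n_species)
  for (k in seq_len(n_sources)) {
    F_raw[, k] <- 0                     # marker species: k loads only on k
    F_raw[k, k] <- stats::rgamma(1, shape = 2) + 0.5
    zero <- G[k, k]                     # pure-plume sample for source k
    G[k, ] <- 0
    G[k, k] <- zero
  }
  F_true <- F_raw / rowSums(F_raw)
  noise <- matrix(rlnorm_mean1(n_samples * n_species, noise_fraction),
                  n_samples, n_species)
  X <- (G %*% F_true) * noise
  if (is.null(mdl)) mdl <- 0.01 * apply(X, 2, stats::median)
  if (length(mdl) == 1L) mdl <- rep(mdl, n_species)
  U <- sqrt((0.1 * X)^2 + matrix(mdl, n_samples, n_species, byrow = TRUE)^2)
  list(X = X, U = U, G_true = G, F_true = F_true, mdl = mdl)
}

#' Moment-matched lognormal draws
#'
#' Draws `n` lognormal samples whose distribution has the given arithmetic
#' mean and standard deviation (parameters solved by moment matching:
#' `sdlog^2 = log(1 + (sd/mean)^2)`, `meanlog = log(mean) - sdlog^2/2`).
#' `sd = 0` degenerates to a constant series at `mean`.
#'
#' @param mean arithmetic mean, > 0 (pptv in typical use).
#' @param sd arithmetic standard deviation, >= 0.
#' @param n number of draws.
#' @param seed integer RNG seed.
#' @return numeric vector of `n` positive draws.
#' @export
generate_lognormal_series <- function(mean, sd, n, seed = 1L) {
  if (mean <= 0) stop("mean must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  set.seed(as.integer(seed))
  if (sd == 0) return(rep(mean, n))
  par <- lognormal_moments(mean, sd)
  stats::rlnorm(n, meanlog = par["meanlog"], sdlog = par["sdlog"])
}

#' Write campaign ground truth to CSV
#'
#' Companion truth files for a synthetic campaign: `G_true.csv` (samples x
#' sources contributions) and `F_true.csv` (sources x species profiles).
#'
#' @param campaign `synthetic_campaign`.
#' @param dir output directory (created if absent).
#' @return character vector of the two paths, invisibly.
#' @export
write_campaign_truth <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "G_true.csv")
  fp <- file.path(dir, "F_true.csv")
  utils::write.csv(as.data.frame(campaign$true_contributions), gp, row.names = FALSE)
  utils::write.csv(as.data.frame(campaign$true_profiles), fp, row.names = TRUE)
  invisible(c(gp, fp))
}
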