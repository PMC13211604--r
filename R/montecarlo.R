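#' Monte-Carlo configuration for the risk chain
#'
#' Declares the uncertain inputs of the inhalation risk model as
#' [dist_spec()] objects. Defaults: per-species ambient mixing ratios (CA,
#' pptv) are lognormal, moment-matched to the campaign mean/SD table;
#' exposure time and frequency are point values (ET 24 h d^-1,
#' EF 365 d a^-1); exposure duration ED is normal with mean 74.8 a and a
#' 10% CV, truncated to (0, 100]; IUR and RfC are point values from the
#' registry. The averaging time AT is by default derived within each draw
#' as `ED * 365 * 24` (fully correlated with ED); an independent AT spec
#' may be supplied instead.
#'
#' @param registry `species_registry`.
#' @param means data frame `name`, `mean`, `sd` (pptv) for the CA fits.
#' @param n_iter draws per replication (default 10000, minimum 100).
#' @param n_rep replications (default 100, minimum 2).
#' @param seed master seed; replication seeds are derived from it, so
#'   increasing `n_rep` preserves earlier replications.
#' @param ca_specs optional named list of `dist_spec` overriding CA per
#'   species.
#' @param et_spec,ef_spec,ed_spec exposure-parameter specs.
#' @param at_rule `"derived"` (AT = ED*365*24 per draw) or `"independent"`.
#' @param at_spec `dist_spec` for AT when `at_rule = "independent"`.
#' @param iur_specs,rfc_specs optional named lists of `dist_spec`
#'   overriding the registry point values.
#' @param molar_volume L mol^-1 for the pptv conversion.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(registry = load_registry(vhh_species()),
                      means = vhh_campaign_means(),
                      n_iter = 10000, n_rep = 100, seed = 1L,
                      ca_specs = NULL,
                      et_spec = dist_spec("point", value = 24),
                      ef_spec = dist_spec("point", value = 365),
                      ed_spec = dist_spec("normal", mean = 74.8, sd = 7.48,
                                          lower = 0, upper = 100),
                      at_rule = c("derived", "independent"),
                      at_spec = NULL,
                      iur_specs = NULL, rfc_specs = NULL,
                      molar_volume = 24.45) {
  if (n_iter < 100) stop("n_iter must be >= 100")
  if (n_rep < 2) stop("n_rep must be >= 2")
  at_rule <- match.arg(at_rule)
  if (at_rule == "independent" && is.null(at_spec)) {
    stop("independent AT rule requires at_spec")
  }
  idx <- match(means$name, registry$name)
  if (anyNA(idx)) stop("species not in registry: ",
                       paste(means$name[is.na(idx)], collapse = ", "))
  reg <- registry[idx, , drop = FALSE]
  if (is.null(ca_specs)) {
    ca_specs <- stats::setNames(
      Map(lognormal_from_moments, means$mean, means$sd), means$name)
  }
  if (!all(means$name %in% names(ca_specs))) stop("ca_specs must cover every species")
  point_or <- function(overrides, values, names) {
    out <- stats::setNames(lapply(values, function(v) {
      if (is.na(v)) NULL else dist_spec("point", value = v)
    }), names)
    for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
    out
  }
  structure(list(registry = reg, means = means,
                 n_iter = as.integer(n_iter), n_rep = as.integer(n_rep),
                 seed = as.integer(seed),
                 ca_specs = ca_specs, et_spec = et_spec, ef_spec = ef_spec,
                 ed_spec = ed_spec, at_rule = at_rule, at_spec = at_spec,
                 iur_specs = point_or(iur_specs, reg$iur, reg$name),
                 rfc_specs = point_or(rfc_specs, reg$rfc, reg$name),
                 molar_volume = molar_volume),
            class = "mc_config")
}

#' Replicated Monte-Carlo of a scalar model
#'
#' Low-level engine: runs `n_rep` independent replications of `n_iter`
#' draws of `draw_fun` (a function of a draw count returning that many
#' model outputs), retaining per-replication means and SDs, pooled
#' summaries and the MCE/SD convergence diagnostic. Replication seeds are
#' derived deterministically from `seed`.
#'
#' @param draw_fun `function(n)` returning `n` output draws.
#' @param n_iter draws per replication.
#' @param n_rep number of replications (>= 2).
#' @param seed master seed.
#' @return list with `rep_means`, `rep_sds`, `summary`
#'   (mean/median/p95 of the pooled draws), `mce` (SD of replication
#'   means), `sd` (minimum replication SD), `mce_sd_ratio_pct`, `pass`
#'   (ratio < 5), `draws` (pooled vector), `seeds`.
#' @export
replicated_mc <- function(draw_fun, n_iter, n_rep, seed = 1L) {
  if (n_rep < 2) stop("n_rep must be >= 2")
  seeds <- derive_seeds(seed, n_rep)
  draws <- matrix(NA_real_, n_iter, n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(seeds[r])
    draws[, r] <- draw_fun(n_iter)
  }
  rep_means <- colMeans(draws)
  rep_sds <- apply(draws, 2, stats::sd)
  conv <- mce_sd_ratio(rep_means, rep_sds)
  pooled <- as.vector(draws)
  c(list(rep_means = rep_means, rep_sds = rep_sds,
         summary = summarize_draws(pooled), draws = pooled, seeds = seeds),
    conv)
}

#' MCE/SD convergence ratio
#'
#' Monte-Carlo error (MCE) is the standard deviation of the replication
#' means; SD is the minimum of the within-replication standard deviations
#' (a conservative choice that inflates the ratio). The diagnostic is
#' `100 * MCE / SD` (%); below 5% is conventionally acceptable. A zero SD
#' (degenerate output) makes the ratio undefined and is reported as `NA`.
#'
#' @param rep_means per-replication means (>= 2).
#' @param rep_sds per-replication standard deviations.
#' @return list with `mce`, `sd`, `mce_sd_ratio_pct` (`NA` if undefined)
#'   and `pass` (`ratio < 5`, `NA` if undefined).
#' @export
mce_sd_ratio <- function(rep_means, rep_sds) {
  if (length(rep_means) < 2L) stop("need at least 2 replications")
  if (length(rep_means) != length(rep_sds)) stop("means and SDs must align")
  mce <- stats::sd(rep_means)
  sd_min <- min(rep_sds)
  if (sd_min == 0) {
    return(list(mce = mce, sd = sd_min, mce_sd_ratio_pct = NA_real_,
                pass = NA))
  }
  ratio <- 100 * mce / sd_min
  list(mce = mce, sd = sd_min, mce_sd_ratio_pct = ratio, pass = ratio < 5)
}

#' Summary statistics of a draw vector
#'
#' Mean, median and 95th percentile (linear-interpolation quantile).
#'
#' @param draws nonempty numeric vector.
#' @return list with `mean`, `median`, `p95`.
#' @export
summarize_draws <- function(draws) {
  if (length(draws) < 1L) stop("empty draws")
  list(mean = mean(draws),
       median = stats::median(draws),
       p95 = unname(stats::quantile(draws, 0.95, type = 7)))
}

#' Replicated Monte-Carlo risk simulation
#'
#' Propagates the configured input distributions through the full risk
#' chain (pptv conversion, EC, LCR, HQ) in `n_rep` replications of
#' `n_iter` draws. Within a draw, ET/EF/ED (and the derived AT) are shared
#' across species; CA draws are independent across species. Outputs are
#' the per-species LCR (species with an IUR), cumulative LCR, per-species
#' HQ (species with an RfC) and HI.
#'
#' @param config `mc_config`.
#' @param keep_draws retain pooled draws per output (needed for the
#'   summaries; default `TRUE`).
#' @return object of class `mc_result`: `summary` data frame (per output:
#'   mean, median, p95, MCE, SD, `mce_sd_ratio_pct`, `pass`), `rep_means`
#'   and `rep_sds` (n_rep x outputs matrices), `draws` (named list of
#'   pooled draw vectors, if kept), `seeds`, `config`.
#' @export
run_mc <- function(config, keep_draws = TRUE) {
  stopifnot(inherits(config, "mc_config"))
  reg <- config$registry
  n <- config$n_iter
  seeds <- derive_seeds(config$seed, config$n_rep)

  lcr_species <- reg$name[!vapply(config$iur_specs[reg$name], is.null, logical(1))]
  hq_species <- reg$name[!vapply(config$rfc_specs[reg$name], is.null, logical(1))]
  out_names <- c(paste0("LCR_", lcr_species), "LCR_total",
                 paste0("HQ_", hq_species), "HI")
  K <- length(out_names)

  rep_means <- matrix(NA_real_, config$n_rep, K, dimnames = list(NULL, out_names))
  rep_sds <- rep_means
  pooled <- if (keep_draws) {
    stats::setNames(lapply(seq_len(K), function(k) {
      numeric(n * config$n_rep)
    }), out_names)
  } else NULL

  mw <- stats::setNames(reg$mw, reg$name)
  for (r in seq_len(config$n_rep)) {
    set.seed(seeds[r])
    ET <- rdist(config$et_spec, n)
    EF <- rdist(config$ef_spec, n)
    ED <- rdist(config$ed_spec, n)
    AT <- if (config$at_rule == "derived") ED * 365 * 24 else rdist(config$at_spec, n)
    efac <- ET * EF * ED / AT

    out <- matrix(0, n, K, dimnames = list(NULL, out_names))
    lcr_total <- numeric(n)
    hi <- numeric(n)
    for (sp in reg$name) {
      ca_ug <- pptv_to_ugm3(rdist(config$ca_specs[[sp]], n), mw[[sp]],
                            config$molar_volume)
      ec <- ca_ug * efac
      if (sp %in% lcr_species) {
        lcr <- ec * rdist(config$iur_specs[[sp]], n)
        out[, paste0("LCR_", sp)] <- lcr
        lcr_total <- lcr_total + lcr
      }
      if (sp %in% hq_species) {
        hq <- ec / (rdist(config$rfc_specs[[sp]], n) * 1000)
        out[, paste0("HQ_", sp)] <- hq
        hi <- hi + hq
      }
    }
    out[, "LCR_total"] <- lcr_total
    out[, "HI"] <- hi

    rep_means[r, ] <- colMeans(out)
    rep_sds[r, ] <- apply(out, 2, stats::sd)
    if (keep_draws) {
      at <- ((r - 1L) * n + 1L):(r * n)
      for (k in seq_len(K)) pooled[[k]][at] <- out[, k]
    }
  }

  summary <- do.call(rbind, lapply(seq_len(K), function(k) {
    conv <- mce_sd_ratio(rep_means[, k], rep_sds[, k])
    s <- if (keep_draws) summarize_draws(pooled[[k]]) else
      list(mean = mean(rep_means[, k]), median = NA_real_, p95 = NA_real_)
    data.frame(output = out_names[k], mean = s$mean, median = s$median,
               p95 = s$p95, MCE = conv$mce, SD = conv$sd,
               mce_sd_ratio_pct = conv$mce_sd_ratio_pct, pass = conv$pass,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, rep_means = rep_means, rep_sds = rep_sds,
                 draws = pooled, seeds = seeds, config = config),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result> ", x$config$n_rep, " replications x ", x$config$n_iter,
      " draws (seed ", x$config$seed, ")\n", sep = "")
  df <- x$summary
  df$mean <- signif(df$mean, 3); df$median <- signif(df$median, 3)
  df$p95 <- signif(df$p95, 3); df$MCE <- signif(df$MCE, 3)
  df$SD <- signif(df$SD, 3)
  df$mce_sd_ratio_pct <- round(df$mce_sd_ratio_pct, 2)
  print(df)
  invisible(x)
}
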