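#' Pipeline run configuration
#'
#' Collects paths, stage toggles and stage parameters for an end-to-end
#' campaign analysis. With no `input_csv`, a synthetic campaign is
#' generated (stage `simulate`); otherwise the CSV is loaded. A single
#' global seed deterministically derives per-stage seeds (stage-name
#' hashing), so any stage can be rerun in isolation with the same result.
#'
#' @param output_dir directory for all artifacts (created if needed).
#' @param seed global integer seed.
#' @param input_csv optional campaign CSV (see [read_campaign_csv()]).
#' @param registry `species_registry`.
#' @param stages character vector of stages to run, in pipeline order,
#'   from: `simulate`, `describe`, `pmf`, `risk`, `distfit`, `mc`, `sobol`.
#' @param filter_threshold detection-fraction threshold (strict `>`).
#' @param pmf_factors,pmf_starts PMF factor count and random restarts.
#' @param mc_n_iter,mc_n_rep Monte-Carlo draws per replication and
#'   replication count (`mc_n_rep >= 2`, validated here).
#' @param sobol_n Sobol base sample size.
#' @param sobol_species species for the sensitivity stage (default: the
#'   species with the highest deterministic LCR).
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir,
                       seed = 1L,
                       input_csv = NULL,
                       registry = load_registry(vhh_species()),
                       stages = c("simulate", "describe", "pmf", "risk",
                                  "distfit", "mc", "sobol"),
                       filter_threshold = 0.60,
                       pmf_factors = 4, pmf_starts = 20,
                       mc_n_iter = 10000, mc_n_rep = 100,
                       sobol_n = 2^13,
                       sobol_species = NULL) {
  known <- c("simulate", "describe", "pmf", "risk", "distfit", "mc", "sobol")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(input_csv) && !file.exists(input_csv)) {
    stop("input_csv not found: ", input_csv)
  }
  if (mc_n_rep < 2) stop("mc_n_rep must be >= 2")
  if (mc_n_iter < 100) stop("mc_n_iter must be >= 100")
  if (filter_threshold <= 0 || filter_threshold >= 1) {
    stop("filter_threshold must be in (0, 1)")
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 input_csv = input_csv, registry = registry,
                 stages = known[known %in% stages],
                 filter_threshold = filter_threshold,
                 pmf_factors = pmf_factors, pmf_starts = pmf_starts,
                 mc_n_iter = mc_n_iter, mc_n_rep = mc_n_rep,
                 sobol_n = sobol_n, sobol_species = sobol_species),
            class = "run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads a flat mapping of [run_config()] arguments (e.g. `output_dir`,
#' `seed`, `stages`, `mc_n_iter`) from a `.yaml`/`.yml` or `.json` file.
#'
#' @param path configuration file.
#' @param ... overrides passed to [run_config()] on top of the file values.
#' @return `run_config` object.
#' @export
run_config_from_file <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json")
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

# stage-name hashing: stable seed per stage below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1))
}

#' Run the full campaign pipeline
#'
#' Executes the configured stages in order: campaign simulation (or CSV
#' load), detection filtering and descriptive statistics, PMF source
#' apportionment, deterministic risk, distribution fitting, replicated
#' Monte-Carlo risk, and Sobol sensitivity. Every artifact is written under
#' `output_dir` and listed in a manifest (stage, file, seed, md5). A stage
#' failure aborts the downstream stages and is reported in `$error`.
#'
#' @param config `run_config`.
#' @return list of class `report_bundle` with per-stage results, `manifest`
#'   (data frame) and `error` (`NULL` on success).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config, error = NULL)
  manifest <- data.frame(stage = character(), artifact = character(),
                         seed = integer(), md5 = character(),
                         stringsAsFactors = FALSE)
  art <- function(stage, file, seed) {
    path <- file.path(config$output_dir, file)
    manifest <<- rbind(manifest, data.frame(
      stage = stage, artifact = file, seed = seed,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE))
    path
  }
  run_stage <- function(stage, fun) {
    if (!(stage %in% config$stages) || !is.null(bundle$error)) return(invisible())
    sseed <- stage_seed(config$seed, stage)
    res <- tryCatch(fun(sseed), error = function(e) e)
    if (inherits(res, "error")) {
      bundle$error <<- list(stage = stage, message = conditionMessage(res))
    } else {
      bundle[[stage]] <<- res
    }
    invisible()
  }

  run_stage("simulate", function(sseed) {
    if (is.null(config$input_csv)) {
      camp <- generate_campaign(campaign_config(registry = config$registry,
                                                seed = sseed))
      path <- file.path(config$output_dir, "campaign.csv")
      write_campaign_csv(camp$concentrations, path)
      write_campaign_truth(camp, config$output_dir)
      art("simulate", "campaign.csv", sseed)
      art("simulate", "G_true.csv", sseed)
      art("simulate", "F_true.csv", sseed)
      camp
    } else {
      conc <- read_campaign_csv(config$input_csv, config$registry)
      file.copy(config$input_csv, file.path(config$output_dir, "campaign.csv"),
                overwrite = TRUE)
      art("simulate", "campaign.csv", sseed)
      list(concentrations = conc, tracer = NULL)
    }
  })
  campaign <- bundle$simulate

  run_stage("describe", function(sseed) {
    conc <- detection_filter(campaign$concentrations, config$filter_threshold)
    comp <- composition_summary(conc)
    diur <- diurnal_profile(conc)
    corr <- correlation_matrix(conc, tracer = campaign$tracer)
    means <- data.frame(name = comp$species$name, mean = comp$species$mean)
    enh <- enhancement_table(means, conc$registry)
    utils::write.csv(comp$species,
                     file.path(config$output_dir, "composition.csv"),
                     row.names = FALSE)
    utils::write.csv(enh, file.path(config$output_dir, "enhancement.csv"),
                     row.names = FALSE)
    art("describe", "composition.csv", sseed)
    art("describe", "enhancement.csv", sseed)
    list(filtered = conc, composition = comp, diurnal = diur,
         correlation = corr, enhancement = enh,
         dropped = attr(conc, "dropped"))
  })

  run_stage("pmf", function(sseed) {
    conc <- bundle$describe$filtered %||% campaign$concentrations
    prep <- assign_uncertainties(conc)
    fit <- fit_pmf(prep$X, prep$U, n_factors = config$pmf_factors,
                   n_starts = config$pmf_starts, seed = sseed)
    contrib <- factor_contributions(fit)
    prof <- species_profile_percentages(fit)
    utils::write.csv(as.data.frame(fit$G), file.path(config$output_dir, "G.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fit$F), file.path(config$output_dir, "F.csv"))
    utils::write.csv(data.frame(factor = names(contrib), pct = contrib),
                     file.path(config$output_dir, "contributions.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(prof),
                     file.path(config$output_dir, "profile_percentages.csv"))
    jsonlite::write_json(list(Q = fit$Q, Q_expected = fit$Q_expected,
                              n_starts = fit$n_starts,
                              best_seed = fit$best_seed,
                              converged = fit$converged,
                              iteration_count = fit$iteration_count,
                              seed = sseed),
                         file.path(config$output_dir, "fit_report.json"),
                         auto_unbox = TRUE)
    for (f in c("G.csv", "F.csv", "contributions.csv",
                "profile_percentages.csv", "fit_report.json")) {
      art("pmf", f, sseed)
    }
    list(prep = prep, fit = fit, contributions = contrib, profiles = prof)
  })

  run_stage("risk", function(sseed) {
    conc <- bundle$describe$filtered %||% campaign$concentrations
    means <- data.frame(name = colnames(conc$values),
                        mean = colMeans(conc$values, na.rm = TRUE))
    rt <- risk_table(means, conc$registry)
    out <- rt$species
    out$seed <- sseed
    utils::write.csv(out, file.path(config$output_dir, "risk.csv"),
                     row.names = FALSE)
    art("risk", "risk.csv", sseed)
    rt
  })

  run_stage("distfit", function(sseed) {
    conc <- bundle$describe$filtered %||% campaign$concentrations
    mdl <- conc$registry$mdl
    tabs <- lapply(seq_len(ncol(conc$values)), function(j) {
      x <- conc$values[, j]
      x[conc$below_mdl[, j]] <- mdl[j] / 2   # censoring substitution
      sel <- select_distribution(x[!is.na(x)])
      data.frame(species = colnames(conc$values)[j], sel$table)
    })
    tab <- do.call(rbind, tabs)
    utils::write.csv(tab, file.path(config$output_dir, "distribution_fits.csv"),
                     row.names = FALSE)
    art("distfit", "distribution_fits.csv", sseed)
    tab
  })

  run_stage("mc", function(sseed) {
    conc <- bundle$describe$filtered %||% campaign$concentrations
    means <- data.frame(name = colnames(conc$values),
                        mean = colMeans(conc$values, na.rm = TRUE),
                        sd = apply(conc$values, 2, stats::sd, na.rm = TRUE))
    cfg <- mc_config(registry = conc$registry, means = means,
                     n_iter = config$mc_n_iter, n_rep = config$mc_n_rep,
                     seed = sseed)
    res <- run_mc(cfg)
    utils::write.csv(res$summary, file.path(config$output_dir, "mc_summary.csv"),
                     row.names = FALSE)
    diag <- data.frame(replication = seq_len(cfg$n_rep), seed = res$seeds,
                       mean_LCR_total = res$rep_means[, "LCR_total"],
                       sd_LCR_total = res$rep_sds[, "LCR_total"],
                       mean_HI = res$rep_means[, "HI"],
                       sd_HI = res$rep_sds[, "HI"])
    utils::write.csv(diag, file.path(config$output_dir, "mc_replications.csv"),
                     row.names = FALSE)
    art("mc", "mc_summary.csv", sseed)
    art("mc", "mc_replications.csv", sseed)
    res
  })

  run_stage("sobol", function(sseed) {
    conc <- bundle$describe$filtered %||% campaign$concentrations
    reg <- conc$registry
    sp <- config$sobol_species
    if (is.null(sp)) {
      means <- data.frame(name = colnames(conc$values),
                          mean = colMeans(conc$values, na.rm = TRUE))
      rt <- risk_table(means, reg)
      lcr <- rt$species[!is.na(rt$species$LCR), ]
      sp <- lcr$name[which.max(lcr$LCR)]
    }
    mu <- mean(conc$values[, sp], na.rm = TRUE)
    sdv <- stats::sd(conc$values[, sp], na.rm = TRUE)
    res <- risk_sobol(sp, reg, ca_spec = lognormal_from_moments(mu, sdv),
                      N = config$sobol_n, seed = sseed)
    out <- res$indices
    out$rank <- match(out$input, rank_inputs(res))
    out$species <- sp
    utils::write.csv(out, file.path(config$output_dir, "sobol.csv"),
                     row.names = FALSE)
    art("sobol", "sobol.csv", sseed)
    res
  })

  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  bundle$manifest <- manifest
  class(bundle) <- "report_bundle"
  bundle
}

#' Render a human-readable pipeline report
#'
#' Prints the composition shares, enhancement table, PMF factor
#' contributions, risk classification table, Monte-Carlo summary and Sobol
#' ranking from a pipeline bundle. Stages absent from the bundle are noted
#' and skipped without failing.
#'
#' @param bundle `report_bundle` from [run_pipeline()].
#' @param file optional path; when given the report is also written there.
#' @return the report lines, invisibly.
#' @export
render_report <- function(bundle, file = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  lines <- character()
  put <- function(...) lines <<- c(lines, paste0(...))
  put("Campaign analysis report (global seed ", bundle$config$seed, ")")
  put(strrep("=", 50))
  if (!is.null(bundle$error)) {
    put("PIPELINE ABORTED at stage '", bundle$error$stage, "': ",
        bundle$error$message)
  }
  if (!is.null(bundle$describe)) {
    comp <- bundle$describe$composition
    put("", "Composition (", nrow(comp$species), " species, grand total ",
        round(comp$grand_total, 0), " pptv):")
    for (i in seq_len(nrow(comp$species))) {
      put(sprintf("  %-22s %8.1f pptv  %5.1f%%", comp$species$name[i],
                  comp$species$mean[i], comp$species$share_pct[i]))
    }
    for (i in seq_len(nrow(comp$groups))) {
      put(sprintf("  group %-16s %8.1f pptv  %5.1f%%", comp$groups$category[i],
                  comp$groups$total[i], comp$groups$share_pct[i]))
    }
    enh <- bundle$describe$enhancement
    put("", "Background enhancements:")
    for (i in seq_len(nrow(enh))) {
      put(sprintf("  %-22s +%7.1f pptv  %6.1f%%", enh$name[i],
                  enh$absolute_enhancement[i], enh$percent_enhancement[i]))
    }
  } else put("", "[describe stage not run]")
  if (!is.null(bundle$pmf)) {
    put("", "PMF factor contributions:")
    co <- bundle$pmf$contributions
    for (k in seq_along(co)) put(sprintf("  %-10s %5.1f%%", names(co)[k], co[k]))
  } else put("", "[pmf stage not run]")
  if (!is.null(bundle$risk)) {
    rs <- bundle$risk$species
    put("", "Deterministic risk:")
    flagged <- rs[!is.na(rs$LCR) & rs$LCR >= 1e-6, ]
    for (i in seq_len(nrow(flagged))) {
      put(sprintf("  %-22s LCR %.2e  (%s)", flagged$name[i], flagged$LCR[i],
                  flagged$lcr_class[i]))
    }
    put(sprintf("  cumulative LCR %.2e (%s); HI %.2f (%s)",
                bundle$risk$cumulative_LCR, bundle$risk$cumulative_LCR_class,
                bundle$risk$HI, bundle$risk$HI_class))
  } else put("", "[risk stage not run]")
  if (!is.null(bundle$mc)) {
    sm <- bundle$mc$summary
    tot <- sm[sm$output %in% c("LCR_total", "HI"), ]
    put("", "Monte-Carlo summary (totals):")
    for (i in seq_len(nrow(tot))) {
      put(sprintf("  %-10s mean %.3e  median %.3e  p95 %.3e  MCE/SD %.2f%%",
                  tot$output[i], tot$mean[i], tot$median[i], tot$p95[i],
                  tot$mce_sd_ratio_pct[i]))
    }
  } else put("", "[mc stage not run]")
  if (!is.null(bundle$sobol)) {
    put("", "Sobol total-order ranking: ",
        paste(rank_inputs(bundle$sobol), collapse = " > "))
  } else put("", "[sobol stage not run]")
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(lines)
}
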