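#' Inhalation exposure parameters
#'
#' Residential chronic-exposure defaults for the adult population:
#' exposure time ET (h d^-1), exposure frequency EF (d a^-1), exposure
#' duration ED (a) and averaging time AT (h). With the defaults
#' (ET 24, EF 365, ED 74.8, AT = 74.8 * 365 * 24) the exposure factor
#' `ET * EF * ED / AT` is exactly 1, so EC equals the ambient concentration.
#'
#' @param ET exposure time, h d^-1.
#' @param EF exposure frequency, d a^-1.
#' @param ED exposure duration, a.
#' @param AT averaging time, h (default `ED * 365 * 24`).
#' @return list of class `exposure_parameters`.
#' @export
exposure_parameters <- function(ET = 24, EF = 365, ED = 74.8,
                                AT = ED * 365 * 24) {
  if (any(c(ET, EF, ED, AT) <= 0)) stop("all exposure parameters must be > 0")
  structure(list(ET = ET, EF = EF, ED = ED, AT = AT),
            class = "exposure_parameters")
}

#' Exposure concentration
#'
#' `EC = CA * ET * EF * ED / AT` (ug m^-3): the time-weighted ambient
#' concentration entering both the cancer and non-cancer risk equations.
#'
#' @param CA ambient mass concentration, ug m^-3, >= 0.
#' @param params `exposure_parameters`.
#' @return EC in ug m^-3 (vectorized over `CA`).
#' @export
exposure_concentration <- function(CA, params = exposure_parameters()) {
  if (any(CA < 0, na.rm = TRUE)) stop("CA must be >= 0")
  if (params$AT == 0) stop("AT must be nonzero")
  CA * params$ET * params$EF * params$ED / params$AT
}

#' Lifetime cancer risk
#'
#' `LCR = EC * IUR`, the excess lifetime cancer probability from continuous
#' inhalation exposure at EC, with IUR the inhalation unit risk per ug m^-3.
#'
#' @param EC exposure concentration, ug m^-3, >= 0.
#' @param iur inhalation unit risk, per ug m^-3, >= 0.
#' @return dimensionless risk (vectorized).
#' @export
lifetime_cancer_risk <- function(EC, iur) {
  if (any(EC < 0, na.rm = TRUE) || any(iur < 0, na.rm = TRUE)) {
    stop("EC and IUR must be >= 0")
  }
  EC * iur
}

#' Hazard quotient
#'
#' `HQ = EC / (RfC * 1000)`: the ratio of the exposure concentration
#' (ug m^-3) to the inhalation reference concentration (mg m^-3; the factor
#' 1000 converts it to ug m^-3).
#'
#' @param EC exposure concentration, ug m^-3, >= 0.
#' @param rfc reference concentration, mg m^-3, > 0.
#' @return dimensionless hazard quotient (vectorized).
#' @export
hazard_quotient <- function(EC, rfc) {
  if (any(rfc <= 0, na.rm = TRUE)) stop("RfC must be > 0")
  if (any(EC < 0, na.rm = TRUE)) stop("EC must be >= 0")
  EC / (rfc * 1000)
}

#' Hazard index
#'
#' Sum of hazard quotients over the assessed compounds; an HI above 1 flags
#' a potential cumulative non-carcinogenic risk.
#'
#' @param HQs numeric vector of hazard quotients (at least one).
#' @return HI, a simple sum.
#' @export
hazard_index <- function(HQs) {
  if (length(HQs) < 1L) stop("need at least one HQ")
  sum(HQs)
}

#' Classify a risk value
#'
#' Carcinogenic scale (`type = "LCR"`): below 1e-6 is negligible, 1e-6 to
#' 1e-4 (closed lower bound) is potential risk, above 1e-4 is definite
#' concern. Non-carcinogenic scale (`type = "HI"` or `"HQ"`): at or below 1
#' is negligible, above 1 is potential risk.
#'
#' @param value finite nonnegative risk value (vectorized).
#' @param type `"LCR"`, `"HI"` or `"HQ"`.
#' @param thresholds for LCR, `c(lower, upper)` (default `c(1e-6, 1e-4)`);
#'   for HI/HQ a single threshold (default 1).
#' @return character vector of category labels.
#' @export
classify_risk <- function(value, type = c("LCR", "HI", "HQ"),
                          thresholds = NULL) {
  type <- match.arg(type)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("risk values must be finite and >= 0")
  }
  if (type == "LCR") {
    thr <- thresholds %||% c(1e-6, 1e-4)
    ifelse(value < thr[1], "negligible",
           ifelse(value <= thr[2], "potential carcinogenic risk",
                  "definite carcinogenic concern"))
  } else {
    thr <- thresholds %||% 1
    ifelse(value <= thr, "negligible", "potential non-carcinogenic risk")
  }
}

#' Deterministic risk table
#'
#' Runs the full point-estimate risk chain for a set of species: pptv to
#' ug m^-3 conversion, exposure concentration, lifetime cancer risk (for
#' species with an IUR), hazard quotient (for species with an RfC), totals
#' (cumulative LCR and HI) and threshold classifications.
#'
#' @param means data frame with `name` and `mean` (pptv).
#' @param registry `species_registry`.
#' @param params `exposure_parameters`.
#' @param molar_volume L mol^-1 for the unit conversion.
#' @return list of class `risk_table`: `species` data frame
#'   (`name`, `CA_pptv`, `CA_ugm3`, `EC`, `LCR`, `HQ`, `lcr_class`,
#'   `hq_class`), `cumulative_LCR`, `HI`, and their classifications.
#' @export
risk_table <- function(means, registry, params = exposure_parameters(),
                       molar_volume = 24.45) {
  idx <- match(means$name, registry$name)
  if (anyNA(idx)) stop("species not in registry: ",
                       paste(means$name[is.na(idx)], collapse = ", "))
  reg <- registry[idx, , drop = FALSE]
  ca_ug <- pptv_to_ugm3(means$mean, reg$mw, molar_volume)
  ec <- exposure_concentration(ca_ug, params)
  lcr <- ifelse(is.na(reg$iur), NA_real_, ec * reg$iur)
  hq <- ifelse(is.na(reg$rfc), NA_real_, ec / (reg$rfc * 1000))
  species <- data.frame(
    name = means$name, CA_pptv = means$mean, CA_ugm3 = ca_ug, EC = ec,
    LCR = lcr, HQ = hq,
    lcr_class = ifelse(is.na(lcr), NA_character_, classify_risk(ifelse(is.na(lcr), 0, lcr), "LCR")),
    hq_class = ifelse(is.na(hq), NA_character_, classify_risk(ifelse(is.na(hq), 0, hq), "HQ")),
    stringsAsFactors = FALSE)
  cum_lcr <- sum(lcr, na.rm = TRUE)
  hi <- hazard_index(hq[!is.na(hq)])
  structure(list(species = species,
                 cumulative_LCR = cum_lcr,
                 HI = hi,
                 cumulative_LCR_class = classify_risk(cum_lcr, "LCR"),
                 HI_class = classify_risk(hi, "HI")),
            class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  df <- x$species
  df$CA_ugm3 <- signif(df$CA_ugm3, 4); df$EC <- signif(df$EC, 4)
  df$LCR <- signif(df$LCR, 3); df$HQ <- signif(df$HQ, 3)
  print(df)
  cat("cumulative LCR:", signif(x$cumulative_LCR, 3),
      "(", x$cumulative_LCR_class, ")\n")
  cat("HI:", signif(x$HI, 3), "(", x$HI_class, ")\n")
  invisible(x)
}
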