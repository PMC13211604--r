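#' Species metadata registry
#'
#' A `species_registry` holds the physical and toxicological constants of the
#' halocarbons handled by the package: molecular weight, atmospheric lifetime,
#' ozone depletion potential (ODP), 100-year global warming potential
#' (GWP100), method detection limit (MDL), Northern-Hemisphere background
#' mixing ratio, inhalation unit risk (IUR, per ug m^-3) and inhalation
#' reference concentration (RfC, mg m^-3). Species fall into exactly two
#' regulatory categories: `regulated_CFC` (Montreal-Protocol phased-out
#' substances, including bromomethane despite its short lifetime) and
#' `unregulated_VSLS` (uncontrolled chlorinated very short-lived substances).
#'
#' @param table data frame with columns `name`, `category`, `mw`, `mdl` and
#'   optionally `lifetime`, `odp`, `gwp100`, `background`, `iur`, `rfc`.
#'   Missing optional entries are `NA`.
#' @return An object of class `species_registry`: a validated data frame with
#'   one row per species, in input order.
#' @examples
#' reg <- load_registry(vhh_species())
#' nrow(reg)            # 14
#' reg$mw[reg$name == "Chloroform"]
#' @export
load_registry <- function(table) {
  table <- as.data.frame(table)
  required <- c("name", "category", "mw", "mdl")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L) {
    stop("species table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  optional <- c("lifetime", "odp", "gwp100", "background", "iur", "rfc")
  for (col in optional) if (is.null(table[[col]])) table[[col]] <- NA_real_
  table <- table[, c(required, optional)]

  table$name <- as.character(table$name)
  table$category <- as.character(table$category)
  num_cols <- c("mw", "mdl", optional)
  for (col in num_cols) table[[col]] <- as.numeric(table[[col]])

  if (anyDuplicated(table$name)) {
    stop("duplicate species name(s): ",
         paste(unique(table$name[duplicated(table$name)]), collapse = ", "))
  }
  bad_cat <- setdiff(unique(table$category), c("regulated_CFC", "unregulated_VSLS"))
  if (length(bad_cat) > 0L) {
    stop("unknown category label(s): ", paste(bad_cat, collapse = ", "))
  }
  if (any(is.na(table$mw)) || any(table$mw <= 0)) {
    stop("molecular weight must be present and > 0 for every species")
  }
  if (any(is.na(table$mdl)) || any(table$mdl < 0)) {
    stop("MDL must be present and >= 0 for every species")
  }
  if (any(!is.na(table$lifetime) & table$lifetime <= 0)) {
    stop("atmospheric lifetime must be > 0 where present")
  }
  if (any(!is.na(table$iur) & table$iur < 0)) stop("IUR must be >= 0 where present")
  if (any(!is.na(table$rfc) & table$rfc <= 0)) stop("RfC must be > 0 where present")

  rownames(table) <- NULL
  class(table) <- c("species_registry", "data.frame")
  table
}

#' Packaged species parameter table
#'
#' Returns the default 14-species parameter table (6 regulated CFCs, 8
#' unregulated VSLSs) shipped with the package. Molecular weights are
#' standard; lifetimes, ODP, GWP100 and background mixing ratios are
#' campaign-level literature constants. IUR and RfC values are taken from the
#' US EPA IRIS database, supplemented by California OEHHA chronic RELs where
#' IRIS gives none (chloroform, 1,2-dichloroethane, 1,1-dichloroethane); the
#' 1,1-dichloroethane RfC is a provisional (HEAST-era) value. Per-species
#' MDLs are synthetic: representative values placed inside the 2-17 pptv
#' range typical of TO-15 canister GC/MS analysis, since per-species limits
#' are instrument specific.
#'
#' @param path optional path to an alternative CSV with the same columns.
#' @return data frame suitable for [load_registry()].
#' @export
vhh_species <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vhh_species.csv", package = "halorisk")
  }
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Packaged campaign summary statistics
#'
#' Per-species mean and standard deviation of the summertime urban campaign
#' mixing ratios (pptv) used to parameterize distribution fits and worked
#' examples.
#'
#' @param path optional path to an alternative CSV (`name`, `mean`, `sd`).
#' @return data frame with columns `name`, `mean`, `sd` (pptv).
#' @export
vhh_campaign_means <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vhh_campaign_means.csv", package = "halorisk")
  }
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.species_registry <- function(x, ...) {
  cat("<species_registry> ", nrow(x), " species (",
      sum(x$category == "regulated_CFC"), " regulated_CFC, ",
      sum(x$category == "unregulated_VSLS"), " unregulated_VSLS)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Convert mixing ratio to mass concentration
#'
#' Converts a mixing ratio in parts per trillion by volume (pptv) to a mass
#' concentration in ug m^-3 using the ideal-gas molar volume. The default
#' molar volume of 24.45 L mol^-1 corresponds to 25 degC and 1 atm.
#'
#' @param mixing_ratio numeric vector, pptv; must be >= 0.
#' @param molecular_weight g mol^-1, > 0.
#' @param molar_volume L mol^-1, > 0 (default 24.45).
#' @return mass concentration in ug m^-3:
#'   `mixing_ratio * molecular_weight / (molar_volume * 1000)`.
#' @examples
#' pptv_to_ugm3(64, 119.38)   # chloroform, ~0.3125 ug m^-3
#' @seealso [ugm3_to_pptv()]
#' @export
pptv_to_ugm3 <- function(mixing_ratio, molecular_weight, molar_volume = 24.45) {
  if (any(mixing_ratio < 0, na.rm = TRUE)) stop("mixing_ratio must be >= 0")
  if (any(molecular_weight <= 0)) stop("molecular_weight must be > 0")
  if (any(molar_volume <= 0)) stop("molar_volume must be > 0")
  mixing_ratio * molecular_weight / (molar_volume * 1000)
}

#' Convert mass concentration to mixing ratio
#'
#' Inverse of [pptv_to_ugm3()]; round-trips to within floating-point error.
#'
#' @param ugm3 numeric vector, ug m^-3; must be >= 0.
#' @inheritParams pptv_to_ugm3
#' @return mixing ratio in pptv.
#' @export
ugm3_to_pptv <- function(ugm3, molecular_weight, molar_volume = 24.45) {
  if (any(ugm3 < 0, na.rm = TRUE)) stop("ugm3 must be >= 0")
  if (any(molecular_weight <= 0)) stop("molecular_weight must be > 0")
  if (any(molar_volume <= 0)) stop("molar_volume must be > 0")
  ugm3 * molar_volume * 1000 / molecular_weight
}
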