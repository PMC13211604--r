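#' Sample-by-species concentration matrix
#'
#' Container for a campaign's wide-format concentration table: a samples x
#' species numeric matrix of mixing ratios (pptv), per-sample timestamps
#' (date plus diurnal window label), and a below-MDL flag matrix. Missing
#' measurements are `NA` in `values` and count as non-detections.
#'
#' @param values numeric samples x species matrix (pptv), `NA` = missing.
#' @param dates per-sample date labels (length = nrow(values)).
#' @param windows per-sample diurnal window labels (length = nrow(values)).
#' @param registry `species_registry` covering every column of `values`
#'   (column order must match registry order for the covered species).
#' @param below_mdl optional logical matrix of the same shape; if omitted it
#'   is derived as `values < MDL` (with `NA` flagged as below).
#' @return object of class `concentration_matrix`.
#' @export
concentration_matrix <- function(values, dates, windows, registry,
                                 below_mdl = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (length(dates) != nrow(values) || length(windows) != nrow(values)) {
    stop("dates and windows must have one entry per sample (row)")
  }
  if (is.null(colnames(values))) stop("values must have species column names")
  sp <- colnames(values)
  if (!all(sp %in% registry$name)) {
    stop("species missing from registry: ",
         paste(setdiff(sp, registry$name), collapse = ", "))
  }
  reg <- registry[match(sp, registry$name), , drop = FALSE]
  class(reg) <- c("species_registry", "data.frame")
  if (any(values < 0, na.rm = TRUE)) stop("concentrations must be >= 0 or NA")
  if (is.null(below_mdl)) {
    below_mdl <- sweep(values, 2, reg$mdl, `<`)
    below_mdl[is.na(values)] <- TRUE
  }
  below_mdl <- as.matrix(below_mdl)
  if (!identical(dim(below_mdl), dim(values))) {
    stop("below_mdl flags must have the same shape as values")
  }
  structure(
    list(values = values,
         dates = as.character(dates),
         windows = as.character(windows),
         below_mdl = below_mdl,
         registry = reg),
    class = "concentration_matrix")
}

#' @export
print.concentration_matrix <- function(x, ...) {
  cat("<concentration_matrix> ", nrow(x$values), " samples x ",
      ncol(x$values), " species; ",
      length(unique(x$windows)), " diurnal windows; ",
      sum(x$below_mdl), " below-MDL cells\n", sep = "")
  invisible(x)
}

#' @export
dim.concentration_matrix <- function(x) dim(x$values)

#' Write a campaign to CSV
#'
#' One row per sample: `date`, `window_start`, then species columns in
#' registry order.
#'
#' @param x `concentration_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_campaign_csv <- function(x, path) {
  df <- data.frame(date = x$dates, window_start = x$windows,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a campaign CSV
#'
#' Inverse of [write_campaign_csv()].
#'
#' @param path CSV with columns `date`, `window_start`, then species.
#' @param registry `species_registry` naming the species columns.
#' @return `concentration_matrix`.
#' @export
read_campaign_csv <- function(path, registry) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = c(date = "character",
                                       window_start = "character"))
  sp <- setdiff(names(df), c("date", "window_start"))
  vals <- as.matrix(df[, sp, drop = FALSE])
  concentration_matrix(vals, df$date, df$window_start, registry)
}
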