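# Shared fixtures built in code.

fixture_registry <- function() load_registry(vhh_species())

fixture_means <- function() vhh_campaign_means()

# tiny registry for toy matrices
toy_registry <- function(n = 3, mdl = 1) {
  load_registry(data.frame(
    name = paste0("sp", seq_len(n)),
    category = "unregulated_VSLS",
    mw = 100, mdl = mdl))
}

toy_matrix <- function(values, mdl = 1, windows = NULL) {
  n <- nrow(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("sp", seq_len(ncol(values)))
  reg <- toy_registry(ncol(values), mdl = mdl)
  if (is.null(windows)) windows <- rep("w1", n)
  concentration_matrix(values, dates = rep("d1", n),
                       windows = windows, registry = reg)
}
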