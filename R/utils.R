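# Internal helpers shared across modules.

# Moment-match a lognormal to an arithmetic mean/sd.
# Returns c(meanlog, sdlog); sd = 0 collapses to a point mass (sdlog 0).
lognormal_moments <- function(mean, sd) {
  if (any(mean <= 0)) stop("mean must be > 0 for a lognormal")
  if (any(sd < 0)) stop("sd must be >= 0")
  sdlog2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Deterministic child seeds below 2^31 derived from a master seed.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# All permutations of 1..n as a list (n <= 8 in practice).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
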