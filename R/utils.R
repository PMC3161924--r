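#' @importFrom stats mad median quantile rnorm rlnorm runif fisher.test cor
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

#' Derive a child RNG seed from a parent seed
#'
#' Deterministic splitting of one user-facing seed into independent stream
#' seeds (one per simulated allele, one for the shared noise, one per cohort
#' sample), so that composite simulations are reproducible and their parts
#' can be regenerated in isolation. Always returns an integer in
#' `[0, 2^31 - 2]`.
#'
#' @param seed integer parent seed
#' @param i stream index (>= 1)
#' @return integer seed
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 7919 + i * 104729) %% 2147483647)
}

# Run expr with a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Percentage of x/n floored to one decimal, the convention used for the
# printed cohort frequencies (4/66 -> 6.0, 1/42 -> 2.3).
pct_floor <- function(x, n) floor(1000 * x / n) / 10

# Reverse complement of an ACGT string.
revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

check_acgt <- function(s, what = "sequence") {
  ch <- strsplit(s, "")[[1]]
  bad <- which(!ch %in% BASES)
  if (length(bad))
    stop(sprintf("%s contains non-ACGT character '%s' at index %d",
                 what, ch[bad[1]], bad[1]), call. = FALSE)
  invisible(s)
}
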