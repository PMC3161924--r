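random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

# Chromatogram with one Gaussian peak per row of `amps` (bases x positions
# matrix with rownames A/C/G/T), noise-free; for threshold-arithmetic tests.
make_peak_trace <- function(amps, spacing = 12, sigma = 2.5) {
  n <- ncol(amps)
  total <- ceiling((n + 1.5) * spacing)
  t <- seq_len(total) - 1
  ch <- lapply(c("A", "C", "G", "T"), function(b) {
    y <- numeric(total)
    for (j in seq_len(n)) {
      mu <- spacing + (j - 1) * spacing
      y <- y + amps[b, j] * exp(-(t - mu)^2 / (2 * sigma^2))
    }
    y
  })
  names(ch) <- c("A", "C", "G", "T")
  chromatogram(ch, peak_spacing_hint = spacing, sample_id = "synthetic")
}

# A called_sequence built directly from primary/secondary columns
# (qualities fixed at 40), bypassing trace simulation.
make_called <- function(primary, secondary = rep(NA_character_, length(primary)),
                        quality = rep(40L, length(primary))) {
  n <- length(primary)
  calls <- data.frame(base_index = seq_len(n) - 1L,
                      trace_position = as.integer(seq(12, by = 12, length.out = n)),
                      primary_base = primary,
                      secondary_base = secondary,
                      primary_amp = rep(100, n),
                      secondary_amp = ifelse(is.na(secondary), NA, 80),
                      ratio = ifelse(is.na(secondary), NA, 0.8),
                      quality = quality,
                      stringsAsFactors = FALSE)
  structure(list(calls = calls,
                 primary_string = paste(primary, collapse = ""),
                 source = list(sample_id = "synthetic", amplicon_id = "amp",
                               strand = "+", spacing = 12)),
            class = "called_sequence")
}

# Observed call columns for a diploid pair of alleles with clean calling:
# primary/secondary order randomized per position (amplitude flips).
columns_for_pair <- function(alleleA, alleleB) {
  a <- strsplit(alleleA, "")[[1]]
  b <- strsplit(alleleB, "")[[1]]
  n <- min(length(a), length(b))
  p <- s <- character(n)
  for (i in seq_len(n)) {
    pair <- sample(c(a[i], b[i]))
    p[i] <- pair[1]
    s[i] <- if (pair[1] == pair[2]) NA_character_ else pair[2]
  }
  list(p = p, s = s)
}
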