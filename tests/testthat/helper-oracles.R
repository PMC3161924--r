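# Independent brute-force oracles. These deliberately share no code with
# the package implementation.

# Best global-local affine alignment score by recursive enumeration with
# memoization over (read position, ref position, state). The read is
# aligned end-to-end; reference flanks are free. Scoring must mirror
# align_to_reference: match 2, mismatch -4, gap open 2, extend 2 (a gap of
# length L costs 2 + 2L).
oracle_alignment_score <- function(read, ref,
                                   match = 2, mismatch = -4,
                                   gap_open = 2, gap_ext = 2) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(f)
  memo <- new.env(hash = TRUE)
  # state: 0 none/match, 1 in read-gap (ref consumed), 2 in ref-gap
  best_from <- function(i, j, state) {
    if (i > n) return(0)                      # remaining ref flank is free
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- -Inf
    if (j <= m) {
      sc <- if (r[i] == f[j]) match else mismatch
      out <- max(out, sc + best_from(i + 1, j + 1, 0))
      pen <- if (state == 1) gap_ext else gap_open + gap_ext
      out <- max(out, -pen + best_from(i, j + 1, 1))
    }
    pen <- if (state == 2) gap_ext else gap_open + gap_ext
    out <- max(out, -pen + best_from(i + 1, j, 2))
    memo[[key]] <- out
    out
  }
  max(vapply(seq_len(m + 1) - 1, function(start)
    best_from(1, start + 1, 0), 1))
}

# Exhaustive (direction, k, breakpoint) consistency maximization for call
# columns whose pre-divergence reference mapping is position i -> ref[i]
# (instances are built that way). Scores unordered set equality between
# the predicted and observed base pair at every position where the
# prediction is defined.
oracle_indel_search <- function(p, s, reference, K = 5) {
  refc <- strsplit(reference, "")[[1]]
  n <- length(p)
  best <- list(score = -1)
  for (dir in c("del", "ins")) for (k in seq_len(K)) {
    for (b in 6:(length(refc) - k)) {
      num <- 0L; den <- 0L
      for (i in seq_len(n)) {
        pred2 <- if (i < b) refc[i]
          else if (dir == "del") {
            if (i + k <= length(refc)) refc[i + k] else NA
          } else {
            if (i < b + k) NA else refc[i - k]
          }
        if (is.na(pred2) || i > length(refc)) next
        den <- den + 1L
        pred <- sort(unique(c(refc[i], pred2)))
        obs <- sort(unique(c(p[i], if (!is.na(s[i])) s[i])))
        if (identical(pred, obs)) num <- num + 1L
      }
      sc <- if (den) num / den else 0
      if (sc > best$score + 1e-9)
        best <- list(direction = dir, k = k, b = b, score = sc)
    }
  }
  best
}

# Coding-effect oracle via seqinr's translation tables (independent of
# Biostrings::GENETIC_CODE used by the implementation).
oracle_codon_effect <- function(codon, off, alt) {
  tr <- function(cd) seqinr::translate(strsplit(cd, "")[[1]])
  mut <- codon
  substr(mut, off, off) <- alt
  aa0 <- tr(codon); aa1 <- tr(mut)
  if (aa0 == aa1) "synonymous" else if (aa1 == "*") "nonsense" else "missense"
}
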