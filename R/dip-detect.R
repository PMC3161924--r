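#' Detect the onset of a degenerate (two-allele) region
#'
#' Returns the smallest 0-based base index `i` such that the fraction of
#' positions in `[i, i + min_run)` carrying a secondary call is at least
#' `dens_thresh` while the region before `i` has secondary density below
#' 0.2; `NULL` when no such changepoint exists. This is where the two
#' superposed alleles of a heterozygous indel carrier diverge.
#'
#' @param called a `called_sequence` with >= 20 calls
#' @param min_run run length examined after the candidate onset
#' @param dens_thresh minimum secondary-call density inside the run
#' @return 0-based base index, or `NULL`
#' @export
detect_onset <- function(called, min_run = 8, dens_thresh = 0.6) {
  stopifnot(inherits(called, "called_sequence"))
  sec <- as.integer(!is.na(called$calls$secondary_base))
  n <- length(sec)
  if (n < 20) stop("need >= 20 called bases", call. = FALSE)
  cum <- cumsum(sec)
  dens <- function(from, len) {
    to <- min(n, from + len - 1)
    (cum[to] - if (from > 1) cum[from - 1] else 0) / (to - from + 1)
  }
  for (i in seq_len(n - min_run + 1)) {
    if (!sec[i]) next   # the onset itself must be a degenerate call
    pre <- if (i > 1) cum[i - 1] / (i - 1) else 0
    # short window passes the density gate and the degeneracy is
    # sustained over three runs (a real superposition persists; sparse
    # random secondaries do not)
    if (dens(i, min_run) >= dens_thresh && pre < 0.2 &&
        dens(i, 3 * min_run) >= 0.5)
      return(i - 1L)
  }
  NULL
}

# Lag-k column match score maximized over the unobserved allele-role
# assignment. At each call the unordered pair {primary, secondary} holds
# the two allele bases; the lag-k relation says one allele's base at i
# reappears as the other allele's base at i+k. Which observed base plays
# which role is decided per position by dynamic programming along the k
# residue chains, maximizing the number of satisfied lag constraints.
chain_match_score <- function(p, s, idx, k) {
  inf <- !is.na(s[idx]) | !is.na(s[idx + k])
  ninf <- sum(inf)
  if (ninf == 0) return(c(score = NA_real_, n_informative = 0))
  inf_set <- idx[inf]
  nsat <- 0
  first <- idx[1]
  for (r in seq_len(k)) {
    chain <- idx[seq(r, length(idx), by = k)]
    if (!length(chain)) next
    chain2 <- c(chain, chain[length(chain)] + k)
    m <- length(chain2)
    sc <- ifelse(is.na(s[chain2]), p[chain2], s[chain2])
    b1 <- rbind(p[chain2], sc)   # allele-1 base under state 1/2
    b2 <- rbind(sc, p[chain2])   # allele-2 base under state 1/2
    dp <- c(0, 0)
    for (j in seq_len(m - 1)) {
      cinf <- chain2[j] %in% inf_set
      ndp <- c(-Inf, -Inf)
      for (st2 in 1:2) for (st1 in 1:2) {
        v <- dp[st1] + as.integer(cinf && b2[st1, j] == b1[st2, j + 1])
        if (v > ndp[st2]) ndp[st2] <- v
      }
      dp <- ndp
    }
    nsat <- nsat + max(dp)
  }
  c(score = nsat / ninf, n_informative = ninf)
}

#' Shift-autocorrelation curve of a degenerate trace region
#'
#' For each candidate indel size `k` in `1..K`, scores how well the
#' primary/secondary call columns in the window `[onset, onset + W)` match
#' themselves shifted by `k` bases. In the default `"calls"` mode the score
#' is the fraction of informative positions (those where either compared
#' site has a secondary call) whose lag-k base constraint can be satisfied
#' under a consistent allele-role assignment (dynamic programming per
#' residue chain); a heterozygous indel of size `k` drives `S(k)` towards 1.
#' In `"signal"` mode the score is the mean across channels of the Pearson
#' correlation between the raw signal and itself shifted by `k` peak
#' spacings, rescaled to `[0, 1]`.
#'
#' @param called a `called_sequence`
#' @param onset 0-based base index where the degenerate region starts
#' @param K maximum shift, bases
#' @param W window length, bases (truncated to the available calls; at
#'   least 15 after truncation)
#' @param mode `"calls"` or `"signal"`
#' @param chrom the source [chromatogram()], required for `"signal"` mode
#' @return object of class `autocorrelation_curve`: list with `onset`,
#'   `W`, `scores` (length `K`, `NA` where no informative positions), and
#'   `n_informative`
#' @export
autocorrelation_curve <- function(called, onset, K = 10, W = 40,
                                  mode = c("calls", "signal"),
                                  chrom = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(called, "called_sequence"))
  n <- nrow(called$calls)
  W <- min(W, n - onset - K)
  if (W < 15) stop("window too short", call. = FALSE)
  idx <- (onset + 1):(onset + W)          # 1-based rows
  scores <- rep(NA_real_, K)
  n_inf <- integer(K)
  if (mode == "calls") {
    p <- called$calls$primary_base
    s <- called$calls$secondary_base
    for (k in seq_len(K)) {
      res <- chain_match_score(p, s, idx, k)
      scores[k] <- res["score"]
      n_inf[k] <- res["n_informative"]
    }
  } else {
    if (is.null(chrom)) stop("signal mode needs the source chromatogram",
                             call. = FALSE)
    sp <- called$source$spacing %||% chrom$peak_spacing_hint
    t0 <- called$calls$trace_position[onset + 1] + 1
    t1 <- called$calls$trace_position[min(n, onset + W)] + 1
    for (k in seq_len(K)) {
      lag <- round(k * sp)
      tt <- t0:min(t1, length(chrom) - lag)
      if (length(tt) < 10) next
      r <- mean(vapply(BASES, function(b)
        suppressWarnings(cor(chrom$channels[[b]][tt],
                             chrom$channels[[b]][tt + lag])), 1),
        na.rm = TRUE)
      scores[k] <- (r + 1) / 2
      n_inf[k] <- length(tt)
    }
  }
  structure(list(onset = onset, W = W, scores = scores,
                 n_informative = n_inf, mode = mode),
            class = "autocorrelation_curve")
}

#' @export
print.autocorrelation_curve <- function(x, ...) {
  cat(sprintf("<autocorrelation_curve> onset %d, W %d, mode %s\n",
              x$onset, x$W, x$mode))
  print(round(stats::setNames(x$scores, seq_along(x$scores)), 3))
  invisible(x)
}

#' Left-normalize an indel against the reference
#'
#' Shifts an insertion or deletion to its leftmost equivalent position
#' within a repeat run (the standard VCF-style representation): while the
#' reference base preceding the event equals the last base of the indel
#' sequence, the event moves one base left. Idempotent.
#'
#' @param position 1-based position of the first affected reference base
#'   (for insertions, the base before which the sequence is inserted)
#' @param seq inserted or deleted bases
#' @param kind `"ins"` or `"del"`
#' @param reference reference sequence
#' @return list with `position`, `seq`, `kind`, and `shifted` (number of
#'   positions moved)
#' @export
left_normalize <- function(position, seq, kind = c("del", "ins"), reference) {
  kind <- match.arg(kind)
  k <- nchar(seq)
  position <- as.integer(position)
  if (position < 1 || position + (kind == "del") * k - 1 > nchar(reference))
    stop("indel outside reference bounds", call. = FALSE)
  shifted <- 0L
  while (position > 1 &&
         substr(reference, position - 1, position - 1) == substr(seq, k, k)) {
    seq <- paste0(substr(reference, position - 1, position - 1),
                  substr(seq, 1, k - 1))
    position <- position - 1L
    shifted <- shifted + 1L
  }
  list(position = position, seq = seq, kind = kind, shifted = shifted)
}

#' Deconvolve the two alleles of a heterozygous indel trace
#'
#' Reference-guided assignment: the reference allele tracks reference
#' positions from the onset; under the deletion hypothesis the second
#' allele runs `k` bases ahead (`ref[r + d + k]`), under the insertion
#' hypothesis `k` bases behind (`ref[r + d - k]`, with the first `k`
#' post-onset bases of the second allele read off the trace). Each
#' hypothesis is scored by the fraction of window positions whose
#' predicted unordered base pair is contained in the observed
#' {primary, secondary} set; the better hypothesis fixes the direction.
#'
#' @param called a `called_sequence`
#' @param onset 0-based onset of the degenerate region
#' @param k indel size (>= 1)
#' @param reference amplicon reference sequence
#' @param W scoring window, bases
#' @param min_consistency both-hypothesis floor below which deconvolution
#'   is declared failed
#' @return list with `direction` (`"ins"`/`"del"`), `indel_sequence`,
#'   `ref_position` (1-based, not yet left-normalized), `alleleA`,
#'   `alleleB`, `consistency`, `failed`
#' @export
deconvolve_alleles <- function(called, onset, k, reference, W = 40,
                               min_consistency = 0.7) {
  if (k < 1) stop("shift k must be >= 1", call. = FALSE)
  stopifnot(inherits(called, "called_sequence"))
  # anchor the reference register on the clean prefix only: degenerate
  # calls between the true divergence and the detected onset can push an
  # aligner gap that would mis-register r_onset by up to k
  first_sec <- which(!is.na(called$calls$secondary_base))[1]
  n_clean <- min(onset, if (is.na(first_sec)) onset else first_sec - 1L)
  if (n_clean < 1) stop("no clean pre-onset region", call. = FALSE)
  aln <- align_to_reference(substr_called(called, n_clean), reference)
  if (aln$unalignable)
    stop("pre-onset region does not align to the reference", call. = FALSE)
  mp <- aln$pairs[!is.na(aln$pairs$base_index) & !is.na(aln$pairs$ref_pos), ]
  r_onset <- mp$ref_pos[nrow(mp)] + (onset - 1L - mp$base_index[nrow(mp)]) + 1L
  p <- called$calls$primary_base
  s <- called$calls$secondary_base
  n <- nrow(called$calls)
  refch <- strsplit(reference, "")[[1]]
  W <- min(W, n - onset)
  d_max <- W - 1
  score_hyp <- function(off) {  # off = +k deletion, -k insertion
    num <- 0L; den <- 0L
    for (d in 0:d_max) {
      i <- onset + d + 1L
      r1 <- r_onset + d
      r2 <- r1 + off
      if (off < 0 && d < k) next       # inserted bases, not predicted
      if (r1 > length(refch) || r2 > length(refch) || r2 < 1) next
      den <- den + 1L
      # unordered set equality, as in refine_breakpoint: a hypothesis
      # that leaves an observed secondary unexplained must not score
      pred_set <- sort(unique(c(refch[r1], refch[r2])))
      obs_set <- sort(unique(c(p[i], if (!is.na(s[i])) s[i])))
      if (identical(pred_set, obs_set)) num <- num + 1L
    }
    if (den == 0) 0 else num / den
  }
  sc_del <- score_hyp(k)
  sc_ins <- score_hyp(-k)
  direction <- if (sc_del >= sc_ins) "del" else "ins"
  consistency <- max(sc_del, sc_ins)
  failed <- consistency < min_consistency
  # The detected onset can lag the true divergence point by a few bases
  # (chance agreement of the two alleles right after the breakpoint), so
  # scan candidate breakpoints around r_onset and keep the leftmost
  # maximizer of pair consistency over an extended window.
  bp <- refine_breakpoint(called, onset, k, direction, r_onset, reference, W)
  ref_position <- bp$position
  pre_ref <- substr(reference, aln$ref_start, ref_position - 1L)
  span <- min(length(refch), r_onset + d_max)
  if (direction == "del") {
    indel_seq <- substr(reference, ref_position, ref_position + k - 1L)
    alleleA <- paste0(pre_ref, substr(reference, ref_position, span))
    alleleB <- paste0(pre_ref, substr(reference, ref_position + k, span))
  } else {
    ins <- character(k)
    i0 <- onset + (ref_position - r_onset)   # call index of first inserted base
    for (d in seq_len(k) - 1L) {
      i <- i0 + d + 1L
      if (i < 1 || i > n) { ins[d + 1L] <- "N"; next }
      a1 <- if (ref_position + d <= length(refch)) refch[ref_position + d] else ""
      ins[d + 1L] <- if (!is.na(s[i]) && p[i] == a1) s[i]
        else if (!is.na(s[i]) && s[i] == a1) p[i]
        else p[i]
    }
    indel_seq <- paste(ins, collapse = "")
    alleleA <- paste0(pre_ref, substr(reference, ref_position, span))
    alleleB <- paste0(pre_ref, indel_seq,
                      substr(reference, ref_position, span - k))
  }
  list(direction = direction, indel_sequence = indel_seq,
       ref_position = ref_position, alleleA = alleleA, alleleB = alleleB,
       consistency = consistency, failed = failed,
       score_del = sc_del, score_ins = sc_ins)
}

# Scan breakpoints b around the onset-implied reference position and score
# each by the fraction of calls whose predicted unordered base pair
# (reference allele vs indel allele diverging at b) is contained in the
# observed {primary, secondary} set. Leftmost maximizer wins, so repeat
# ambiguity resolves towards the left before formal normalization.
refine_breakpoint <- function(called, onset, k, direction, r_onset,
                              reference, W = 40, slack = 8L) {
  p <- called$calls$primary_base
  s <- called$calls$secondary_base
  n <- nrow(called$calls)
  refch <- strsplit(reference, "")[[1]]
  i_lo <- max(1L, onset - 10L + 1L)
  i_hi <- min(n, onset + W)
  cand_b <- max(1L, r_onset - k - slack):min(length(refch), r_onset + slack)
  best_b <- r_onset; best_sc <- -1
  for (b in cand_b) {
    num <- 0L; den <- 0L
    for (i in i_lo:i_hi) {
      r1 <- r_onset + (i - 1L - onset)
      if (r1 < 1 || r1 > length(refch)) next
      pred2 <- if (r1 < b) refch[r1]
        else if (direction == "del") {
          if (r1 + k > length(refch)) NA_character_ else refch[r1 + k]
        } else {
          if (r1 < b + k) NA_character_            # inserted, unknown
          else refch[r1 - k]
        }
      if (is.na(pred2)) next
      den <- den + 1L
      # set equality between predicted and observed unordered pairs:
      # containment alone cannot reject a breakpoint whose prediction
      # leaves an observed secondary base unexplained
      pred_set <- sort(unique(c(refch[r1], pred2)))
      obs_set <- sort(unique(c(p[i], if (!is.na(s[i])) s[i])))
      if (identical(pred_set, obs_set)) num <- num + 1L
    }
    sc <- if (den) num / den else 0
    if (sc > best_sc + 1e-9) { best_sc <- sc; best_b <- b }
  }
  list(position = best_b, consistency = best_sc)
}

# First `n_keep` calls of a called sequence (helper for pre-onset alignment).
substr_called <- function(called, n_keep) {
  calls <- called$calls[seq_len(n_keep), , drop = FALSE]
  structure(list(calls = calls,
                 primary_string = paste(calls$primary_base, collapse = ""),
                 source = called$source),
            class = "called_sequence")
}

#' Detect a heterozygous indel in a called trace
#'
#' The full detector: find the degenerate-region onset, compute the
#' shift-autocorrelation curve, take the maximizing shift `k*` (ties
#' towards smaller `k`), and emit a candidate only when `S(k*) >= theta`,
#' the margin over the runner-up is at least `delta`, and at least
#' `min_informative` positions informed the score. The candidate carries
#' the deconvolved alleles, direction, and a left-normalized reference
#' position.
#'
#' @param called a `called_sequence`
#' @param reference amplicon reference sequence
#' @param K maximum shift considered, bases
#' @param theta minimum autocorrelation score
#' @param delta minimum margin over the second-best shift
#' @param W window length, bases
#' @param min_informative minimum informative positions behind `S(k*)`
#' @param mode score mode passed to [autocorrelation_curve()]
#' @param chrom source chromatogram (signal mode only)
#' @return an `indel_candidate` (list) or `NULL`; fields: `k`, `direction`,
#'   `onset`, `refined_ref_position`, `indel_sequence`, `score`, `margin`,
#'   `alleleA`, `alleleB`, `refinement_source`, `repeat_shift`,
#'   `consistency`
#' @export
detect_het_indel <- function(called, reference, K = 10, theta = 0.8,
                             delta = 0.15, W = 40, min_informative = 8,
                             mode = c("calls", "signal"), chrom = NULL) {
  mode <- match.arg(mode)
  onset <- detect_onset(called)
  if (is.null(onset)) return(NULL)
  curve <- tryCatch(autocorrelation_curve(called, onset, K = K, W = W,
                                          mode = mode, chrom = chrom),
                    error = function(e) NULL)
  if (is.null(curve) || all(is.na(curve$scores))) return(NULL)
  sc <- curve$scores
  k_star <- which(sc == max(sc, na.rm = TRUE))[1]   # ties -> smaller k
  second <- if (sum(!is.na(sc)) > 1) max(sc[-k_star], na.rm = TRUE) else 0
  margin <- sc[k_star] - max(second, 0)
  if (is.na(sc[k_star]) || sc[k_star] < theta || margin < delta ||
      curve$n_informative[k_star] < min_informative)
    return(NULL)
  dec <- tryCatch(deconvolve_alleles(called, onset, k_star, reference, W = W),
                  error = function(e) NULL)
  if (is.null(dec) || dec$failed) return(NULL)
  nv <- left_normalize(dec$ref_position, dec$indel_sequence, dec$direction,
                       reference)
  structure(list(k = k_star, direction = dec$direction, onset = onset,
                 refined_ref_position = nv$position,
                 indel_sequence = nv$seq,
                 score = unname(sc[k_star]), margin = unname(margin),
                 alleleA = dec$alleleA, alleleB = dec$alleleB,
                 refinement_source = "het_deconvolution",
                 repeat_shift = nv$shifted,
                 consistency = dec$consistency,
                 curve = curve,
                 sample_id = called$source$sample_id),
            class = "indel_candidate")
}

#' @export
print.indel_candidate <- function(x, ...) {
  cat(sprintf("<indel_candidate> %s of %d bp ('%s') at ref %d (onset %d), S=%.2f margin=%.2f [%s]\n",
              x$direction, x$k, x$indel_sequence, x$refined_ref_position,
              x$onset, x$score, x$margin, x$refinement_source))
  invisible(x)
}

#' Refine heterozygous indel positions using homozygous carriers
#'
#' When any cohort trace alignment shows a clean homozygous gap of the
#' same kind and size within `k` plus the local repeat-run length of a
#' heterozygous candidate's estimate, every matching candidate's position
#' is replaced by the left-aligned homozygous gap position and its
#' `refinement_source` set to `"homozygous_carrier"`. Conflicting
#' homozygous positions for the same locus produce a warning and leave
#' the heterozygous estimates untouched.
#'
#' @param candidates list of `indel_candidate` objects from one amplicon
#' @param cohort_alignments list of `trace_alignment` objects for the
#'   cohort's traces on the same amplicon
#' @return the candidate list, refined where possible
#' @export
refine_with_homozygotes <- function(candidates, cohort_alignments) {
  if (!length(candidates)) return(candidates)
  homs <- do.call(rbind, lapply(cohort_alignments, alignment_hom_indels))
  if (is.null(homs) || !nrow(homs)) return(candidates)
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    if (is.null(cand)) next
    tol <- cand$k + cand$repeat_shift
    match <- homs[homs$kind == cand$direction & homs$size == cand$k &
                  abs(homs$position - cand$refined_ref_position) <= tol, ,
                  drop = FALSE]
    if (!nrow(match)) next
    upos <- unique(match$position)
    if (length(upos) > 1) {
      warning("conflicting homozygous positions for ", cand$direction,
              " of size ", cand$k, "; keeping heterozygous estimate",
              call. = FALSE)
      next
    }
    cand$refined_ref_position <- upos
    cand$indel_sequence <- match$seq[1]
    cand$refinement_source <- "homozygous_carrier"
    candidates[[ci]] <- cand
  }
  candidates
}
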