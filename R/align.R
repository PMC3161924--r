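# match 2 / mismatch -4 / gap open 2 / extend 2: a 1-base read gap (8 - 4)
# beats a substitution path (6 - 4), so homozygous indel signatures align
# as gaps, while an isolated mismatch (-4) still beats a gap pair (-8)
ALN_MATCH <- 2; ALN_MISMATCH <- -4; ALN_GAP_OPEN <- 2; ALN_GAP_EXT <- 2

#' Align a called sequence to an amplicon reference
#'
#' Global-local affine-gap alignment of the primary base string into the
#' reference (the read is aligned end-to-end, the reference locally), via
#' `Biostrings::pairwiseAlignment` with match 2, mismatch -3, gap opening
#' 5 and gap extension 2. An alignment with identity below 50% is returned
#' flagged `unalignable` rather than raising an error.
#'
#' @param called a `called_sequence` from [call_bases()]
#' @param reference reference sequence (ACGT string), length >= 10
#' @param reference_id label carried into downstream variant calls
#' @return object of class `trace_alignment`: list with `called`,
#'   `reference_id`, `ref_start` (1-based), `pairs` (data frame with
#'   0-based `base_index`, `NA` for a read gap, and 1-based `ref_pos`,
#'   `NA` for an inserted read base), `score`, `identity`, `unalignable`
#' @export
align_to_reference <- function(called, reference, reference_id = "ref") {
  stopifnot(inherits(called, "called_sequence"))
  if (nchar(reference) < 5) stop("reference too short (< 5)", call. = FALSE)
  read <- called$primary_string
  if (!nzchar(read)) stop("called sequence is empty", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = ALN_MATCH,
                                                  mismatch = ALN_MISMATCH)
  aln <- Biostrings::pairwiseAlignment(read, reference,
                                       type = "global-local",
                                       substitutionMatrix = mat,
                                       gapOpening = ALN_GAP_OPEN,
                                       gapExtension = ALN_GAP_EXT)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_start <- Biostrings::start(Biostrings::subject(aln))
  bi <- -1L; rp <- ref_start - 1L
  pairs <- data.frame(base_index = integer(length(pat)),
                      ref_pos = integer(length(pat)))
  for (i in seq_along(pat)) {
    pairs$base_index[i] <- if (pat[i] == "-") NA_integer_ else (bi <- bi + 1L)
    pairs$ref_pos[i] <- if (sub[i] == "-") NA_integer_ else (rp <- rp + 1L)
  }
  ncomp <- sum(!is.na(pairs$base_index) & !is.na(pairs$ref_pos))
  nid <- sum(pat == sub)
  identity <- if (ncomp > 0) 100 * nid / ncomp else 0
  structure(list(called = called, reference_id = reference_id,
                 reference = reference, ref_start = ref_start,
                 pairs = pairs, score = Biostrings::score(aln),
                 identity = identity, unalignable = identity < 50),
            class = "trace_alignment")
}

#' @export
print.trace_alignment <- function(x, ...) {
  cat(sprintf("<trace_alignment> %s: ref_start %d, score %.1f, identity %.1f%%%s\n",
              x$reference_id, x$ref_start, x$score, x$identity,
              if (x$unalignable) " [unalignable]" else ""))
  invisible(x)
}

# Homozygous indels evident in a trace alignment: maximal gap runs.
# Read gaps (base_index NA) are deletions relative to the reference;
# reference gaps (ref_pos NA) are insertions. A gap is "clean" when the
# secondary-call density in the 8 calls after the gap is below 0.2 (a
# heterozygous carrier would be degenerate there).
alignment_hom_indels <- function(aln) {
  p <- aln$pairs
  out <- list()
  runs <- function(idx) {
    if (!length(idx)) return(list())
    b <- cumsum(c(TRUE, diff(idx) != 1))
    split(idx, b)
  }
  sec <- !is.na(aln$called$calls$secondary_base)
  clean_after <- function(row) {
    if (row + 1 > length(sec)) return(TRUE)
    look <- (row + 1):min(length(sec), row + 8)
    mean(sec[look]) < 0.2
  }
  for (r in runs(which(is.na(p$base_index)))) {
    pos <- p$ref_pos[r]
    seqs <- substr(aln$reference, min(pos), max(pos))
    rest <- p$base_index[seq_len(nrow(p)) > max(r)]
    nb <- rest[!is.na(rest)][1]
    if (is.na(nb) || clean_after(nb + 1)) {
      nv <- left_normalize(min(pos), seqs, "del", aln$reference)
      out[[length(out) + 1L]] <- data.frame(kind = "del",
                                            position = nv$position,
                                            seq = nv$seq,
                                            size = nchar(nv$seq))
    }
  }
  for (r in runs(which(is.na(p$ref_pos)))) {
    bi <- p$base_index[r]
    seqs <- substr(aln$called$primary_string, min(bi) + 1, max(bi) + 1)
    prev <- p$ref_pos[seq_len(r[1] - 1)]
    prev <- prev[!is.na(prev)]
    at <- if (length(prev)) prev[length(prev)] + 1L else aln$ref_start
    if (clean_after(max(bi) + 1)) {
      nv <- left_normalize(at, seqs, "ins", aln$reference)
      out[[length(out) + 1L]] <- data.frame(kind = "ins",
                                            position = nv$position,
                                            seq = nv$seq,
                                            size = nchar(nv$seq))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), position = integer(), seq = character(),
               size = integer())
}

#' Per-reference-position site statistics of an alignment
#'
#' Used to interrogate a matched-normal trace at a tumor variant position:
#' reports the called quality and the secondary/primary amplitude ratio at
#' every aligned reference position.
#'
#' @param aln a `trace_alignment`
#' @return data frame with `position`, `primary_base`, `secondary_base`,
#'   `ratio`, `quality`
#' @export
site_table <- function(aln) {
  stopifnot(inherits(aln, "trace_alignment"))
  p <- aln$pairs[!is.na(aln$pairs$base_index) & !is.na(aln$pairs$ref_pos), ]
  calls <- aln$called$calls[p$base_index + 1, ]
  data.frame(position = p$ref_pos,
             primary_base = calls$primary_base,
             secondary_base = calls$secondary_base,
             ratio = ifelse(is.na(calls$ratio), 0, calls$ratio),
             quality = calls$quality,
             stringsAsFactors = FALSE)
}
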