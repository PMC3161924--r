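new_variant_call <- function(reference_id, position, ref, alt, kind,
                             zygosity, quality, trace_id, strand,
                             flags = character(), extra = list()) {
  list(reference_id = reference_id, position = as.integer(position),
       ref = ref, alt = alt, kind = kind, zygosity = zygosity,
       quality = as.integer(quality),
       support = data.frame(trace_id = trace_id, strand = strand,
                            stringsAsFactors = FALSE),
       flags = flags, extra = extra)
}

variant_key <- function(v) paste(v$position, v$ref, v$alt, sep = ":")

#' Call heterozygous and homozygous SNVs from a trace alignment
#'
#' At every aligned position a heterozygous SNV is called when a secondary
#' peak passes the ratio and quality gates and either the secondary base
#' differs from the reference or the primary differs while the secondary
#' matches it; a homozygous SNV when the primary differs from the
#' reference with no secondary call. Positions from two bases before a
#' heterozygous-indel onset onward are suppressed (the superposed region
#' is unreliable for point calls).
#'
#' @param aln a `trace_alignment` (not flagged unalignable)
#' @param min_ratio minimum secondary/primary amplitude ratio
#' @param min_qual minimum call quality
#' @param indel_onset optional 0-based onset of a detected heterozygous
#'   indel in the same trace
#' @return list of variant calls
#' @export
call_het_snvs <- function(aln, min_ratio = 0.25, min_qual = 20,
                          indel_onset = NULL) {
  stopifnot(inherits(aln, "trace_alignment"))
  if (aln$unalignable) stop("alignment is flagged unalignable", call. = FALSE)
  calls <- aln$called$calls
  src <- aln$called$source
  trace_id <- paste0(src$sample_id %||% "trace", "/", src$strand)
  p <- aln$pairs[!is.na(aln$pairs$base_index) & !is.na(aln$pairs$ref_pos), ]
  out <- list()
  for (r in seq_len(nrow(p))) {
    bi <- p$base_index[r]
    if (!is.null(indel_onset) && bi >= indel_onset - 2) next
    cc <- calls[bi + 1, ]
    refb <- substr(aln$reference, p$ref_pos[r], p$ref_pos[r])
    if (cc$quality < min_qual) next
    if (!is.na(cc$secondary_base)) {
      if (cc$ratio < min_ratio) next
      alt <- if (cc$secondary_base != refb) cc$secondary_base
        else if (cc$primary_base != refb) cc$primary_base
        else NA_character_
      if (is.na(alt)) next
      out[[length(out) + 1L]] <- new_variant_call(
        aln$reference_id, p$ref_pos[r], refb, alt, "snv", "het",
        cc$quality, trace_id, src$strand)
    } else if (cc$primary_base != refb) {
      out[[length(out) + 1L]] <- new_variant_call(
        aln$reference_id, p$ref_pos[r], refb, cc$primary_base, "snv", "hom",
        cc$quality, trace_id, src$strand)
    }
  }
  out
}

#' Map variant calls from a reverse-strand frame to the forward frame
#'
#' Calls made against the reverse-complemented reference are flipped:
#' positions are mirrored, alleles reverse-complemented, and indels
#' re-left-normalized against the forward reference.
#'
#' @param calls list of variant calls in the reverse frame
#' @param reference forward reference sequence
#' @return list of calls in the forward frame
#' @export
flip_calls_to_forward <- function(calls, reference) {
  L <- nchar(reference)
  lapply(calls, function(v) {
    if (v$kind == "snv") {
      v$position <- L - v$position + 1L
      v$ref <- revcomp(v$ref); v$alt <- revcomp(v$alt)
    } else if (v$kind == "del") {
      k <- nchar(v$ref)
      v$position <- L - (v$position + k - 1L) + 1L
      v$ref <- revcomp(v$ref)
      nv <- left_normalize(v$position, v$ref, "del", reference)
      v$position <- nv$position; v$ref <- nv$seq
    } else if (v$kind == "ins") {
      k <- nchar(v$alt)
      v$position <- L - v$position + 2L
      v$alt <- revcomp(v$alt)
      nv <- left_normalize(v$position, v$alt, "ins", reference)
      v$position <- nv$position; v$alt <- nv$seq
    }
    v
  })
}

#' Merge and cross-validate variant calls from multiple traces
#'
#' Calls are merged by their normalized (position, ref, alt) key with
#' support unioned. A call observed on only one strand while some other
#' covering trace ran the opposite strand is flagged `single_strand`
#' (retained, not dropped — indel superposition can masquerade as poor
#' quality, so sensitivity is favoured). Discordant zygosity between
#' supporting traces is flagged `zygosity_conflict`.
#'
#' @param calls_by_trace list of per-trace call lists
#' @param coverage optional data frame with `trace_id`, `strand`,
#'   `ref_start`, `ref_end` describing what each trace covered; without
#'   it no single-strand flagging is possible
#' @return merged list of calls, ordered by position then alt
#' @export
cross_validate <- function(calls_by_trace, coverage = NULL) {
  flat <- unlist(calls_by_trace, recursive = FALSE)
  if (!length(flat)) return(list())
  keys <- vapply(flat, variant_key, "")
  merged <- lapply(split(seq_along(flat), keys), function(ix) {
    v <- flat[[ix[1]]]
    v$support <- unique(do.call(rbind, lapply(flat[ix], `[[`, "support")))
    rownames(v$support) <- NULL
    zyg <- unique(vapply(flat[ix], `[[`, "", "zygosity"))
    if (length(zyg) > 1) v$flags <- union(v$flags, "zygosity_conflict")
    v$quality <- max(vapply(flat[ix], `[[`, 1L, "quality"))
    if (!is.null(coverage)) {
      cov <- coverage[coverage$ref_start <= v$position &
                      coverage$ref_end >= v$position, , drop = FALSE]
      missing_strand <- setdiff(unique(cov$strand), unique(v$support$strand))
      if (length(missing_strand) && length(unique(v$support$strand)) == 1)
        v$flags <- union(v$flags, "single_strand")
    }
    v
  })
  ord <- order(vapply(merged, `[[`, 1L, "position"),
               vapply(merged, `[[`, "", "alt"))
  unname(merged[ord])
}

#' Write variant calls as VCF 4.2
#'
#' Indels use the standard anchor-base convention (`POS` is the base
#' before the event); an indel at reference position 1 is padded with the
#' following base and flagged. Records are ordered by position then
#' alternate allele; genotypes are `0/1` (het) or `1/1` (hom). Indel
#' records carry `K`, `SCORE` and `MARGIN` in INFO when available.
#'
#' @param calls merged call list (normalized)
#' @param reference forward reference sequence
#' @param reference_id contig name
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(calls, reference, reference_id, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", reference_id, nchar(reference)),
           "##INFO=<ID=K,Number=1,Type=Integer,Description=\"Indel shift size\">",
           "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Autocorrelation score\">",
           "##INFO=<ID=MARGIN,Number=1,Type=Float,Description=\"Score margin over runner-up\">",
           "##INFO=<ID=FLAGS,Number=.,Type=String,Description=\"Call flags\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "sample", sep = "\t"))
  rows <- lapply(calls, function(v) {
    flags <- v$flags
    if (v$kind == "snv") {
      pos <- v$position; ref <- v$ref; alt <- v$alt
    } else if (v$kind == "del") {
      if (v$position == 1) {
        nxt <- substr(reference, v$position + nchar(v$ref),
                      v$position + nchar(v$ref))
        pos <- 1; ref <- paste0(v$ref, nxt); alt <- nxt
        flags <- union(flags, "no_left_anchor")
      } else {
        pos <- v$position - 1L
        anchor <- substr(reference, pos, pos)
        ref <- paste0(anchor, v$ref); alt <- anchor
      }
    } else {  # ins
      if (v$position == 1) {
        nxt <- substr(reference, 1, 1)
        pos <- 1; ref <- nxt; alt <- paste0(v$alt, nxt)
        flags <- union(flags, "no_left_anchor")
      } else {
        pos <- v$position - 1L
        anchor <- substr(reference, pos, pos)
        ref <- anchor; alt <- paste0(anchor, v$alt)
      }
    }
    info <- character()
    if (!is.null(v$extra$k)) info <- c(info, paste0("K=", v$extra$k))
    if (!is.null(v$extra$score))
      info <- c(info, sprintf("SCORE=%.3f", v$extra$score))
    if (!is.null(v$extra$margin))
      info <- c(info, sprintf("MARGIN=%.3f", v$extra$margin))
    if (length(flags)) info <- c(info, paste0("FLAGS=", paste(flags, collapse = ",")))
    gt <- if (v$zygosity == "hom") "1/1" else "0/1"
    list(pos = pos, alt = alt,
         line = paste(reference_id, pos, ".", ref, alt, v$quality, "PASS",
                      if (length(info)) paste(info, collapse = ";") else ".",
                      "GT", gt, sep = "\t"))
  })
  ord <- order(vapply(rows, `[[`, 1, "pos"), vapply(rows, `[[`, "", "alt"))
  writeLines(c(hdr, vapply(rows[ord], `[[`, "", "line")), path)
  invisible(path)
}

#' Read a chromadip VCF back into normalized calls
#'
#' Inverse of [write_vcf()] for round-tripping: anchor bases are stripped
#' and indels restored to the internal left-normalized representation.
#'
#' @param path VCF file
#' @return list of calls with `position`, `ref`, `alt`, `kind`, `zygosity`
#' @export
read_vcf_calls <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  lapply(strsplit(ln, "\t"), function(f) {
    pos <- as.integer(f[2]); ref <- f[4]; alt <- f[5]
    flags <- if (grepl("FLAGS=", f[8]))
      strsplit(sub(".*FLAGS=([^;]*).*", "\\1", f[8]), ",")[[1]] else character()
    if (nchar(ref) == 1 && nchar(alt) == 1) {
      kind <- "snv"
    } else if (nchar(ref) > nchar(alt)) {
      kind <- "del"
      if ("no_left_anchor" %in% flags) {
        ref <- substr(ref, 1, nchar(ref) - 1)
      } else {
        pos <- pos + 1L
        ref <- substr(ref, 2, nchar(ref))
      }
      alt <- ""
    } else {
      kind <- "ins"
      if ("no_left_anchor" %in% flags) {
        alt <- substr(alt, 1, nchar(alt) - 1)
      } else {
        pos <- pos + 1L
        alt <- substr(alt, 2, nchar(alt))
      }
      ref <- ""
    }
    list(position = pos, ref = ref, alt = alt, kind = kind,
         zygosity = if (f[10] == "1/1") "hom" else "het",
         quality = as.integer(f[6]), flags = flags)
  })
}

#' Turn an indel candidate into a variant call
#'
#' @param cand an `indel_candidate` from [detect_het_indel()]
#' @param reference_id contig name
#' @param trace_id,strand support labels
#' @param zygosity `"het"` (default) or `"hom"`
#' @return a variant call
#' @export
indel_to_call <- function(cand, reference_id = "ref", trace_id = "trace",
                          strand = "+", zygosity = "het") {
  new_variant_call(reference_id, cand$refined_ref_position,
                   ref = if (cand$direction == "del") cand$indel_sequence else "",
                   alt = if (cand$direction == "ins") cand$indel_sequence else "",
                   kind = cand$direction, zygosity = zygosity,
                   quality = min(40L, round(40 * cand$score)),
                   trace_id = trace_id, strand = strand,
                   flags = if (cand$repeat_shift > 0) "repeat_run" else character(),
                   extra = list(k = cand$k, score = cand$score,
                                margin = cand$margin,
                                refinement_source = cand$refinement_source))
}
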