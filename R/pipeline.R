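#' Call all variants from one sample's traces on an amplicon
#'
#' Runs the full per-sample pipeline: base calling, alignment (reverse
#' traces are aligned against the reverse-complemented reference and
#' their calls mapped back to the forward frame), heterozygous indel
#' detection, SNV calling with indel-adjacent suppression, and
#' cross-validation across strands.
#'
#' @param traces named list of [chromatogram()]s (e.g. `fwd`, `rev`)
#' @param reference forward amplicon reference sequence
#' @param reference_id contig label
#' @param min_ratio,min_qual SNV gates passed to [call_het_snvs()]
#' @param ... further arguments to [detect_het_indel()]
#' @return list with `calls` (merged variant calls), `alignments`
#'   (forward-frame alignments keyed like `traces`), `sites`
#'   (forward-strand [site_table()]), `indel_candidates`
#' @export
call_sample_variants <- function(traces, reference, reference_id = "ref",
                                 min_ratio = 0.25, min_qual = 20, ...) {
  per_trace <- list()
  alignments <- list()
  sites <- NULL
  cands <- list()
  coverage <- NULL
  for (nm in names(traces)) {
    chrom <- traces[[nm]]
    cs <- call_bases(chrom, min_secondary_ratio = min_ratio)
    ref_use <- if (chrom$strand == "-") revcomp(reference) else reference
    aln <- align_to_reference(cs, ref_use, reference_id)
    if (aln$unalignable) next
    cand <- detect_het_indel(cs, ref_use, ...)
    onset <- if (!is.null(cand)) cand$onset else NULL
    calls <- call_het_snvs(aln, min_ratio = min_ratio, min_qual = min_qual,
                           indel_onset = onset)
    if (!is.null(cand)) {
      calls <- c(calls, list(indel_to_call(cand, reference_id,
                                           trace_id = paste0(chrom$sample_id, "/", nm),
                                           strand = chrom$strand)))
      cands[[nm]] <- cand
    }
    if (chrom$strand == "-") {
      calls <- flip_calls_to_forward(calls, reference)
      rng <- range(aln$pairs$ref_pos, na.rm = TRUE)
      cov <- data.frame(trace_id = paste0(chrom$sample_id, "/", nm),
                        strand = "-",
                        ref_start = nchar(reference) - rng[2] + 1,
                        ref_end = nchar(reference) - rng[1] + 1)
    } else {
      rng <- range(aln$pairs$ref_pos, na.rm = TRUE)
      cov <- data.frame(trace_id = paste0(chrom$sample_id, "/", nm),
                        strand = "+", ref_start = rng[1], ref_end = rng[2])
      sites <- rbind(sites, site_table(aln))
    }
    coverage <- rbind(coverage, cov)
    alignments[[nm]] <- aln
    per_trace[[nm]] <- calls
  }
  list(calls = cross_validate(per_trace, coverage),
       alignments = alignments, sites = sites, indel_candidates = cands)
}

#' Screen a simulated tumor/normal cohort for somatic mutations
#'
#' Applies [call_sample_variants()] to every sample's tumor and normal
#' traces, refines heterozygous indel positions with any homozygous
#' carriers seen in the cohort, and classifies each tumor variant with
#' [classify_somatic()].
#'
#' @param fixture a cohort from [make_cohort_fixture()]
#' @param known_positions known-polymorphism positions
#' @param ... arguments passed to [call_sample_variants()]
#' @return data frame with one row per tumor variant: `sample`,
#'   `position`, `ref`, `alt`, `kind`, `zygosity`, `status`
#' @export
screen_cohort <- function(fixture, known_positions = integer(), ...) {
  ref <- fixture$reference
  rows <- list()
  for (s in names(fixture$samples)) {
    sm <- fixture$samples[[s]]
    tum <- call_sample_variants(sm$tumor, ref, ...)
    nor <- call_sample_variants(sm$normal, ref, ...)
    classified <- classify_somatic(tum$calls, nor$calls, nor$sites)
    for (v in classified) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, position = v$position, ref = v$ref, alt = v$alt,
        kind = v$kind, zygosity = v$zygosity, status = v$status,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), position = integer(),
               ref = character(), alt = character(), kind = character(),
               zygosity = character(), status = character())
}
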