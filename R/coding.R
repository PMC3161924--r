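#' Annotate the coding effect of a variant
#'
#' For SNVs, the affected codon is substituted and translated with the
#' standard genetic code: an unchanged amino acid is synonymous, a gained
#' stop is nonsense, anything else missense. Indels whose size is not a
#' multiple of 3 are frameshift; in-frame indels are reported as
#' `"inframe"`. Coordinates are 1-based CDS positions.
#'
#' @param position 1-based CDS position of the variant (first affected
#'   base for indels)
#' @param ref,alt reference and alternate alleles (SNV: single bases;
#'   del: `alt = ""`; ins: `ref = ""`)
#' @param cds coding sequence, length divisible by 3
#' @param codon_table named translation vector, default
#'   `Biostrings::GENETIC_CODE`
#' @return list with `effect` (`missense`/`nonsense`/`synonymous`/
#'   `frameshift`/`inframe`), `aa_change` (e.g. `"R1414X"`), `hgvs_c`
#'   (e.g. `"c.C4240T"`), `hgvs_p`
#' @export
annotate_coding_effect <- function(position, ref, alt, cds,
                                   codon_table = Biostrings::GENETIC_CODE) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3", call. = FALSE)
  if (position < 1 || position > nchar(cds))
    stop("position ", position, " beyond the CDS", call. = FALSE)
  if (nchar(ref) != nchar(alt)) {
    k <- abs(nchar(ref) - nchar(alt))
    eff <- if (k %% 3 == 0) "inframe" else "frameshift"
    codon_index <- (position - 1) %/% 3 + 1
    return(list(effect = eff, aa_change = sprintf("fs@%d", codon_index),
                hgvs_c = sprintf("c.%d%s", position,
                                 if (nchar(ref) > nchar(alt))
                                   paste0("del", ref) else paste0("ins", alt)),
                hgvs_p = NA_character_))
  }
  if (substr(cds, position, position) != ref)
    stop("reference mismatch: CDS has ",
         substr(cds, position, position), " at ", position, call. = FALSE)
  codon_index <- (position - 1) %/% 3 + 1
  offset <- (position - 1) %% 3
  codon <- substr(cds, 3 * codon_index - 2, 3 * codon_index)
  alt_codon <- codon
  substr(alt_codon, offset + 1, offset + 1) <- alt
  aa_ref <- unname(codon_table[codon])
  aa_alt <- unname(codon_table[alt_codon])
  effect <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense" else "missense"
  aa_alt_sym <- if (aa_alt == "*") "X" else aa_alt
  aa_change <- paste0(aa_ref, codon_index, aa_alt_sym)
  list(effect = effect, aa_change = aa_change,
       hgvs_c = sprintf("c.%s%d%s", ref, position, alt),
       hgvs_p = aa_change)
}

#' Expected nonsynonymous:synonymous ratio under neutrality
#'
#' Enumerates all nine single-base substitutions of every codon of the
#' CDS (excluding a terminal stop codon), classifies each against the
#' translation (stop gains count as nonsynonymous), and weights by the
#' supplied substitution spectrum (uniform by default). The ratio is the
#' neutral expectation against which an observed NS:S ratio is compared.
#'
#' @param cds coding sequence, length divisible by 3, no ambiguity codes
#' @param spectrum optional named weights for substitution types, names
#'   like `"C>T"`; missing types get weight 0
#' @param codon_table named translation vector
#' @return list with `ns`, `s`, and `ratio` (`NA` when `s` is 0)
#' @export
expected_ns_ratio <- function(cds, spectrum = NULL,
                              codon_table = Biostrings::GENETIC_CODE) {
  check_acgt(cds, "CDS")
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3", call. = FALSE)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  if (length(codons) && codon_table[codons[length(codons)]] == "*")
    codons <- codons[-length(codons)]
  ns <- 0; s <- 0
  for (codon in codons) {
    aa <- codon_table[codon]
    for (off in 1:3) {
      refb <- substr(codon, off, off)
      for (b in setdiff(BASES, refb)) {
        w <- if (is.null(spectrum)) 1 else
          spectrum[paste0(refb, ">", b)] %||% 0
        if (is.na(w)) w <- 0
        mut <- codon
        substr(mut, off, off) <- b
        if (codon_table[mut] == aa) s <- s + w else ns <- ns + w
      }
    }
  }
  list(ns = ns, s = s, ratio = if (s > 0) ns / s else NA_real_)
}

#' Synthetic ATAD5-like coding sequence
#'
#' A synthetic stand-in CDS (the screen's real coding sequence is not
#' redistributed here): 1600 codons plus a terminal stop, filled with
#' alanine codons except at the eleven codons touched by the packaged
#' mutation table, which are set so that each tabulated nucleotide change
#' produces its tabulated amino-acid change. Used by the annotation
#' examples, tests and the cohort acceptance script.
#'
#' @return CDS string (length 4803)
#' @export
synthetic_atad5_cds <- function() {
  n_codons <- 1600
  codons <- rep("GCT", n_codons)
  special <- c("91" = "CCT", "298" = "GAA", "302" = "AGT", "390" = "GCT",
               "638" = "AGT", "723" = "GAA", "1381" = "GAC", "1414" = "CGA",
               "1460" = "GAG", "1516" = "CCA", "1589" = "TCT")
  codons[as.integer(names(special))] <- special
  paste0(paste(codons, collapse = ""), "TAA")
}
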