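#' Classify tumor variants as somatic, germline, known polymorphism or ambiguous
#'
#' Mirrors the matched-normal resequencing step of a tumor screen: a tumor
#' variant at a position on the known-polymorphism list is labelled
#' `known_polymorphism` (takes precedence); one whose (position, ref, alt)
#' also appears in the matched normal is `germline`; otherwise the normal
#' trace itself is interrogated at the site — a clean, high-quality normal
#' site (quality >= `min_normal_qual`, secondary ratio <
#' `normal_ratio_max`) makes the variant `somatic`, anything less
#' evaluable makes it `ambiguous`. Without a matched normal every variant
#' is `ambiguous` (with a warning).
#'
#' @param tumor_calls merged tumor variant calls
#' @param normal_calls merged matched-normal calls (or `NULL`)
#' @param normal_sites data frame from [site_table()] on the normal
#'   alignment(s); used to check quality/ratio at variant positions
#' @param known_positions integer vector of known-polymorphism positions
#' @param normal_ratio_max maximum secondary ratio tolerated at a clean
#'   normal site
#' @param min_normal_qual minimum normal site quality
#' @return list of somatic calls: each tumor call gains a `status` field
#' @export
classify_somatic <- function(tumor_calls, normal_calls, normal_sites = NULL,
                             known_positions = integer(),
                             normal_ratio_max = 0.15, min_normal_qual = 20) {
  if (is.null(normal_calls)) {
    warning("no matched normal: all tumor variants are ambiguous",
            call. = FALSE)
    return(lapply(tumor_calls, function(v) { v$status <- "ambiguous"; v }))
  }
  normal_keys <- vapply(normal_calls, variant_key, "")
  lapply(tumor_calls, function(v) {
    v$status <- if (v$position %in% known_positions) {
      "known_polymorphism"
    } else if (variant_key(v) %in% normal_keys) {
      "germline"
    } else if (!is.null(normal_sites)) {
      hit <- normal_sites[normal_sites$position == v$position, , drop = FALSE]
      if (!nrow(hit)) "ambiguous"
      else {
        best <- hit[which.max(hit$quality), ]
        if (best$quality < min_normal_qual) "ambiguous"
        else if (best$ratio >= normal_ratio_max) "ambiguous"
        else "somatic"
      }
    } else "somatic"
    v
  })
}

#' Classify allelic expression at a heterozygous variant site
#'
#' Given the called RT-PCR trace at a site known to be heterozygous in
#' genomic DNA, expression is biallelic when both the wild-type and the
#' mutant base are detected (the minor one with a secondary ratio of at
#' least `ratio`), monoallelic when only one is, and indeterminate when
#' the site quality is below 20.
#'
#' @param site one-row data frame from [site_table()] at the variant
#'   position (fields `primary_base`, `secondary_base`, `ratio`,
#'   `quality`)
#' @param wt_base,mut_base the two genomic alleles
#' @param ratio minimum secondary ratio for the minor allele
#' @return `"biallelic"`, `"monoallelic"` or `"indeterminate"`
#' @export
classify_allelic_expression <- function(site, wt_base, mut_base,
                                        ratio = 0.2) {
  if (site$quality < 20) return("indeterminate")
  seen <- site$primary_base
  if (!is.na(site$secondary_base) && site$ratio >= ratio)
    seen <- c(seen, site$secondary_base)
  if (all(c(wt_base, mut_base) %in% seen)) "biallelic" else "monoallelic"
}

#' Load the packaged endometrial-tumor mutation table
#'
#' Eleven somatic coding mutations found by resequencing the cohort's 108
#' endometrial tumors (66 non-endometrioid, 42 endometrioid), as a data
#' frame with columns `case`, `subtype`, `c_change`, `aa_change`, `type`.
#'
#' @return data frame with 11 rows
#' @export
load_mutation_table <- function() {
  read.delim(system.file("extdata", "endometrial_mutations.tsv",
                         package = "chromadip"),
             stringsAsFactors = FALSE)
}

# Parse "c.G905T" into ref base, CDS position, alt base.
parse_c_change <- function(x) {
  m <- regmatches(x, regexec("^c\\.([ACGT])(\\d+)([ACGT])$", x))[[1]]
  if (length(m) != 4) stop("cannot parse nucleotide change: ", x, call. = FALSE)
  list(ref = m[2], position = as.integer(m[3]), alt = m[4])
}

#' Summarize a somatic mutation cohort
#'
#' Computes the headline statistics of a resequencing screen: mutation
#' and mutated-case counts, per-subtype frequencies (percent, floored to
#' one decimal), the observed nonsynonymous:synonymous ratio and its fold
#' over the neutral expectation, the reference-base spectrum, the number
#' of truncating (nonsense/frameshift) mutations, and the number of cases
#' carrying multiple mutations.
#'
#' @param mutations data frame with columns `case`, `subtype`, `c_change`,
#'   `type` (e.g. from [load_mutation_table()] or a somatic call set)
#' @param cohort_sizes named integer vector of cases screened per subtype,
#'   e.g. `c(NEEC = 66, EEC = 42)`
#' @param expected_ratio neutral NS:S expectation used for the fold
#'   statistic (or compute one with [expected_ns_ratio()])
#' @return list of class `cohort_summary`
#' @export
summarize_cohort <- function(mutations, cohort_sizes = c(NEEC = 66, EEC = 42),
                             expected_ratio = 2.0) {
  stopifnot(all(c("case", "subtype", "c_change", "type") %in% names(mutations)))
  if (any(is.na(mutations$subtype) | !nzchar(mutations$subtype)))
    warning("records without subtype are counted overall only", call. = FALSE)
  n_mut <- nrow(mutations)
  cases <- unique(mutations$case)
  n_cases <- length(cases)
  n_total <- as.integer(sum(cohort_sizes))
  per_subtype <- lapply(names(cohort_sizes), function(st) {
    cs <- unique(mutations$case[mutations$subtype %in% st])
    list(subtype = st, n_cases = length(cs), size = cohort_sizes[[st]],
         freq = pct_floor(length(cs), cohort_sizes[[st]]))
  })
  names(per_subtype) <- names(cohort_sizes)
  type <- tolower(mutations$type)
  ns_count <- sum(type %in% c("missense", "nonsense", "frameshift"))
  s_count <- sum(type == "synonymous")
  ns_s_ratio <- if (s_count > 0) ns_count / s_count else NA_real_
  parsed <- lapply(mutations$c_change, parse_c_change)
  refs <- vapply(parsed, `[[`, "", "ref")
  ref_base_counts <- vapply(BASES, function(b) sum(refs == b), 1L)
  mult <- table(mutations$case)
  structure(list(
    n_mutations = n_mut,
    n_cases_mutated = n_cases,
    n_cases_total = n_total,
    freq_overall = pct_floor(n_cases, n_total),
    per_subtype = per_subtype,
    ns_count = ns_count, s_count = s_count,
    ns_s_ratio = ns_s_ratio,
    expected_ratio = expected_ratio,
    fold_vs_expected = if (!is.na(ns_s_ratio)) ns_s_ratio / expected_ratio
      else NA_real_,
    ref_base_counts = ref_base_counts,
    n_truncating = sum(type %in% c("nonsense", "frameshift")),
    n_cases_multiple = sum(mult >= 2)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%d somatic mutations in %d of %d cases (%.1f%%)\n",
              x$n_mutations, x$n_cases_mutated, x$n_cases_total,
              x$freq_overall))
  for (st in x$per_subtype)
    cat(sprintf("  %s: %d of %d (%.1f%%)\n", st$subtype, st$n_cases,
                st$size, st$freq))
  cat(sprintf("NS:S = %d:%d (%.1f), %.1f-fold over expected %.1f\n",
              x$ns_count, x$s_count, x$ns_s_ratio, x$fold_vs_expected,
              x$expected_ratio))
  cat(sprintf("reference bases A/C/G/T: %s; truncating: %d; cases with multiple mutations: %d\n",
              paste(x$ref_base_counts, collapse = "/"), x$n_truncating,
              x$n_cases_multiple))
  invisible(x)
}

#' Fisher's exact test of mutation frequency between two subtypes
#'
#' Utility comparison of mutated-case counts between two cohort subtypes
#' (two-sided).
#'
#' @param summary a `cohort_summary` with exactly two subtypes
#' @return the `htest` object from [stats::fisher.test()]
#' @export
subtype_fisher_test <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"),
            length(summary$per_subtype) == 2)
  m <- vapply(summary$per_subtype, function(st)
    c(st$n_cases, st$size - st$n_cases), numeric(2))
  fisher.test(m)
}
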