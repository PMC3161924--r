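test_that("somatic status follows the matched-normal rules", {
  tum <- list(chromadip:::new_variant_call("amp", 10L, "G", "T", "snv",
                                           "het", 40L, "t/+", "+"),
              chromadip:::new_variant_call("amp", 25L, "C", "A", "snv",
                                           "het", 40L, "t/+", "+"),
              chromadip:::new_variant_call("amp", 33L, "G", "A", "snv",
                                           "het", 40L, "t/+", "+"),
              chromadip:::new_variant_call("amp", 40L, "C", "T", "snv",
                                           "het", 40L, "t/+", "+"))
  nor <- list(chromadip:::new_variant_call("amp", 25L, "C", "A", "snv",
                                           "het", 40L, "n/+", "+"))
  sites <- data.frame(position = c(10L, 33L, 40L),
                      primary_base = c("G", "G", "C"),
                      secondary_base = NA_character_,
                      ratio = c(0, 0, 0), quality = c(40L, 12L, 40L))
  got <- classify_somatic(tum, nor, sites, known_positions = 40L)
  status <- vapply(got, `[[`, "", "status")
  expect_identical(status, c("somatic", "germline", "ambiguous",
                             "known_polymorphism"))

  expect_warning(res <- classify_somatic(tum, NULL), "ambiguous")
  expect_true(all(vapply(res, `[[`, "", "status") == "ambiguous"))
})

test_that("a high normal secondary ratio blocks a somatic label", {
  tum <- list(chromadip:::new_variant_call("amp", 10L, "G", "T", "snv",
                                           "het", 40L, "t/+", "+"))
  sites <- data.frame(position = 10L, primary_base = "G",
                      secondary_base = "T", ratio = 0.2, quality = 40L)
  got <- classify_somatic(tum, list(), sites)
  expect_identical(got[[1]]$status, "ambiguous")
})

test_that("tabulated nucleotide changes reproduce their amino-acid effects", {
  cds <- synthetic_atad5_cds()
  tab <- load_mutation_table()
  expect_identical(nrow(tab), 11L)
  for (i in seq_len(nrow(tab))) {
    ch <- chromadip:::parse_c_change(tab$c_change[i])
    ann <- annotate_coding_effect(ch$position, ch$ref, ch$alt, cds)
    expect_identical(ann$aa_change, tab$aa_change[i], info = tab$c_change[i])
    expect_identical(ann$effect, tolower(tab$type[i]), info = tab$c_change[i])
    expect_identical(ann$hgvs_c, tab$c_change[i])
  }
  # spot anchors: R1414X and E723X nonsense, E1460E synonymous
  expect_identical(annotate_coding_effect(4240, "C", "T", cds)$aa_change,
                   "R1414X")
  expect_identical(annotate_coding_effect(2167, "G", "T", cds)$effect,
                   "nonsense")
  expect_identical(annotate_coding_effect(4380, "G", "A", cds)$effect,
                   "synonymous")
  expect_error(annotate_coding_effect(99999, "A", "C", cds), "beyond")
  # frameshift vs in-frame indels
  expect_identical(annotate_coding_effect(10, "AC", "", cds)$effect,
                   "frameshift")
  expect_identical(annotate_coding_effect(10, "ACG", "", cds)$effect,
                   "inframe")
})

test_that("effect classification matches an independent translation oracle", {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  for (codon in codons) {
    for (off in 1:3) {
      refb <- substr(codon, off, off)
      for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
        cds <- paste0(codon, "TAA")
        # skip stop reference codons: not meaningful inside a CDS
        if (seqinr::translate(strsplit(codon, "")[[1]]) == "*") next
        got <- annotate_coding_effect(off, refb, alt, cds)$effect
        expect_identical(got, oracle_codon_effect(codon, off, alt),
                         info = paste(codon, off, alt))
      }
    }
  }
})

test_that("neutral NS:S enumeration matches hand counts and conserves", {
  g <- expected_ns_ratio("GGG")
  expect_identical(c(g$ns, g$s), c(6, 3))
  expect_equal(g$ratio, 2.0)
  m <- expected_ns_ratio("ATG")
  expect_identical(c(m$ns, m$s), c(9, 0))
  expect_true(is.na(m$ratio))
  set.seed(5)
  for (i in 1:5) {
    n_codon <- sample(3:20, 1)
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * n_codon, TRUE),
                 collapse = "")
    r <- expected_ns_ratio(cds)
    stops <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    n_internal <- n_codon - unname(Biostrings::GENETIC_CODE[stops[n_codon]] == "*")
    expect_equal(r$ns + r$s, 9 * n_internal)
    # codon-order permutation invariance
    perm <- sample(seq_len(n_codon))
    cds_p <- paste(stops[perm], collapse = "")
    r_p <- expected_ns_ratio(cds_p)
    has_stop <- any(Biostrings::GENETIC_CODE[stops] == "*")
    if (!has_stop)
      expect_identical(r_p[c("ns", "s")], r[c("ns", "s")])
  }
  expect_error(expected_ns_ratio("GGN"), "non-ACGT")
})

test_that("allelic expression calls depend on both alleles being detected", {
  bi <- data.frame(position = 10L, primary_base = "C", secondary_base = "T",
                   ratio = 0.6, quality = 40L)
  expect_identical(classify_allelic_expression(bi, "C", "T"), "biallelic")
  mono <- data.frame(position = 10L, primary_base = "T",
                     secondary_base = NA_character_, ratio = 0, quality = 40L)
  expect_identical(classify_allelic_expression(mono, "C", "T"), "monoallelic")
  weak <- bi; weak$ratio <- 0.1
  expect_identical(classify_allelic_expression(weak, "C", "T"), "monoallelic")
  lowq <- bi; lowq$quality <- 12L
  expect_identical(classify_allelic_expression(lowq, "C", "T"),
                   "indeterminate")
})

test_that("RT-PCR traces from an equal allele mix read as biallelic", {
  ok <- 0
  for (s in 1:25) {
    set.seed(s)
    ref <- random_seq(40)
    alt <- apply_variant(ref, list(kind = "snv", position = 20,
                                   ref = substr(ref, 20, 20),
                                   alt = other_base(substr(ref, 20, 20))))
    cs <- call_bases(simulate_diploid_trace(ref, alt, sim_config(seed = 40 + s)))
    sites <- site_table(align_to_reference(cs, ref))
    site <- sites[sites$position == 20, ]
    if (classify_allelic_expression(site, substr(ref, 20, 20),
                                    substr(alt, 20, 20)) == "biallelic")
      ok <- ok + 1
  }
  expect_gte(ok / 25, 0.95)
})

test_that("cohort summary reproduces the screen's headline numbers", {
  sm <- summarize_cohort(load_mutation_table())
  expect_identical(sm$n_mutations, 11L)
  expect_identical(sm$n_cases_mutated, 5L)
  expect_identical(sm$n_cases_total, 108L)
  expect_equal(sm$freq_overall, 4.6)
  expect_equal(sm$per_subtype$NEEC$freq, 6.0)
  expect_identical(sm$per_subtype$NEEC$n_cases, 4L)
  expect_equal(sm$per_subtype$EEC$freq, 2.3)
  expect_identical(c(sm$ns_count, sm$s_count), c(10L, 1L))
  expect_equal(sm$ns_s_ratio, 10.0)
  expect_equal(sm$fold_vs_expected, 5.0)
  expect_identical(sm$n_truncating, 2L)
  expect_identical(sm$n_cases_multiple, 2L)
  expect_identical(unname(sm$ref_base_counts["C"] + sm$ref_base_counts["G"]),
                   11L)
  expect_identical(unname(sm$ref_base_counts["A"] + sm$ref_base_counts["T"]),
                   0L)
  # conservation: NS + S = total; subtype case counts sum to overall
  expect_identical(sm$ns_count + sm$s_count, sm$n_mutations)
  expect_identical(sm$per_subtype$NEEC$n_cases + sm$per_subtype$EEC$n_cases,
                   sm$n_cases_mutated)
  p <- subtype_fisher_test(sm)$p.value
  expect_true(p > 0 && p <= 1)
})

test_that("records without subtype are counted overall with a warning", {
  tab <- load_mutation_table()
  tab$subtype[1] <- ""
  expect_warning(sm <- summarize_cohort(tab), "overall only")
  expect_identical(sm$n_mutations, 11L)
})

test_that("simulated tumor/normal screening matches the planted labels", {
  ref <- paste0("ACGTAGCTTGACCAGTTGACCAGGTACGATCGATTACCGG",
                "ATCGATGCATGCATTGCAGCTAGCTTAAGG")
  ob <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  vars <- data.frame(
    sample   = c("P1", "P1", "P2", "P3", "P3", "P4"),
    kind     = c("snv", "snv", "snv", "snv", "snv", "del"),
    position = c(15, 45, 25, 20, 50, 30),
    ref      = c(substr(ref, 15, 15), substr(ref, 45, 45), substr(ref, 25, 25),
                 substr(ref, 20, 20), substr(ref, 50, 50), substr(ref, 30, 31)),
    alt      = c(ob(substr(ref, 15, 15)), ob(substr(ref, 45, 45)),
                 ob(substr(ref, 25, 25)), ob(substr(ref, 20, 20)),
                 ob(substr(ref, 50, 50)), ""),
    zygosity = "het",
    somatic  = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  fx <- make_cohort_fixture(ref, vars, samples = c("P1", "P2", "P3", "P4", "P5"),
                            config = sim_config(seed = 55))
  res <- screen_cohort(fx)
  truth <- fx$truth
  expect_identical(nrow(res), nrow(truth))
  merged <- merge(truth, res, by = c("sample", "position", "ref", "alt"))
  expect_identical(nrow(merged), nrow(truth))
  expect_identical(merged$status,
                   ifelse(merged$somatic, "somatic", "germline"))
})
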