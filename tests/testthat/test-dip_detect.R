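test_that("onset detection: clean traces none, planted deletion near truth", {
  set.seed(31)
  sq <- random_seq(60)
  cs <- call_bases(simulate_allele_trace(sq, sim_config(seed = 31)))
  expect_null(detect_onset(cs))

  set.seed(3)
  ref <- random_seq(70)
  alt <- apply_variant(ref, list(kind = "del", position = 31,
                                 ref = substr(ref, 31, 32), alt = ""))
  cs2 <- call_bases(simulate_diploid_trace(ref, alt, sim_config(seed = 3)))
  expect_true(detect_onset(cs2) %in% c(30L, 31L))
  expect_error(detect_onset(make_called(rep("A", 10))), ">= 20")
})

test_that("sparse random secondaries almost never produce an onset, never a candidate", {
  onsets <- 0
  for (s in 1:20) {
    set.seed(s)
    p <- strsplit(random_seq(70), "")[[1]]
    sec <- ifelse(runif(70) < 0.3, vapply(p, other_base, ""), NA_character_)
    cs <- make_called(p, sec)
    if (!is.null(detect_onset(cs))) onsets <- onsets + 1
    expect_null(detect_het_indel(cs, paste(p, collapse = "")))
  }
  expect_lte(onsets, 1)
})

test_that("hand-built lag-1 superposition scores S(1) = 1", {
  p <- c("A", "C", "G", "T", "A", "C",
         "G", "T", "A", "C", "G", "T", "A", "C", "G", "T", "A", "C", "G",
         "T", "A", "C", "G", "T", "A", "C")
  s <- c(p[-1], NA)
  s[s == p] <- NA
  cs <- make_called(p, s)
  curve <- autocorrelation_curve(cs, onset = 0, K = 5, W = 20)
  expect_equal(unname(curve$scores[1]), 1.0)
  expect_identical(which.max(curve$scores), 1L)
})

test_that("autocorrelation scores stay in [0,1]; homozygous windows are empty", {
  cs <- make_called(strsplit(random_seq(60), "")[[1]])
  curve <- autocorrelation_curve(cs, onset = 10, K = 10, W = 40)
  expect_true(all(is.na(curve$scores)))
  expect_true(all(curve$n_informative == 0))
  for (s in 1:10) {
    set.seed(s)
    p <- strsplit(random_seq(60), "")[[1]]
    sec <- ifelse(runif(60) < 0.5, vapply(p, other_base, ""), NA_character_)
    sc <- autocorrelation_curve(make_called(p, sec), onset = 5, K = 8,
                                W = 40)$scores
    expect_true(all(sc >= 0 & sc <= 1, na.rm = TRUE))
  }
  expect_error(autocorrelation_curve(make_called(strsplit(random_seq(30), "")[[1]]),
                                     onset = 10, K = 10, W = 40),
               "window too short")
})

test_that("random secondary calls rarely reach the candidate threshold", {
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    p <- strsplit(random_seq(70), "")[[1]]
    sec <- ifelse(runif(70) < 0.3, vapply(p, other_base, ""), NA_character_)
    sc <- autocorrelation_curve(make_called(p, sec), onset = 10, K = 10,
                                W = 40)$scores
    if (max(sc, na.rm = TRUE) >= 0.8) hits <- hits + 1
  }
  expect_lte(hits, 1)
})

test_that("deconvolution recovers direction and sequence from planted pairs", {
  alleleA <- "ACGTACGTACGTACGTACGTACGTACGTACGT"
  alleleB <- "ACGTCGTACGTACGTACGTACGTACGTACGT"  # deletion of base 5 ("A")
  set.seed(8)
  cols <- columns_for_pair(alleleA, alleleB)
  cs <- make_called(cols$p, cols$s)
  dec <- deconvolve_alleles(cs, onset = 4, k = 1, reference = alleleA, W = 20)
  expect_identical(dec$direction, "del")
  nv <- left_normalize(dec$ref_position, dec$indel_sequence, "del", alleleA)
  expect_identical(nv$seq, "A")
  expect_identical(left_normalize(5, "A", "del", alleleA)$position, nv$position)
  expect_false(dec$failed)
  expect_gte(dec$consistency, 0.9)

  # insertion mirror: alleleB gains a base, reference is the short allele
  set.seed(9)
  colsi <- columns_for_pair(alleleB, alleleA)
  csi <- make_called(colsi$p, colsi$s)
  deci <- deconvolve_alleles(csi, onset = 4, k = 1, reference = alleleB, W = 20)
  expect_identical(deci$direction, "ins")
  expect_error(deconvolve_alleles(cs, onset = 4, k = 0, reference = alleleA),
               ">= 1")
})

test_that("left normalization shifts through repeat runs and is idempotent", {
  ref <- "CCAAAAGG"
  nv <- left_normalize(7, "A", "del", ref)
  expect_identical(nv$position, 3L)
  expect_identical(nv$seq, "A")
  again <- left_normalize(nv$position, nv$seq, "del", ref)
  expect_identical(again$position, nv$position)
  expect_identical(again$shifted, 0L)
  # already left-aligned stays put
  expect_identical(left_normalize(3, "G", "del", "ATGCA")$position, 3L)
  # idempotence on random indels
  for (i in 1:25) {
    set.seed(i)
    r <- random_seq(40)
    pos <- sample(5:30, 1); k <- sample(1:4, 1)
    kind <- sample(c("del", "ins"), 1)
    sq <- if (kind == "del") substr(r, pos, pos + k - 1) else random_seq(k)
    n1 <- left_normalize(pos, sq, kind, r)
    n2 <- left_normalize(n1$position, n1$seq, kind, r)
    expect_identical(n1[c("position", "seq")], n2[c("position", "seq")])
  }
})

test_that("detector recovers planted sizes and ignores SNV-only traces", {
  hits <- 0; total <- 0
  for (k in c(1, 2, 4, 7, 10)) for (s in 1:4) {
    set.seed(17 * k + s)
    ref <- random_seq(70)
    alt <- apply_variant(ref, list(kind = "del", position = 30,
                                   ref = substr(ref, 30, 29 + k), alt = ""))
    cs <- call_bases(simulate_diploid_trace(ref, alt,
                                            sim_config(seed = 400 + 17 * k + s)))
    cand <- detect_het_indel(cs, ref)
    total <- total + 1
    if (!is.null(cand) && cand$k == k && cand$direction == "del")
      hits <- hits + 1
  }
  expect_gte(hits / total, 0.9)

  for (s in 1:5) {
    set.seed(s)
    ref <- random_seq(70)
    alt <- ref
    for (pp in sample(15:60, 2))
      alt <- apply_variant(alt, list(kind = "snv", position = pp,
                                     ref = substr(alt, pp, pp),
                                     alt = other_base(substr(alt, pp, pp))))
    cs <- call_bases(simulate_diploid_trace(ref, alt, sim_config(seed = 600 + s)))
    expect_null(detect_het_indel(cs, ref))
  }
})

test_that("detector output is invariant under uniform intensity scaling", {
  set.seed(21)
  ref <- random_seq(70)
  alt <- apply_variant(ref, list(kind = "del", position = 30,
                                 ref = substr(ref, 30, 32), alt = ""))
  tr <- simulate_diploid_trace(ref, alt, sim_config(seed = 21))
  tr5 <- tr
  tr5$channels <- lapply(tr$channels, function(x) 5 * x)
  c1 <- detect_het_indel(call_bases(tr), ref)
  c2 <- detect_het_indel(call_bases(tr5), ref)
  expect_identical(c1$k, c2$k)
  expect_identical(c1$direction, c2$direction)
  expect_identical(c1$refined_ref_position, c2$refined_ref_position)
  expect_equal(c1$score, c2$score, tolerance = 1e-6)
})

test_that("homozygous carriers pin the heterozygous indel position", {
  # 2-bp deletion inside a repeat run: hets are ambiguous, the homozygote
  # left-aligns them all to one position
  set.seed(33)
  left <- random_seq(28)
  right <- random_seq(30)
  ref <- paste0(left, "TATATATA", right)   # TA-repeat at 29..36
  del <- substr(ref, 33, 34)
  alt <- apply_variant(ref, list(kind = "del", position = 33, ref = del, alt = ""))
  truth <- left_normalize(33, del, "del", ref)

  het_cands <- list()
  alns <- list()
  for (s in 1:3) {
    cs <- call_bases(simulate_diploid_trace(ref, alt, sim_config(seed = 500 + s)))
    het_cands[[s]] <- detect_het_indel(cs, ref)
    alns[[s]] <- align_to_reference(cs, ref)
  }
  hom_cs <- call_bases(simulate_allele_trace(alt, sim_config(seed = 777)))
  alns[[4]] <- align_to_reference(hom_cs, ref)
  expect_true(all(!vapply(het_cands, is.null, TRUE)))

  refined <- refine_with_homozygotes(het_cands, alns)
  for (cand in refined) {
    expect_identical(cand$refinement_source, "homozygous_carrier")
    expect_identical(cand$refined_ref_position, truth$position)
  }

  # no homozygote: positions untouched
  unrefined <- refine_with_homozygotes(het_cands, alns[1:3])
  for (cand in unrefined)
    expect_identical(cand$refinement_source, "het_deconvolution")

  # homozygote of a different size must not refine
  alt1 <- apply_variant(ref, list(kind = "del", position = 10,
                                  ref = substr(ref, 10, 10), alt = ""))
  hom1 <- align_to_reference(call_bases(simulate_allele_trace(alt1,
    sim_config(seed = 778))), ref)
  mixed <- refine_with_homozygotes(het_cands, c(alns[1:3], list(hom1)))
  for (cand in mixed)
    expect_identical(cand$refinement_source, "het_deconvolution")
})
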