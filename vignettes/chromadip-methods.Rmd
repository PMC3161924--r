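---
title: "Detecting heterozygous indels and somatic point mutations from Sanger traces"
author: "chromadip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting heterozygous indels and somatic point mutations from Sanger traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromadip)
```

## The problem

Capillary (Sanger) resequencing of tumor amplicons reads a *diploid*
template. A heterozygous point variant shows up as two superposed peaks at
one position. A heterozygous insertion or deletion (indel) is worse: from
the breakpoint onward the two alleles are out of register by the indel
size *k*, so every downstream position superposes two different bases and
a naive base caller reports a wall of "degenerate" calls that is easily
mistaken for a failed read. chromadip implements the full screening
pipeline around this signal: base calling with primary and secondary peak
calls, degenerate-region detection, indel sizing by shift
autocorrelation, allele deconvolution, SNV calling with bidirectional
cross-validation, tumor/matched-normal somatic classification, coding
effect annotation, and cohort summary statistics.

## Base calling

`call_bases()` is a deliberately simple Phred-like caller for clean
amplicon traces. Base positions are local maxima of the Gaussian-smoothed
summed signal, at least 0.6 peak spacings apart; the spacing is
re-estimated from the autocovariance of the summed signal around the
metadata hint, which tolerates the ±20% drift the simulator injects. At
each position the strongest channel is the primary call and the
second-strongest becomes a secondary call when it reaches at least
`min_secondary_ratio` (default 0.25, the classic PolyPhred-style
convention) of the primary amplitude and clears the channel noise floor
(a baseline MAD).

Quality is a Phred-scaled score `round(-10 log10 p_err)` with `p_err` the
amplitude ratio of the largest *uncalled* channel peak in a narrow apex
window to the primary, floored at 1e-4 (quality is capped at 40). Two
numerical choices matter here and were tuned on the generative model, not
on any benchmark data:

* the apex window is narrow (spacing/6 ≈ 2 samples) so the Gaussian
  shoulder of a neighbouring peak one spacing away cannot masquerade as an
  uncalled peak;
* an uncalled channel only contributes when it exceeds
  `max(4.5 × channel floor, 0.10 × primary)`. The 4.5 multiplier
  compensates the downward bias of a MAD estimated from zero-clipped
  baseline noise; the 10% relative floor keeps the threshold meaningful at
  heterozygous positions, where the primary amplitude is halved.

These scores are *not* calibrated Phred error probabilities; they are a
monotone cleanliness measure used for gating (SNV calls require quality
≥ 20), and their absolute values should not be compared with real Phred
output.

## Indel detection by shift autocorrelation

`detect_onset()` finds the changepoint where the degenerate region
starts: the smallest call index that itself carries a secondary call,
has secondary density ≥ 0.6 over the next 8 calls and < 0.2 before, and
whose degeneracy is sustained (density ≥ 0.5 over 24 calls). The
sustained condition exists because sparse random secondaries at density
~0.3 produce short dense windows surprisingly often; a genuine
superposition persists for the rest of the read.

`autocorrelation_curve()` scores each candidate shift *k* in `1..K`
(default `K = 10`; Sanger trace quality makes larger shifts academic) by
how well the call columns in a window `W` (default 40) after the onset
match themselves shifted by *k*. The lag-*k* relation of a heterozygous
indel says: one allele's base at position *i* reappears as the other
allele's base at *i + k*. Which observed base (primary or secondary)
belongs to which allele is unobservable — with equal allele dosage the
roles flip essentially at random with the per-peak amplitude noise — so
the score maximizes the number of satisfied lag constraints over the
allele-role assignment, by dynamic programming along the *k* independent
residue chains. The result is in [0, 1], uses only positions where
either compared site has a secondary call (`n_informative`), and is 1.0
for a perfect superposition. A signal-level mode (per-channel Pearson
correlation at lag *k* spacings, rescaled to [0, 1]) is retained as a
cross-check; the call-level mode is the default and the one the
acceptance studies exercise.

`detect_het_indel()` emits a candidate when `S(k*) ≥ theta` (0.8), the
margin over the runner-up is ≥ `delta` (0.15), ties broken towards
smaller *k* (a lag-*k* superposition in a repeat also scores at
multiples of *k*; the smallest consistent shift is the parsimonious
call), and at least 8 informative positions back the score.

## Deconvolution and position refinement

`deconvolve_alleles()` orients the candidate: the reference allele tracks
reference positions from the onset; the deletion hypothesis predicts the
second allele `k` bases ahead, the insertion hypothesis `k` bases behind.
Each hypothesis is scored by the fraction of window positions whose
predicted unordered base pair is contained in the observed
{primary, secondary} set, and the better one fixes the direction (both
below 0.7 flags the deconvolution as failed).

Because chance agreement of the two alleles right after the breakpoint
can delay the detected onset by a few bases, the breakpoint itself is then
re-estimated: every candidate breakpoint within `k + 8` bases is scored by
*set equality* between predicted and observed pairs, and the leftmost
maximizer wins. Set equality (not containment) is essential — a
breakpoint hypothesis that leaves an observed secondary base unexplained
must be penalized. Positions inside repeat runs are inherently ambiguous;
`left_normalize()` then shifts the final call to its leftmost equivalent
position (the VCF convention) and records the shift.

`refine_with_homozygotes()` implements the cohort-level refinement: a
clean homozygous carrier of the same indel shows it as an unambiguous
alignment gap, and every heterozygous candidate of matching kind and size
within `k` plus the repeat-run length is snapped to the homozygote's
left-aligned position.

## SNV calling, cross-validation, somatic classification

`call_het_snvs()` applies the secondary-ratio and quality gates at every
aligned position; positions from two bases before a detected indel onset
onward are suppressed, since superposed columns are unreliable for point
calls. Calls from forward and reverse traces (and overlapping amplicons)
are merged by normalized (position, ref, alt); a call seen on one strand
where another covering trace ran the opposite strand is *flagged*
`single_strand`, not dropped — heterozygous indels can mimic poor-quality
data, so the pipeline follows the sensitivity-first posture and leaves
filtering to configuration. `write_vcf()` emits VCF 4.2 with the standard
anchor-base convention for indels.

`classify_somatic()` mirrors the matched-normal resequencing step: a
known-polymorphism position takes precedence (the list is a plain TSV of
positions, no live database); a variant also called in the normal is
germline; otherwise the normal trace is interrogated at the site and the
variant is somatic only when that site is clean (quality ≥ 20, secondary
ratio < 0.15) — anything less evaluable is ambiguous rather than guessed.

## Coding effects and the neutral NS:S expectation

`annotate_coding_effect()` substitutes and translates the affected codon
(standard genetic code): unchanged amino acid → synonymous, gained stop →
nonsense, otherwise missense; indels of size not divisible by 3 are
frameshift. `expected_ns_ratio()` computes the neutral
nonsynonymous:synonymous expectation by enumerating all nine single-base
substitutions of every internal codon, optionally weighted by a
substitution spectrum; the cohort summary takes a fixed expected ratio
(default 2.0) for its fold statistic, so the headline fold is
reproducible without the full-length human coding sequence. The packaged
CDS (`synthetic_atad5_cds()`) is an explicitly synthetic stand-in — 1600
alanine codons plus a stop, with the eleven codons touched by the
packaged mutation table set so each tabulated nucleotide change produces
its tabulated amino-acid change.

`summarize_cohort()` floors percentages to one decimal. That choice is
deliberate: the tabulated cohort frequencies (4.6% = 5/108, 6.0% = 4/66,
2.3% = 1/42) are only reproducible by truncation toward zero; half-up
rounding would print 6.1 and 2.4. A Fisher's exact comparison of the
subtype frequencies is provided as a utility (`subtype_fisher_test()`)
but is not part of the reproduced statistics, because the construction
behind the originally reported p-value is not derivable from the stated
counts under the standard two-sided convention.

## The synthetic chromatogram generator

`simulate_allele_trace()` renders each base as a Gaussian peak (spacing
12 samples, width 2.5) with log-normal amplitude variation (CV 0.1,
mean 100), mild per-base decay (0.999), position jitter (SD 0.5 samples)
and additive Gaussian baseline noise (SD 2), clipped at zero.
`simulate_diploid_trace()` is the exact equal superposition
`0.5·A + 0.5·B` plus shared noise — the clonal heterozygote of a
macrodissected, high-purity tumor. Deliberately *not* modelled: subclonal
allele fractions, dye blobs, mobility shifts, and polymerase slippage.
Passing tests therefore demonstrate correctness of the inference given
the superposition model, not robustness to every instrument artifact;
real traces with heavy dye artifacts or low tumor purity will be harder
than anything the generator produces. Reverse-strand traces are simulated
as the reverse complement of each allele, so bidirectional
cross-validation is exercised honestly rather than by duplicating the
forward trace.

All randomness flows from one integer seed; composite simulations derive
child seeds (`derive_seed()`) for each allele, the noise stream and each
cohort sample, so any sub-trace can be regenerated in isolation and
identical configurations produce identical bytes on disk.

## Reference study conditions

The test suite and the acceptance script run fixed-size studies chosen as
representative screening workloads: 500 planted heterozygous indels
(sizes 1–10, 50 replicates each, 70-base amplicons, default noise), 100
homozygous/SNV-only negatives, 200 small instances for the exhaustive
(direction, size, breakpoint) oracle comparison, and a 10-pair
tumor/normal cohort for the somatic round trip. Under the default
generator these reproduce size recovery above 95%, zero indel false
positives, full oracle agreement on emitted candidates, and an exact
somatic/germline confusion matrix.

## Known limitations

* One indel per trace: multi-indel superpositions are out of scope, as is
  quantifying allele fractions (TIDE-style decomposition).
* Variants are capped at `K = 10` for indels; larger events are better
  served by assembly or capillary fragment analysis.
* The quality model is a stand-in; gates were chosen for the generative
  model above and should be re-examined before use on instrument data
  with different noise characteristics.
* SCF trace files are not read; ABI `.ab1` support covers the processed
  channel tags (DATA 9–12) only.

## A worked example

```{r example, eval = FALSE}
ref <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
alt <- apply_variant(ref, list(kind = "del", position = 30,
                               ref = substr(ref, 30, 31), alt = ""))
trace <- simulate_diploid_trace(ref, alt, sim_config(seed = 1))
calls <- call_bases(trace)
detect_het_indel(calls, ref)
```
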