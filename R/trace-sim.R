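#' Simulation parameters for synthetic chromatograms
#'
#' Defaults emulate a clean capillary run: 12 samples per base, Gaussian
#' peaks of width 2.5 samples, mean peak amplitude 100 units with 10%
#' log-normal variation, a mild per-base amplitude decay, additive Gaussian
#' baseline noise of 2 units, and 0.5 samples of peak-position jitter.
#'
#' @param peak_spacing samples per base
#' @param peak_sigma Gaussian peak standard deviation, samples
#' @param amp_mean mean peak amplitude, intensity units
#' @param amp_cv coefficient of variation of peak amplitudes
#' @param decay per-base multiplicative amplitude decay
#' @param noise_sd baseline noise standard deviation, intensity units
#' @param spacing_jitter_sd peak position jitter, samples
#' @param seed integer RNG seed
#' @return a list of class `sim_config`
#' @export
sim_config <- function(peak_spacing = 12, peak_sigma = 2.5, amp_mean = 100,
                       amp_cv = 0.1, decay = 0.999, noise_sd = 2.0,
                       spacing_jitter_sd = 0.5, seed = 1L) {
  cfg <- list(peak_spacing = peak_spacing, peak_sigma = peak_sigma,
              amp_mean = amp_mean, amp_cv = amp_cv, decay = decay,
              noise_sd = noise_sd, spacing_jitter_sd = spacing_jitter_sd,
              seed = as.integer(seed))
  pos <- c("peak_spacing", "peak_sigma", "amp_mean", "decay")
  if (any(vapply(cfg[pos], function(x) x <= 0, TRUE)))
    stop("peak_spacing, peak_sigma, amp_mean and decay must be positive",
         call. = FALSE)
  if (cfg$amp_cv < 0 || cfg$noise_sd < 0 || cfg$spacing_jitter_sd < 0)
    stop("amp_cv, noise_sd and spacing_jitter_sd must be >= 0", call. = FALSE)
  if (cfg$peak_sigma >= cfg$peak_spacing / 2)
    stop("peak_sigma must be < peak_spacing / 2", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

cfg_update <- function(cfg, ...) {
  dots <- list(...)
  cfg[names(dots)] <- dots
  do.call(sim_config, unclass(cfg))
}

#' Simulate the chromatogram of a single (haploid) allele
#'
#' Each base j contributes a Gaussian peak of width `peak_sigma` centred at
#' `j * peak_spacing + jitter` in its nucleotide's channel, with amplitude
#' `amp_mean * decay^j` scaled by a unit-mean log-normal draw; Gaussian
#' baseline noise is added to all channels and intensities clamped at zero.
#' Deterministic for a fixed `config$seed`.
#'
#' @param sequence ACGT string, length >= 5
#' @param config a [sim_config()]
#' @param sample_id,amplicon_id,strand labels stored on the result
#' @return a [chromatogram()]
#' @export
simulate_allele_trace <- function(sequence, config = sim_config(),
                                  sample_id = NA_character_,
                                  amplicon_id = NA_character_,
                                  strand = "+") {
  check_acgt(sequence)
  n <- nchar(sequence)
  if (n < 4) stop("sequence must have length >= 4", call. = FALSE)
  seq_ch <- strsplit(sequence, "")[[1]]
  sp <- config$peak_spacing
  total <- ceiling((n + 1.5) * sp)
  with_seed(config$seed, {
    jitter <- rnorm(n, 0, config$spacing_jitter_sd)
    sdlog <- sqrt(log(1 + config$amp_cv^2))
    amps <- config$amp_mean * config$decay^(seq_len(n) - 1) *
      rlnorm(n, -sdlog^2 / 2, sdlog)
    mu <- sp + (seq_len(n) - 1) * sp + jitter
    mat <- matrix(0, nrow = 4, ncol = total, dimnames = list(BASES, NULL))
    half <- ceiling(5 * config$peak_sigma)
    t_all <- seq_len(total) - 1
    for (j in seq_len(n)) {
      lo <- max(1, floor(mu[j]) - half + 1)
      hi <- min(total, ceiling(mu[j]) + half + 1)
      idx <- lo:hi
      mat[seq_ch[j], idx] <- mat[seq_ch[j], idx] +
        amps[j] * exp(-(t_all[idx] - mu[j])^2 / (2 * config$peak_sigma^2))
    }
    if (config$noise_sd > 0)
      mat <- mat + matrix(rnorm(4 * total, 0, config$noise_sd), nrow = 4)
    mat <- pmax(mat, 0)
    chromatogram(list(A = mat["A", ], C = mat["C", ], G = mat["G", ],
                      T = mat["T", ]),
                 peak_spacing_hint = sp, sample_id = sample_id,
                 amplicon_id = amplicon_id, strand = strand)
  })
}

#' Simulate a diploid chromatogram as an equal superposition of two alleles
#'
#' The trace is `0.5 * trace(alleleA) + 0.5 * trace(alleleB)` plus shared
#' baseline noise; the two allele traces are generated noise-free with
#' child seeds `derive_seed(seed, 1)` and `derive_seed(seed, 2)`, and the
#' noise stream uses `derive_seed(seed, 3)`. Alleles of unequal length
#' produce the out-of-register degenerate region downstream of their
#' divergence point that heterozygous indel detection exploits.
#'
#' @param alleleA,alleleB ACGT strings sharing a common prefix of >= 5 bases
#' @param config a [sim_config()]
#' @param sample_id,amplicon_id,strand labels stored on the result
#' @return a [chromatogram()]
#' @export
simulate_diploid_trace <- function(alleleA, alleleB, config = sim_config(),
                                   sample_id = NA_character_,
                                   amplicon_id = NA_character_,
                                   strand = "+") {
  check_acgt(alleleA, "alleleA"); check_acgt(alleleB, "alleleB")
  pref <- 0
  nmin <- min(nchar(alleleA), nchar(alleleB))
  while (pref < nmin &&
         substr(alleleA, pref + 1, pref + 1) == substr(alleleB, pref + 1, pref + 1))
    pref <- pref + 1
  if (pref < 4)
    stop("alleles must share a common prefix of >= 4 bases", call. = FALSE)
  cfg0 <- cfg_update(config, noise_sd = 0)
  trA <- simulate_allele_trace(alleleA, cfg_update(cfg0, seed = derive_seed(config$seed, 1)))
  trB <- simulate_allele_trace(alleleB, cfg_update(cfg0, seed = derive_seed(config$seed, 2)))
  total <- max(length(trA), length(trB))
  pad <- function(x) c(x, rep(0, total - length(x)))
  mat <- vapply(BASES, function(b)
    0.5 * pad(trA$channels[[b]]) + 0.5 * pad(trB$channels[[b]]),
    numeric(total))
  if (config$noise_sd > 0) {
    mat <- mat + with_seed(derive_seed(config$seed, 3),
                           matrix(rnorm(total * 4, 0, config$noise_sd),
                                  ncol = 4))
    mat <- pmax(mat, 0)
  }
  chromatogram(list(A = mat[, "A"], C = mat[, "C"], G = mat[, "G"],
                    T = mat[, "T"]),
               peak_spacing_hint = config$peak_spacing,
               sample_id = sample_id, amplicon_id = amplicon_id,
               strand = strand)
}

#' Apply a planted variant to an allele sequence
#'
#' Variant conventions (1-based, matching the caller's normalized output):
#' SNV substitutes at `position`; deletions remove `ref` starting at
#' `position`; insertions insert `alt` immediately before `position`.
#'
#' @param sequence ACGT reference allele
#' @param variant list or one-row data frame with `kind` (`snv`/`ins`/`del`),
#'   `position`, `ref`, `alt`
#' @return mutated sequence
#' @export
apply_variant <- function(sequence, variant) {
  pos <- as.integer(variant$position)
  kind <- as.character(variant$kind)
  ref <- as.character(variant$ref); alt <- as.character(variant$alt)
  n <- nchar(sequence)
  if (pos < 1 || pos > n + (kind == "ins"))
    stop("variant position ", pos, " outside the amplicon", call. = FALSE)
  if (kind == "snv") {
    if (substr(sequence, pos, pos) != ref)
      stop("reference mismatch at position ", pos, call. = FALSE)
    paste0(substr(sequence, 1, pos - 1), alt, substr(sequence, pos + 1, n))
  } else if (kind == "del") {
    k <- nchar(ref)
    if (pos + k - 1 > n) stop("deletion runs off the amplicon", call. = FALSE)
    if (substr(sequence, pos, pos + k - 1) != ref)
      stop("reference mismatch at position ", pos, call. = FALSE)
    paste0(substr(sequence, 1, pos - 1), substr(sequence, pos + k, n))
  } else if (kind == "ins") {
    paste0(substr(sequence, 1, pos - 1), alt, substr(sequence, pos, n))
  } else stop("unknown variant kind: ", kind, call. = FALSE)
}

#' Build a simulated tumor/matched-normal cohort with a truth table
#'
#' For each sample, tumor and normal diploid traces are simulated on both
#' strands (the reverse-strand trace is the reverse complement of each
#' allele). Somatic variants are planted in the tumor only; germline
#' variants in both tumor and normal. Heterozygous variants go on one
#' allele, homozygous on both. Variants are left-normalized before being
#' written to the truth table so downstream comparison is string equality.
#'
#' @param reference amplicon reference sequence (ACGT)
#' @param variants data frame with columns `sample`, `kind`, `position`,
#'   `ref`, `alt`, `zygosity` (`het`/`hom`), `somatic` (logical); may have
#'   zero rows
#' @param samples character vector of sample ids (defaults to the samples
#'   named in `variants`)
#' @param config a [sim_config()]; per-sample seeds are derived from
#'   `config$seed`
#' @param amplicon_id label for the traces
#' @param outdir optional directory; when given, JSON traces, the reference
#'   FASTA and `truth.tsv` are written there
#' @return list with `samples` (per sample: `tumor` and `normal`, each with
#'   `fwd`/`rev` chromatograms), `truth` (data frame), `reference`, `config`
#' @export
make_cohort_fixture <- function(reference, variants, samples = NULL,
                                config = sim_config(),
                                amplicon_id = "amp1", outdir = NULL) {
  check_acgt(reference, "reference")
  if (is.null(samples))
    samples <- unique(as.character(variants$sample))
  if (nrow(variants) > 0) {
    bad <- variants$position < 1 | variants$position > nchar(reference)
    if (any(bad))
      stop("variant position ", variants$position[which(bad)[1]],
           " outside the amplicon", call. = FALSE)
  }
  truth <- list(); out <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    vs <- variants[as.character(variants$sample) == s, , drop = FALSE]
    mutate <- function(seq, rows) {
      # apply right-to-left so earlier positions stay valid
      if (nrow(rows)) {
        rows <- rows[order(-rows$position), , drop = FALSE]
        for (r in seq_len(nrow(rows))) seq <- apply_variant(seq, rows[r, ])
      }
      seq
    }
    alleles_for <- function(rows) {
      het <- rows[rows$zygosity == "het", , drop = FALSE]
      hom <- rows[rows$zygosity == "hom", , drop = FALSE]
      a1 <- mutate(reference, hom)
      a2 <- mutate(mutate(reference, hom), het)
      list(a1 = a1, a2 = a2)
    }
    tum <- alleles_for(vs)
    nor <- alleles_for(vs[!vs$somatic, , drop = FALSE])
    mk <- function(al, tissue, strand, k) {
      a1 <- al$a1; a2 <- al$a2
      if (strand == "-") { a1 <- revcomp(a1); a2 <- revcomp(a2) }
      simulate_diploid_trace(a1, a2,
        cfg_update(config, seed = derive_seed(config$seed, 10 * si + k)),
        sample_id = paste0(s, "_", tissue), amplicon_id = amplicon_id,
        strand = strand)
    }
    out[[s]] <- list(
      tumor  = list(fwd = mk(tum, "T", "+", 1), rev = mk(tum, "T", "-", 2)),
      normal = list(fwd = mk(nor, "N", "+", 3), rev = mk(nor, "N", "-", 4)))
    if (nrow(vs)) {
      for (r in seq_len(nrow(vs))) {
        v <- vs[r, ]
        nv <- if (v$kind == "snv") {
          list(position = v$position, ref = v$ref, alt = v$alt)
        } else {
          left_normalize(v$position,
                         if (v$kind == "del") v$ref else v$alt,
                         v$kind, reference)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          sample = s, amplicon = amplicon_id,
          position = nv$position %||% v$position,
          ref = if (v$kind == "del") nv$seq else as.character(v$ref),
          alt = if (v$kind == "ins") nv$seq else as.character(v$alt),
          kind = v$kind, zygosity = v$zygosity, somatic = v$somatic,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), amplicon = character(),
               position = integer(), ref = character(), alt = character(),
               kind = character(), zygosity = character(),
               somatic = logical(), stringsAsFactors = FALSE)
  fixture <- list(samples = out, truth = truth, reference = reference,
                  config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(out)) for (tissue in c("tumor", "normal"))
      for (str in c("fwd", "rev"))
        write_trace_json(out[[s]][[tissue]][[str]],
                         file.path(outdir, sprintf("%s_%s_%s.json", s, tissue, str)))
    write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(c(paste0(">", amplicon_id), reference),
               file.path(outdir, "reference.fasta"))
  }
  fixture
}
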