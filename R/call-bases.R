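gauss_smooth <- function(x, sigma = 1.5) {
  half <- ceiling(3 * sigma)
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  y <- stats::filter(x, k, sides = 2)
  y[is.na(y)] <- x[is.na(y)]
  as.numeric(y)
}

# Re-estimate peak spacing from the autocovariance of the summed signal;
# falls back to the hint when no clear periodicity is found.
estimate_spacing <- function(total_sm, hint) {
  lags <- floor(0.7 * hint):ceiling(1.3 * hint)
  lags <- lags[lags >= 2 & lags < length(total_sm) / 2]
  if (!length(lags)) return(hint)
  x <- total_sm - mean(total_sm)
  ac <- vapply(lags, function(l) {
    n <- length(x) - l
    sum(x[1:n] * x[(l + 1):(l + n)]) / n
  }, 1)
  if (max(ac) <= 0) return(hint)
  lags[which.max(ac)]
}

# MAD noise floor of one channel, estimated from its baseline (samples at
# or below the channel median, which is baseline-dominated at typical
# peak densities).
channel_noise_floor <- function(ch) {
  base <- ch[ch <= median(ch)]
  if (!length(base)) return(0)
  mad(base, center = median(base))
}

find_apexes <- function(total_sm, spacing, min_sep = NULL, thr = NULL) {
  n <- length(total_sm)
  cand <- which(diff(sign(diff(total_sm))) < 0) + 1L
  if (!is.null(thr)) cand <- cand[total_sm[cand] >= thr]
  if (!length(cand)) return(integer())
  min_sep <- min_sep %||% max(2, round(0.6 * spacing))
  keep <- logical(length(cand))
  ord <- order(total_sm[cand], decreasing = TRUE)
  taken <- integer()
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= min_sep)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  sort(cand[keep])
}

#' Call bases with primary and secondary peaks from a chromatogram
#'
#' A simplified Phred-style caller. Base positions are the local maxima of
#' the Gaussian-smoothed summed signal, separated by at least 0.6 of the
#' estimated peak spacing (re-estimated from the signal's autocovariance
#' around the metadata hint). At each position the strongest channel is the
#' primary call; the second-strongest is reported as a secondary call when
#' its amplitude is at least `min_secondary_ratio` of the primary and at
#' least `noise_k` channel noise floors (baseline MAD). Quality is
#' `round(-10 log10 p_err)` with `p_err` the amplitude ratio of the largest
#' uncalled channel peak in the base window to the primary (floored at
#' 1e-4, so quality is capped at 40); uncalled channels whose window
#' maximum does not rise above the apex evidence threshold contribute
#' nothing.
#'
#' @param chrom a [chromatogram()]
#' @param min_secondary_ratio secondary/primary amplitude threshold
#' @param noise_k multiple of the channel noise floor a peak must exceed
#' @return object of class `called_sequence`: list with `calls` (data frame
#'   with 0-based `base_index`, 0-based `trace_position`, `primary_base`,
#'   `secondary_base`, amplitudes, `ratio`, `quality`), `primary_string`,
#'   and `source` labels
#' @export
call_bases <- function(chrom, min_secondary_ratio = 0.25, noise_k = 3.0) {
  stopifnot(inherits(chrom, "chromatogram"))
  sm <- lapply(chrom$channels, gauss_smooth)
  total <- sm$A + sm$C + sm$G + sm$T
  floor_tot <- channel_noise_floor(total)
  if (max(total) <= 0 || quantile(total, 0.99) < noise_k * floor_tot)
    stop("no callable bases: trace is flat", call. = FALSE)
  spacing <- estimate_spacing(total, chrom$peak_spacing_hint)
  floors <- vapply(sm, channel_noise_floor, 1)
  thr <- max(noise_k * floor_tot, 0.05 * quantile(total, 0.99))
  apex <- find_apexes(total, spacing, thr = thr)
  if (!length(apex)) stop("no callable bases: trace is flat", call. = FALSE)
  # narrow apex window: wide enough for jitter, too narrow for the
  # shoulders of neighbouring peaks one spacing away
  wq <- max(2L, round(spacing / 6))
  n <- length(apex)
  smm <- rbind(A = sm$A, C = sm$C, G = sm$G, T = sm$T)
  calls <- data.frame(base_index = seq_len(n) - 1L,
                      trace_position = apex - 1L,
                      primary_base = NA_character_,
                      secondary_base = NA_character_,
                      primary_amp = NA_real_, secondary_amp = NA_real_,
                      ratio = NA_real_, quality = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    lo <- max(1, apex[i] - wq); hi <- min(ncol(smm), apex[i] + wq)
    amps <- apply(smm[, lo:hi, drop = FALSE], 1, max)
    ord <- order(amps, decreasing = TRUE)
    prim <- BASES[ord[1]]; pamp <- amps[ord[1]]
    samp <- amps[ord[2]]
    # apex evidence threshold for uncalled channels: clear of the smoothed
    # noise ceiling (zero-clipped noise biases the MAD floor low, hence the
    # 4.5 multiplier) and at least 10% of the primary amplitude
    evid <- pmax(4.5 * floors, 0.10 * pamp)
    sec_ok <- samp >= min_secondary_ratio * pamp && samp >= noise_k * floors[ord[2]]
    qlo <- max(1, apex[i] - wq); qhi <- min(ncol(smm), apex[i] + wq)
    amps_q <- apply(smm[, qlo:qhi, drop = FALSE], 1, max)
    rest <- if (sec_ok) amps_q[ord[3:4]] else amps_q[ord[2:4]]
    rest_thr <- if (sec_ok) evid[ord[3:4]] else evid[ord[2:4]]
    rest <- rest[rest >= rest_thr]
    p_err <- max(1e-4, if (length(rest)) max(rest) / pamp else 0)
    calls$primary_base[i] <- prim
    calls$primary_amp[i] <- pamp
    if (sec_ok) {
      calls$secondary_base[i] <- BASES[ord[2]]
      calls$secondary_amp[i] <- samp
      calls$ratio[i] <- samp / pamp
    }
    calls$quality[i] <- min(40L, as.integer(round(-10 * log10(p_err))))
  }
  structure(list(calls = calls,
                 primary_string = paste(calls$primary_base, collapse = ""),
                 source = list(sample_id = chrom$sample_id,
                               amplicon_id = chrom$amplicon_id,
                               strand = chrom$strand,
                               spacing = spacing)),
            class = "called_sequence")
}

#' @export
print.called_sequence <- function(x, ...) {
  cat(sprintf("<called_sequence> %d bases (%d with secondary calls)\n",
              nrow(x$calls), sum(!is.na(x$calls$secondary_base))))
  cat(" ", substr(x$primary_string, 1, 60),
      if (nchar(x$primary_string) > 60) "..." else "", "\n")
  invisible(x)
}
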