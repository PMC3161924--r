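#' Construct a chromatogram object
#'
#' A chromatogram holds the four per-nucleotide fluorescence intensity
#' series of one capillary sequencing read, plus the expected peak spacing
#' and identifying labels. Sample indices are 0-based; intensities are in
#' arbitrary fluorescence units and must be non-negative.
#'
#' @param channels named list with elements `A`, `C`, `G`, `T`, each a
#'   numeric vector of equal length
#' @param peak_spacing_hint expected samples per base (> 0)
#' @param sample_id,amplicon_id free-text labels
#' @param strand `"+"` or `"-"`
#' @return an object of class `chromatogram`
#' @export
chromatogram <- function(channels, peak_spacing_hint,
                         sample_id = NA_character_,
                         amplicon_id = NA_character_,
                         strand = "+") {
  miss <- setdiff(BASES, names(channels))
  if (length(miss))
    stop("missing channel ", miss[1], call. = FALSE)
  channels <- lapply(channels[BASES], as.numeric)
  lens <- vapply(channels, length, 1L)
  if (length(unique(lens)) != 1)
    stop("channels must have equal length", call. = FALSE)
  if (any(vapply(channels, function(x) any(x < 0 | !is.finite(x)), TRUE)))
    stop("intensities must be finite and >= 0", call. = FALSE)
  if (!is.numeric(peak_spacing_hint) || peak_spacing_hint <= 0)
    stop("peak_spacing_hint must be > 0", call. = FALSE)
  if (lens[1] < 2 * peak_spacing_hint)
    stop("trace shorter than two peak spacings", call. = FALSE)
  structure(list(channels = channels,
                 peak_spacing_hint = as.numeric(peak_spacing_hint),
                 sample_id = sample_id,
                 amplicon_id = amplicon_id,
                 strand = match.arg(strand, c("+", "-"))),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s / %s (%s), %d samples, spacing hint %.1f\n",
              x$sample_id, x$amplicon_id, x$strand,
              length(x$channels$A), x$peak_spacing_hint))
  invisible(x)
}

#' @export
length.chromatogram <- function(x) length(x$channels$A)

#' Read a chromatogram from file
#'
#' Supported formats: the package's JSON trace dialect (keys
#' `channels.{A,C,G,T}`, `peak_spacing_hint`, `sample_id`, `amplicon_id`,
#' `strand`) and ABI `.ab1` (ABIF tags `DATA` 9-12 with `FWO_` channel
#' order). SCF is recognised but not implemented and raises an error.
#'
#' @param path file path
#' @param format one of `"json"`, `"abi"`, `"scf"`
#' @return a [chromatogram()]
#' @export
read_trace <- function(path, format = c("json", "abi", "scf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         json = read_trace_json(path),
         abi  = read_trace_abif(path),
         scf  = stop("SCF reading is not implemented; convert to the JSON ",
                     "trace dialect or ABI .ab1", call. = FALSE))
}

read_trace_json <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                error = function(e)
                  stop("parse error in ", path, ": ", conditionMessage(e),
                       call. = FALSE))
  if (is.null(x$channels))
    stop("parse error in ", path, ": missing key 'channels'", call. = FALSE)
  miss <- setdiff(BASES, names(x$channels))
  if (length(miss))
    stop("missing channel ", miss[1], call. = FALSE)
  chromatogram(x$channels,
               peak_spacing_hint = x$peak_spacing_hint %||% 12,
               sample_id = x$sample_id %||% NA_character_,
               amplicon_id = x$amplicon_id %||% NA_character_,
               strand = x$strand %||% "+")
}

#' Write a chromatogram in the JSON trace dialect
#'
#' @param chrom a [chromatogram()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trace_json <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  obj <- list(channels = lapply(chrom$channels, function(x) round(x, 4)),
              peak_spacing_hint = chrom$peak_spacing_hint,
              sample_id = chrom$sample_id,
              amplicon_id = chrom$amplicon_id,
              strand = chrom$strand)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## --- minimal ABIF (.ab1) support ------------------------------------------
## ABIF layout: 4-byte magic "ABIF", int16 version, then a 28-byte root
## directory entry whose dataoffset points at `numelements` further 28-byte
## entries. Processed trace channels live in DATA tags 9-12 (int16 arrays),
## channel order in FWO_ tag 1 (4 chars).

read_abif_entry <- function(con) {
  name <- rawToChar(readBin(con, "raw", 4))
  number <- readBin(con, "integer", 1, 4, endian = "big")
  etype <- readBin(con, "integer", 1, 2, endian = "big")
  esize <- readBin(con, "integer", 1, 2, endian = "big")
  nelem <- readBin(con, "integer", 1, 4, endian = "big")
  dsize <- readBin(con, "integer", 1, 4, endian = "big")
  doff_raw <- readBin(con, "raw", 4)
  readBin(con, "raw", 4)  # datahandle, unused
  list(name = name, number = number, etype = etype, esize = esize,
       nelem = nelem, dsize = dsize, doff_raw = doff_raw,
       doff = sum(as.integer(doff_raw) * c(2^24, 2^16, 2^8, 1)))
}

read_trace_abif <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "ABIF"))
    stop("parse error in ", path, " at byte offset 0: magic is not 'ABIF'",
         call. = FALSE)
  readBin(con, "integer", 1, 2, endian = "big")  # version
  root <- read_abif_entry(con)
  if (root$nelem < 1 || root$doff <= 0)
    stop("parse error in ", path, ": empty ABIF directory", call. = FALSE)
  seek(con, root$doff)
  entries <- lapply(seq_len(root$nelem), function(i) read_abif_entry(con))
  get_entry <- function(name, number)
    Filter(function(e) e$name == name && e$number == number, entries)
  read_payload <- function(e) {
    if (e$dsize <= 4) return(e$doff_raw[seq_len(e$dsize)])
    seek(con, e$doff)
    readBin(con, "raw", e$dsize)
  }
  fwo <- get_entry("FWO_", 1)
  order <- if (length(fwo)) {
    strsplit(rawToChar(read_payload(fwo[[1]])[1:4]), "")[[1]]
  } else c("G", "A", "T", "C")
  channels <- list()
  for (i in 1:4) {
    e <- get_entry("DATA", 8L + i)
    if (!length(e))
      stop("parse error in ", path, ": missing tag DATA ", 8 + i,
           call. = FALSE)
    raw <- read_payload(e[[1]])
    vals <- readBin(raw, "integer", n = e[[1]]$nelem, size = 2,
                    signed = TRUE, endian = "big")
    channels[[order[i]]] <- pmax(0, as.numeric(vals))
  }
  spac <- get_entry("SPAC", 1)
  hint <- if (length(spac)) {
    readBin(read_payload(spac[[1]]), "numeric", 1, size = 4, endian = "big")
  } else 12
  chromatogram(channels, peak_spacing_hint = hint,
               sample_id = sub("\\.ab1$", "", basename(path)))
}

# Internal ABIF writer (round-trip testing of the reader only).
write_trace_abif <- function(chrom, path, order = c("G", "A", "T", "C")) {
  stopifnot(inherits(chrom, "chromatogram"))
  n <- length(chrom)
  payloads <- list()
  dirent <- function(name, number, etype, esize, nelem, payload) {
    list(name = name, number = number, etype = etype, esize = esize,
         nelem = nelem, payload = payload)
  }
  ents <- list(dirent("FWO_", 1L, 2L, 1L, 4L, charToRaw(paste(order, collapse = ""))))
  for (i in 1:4) {
    vals <- as.integer(round(pmin(32767, chrom$channels[[order[i]]])))
    ents[[length(ents) + 1L]] <-
      dirent("DATA", 8L + i, 4L, 2L,  n,
             writeBin(vals, raw(), size = 2, endian = "big"))
  }
  ents[[length(ents) + 1L]] <-
    dirent("SPAC", 1L, 7L, 4L, 1L,
           writeBin(chrom$peak_spacing_hint, raw(), size = 4, endian = "big"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("ABIF"), con)
  writeBin(101L, con, size = 2, endian = "big")
  # data payloads start after header (6) + root entry (28) + 2 pad
  data_start <- 6 + 28 + 2
  offs <- integer(length(ents))
  off <- data_start
  for (i in seq_along(ents)) {
    offs[i] <- off
    if (length(ents[[i]]$payload) > 4) off <- off + length(ents[[i]]$payload)
  }
  dir_off <- off
  write_entry <- function(name, number, etype, esize, nelem, dsize, doff_field) {
    writeBin(charToRaw(name), con)
    writeBin(as.integer(number), con, size = 4, endian = "big")
    writeBin(as.integer(etype), con, size = 2, endian = "big")
    writeBin(as.integer(esize), con, size = 2, endian = "big")
    writeBin(as.integer(nelem), con, size = 4, endian = "big")
    writeBin(as.integer(dsize), con, size = 4, endian = "big")
    writeBin(doff_field, con)
    writeBin(raw(4), con)
  }
  int_be <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")
  write_entry("tdir", 1L, 18L, 28L, length(ents), 28L * length(ents),
              int_be(dir_off))
  writeBin(raw(2), con)
  for (e in ents) if (length(e$payload) > 4) writeBin(e$payload, con)
  for (i in seq_along(ents)) {
    e <- ents[[i]]
    dsize <- e$nelem * e$esize
    doff_field <- if (length(e$payload) > 4) int_be(offs[i]) else {
      p <- e$payload
      c(p, raw(4 - length(p)))
    }
    write_entry(e$name, e$number, e$etype, e$esize, e$nelem, dsize, doff_field)
  }
  invisible(path)
}
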