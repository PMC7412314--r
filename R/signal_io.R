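#' ECG record container
#'
#' Bundles a single-lead amplitude series (millivolts) with its sampling
#' frequency.  Millivolts are the canonical amplitude scale of the whole
#' pipeline; all threshold constants are interpreted on this scale.
#'
#' @param samples Numeric vector of amplitudes in mV, length >= 2, all finite.
#' @param fs Sampling frequency in Hz (> 0).
#' @param record_id Text label for the record.
#' @param lead Optional lead label.
#' @return An object of class `ecg_record` with fields `samples`, `fs`,
#'   `record_id`, `lead`.
#' @export
ecg_record <- function(samples, fs, record_id = "record", lead = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("an ECG record needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs),
         record_id = as.character(record_id)[1L],
         lead = if (is.null(lead)) NULL else as.character(lead)[1L]),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'%s: %d samples @ %g Hz (%.1f s)>\n",
              x$record_id,
              if (is.null(x$lead)) "" else paste0(" lead ", x$lead),
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Beat annotation container
#'
#' Beat positions as 0-based sample indices (matching the on-disk plain-text
#' format and the WFDB convention), strictly increasing.
#'
#' @param indices Integer-like vector of 0-based sample positions, strictly
#'   increasing.
#' @param labels Optional character vector of per-beat symbols (same length).
#' @param record_length Optional record length used to validate the upper
#'   bound on indices.
#' @return An object of class `beat_annotations` with fields `indices`,
#'   `labels`.
#' @export
beat_annotations <- function(indices, labels = NULL, record_length = NULL) {
  indices <- as.numeric(indices)
  if (anyNA(indices)) stop("beat indices must not be NA", call. = FALSE)
  if (length(indices) && any(indices < 0))
    stop("beat indices must be >= 0", call. = FALSE)
  if (length(indices) > 1L && any(diff(indices) <= 0))
    stop("beat indices must be strictly increasing", call. = FALSE)
  if (!is.null(record_length) && length(indices) &&
      any(indices >= record_length))
    stop("beat indices must lie within [0, record length)", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(indices))
      stop("`labels` must match `indices` in length", call. = FALSE)
  }
  structure(list(indices = indices, labels = labels),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations: %d beats>\n", length(x$indices)))
  invisible(x)
}

#' @export
length.beat_annotations <- function(x) length(x$indices)

#' Read an ECG record from disk
#'
#' Supports the WFDB `.hea`/`.dat` pair (signal formats 212, 16 and 80) and a
#' simple two-column CSV (`sample_index,millivolts`; header optional; `fs`
#' supplied out of band).  WFDB samples are converted to millivolts as
#' `(adu - baseline) / gain`.
#'
#' @param path For WFDB, the record path with or without the `.hea` extension;
#'   for CSV, the file path.
#' @param format `"wfdb"` or `"csv"`.
#' @param channel 1-based signal channel to extract (WFDB only).
#' @param fs Sampling frequency in Hz; required for CSV, ignored for WFDB.
#' @param record_id Optional record label; defaults to the file stem.
#' @return An [ecg_record].
#' @export
read_record <- function(path, format = c("wfdb", "csv"), channel = 1L,
                        fs = NULL, record_id = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(fs)) stop("CSV records require an explicit `fs`", call. = FALSE)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    first <- readLines(path, n = 1L)
    has_header <- !grepl("^\\s*[-+0-9.]", first)
    tab <- utils::read.csv(path, header = has_header,
                           col.names = c("index", "mv"))
    ecg_record(tab$mv, fs = fs,
               record_id = record_id %||% sub("\\.[^.]*$", "", basename(path)))
  } else {
    rec <- read_wfdb_signal(path, channel = channel)
    ecg_record(rec$mv, fs = rec$fs,
               record_id = record_id %||% rec$name, lead = rec$lead)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ECG record as CSV
#'
#' Two columns, `index,mv`, with a header; `index` is the 0-based sample
#' position.  [read_record] inverts it (given the same `fs`).
#'
#' @param record An [ecg_record].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  df <- data.frame(index = seq_along(record$samples) - 1L,
                   mv = record$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read beat annotations
#'
#' Plain-text format: one 0-based sample index per line, optionally followed
#' by a tab and a label.  WFDB format: the MIT annotation file (`.atr` etc.);
#' only beat-class annotations are retained (non-beat symbols such as rhythm
#' changes and artifacts are dropped).
#'
#' @param path Annotation file path.
#' @param format `"text"` or `"wfdb"`.
#' @param record_length Optional bound used to validate indices.
#' @return A [beat_annotations].
#' @export
read_annotations <- function(path, format = c("text", "wfdb"),
                             record_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "text") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
      return(beat_annotations(numeric(0)))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    idx <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    if (anyNA(idx))
      stop("malformed annotation line(s) in ", path, call. = FALSE)
    labs <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_, "")
    if (all(is.na(labs))) labs <- NULL
    if (length(idx) > 1L && any(diff(idx) <= 0))
      stop("annotation indices must be strictly increasing", call. = FALSE)
    beat_annotations(idx, labels = labs, record_length = record_length)
  } else {
    read_wfdb_annotations(path, record_length = record_length)
  }
}

#' Write beat annotations as plain text
#'
#' One 0-based index per line; if labels are present, `index<TAB>label`.
#' [read_annotations] inverts it.
#'
#' @param ann A [beat_annotations].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "beat_annotations"))
  lines <- if (is.null(ann$labels)) {
    format(ann$indices, scientific = FALSE, trim = TRUE)
  } else {
    paste(format(ann$indices, scientific = FALSE, trim = TRUE),
          ann$labels, sep = "\t")
  }
  writeLines(as.character(lines), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# WFDB readers (hand-written: no WFDB package exists in the supported stack).
# Formats 212 (two 12-bit two's-complement samples per 3 bytes), 16
# (little-endian int16) and 80 (offset-128 uint8) cover the MIT-BIH records.

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header: ", hea_path, call. = FALSE)
  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(rec) < 3L)
    stop("malformed WFDB record line in ", hea_path, call. = FALSE)
  name <- rec[[1L]]
  nsig <- as.integer(rec[[2L]])
  fs <- as.numeric(sub("/.*$", "", rec[[3L]]))   # strip counter frequency
  if (is.na(nsig) || is.na(fs))
    stop("malformed WFDB record line in ", hea_path, call. = FALSE)
  nsamp <- if (length(rec) >= 4L) as.integer(rec[[4L]]) else NA_integer_
  if (length(lines) < 1L + nsig)
    stop("WFDB header declares ", nsig, " signals but has too few lines",
         call. = FALSE)
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 2L) stop("malformed WFDB signal line", call. = FALSE)
    fmt <- as.integer(sub("x.*$|:.*$|\\+.*$", "", f[[2L]]))
    gain_field <- if (length(f) >= 3L) f[[3L]] else "200"
    gain <- as.numeric(sub("\\(.*$|/.*$", "", gain_field))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else NA_real_
    adc_zero <- if (length(f) >= 6L) suppressWarnings(as.numeric(f[[6L]])) else NA_real_
    if (is.na(baseline)) baseline <- if (!is.na(adc_zero)) adc_zero else 0
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else NA_character_
    list(file = f[[1L]], fmt = fmt, gain = gain, baseline = baseline,
         desc = desc)
  })
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_wfdb_signal <- function(path, channel = 1L) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path))
    stop("WFDB header not found: ", hea_path, call. = FALSE)
  hdr <- parse_wfdb_header(hea_path)
  if (channel < 1L || channel > hdr$nsig)
    stop("channel ", channel, " out of range (record has ", hdr$nsig,
         " signals)", call. = FALSE)
  sig <- hdr$signals[[channel]]
  fmt <- sig$fmt
  same_file <- vapply(hdr$signals, function(s) s$file == sig$file, TRUE)
  lanes <- sum(same_file)                   # signals multiplexed in this .dat
  lane <- sum(same_file[seq_len(channel)])  # our position among them
  dat_path <- file.path(dirname(hea_path), sig$file)
  if (!file.exists(dat_path))
    stop("WFDB signal file not found: ", dat_path, call. = FALSE)
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  adus <- switch(as.character(fmt),
    "212" = decode_fmt212(raw),
    "16"  = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
      v
    },
    "80"  = as.integer(raw) - 128L,
    stop("unsupported WFDB signal format: ", fmt, call. = FALSE))
  # de-multiplex round-robin frames
  keep <- seq.int(lane, length(adus), by = lanes)
  adus <- adus[keep]
  if (!is.na(hdr$nsamp) && hdr$nsamp > 0L) adus <- adus[seq_len(min(length(adus), hdr$nsamp))]
  mv <- (adus - sig$baseline) / sig$gain
  list(mv = mv, fs = hdr$fs, name = hdr$name, lead = sig$desc)
}

# Two 12-bit two's-complement samples packed into 3 bytes.
decode_fmt212 <- function(raw) {
  n3 <- length(raw) %/% 3L
  if (n3 == 0L) return(integer(0))
  b <- as.integer(raw[seq_len(3L * n3)])
  b1 <- b[seq(1L, by = 3L, length.out = n3)]
  b2 <- b[seq(2L, by = 3L, length.out = n3)]
  b3 <- b[seq(3L, by = 3L, length.out = n3)]
  s1 <- b1 + bitwAnd(b2, 0x0FL) * 256L
  s2 <- b3 + bitwAnd(bitwShiftR(b2, 4L), 0x0FL) * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

#' Write a single-channel WFDB record (format 16)
#'
#' Minimal writer used mainly to build round-trip fixtures in tests: quantizes
#' millivolt samples with the given gain, writes `<record>.dat` (little-endian
#' int16) and `<record>.hea`.
#'
#' @param record An [ecg_record].
#' @param dir Output directory.
#' @param gain ADC gain in adu/mV.
#' @param baseline ADC value corresponding to 0 mV.
#' @return The header path, invisibly.
#' @export
write_record_wfdb <- function(record, dir, gain = 200, baseline = 0) {
  stopifnot(inherits(record, "ecg_record"))
  name <- record$record_id
  adus <- as.integer(round(record$samples * gain + baseline))
  if (any(adus < -32768L | adus > 32767L))
    stop("samples overflow int16 at this gain", call. = FALSE)
  dat <- paste0(name, ".dat")
  writeBin(adus, file.path(dir, dat), size = 2L, endian = "little")
  hea <- c(
    sprintf("%s 1 %g %d", name, record$fs, length(record$samples)),
    sprintf("%s 16 %g(%d) 16 %d %d 0 0 %s", dat, gain, as.integer(baseline),
            as.integer(baseline), adus[1L], record$lead %||% "MLII"))
  hea_path <- file.path(dir, paste0(name, ".hea"))
  writeLines(hea, hea_path)
  invisible(hea_path)
}

# MIT annotation codes considered beats (NORMAL..UNKNOWN, BBB, escapes, PFUS)
WFDB_BEAT_CODES <- c(1:13, 25L, 34L, 35L, 38L)

read_wfdb_annotations <- function(path, record_length = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  n <- length(raw) %/% 2L
  b <- as.integer(raw)
  i <- 1L  # byte cursor (1-based)
  t <- 0
  idx <- numeric(0)
  codes <- integer(0)
  while (i + 1L <= 2L * n) {
    lo <- b[i]; hi <- b[i + 1L]
    i <- i + 2L
    a <- lo + hi * 256L
    code <- bitwShiftR(a, 10L)
    delta <- bitwAnd(a, 0x3FFL)
    if (code == 0L && delta == 0L) break          # EOF
    if (code == 59L) {                            # SKIP: 4-byte interval next
      if (i + 3L > length(b)) break
      interval <- b[i + 2L] + b[i + 3L] * 256L +
        b[i] * 65536L + b[i + 1L] * 16777216L
      if (interval > 2^31) interval <- interval - 2^32
      t <- t + interval
      i <- i + 4L
    } else if (code == 63L) {                     # AUX: skip payload (+ pad)
      skip <- delta + (delta %% 2L)
      i <- i + skip
    } else if (code %in% c(60L, 61L, 62L)) {      # NUM/SUB/CHN: no time
      next
    } else {
      t <- t + delta
      idx <- c(idx, t)
      codes <- c(codes, code)
    }
  }
  keep <- codes %in% WFDB_BEAT_CODES
  labs <- wfdb_code_symbol(codes[keep])
  beat_annotations(idx[keep], labels = labs, record_length = record_length)
}

wfdb_code_symbol <- function(codes) {
  sym <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/", "Q")
  out <- rep("Q", length(codes))
  small <- codes >= 1L & codes <= 13L
  out[small] <- sym[codes[small]]
  out[codes == 25L] <- "B"
  out[codes == 34L] <- "e"
  out[codes == 35L] <- "n"
  out[codes == 38L] <- "f"
  out
}
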