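# Corpus input/output: mono WAV audio, TIMIT-style phone label files, level
# equalization and fricative token extraction.

#' Construct an utterance
#'
#' An utterance is a mono full-scale waveform with an identifier and a
#' sampling rate.
#'
#' @param id character identifier.
#' @param samples numeric vector in `[-1, 1]` (full scale), finite, non-empty.
#' @param fs sampling rate in Hz.
#' @return an object of class `utterance`.
#' @export
utterance <- function(id, samples, fs) {
  stopifnot(is.character(id), length(id) == 1)
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("utterance must contain at least one sample")
  if (!all(is.finite(samples))) stop("utterance samples must be finite")
  if (!(is.numeric(fs) && length(fs) == 1 && fs > 0)) stop("fs must be positive")
  structure(list(id = id, samples = samples, fs = fs), class = "utterance")
}

#' @export
print.utterance <- function(x, ...) {
  cat(sprintf("<utterance '%s': %d samples @ %g Hz (%.3f s)>\n",
              x$id, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read a mono WAV file
#'
#' Supports uncompressed PCM (8/16/24/32-bit integer) and IEEE float32 mono
#' WAV. Samples are returned full-scale in `[-1, 1]`.
#'
#' @param path file path.
#' @param id utterance id; defaults to the file name without extension.
#' @return an [utterance()].
#' @export
read_wav <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "raw", size)
    } else if (identical(tag, "data")) {
      data <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt/data chunk in ", path)
  u16 <- function(r, off) sum(as.integer(r[off + 1:2]) * c(1, 256))
  u32 <- function(r, off) sum(as.double(r[off + 1:4]) * 256^(0:3))
  audio_format <- u16(fmt, 0)
  n_channels <- u16(fmt, 2)
  fs <- u32(fmt, 4)
  bits <- u16(fmt, 14)
  if (n_channels != 1) stop("only mono WAV is supported (got ", n_channels, " channels)")
  if (audio_format == 1) {
    if (bits == 8) {
      x <- (as.integer(data) - 128) / 128
    } else if (bits %in% c(16, 32)) {
      x <- readBin(data, "integer", length(data) %/% (bits / 8), bits / 8,
                   signed = TRUE, endian = "little") / 2^(bits - 1)
    } else if (bits == 24) {
      n <- length(data) %/% 3
      m <- matrix(as.integer(data[1:(3 * n)]), nrow = 3)
      v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
      v <- ifelse(v >= 2^23, v - 2^24, v)
      x <- v / 2^23
    } else stop("unsupported PCM bit depth: ", bits)
  } else if (audio_format == 3 && bits == 32) {
    x <- readBin(data, "double", length(data) %/% 4, 4, endian = "little")
  } else {
    stop("unsupported WAV format code ", audio_format, " / ", bits, " bits")
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  utterance(id, x, fs)
}

#' Write a mono WAV file
#'
#' @param u an [utterance()].
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(u, path, bits = 16) {
  stopifnot(inherits(u, "utterance"), bits %in% c(16, 32))
  x <- u$samples
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(u$fs), con, 4, endian = "little")
  writeBin(as.integer(u$fs * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.double(x), con, 4, endian = "little")
  }
  invisible(path)
}

#' Read TIMIT-style phone labels
#'
#' Parses a `.phn` dialect label file: one segment per line,
#' `start_sample end_sample label`, 0-based, end-exclusive, in samples.
#'
#' @param path file path.
#' @return data.frame with integer columns `start`, `end` and character
#'   `label`, in file order.
#' @export
read_phone_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  out <- data.frame(start = integer(0), end = integer(0), label = character(0))
  for (i in keep) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed label line %d in %s: fewer than 3 fields", i, path))
    }
    start <- suppressWarnings(as.integer(fields[1]))
    end <- suppressWarnings(as.integer(fields[2]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("malformed label line %d in %s: non-integer boundary", i, path))
    }
    if (!(start >= 0 && end > start)) {
      stop(sprintf("invalid segment on line %d in %s: need 0 <= start < end", i, path))
    }
    out <- rbind(out, data.frame(start = start, end = end, label = fields[3]))
  }
  out
}

#' Write TIMIT-style phone labels
#'
#' @param segs data.frame with `start`, `end`, `label` (as returned by
#'   [read_phone_labels()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phone_labels <- function(segs, path) {
  stopifnot(all(c("start", "end", "label") %in% names(segs)))
  writeLines(sprintf("%d %d %s", segs$start, segs$end, segs$label), path)
  invisible(path)
}

#' Mapping from phone labels to place-of-articulation groups
#'
#' The eight obstruent fricatives map onto three groups: labiodental and
#' interdental are merged as non-sibilant. Both ARPAbet (`th`, `dh`, `sh`,
#' `zh`) and IPA spellings are accepted. The glottal /h/ is deliberately
#' absent.
#'
#' @return named character vector: names are phone labels, values group names.
#' @export
fricative_group_map <- function() {
  c(f = "NONSIB", th = "NONSIB", v = "NONSIB", dh = "NONSIB",
    s = "ALV", z = "ALV", sh = "PAL", zh = "PAL",
    "θ" = "NONSIB", "ð" = "NONSIB",
    "ʃ" = "PAL", "ʒ" = "PAL", "З" = "PAL")
}

#' Equalize an utterance to a target RMS level
#'
#' Rescales the waveform (a scalar multiple, shape preserved) so that its RMS
#' equals `target_rms`.
#'
#' @param u an [utterance()].
#' @param target_rms target RMS amplitude, full scale (default 0.05).
#' @return the rescaled [utterance()].
#' @export
rms_equalize <- function(u, target_rms = 0.05) {
  stopifnot(inherits(u, "utterance"), target_rms > 0)
  r <- rms(u$samples)
  if (r == 0) stop("cannot RMS-equalize an all-zero signal")
  utterance(u$id, u$samples * (target_rms / r), u$fs)
}

#' Construct a phone token
#'
#' A labeled fricative segment: the waveform excised from an utterance plus
#' its phone label, group and provenance.
#'
#' @param utterance_id source utterance id.
#' @param phone phone label.
#' @param group one of `FRIC_GROUPS`.
#' @param samples numeric waveform.
#' @param fs sampling rate Hz.
#' @param start,end source sample span (0-based, end-exclusive).
#' @return object of class `phone_token`.
#' @export
phone_token <- function(utterance_id, phone, group, samples, fs,
                        start = NA_integer_, end = NA_integer_) {
  group <- match.arg(group, FRIC_GROUPS)
  structure(list(utterance_id = utterance_id, phone = phone, group = group,
                 samples = as.numeric(samples), fs = fs,
                 start = start, end = end),
            class = "phone_token")
}

#' @export
print.phone_token <- function(x, ...) {
  cat(sprintf("<phone_token /%s/ (%s) from '%s': %d samples @ %g Hz>\n",
              x$phone, x$group, x$utterance_id, length(x$samples), x$fs))
  invisible(x)
}

#' Extract labeled fricative tokens from an utterance
#'
#' Segments whose label maps to a fricative group are excised verbatim;
#' all other labels (vowels, stops, /h/, silence, ...) are skipped.
#'
#' @param u an [utterance()].
#' @param segs segment data.frame from [read_phone_labels()].
#' @param phone_map named mapping from phone label to group; defaults to
#'   [fricative_group_map()].
#' @return list of [phone_token()] objects (possibly empty).
#' @export
extract_fricative_tokens <- function(u, segs, phone_map = fricative_group_map()) {
  stopifnot(inherits(u, "utterance"))
  n <- length(u$samples)
  tokens <- list()
  for (i in seq_len(nrow(segs))) {
    lab <- segs$label[i]
    if (!lab %in% names(phone_map)) next
    if (segs$end[i] > n) {
      stop(sprintf("segment %d (%d..%d) exceeds signal length %d",
                   i, segs$start[i], segs$end[i], n))
    }
    tokens[[length(tokens) + 1]] <- phone_token(
      u$id, lab, phone_map[[lab]],
      u$samples[(segs$start[i] + 1):segs$end[i]], u$fs,
      start = segs$start[i], end = segs$end[i])
  }
  tokens
}

#' Write a token manifest as CSV
#'
#' @param tokens list of [phone_token()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_token_manifest <- function(tokens, path) {
  df <- do.call(rbind, lapply(tokens, function(t) {
    data.frame(utterance_id = t$utterance_id, phone = t$phone, group = t$group,
               start = t$start, end = t$end, fs = t$fs,
               n_samples = length(t$samples))
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
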