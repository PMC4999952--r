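# Core domain types and waveform / feature-table I/O.
#
# Internal time unit is SECONDS throughout the package (several published
# tables label variability statistics "ms" while printing second-scale
# values; see the methods vignette).

#' The 14 feature names in canonical order
#'
#' Eleven HRV parameters (time domain, spectral, Poincare) followed by the
#' three respiration-period parameters.
#'
#' @return character vector of length 14.
#' @export
feature_names <- function() {
  c("mean_nn", "sdnn", "rmssd", "pnn50",
    "vlf", "lf", "hf", "lf_hf",
    "sd1", "sd2", "sd1_sd2",
    "rpdm", "rpdsd", "rpdv")
}

#' Construct a waveform record
#'
#' A uniformly sampled physiological signal: lead-II ECG (mV) or a respiration
#' trace (arbitrary units).
#'
#' @param samples numeric vector of sample values.
#' @param fs sampling rate in Hz (> 0).
#' @param channel `"ECG_II"` or `"RESP"`.
#' @param t0 window start time in seconds (default 0).
#' @return object of class `waveform_record`.
#' @export
waveform_record <- function(samples, fs, channel = c("ECG_II", "RESP"),
                            t0 = 0) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty signal")
  if (!is.finite(fs) || fs <= 0) stop("sampling rate must be positive")
  structure(list(samples = samples, fs = fs, channel = channel, t0 = t0),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %s: %d samples @ %g Hz (%.2f s)\n",
              x$channel, length(x$samples), x$fs, record_duration(x)))
  invisible(x)
}

#' Duration of a waveform record
#'
#' @param rec a [waveform_record()].
#' @return duration in seconds (`length(samples) / fs`).
#' @export
record_duration <- function(rec) length(rec$samples) / rec$fs

#' Bundle an ECG/respiration pair with its group label
#'
#' @param ecg ECG [waveform_record()] (channel `"ECG_II"`).
#' @param resp respiration [waveform_record()] (channel `"RESP"`).
#' @param label `+1` for the pre-VT group, `-1` for control.
#' @param source_id free-text record identifier.
#' @return object of class `labeled_window`.
#' @export
labeled_window <- function(ecg, resp, label, source_id = "") {
  stopifnot(inherits(ecg, "waveform_record"), inherits(resp, "waveform_record"))
  if (ecg$channel != "ECG_II") stop("ecg channel must be ECG_II")
  if (resp$channel != "RESP") stop("resp channel must be RESP")
  if (!label %in% c(1, -1)) stop("label must be +1 (VT) or -1 (control)")
  structure(list(ecg = ecg, resp = resp, label = label,
                 source_id = source_id),
            class = "labeled_window")
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write waveform records to CSV
#'
#' One column per channel; the first line carries `fs=<Hz>` (and `t0=`)
#' metadata, the second the channel names.  Values are written with 17
#' significant digits so the CSV round-trip is bit exact.
#'
#' @param records a `waveform_record` or list of them (equal `fs` and length).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(records, path) {
  if (inherits(records, "waveform_record")) records <- list(records)
  fs <- unique(vapply(records, function(r) r$fs, 0))
  t0 <- unique(vapply(records, function(r) r$t0, 0))
  if (length(fs) != 1 || length(t0) != 1)
    stop("all channels in one file must share fs and t0")
  ns <- unique(vapply(records, function(r) length(r$samples), 0L))
  if (length(ns) != 1) stop("all channels must have equal length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%s,t0=%s", fmt_full(fs), fmt_full(t0)), con)
  writeLines(paste(vapply(records, function(r) r$channel, ""), collapse = ","),
             con)
  mat <- vapply(records, function(r) fmt_full(r$samples), character(ns))
  writeLines(apply(matrix(mat, nrow = ns), 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read waveform records
#'
#' @param path input file (for `"wfdb"`, the `.hea` header file).
#' @param format `"csv"` (native format of [write_record()]), `"edf"`
#'   (16-bit EDF), or `"wfdb"` (header plus format-16 signal file).
#' @return named list of [waveform_record()] objects, one per channel.
#' @export
read_record <- function(path, format = c("csv", "edf", "wfdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         csv = read_record_csv(path),
         edf = read_record_edf(path),
         wfdb = read_record_wfdb(path))
}

parse_channel <- function(label) {
  if (grepl("resp", label, ignore.case = TRUE)) "RESP" else "ECG_II"
}

read_record_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  if (length(hdr) < 2) stop("empty signal")
  meta <- strsplit(hdr[1], ",")[[1]]
  kv <- strsplit(meta, "=")
  keys <- vapply(kv, `[`, "", 1)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
  if (!"fs" %in% keys || !is.finite(vals[keys == "fs"]))
    stop("missing sampling rate (expected 'fs=<Hz>' metadata line)")
  fs <- vals[keys == "fs"]
  t0 <- if ("t0" %in% keys) vals[keys == "t0"] else 0
  channels <- strsplit(hdr[2], ",")[[1]]
  dat <- utils::read.csv(path, skip = 1, header = TRUE,
                         colClasses = "numeric", check.names = FALSE)
  if (nrow(dat) == 0) stop("empty signal")
  out <- lapply(seq_along(channels), function(i)
    waveform_record(dat[[i]], fs, parse_channel(channels[i]), t0))
  names(out) <- channels
  out
}

# --- EDF (16-bit) ----------------------------------------------------------

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' @rdname read_record
#' @details The EDF reader handles standard 16-bit EDF: a 256-byte fixed
#'   header, per-signal header blocks, and little-endian integer data records
#'   scaled to physical units by the declared calibration.
read_record_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 8 + 80 + 80 + 8 + 8)          # version, ids, dates
  readBin(con, "raw", 8)                             # header bytes
  readBin(con, "raw", 44)                            # reserved
  ndr <- as.integer(read_ascii(con, 8))
  dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header")
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), "")
  readBin(con, "raw", 80 * ns)                       # transducer
  readBin(con, "raw", 8 * ns)                        # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  readBin(con, "raw", 80 * ns)                       # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8)), 0L)
  readBin(con, "raw", 32 * ns)                       # reserved
  sig <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      sig[[i]] <- c(sig[[i]], d)
    }
  }
  out <- lapply(seq_len(ns), function(i) {
    scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    phys <- (sig[[i]] - dmin[i]) * scale + pmin[i]
    if (length(phys) == 0) stop("empty signal")
    waveform_record(phys, spr[i] / dur, parse_channel(labels[i]))
  })
  names(out) <- labels
  out
}

# Minimal EDF writer (16-bit), provided so EDF reading can be exercised
# without binary fixtures; digitization quantizes to the int16 grid.
write_record_edf <- function(records, path, record_dur = 1) {
  if (inherits(records, "waveform_record")) records <- list(records)
  ns <- length(records)
  spr <- vapply(records, function(r) r$fs * record_dur, 0)
  if (any(abs(spr - round(spr)) > 1e-9))
    stop("fs * record_dur must be an integer for EDF export")
  spr <- as.integer(round(spr))
  ndr <- max(vapply(records, function(r)
    ceiling(length(r$samples) / (r$fs * record_dur)), 0))
  pad <- function(s, n) formatC(substr(s, 1, n), width = -n)
  con <- file(path, "wb")
  on.exit(close(con))
  hdrlen <- 256 + 256 * ns
  writeChar(paste0(pad("0", 8), pad("local patient", 80),
                   pad("local recording", 80), pad("01.01.26", 8),
                   pad("00.00.00", 8), pad(as.character(hdrlen), 8),
                   pad("", 44), pad(as.character(ndr), 8),
                   pad(fmt_full(record_dur), 8), pad(as.character(ns), 4)),
            con, eos = NULL)
  pmin <- vapply(records, function(r) min(r$samples), 0)
  pmax <- vapply(records, function(r) max(r$samples), 0)
  pmax <- ifelse(pmax > pmin, pmax, pmin + 1)
  dmin <- rep(-32768, ns); dmax <- rep(32767, ns)
  wfield <- function(vals, n) writeChar(paste(vapply(vals, pad, "", n),
                                              collapse = ""), con, eos = NULL)
  wfield(vapply(records, function(r) r$channel, ""), 16)
  wfield(rep("", ns), 80)
  wfield(rep("mV", ns), 8)
  wfield(fmt_full(pmin), 8)
  wfield(fmt_full(pmax), 8)
  wfield(as.character(dmin), 8)
  wfield(as.character(dmax), 8)
  wfield(rep("", ns), 80)
  wfield(as.character(spr), 8)
  wfield(rep("", ns), 32)
  for (r in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      a <- (r - 1) * spr[i] + 1
      seg <- records[[i]]$samples[a:min(a + spr[i] - 1,
                                        length(records[[i]]$samples))]
      seg <- c(seg, rep(0, spr[i] - length(seg)))
      dig <- round((seg - pmin[i]) / (pmax[i] - pmin[i]) *
                     (dmax[i] - dmin[i]) + dmin[i])
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# --- WFDB-style (.hea + format-16 .dat) ------------------------------------

#' @rdname read_record
#' @details The WFDB-style reader parses a `.hea` header (record line:
#'   name, channel count, fs, sample count; one line per signal naming the
#'   signal file, format 16, gain/baseline and description) and decodes the
#'   interleaved little-endian 16-bit signal file as
#'   `(adc - baseline) / gain`.
read_record_wfdb <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  ns <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  if (!is.finite(fs) || fs <= 0) stop("missing sampling rate in header")
  siglines <- lines[1 + seq_len(ns)]
  parse_sig <- function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (f[2] != "16") stop("only format 16 signal files are supported")
    gainspec <- f[3]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gainspec)))
    baseline <- if (grepl("\\(", gainspec))
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gainspec)) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], gain = gain, baseline = baseline, desc = desc)
  }
  sigs <- lapply(siglines, parse_sig)
  datfile <- unique(vapply(sigs, `[[`, "", "file"))
  if (length(datfile) != 1) stop("multi-file WFDB records are not supported")
  datpath <- file.path(dirname(path), datfile)
  if (!file.exists(datpath)) stop("signal file not found: ", datpath)
  raw <- readBin(datpath, "integer", file.size(datpath) / 2, size = 2,
                 endian = "little")
  if (length(raw) == 0) stop("empty signal")
  mat <- matrix(raw, nrow = ns)
  out <- lapply(seq_len(ns), function(i) {
    desc <- if (nzchar(sigs[[i]]$desc)) sigs[[i]]$desc else "ECG"
    waveform_record((mat[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain, fs,
                    parse_channel(desc))
  })
  names(out) <- vapply(sigs, function(s) s$desc, "")
  out
}

# Minimal WFDB-style writer (format 16), for exercising the reader.
write_record_wfdb <- function(records, path, gain = 1000) {
  if (inherits(records, "waveform_record")) records <- list(records)
  ns <- length(records)
  fs <- unique(vapply(records, function(r) r$fs, 0))
  if (length(fs) != 1) stop("all channels must share fs")
  base <- sub("\\.hea$", "", basename(path))
  datfile <- paste0(base, ".dat")
  n <- length(records[[1]]$samples)
  hdr <- c(sprintf("%s %d %s %d", base, ns, fmt_full(fs), n),
           vapply(records, function(r)
             sprintf("%s 16 %d(0)/mV 16 0 0 0 0 %s", datfile, gain, r$channel),
             ""))
  writeLines(hdr, path)
  mat <- vapply(records, function(r) round(r$samples * gain), numeric(n))
  con <- file(file.path(dirname(path), datfile), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(mat)), con, size = 2, endian = "little")
  invisible(path)
}

# --- feature tables --------------------------------------------------------

#' Write a feature table
#'
#' CSV with columns `source_id`, the 14 parameters in the canonical
#' [feature_names()] order, and `label`; values carry 17 significant digits so
#' read-back reproduces them exactly.
#'
#' @param features data.frame with at least `source_id`, the feature columns
#'   and `label`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (nrow(features) == 0) stop("empty feature table")
  cols <- c("source_id", feature_names(), "label")
  missing <- setdiff(cols, names(features))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  for (i in seq_len(nrow(features))) {
    vals <- vapply(feature_names(), function(f) fmt_full(features[[f]][i]), "")
    writeLines(paste(c(features$source_id[i], vals,
                       as.character(features$label[i])), collapse = ","), con)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path input file path.
#' @return data.frame with `source_id`, feature columns, `label`.
#' @export
read_feature_table <- function(path) {
  dat <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = c(source_id = "character"))
  expected <- c("source_id", feature_names(), "label")
  if (!identical(names(dat), expected))
    stop("not a feature table (unexpected columns)")
  dat$label <- as.numeric(dat$label)
  dat
}
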