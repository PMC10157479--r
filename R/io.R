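#' Read a waveform record
#'
#' Reads a single-lead ECG waveform (plus an optional compression-reference
#' channel) from either a plain CSV file or a WFDB-compatible record.
#'
#' The CSV dialect is a header row, comma separator and `.` decimal, with a
#' `t` column in seconds and an `ecg_mv` column in millivolts; an optional
#' `cc_onset` 0/1 column marks compression onsets. WFDB records are the
#' classic `.hea`/`.dat` layout restricted to format 16 (16-bit little-endian
#' integers); a channel named `cc_onset` is interpreted as the onset pulse
#' train of the compression reference.
#'
#' @param path Path to the `.csv` file or to the WFDB record (with or without
#'   the `.hea` extension).
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @param role Role tag to attach to the returned segment.
#' @return A list with elements `segment` (an [ecg_segment]) and `reference`
#'   (a [compression_reference] or `NULL`).
#' @seealso [write_record()]
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"),
                        role = "UNKNOWN") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format,
         csv = read_record_csv(path, role),
         wfdb = read_record_wfdb(path, role))
}

#' Write a waveform record
#'
#' Inverse of [read_record()]. When a [compression_reference] is supplied it
#' is stored as an additional `cc_onset` channel holding a unit pulse at each
#' onset sample.
#'
#' @param segment An [ecg_segment].
#' @param path Output path (`.csv` decides the CSV dialect, anything else is
#'   written as a WFDB record; the `.hea` suffix is added if missing).
#' @param reference Optional [compression_reference].
#' @param format `"auto"`, `"csv"` or `"wfdb"`.
#' @param gain WFDB integer conversion gain in adu/mV (default 1000, i.e.
#'   1 microvolt resolution).
#' @return `path`, invisibly.
#' @export
write_record <- function(segment, path, reference = NULL,
                         format = c("auto", "csv", "wfdb"), gain = 1000) {
  stopifnot(is_ecg_segment(segment))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") {
    df <- as_tibble.ecg_segment(segment)
    if (!is.null(reference)) {
      df$cc_onset <- 0L
      idx <- onset_sample_index(reference, segment)
      df$cc_onset[idx] <- 1L
    }
    readr::write_csv(df, path)
  } else {
    write_record_wfdb(segment, path, reference, gain)
  }
  invisible(path)
}

onset_sample_index <- function(reference, segment) {
  idx <- round((reference$onset_times - segment$t0) * segment$fs) + 1L
  idx[idx >= 1L & idx <= length(segment$samples)]
}

read_record_csv <- function(path, role) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read record: file not found: %s", path),
         call. = FALSE)
  }
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed CSV %s: first problem at row %d (%s)",
                 path, probs$row[1], probs$expected[1]), call. = FALSE)
  }
  if (!all(c("t", "ecg_mv") %in% names(df))) {
    stop(sprintf("CSV %s must have columns 't' and 'ecg_mv'", path),
         call. = FALSE)
  }
  if (nrow(df) < 2) stop(sprintf("CSV %s has fewer than 2 rows", path),
                         call. = FALSE)
  for (col in intersect(c("t", "ecg_mv", "cc_onset"), names(df))) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad) > 0) {
      stop(sprintf("malformed CSV %s: non-numeric value in column '%s' at row %d",
                   path, col, bad[1]), call. = FALSE)
    }
    df[[col]] <- num
  }
  fs <- 1 / stats::median(diff(df$t))
  seg <- ecg_segment(df$ecg_mv, fs = round(fs, 6), role = role,
                     t0 = df$t[1])
  ref <- NULL
  if ("cc_onset" %in% names(df) && sum(df$cc_onset > 0) >= 2) {
    ref <- compression_reference(df$t[df$cc_onset > 0], fs = seg$fs)
  }
  list(segment = seg, reference = ref)
}

# --- minimal WFDB (format 16) support ---------------------------------------
# Header: "<record> <nsig> <fs> <nsamp>" then one line per signal:
# "<file> 16 <gain>(<baseline>)/mV 16 0 <first> <chk> 0 <name>".
# Samples are interleaved int16 little-endian in the .dat file.

read_record_wfdb <- function(path, role) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    stop(sprintf("cannot read record: file not found: %s", hea),
         call. = FALSE)
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4) stop(sprintf("malformed WFDB header: %s", hea),
                            call. = FALSE)
  nsig <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  nsamp <- as.integer(rec[4])
  sig <- lines[2:(1 + nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_spec <- f[3]
    baseline <- 0
    gain <- suppressWarnings(as.numeric(sub("\\(.*", "", gain_spec)))
    if (grepl("\\(", gain_spec)) {
      baseline <- as.numeric(sub(".*\\((-?[0-9.]+)\\).*", "\\1", gain_spec))
    }
    if (!is.finite(gain) || gain == 0) gain <- 200
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         name = if (length(f) >= 9) f[length(f)] else paste0("sig", seq_len(1)))
  }
  sigs <- lapply(sig, parse_sig)
  if (any(vapply(sigs, function(s) s$format, "") != "16")) {
    stop("only WFDB format 16 is supported", call. = FALSE)
  }
  dat <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(dat)) {
    stop(sprintf("cannot read record: file not found: %s", dat),
         call. = FALSE)
  }
  raw <- readBin(dat, what = "integer", size = 2, signed = TRUE,
                 n = nsig * nsamp, endian = "little")
  if (length(raw) < nsig * nsamp) {
    stop(sprintf("corrupt WFDB data file %s: expected %d samples, got %d",
                 dat, nsig * nsamp, length(raw)), call. = FALSE)
  }
  m <- matrix(raw, nrow = nsig)
  names_ <- vapply(sigs, function(s) s$name, "")
  ecg_i <- if ("ecg" %in% names_) which(names_ == "ecg")[1] else 1L
  ecg <- (m[ecg_i, ] - sigs[[ecg_i]]$baseline) / sigs[[ecg_i]]$gain
  seg <- ecg_segment(ecg, fs = fs, role = role)
  ref <- NULL
  cc_i <- which(names_ == "cc_onset")
  if (length(cc_i) == 1) {
    pulse <- m[cc_i, ]
    idx <- which(pulse > 0)
    if (length(idx) >= 2) {
      ref <- compression_reference((idx - 1) / fs, fs = fs)
    }
  }
  list(segment = seg, reference = ref)
}

write_record_wfdb <- function(segment, path, reference, gain) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  base <- sub("\\.hea$", "", basename(hea))
  dat_name <- paste0(base, ".dat")
  dat <- file.path(dirname(hea), dat_name)
  x <- round(segment$samples * gain)
  if (any(abs(x) > 32767)) {
    stop("waveform exceeds int16 range at this gain; lower `gain`",
         call. = FALSE)
  }
  chans <- list(ecg = as.integer(x))
  if (!is.null(reference)) {
    pulse <- integer(length(segment$samples))
    pulse[onset_sample_index(reference, segment)] <- 1L
    chans$cc_onset <- pulse
  }
  nsig <- length(chans)
  nsamp <- length(segment$samples)
  m <- do.call(rbind, chans)
  hdr <- c(
    sprintf("%s %d %g %d", base, nsig, segment$fs, nsamp),
    vapply(seq_len(nsig), function(i) {
      g <- if (names(chans)[i] == "ecg") gain else 1
      sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 %s", dat_name, g, m[i, 1],
              names(chans)[i])
    }, "")
  )
  writeLines(hdr, hea)
  writeBin(as.integer(as.vector(m)), dat, size = 2, endian = "little")
  invisible(hea)
}
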