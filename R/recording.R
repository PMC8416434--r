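#' Construct a multichannel EEG recording
#'
#' A recording is a channels-by-samples matrix in microvolts with a sampling
#' rate and montage. Rows are always stored in montage order.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate in samples per second.
#' @param subject_id Opaque subject identifier.
#' @param montage A [qeeg_montage()]; defaults to the 19-channel 10-20 set.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, subject_id = "subject",
                          montage = default_montage()) {
  data <- as.matrix(data)
  if (nrow(data) != length(montage)) {
    qeeg_abort(
      sprintf("data has %d rows but montage has %d channels",
              nrow(data), length(montage)),
      "qeeg_error_validation"
    )
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    qeeg_abort("rate must be a single positive number", "qeeg_error_validation")
  }
  if (!all(is.finite(data))) {
    qeeg_abort("all samples must be finite", "qeeg_error_validation")
  }
  rownames(data) <- as.character(montage)
  structure(
    list(subject_id = as.character(subject_id), data = data,
         rate = rate, montage = montage, accepted = NULL),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id, ": ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$rate, " Hz (",
      round(recording_duration(x), 1), " s)\n", sep = "")
  if (!is.null(x$accepted)) {
    cat("  artifact screening: ", sum(x$accepted), "/", length(x$accepted),
        " 2-s epochs accepted\n", sep = "")
  }
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec An `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$rate

#' Read a recording from disk
#'
#' Two formats are supported. The package's own CSV dialect stores one row
#' per channel (first column the label, remaining columns the samples) with
#' `# key=value` comment-header lines carrying `rate` and `subject_id`.
#' EDF/EDF+ files are read through a minimal reader for the standard
#' 16-bit EDF encoding (read-only convenience; continuous recordings only).
#' In either case channel labels are matched onto the 19-channel montage
#' case-insensitively, legacy T3/T4/T5/T6 names are accepted, extra
#' channels beyond the montage are dropped for 64-channel files, and rows
#' are reordered to montage order.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`; guessed from the extension by default.
#' @param montage Target montage.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path, format = c("auto", "csv", "edf"),
                           montage = default_montage()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    qeeg_abort(paste0("file not found: ", path), "qeeg_error_validation")
  }
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  raw <- switch(format,
    csv = read_recording_csv(path),
    edf = read_edf(path)
  )
  canon <- normalize_channel_labels(raw$labels, montage)
  keep <- !is.na(canon)
  # extra channels are tolerated (64-channel files are subset by label);
  # all montage channels must be present
  missing <- setdiff(as.character(montage), canon[keep])
  if (length(missing) > 0) {
    qeeg_abort(
      paste0("channel mismatch: missing ", paste(missing, collapse = ", ")),
      "qeeg_error_channel_mismatch", missing = missing
    )
  }
  dup <- canon[keep][duplicated(canon[keep])]
  if (length(dup) > 0) {
    qeeg_abort(
      paste0("channel mismatch: duplicated ", paste(unique(dup), collapse = ", ")),
      "qeeg_error_channel_mismatch", duplicated = unique(dup)
    )
  }
  data <- raw$data[keep, , drop = FALSE][match(as.character(montage), canon[keep]), ,
                                         drop = FALSE]
  eeg_recording(data, rate = raw$rate, subject_id = raw$subject_id,
                montage = montage)
}

read_recording_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) qeeg_abort("no channel rows in CSV", "qeeg_error_parse")
  parts <- strsplit(body, ",", fixed = TRUE)
  labels <- vapply(parts, function(p) trimws(p[1]), character(1))
  n_samp <- unique(lengths(parts)) - 1
  if (length(n_samp) != 1) {
    qeeg_abort("channel rows have differing sample counts", "qeeg_error_parse")
  }
  data <- matrix(NA_real_, length(parts), n_samp)
  for (r in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[r]][-1]))
    if (anyNA(v)) {
      qeeg_abort(paste0("non-numeric samples in channel row ", labels[r]),
                 "qeeg_error_parse")
    }
    data[r, ] <- v
  }
  rate <- suppressWarnings(as.numeric(meta$rate %||% NA))
  if (!is.finite(rate)) {
    qeeg_abort("CSV header must carry '# rate=<samples/s>'", "qeeg_error_parse")
  }
  list(labels = labels, data = data, rate = rate,
       subject_id = meta$subject_id %||% basename(path))
}

#' Write a recording in the package CSV dialect
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# rate=", format(rec$rate, digits = 15)),
    paste0("# subject_id=", rec$subject_id)
  ), con)
  rows <- vapply(seq_len(nrow(rec$data)), function(r) {
    paste(c(rownames(rec$data)[r],
            format(rec$data[r, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = ",")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

# Minimal EDF reader: 256-byte fixed header, per-signal header blocks, then
# data records of 16-bit little-endian integers scaled channel-wise from
# digital to physical units. Annotation channels are dropped.
read_edf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd_num <- function(n) suppressWarnings(as.numeric(rd_str(n)))
  version <- rd_str(8)
  if (!identical(version, "0")) {
    qeeg_abort("not an EDF file (bad version field)", "qeeg_error_parse")
  }
  subject_id <- rd_str(80)
  rd_str(80)            # recording id
  rd_str(8); rd_str(8)  # start date, time
  rd_num(8)             # header length
  rd_str(44)            # reserved
  n_records <- rd_num(8)
  record_dur <- rd_num(8)
  ns <- rd_num(4)
  if (!is.finite(ns) || ns < 1) qeeg_abort("bad EDF signal count", "qeeg_error_parse")
  fld <- function(w) vapply(seq_len(ns), function(i) rd_str(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)                       # transducer, physical dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8));  dig_max <- as.numeric(fld(8))
  fld(80)                               # prefiltering
  n_samp <- as.numeric(fld(8))
  fld(32)                               # reserved
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  out <- vector("list", ns)
  for (i in which(keep)) out[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = n_samp[i], size = 2,
                   signed = TRUE, endian = "little")
      if (keep[i]) out[[i]][[r]] <- v
    }
  }
  sig_rate <- n_samp / record_dur
  rate <- unique(sig_rate[keep])
  if (length(rate) != 1) {
    qeeg_abort("EDF signals have mixed sampling rates", "qeeg_error_parse")
  }
  data <- do.call(rbind, lapply(which(keep), function(i) {
    gain[i] * unlist(out[[i]]) + offset[i]
  }))
  # strip common "EEG Fp1-REF" style decorations down to the site name
  lab <- labels[keep]
  lab <- sub("^EEG\\s*", "", lab, ignore.case = TRUE)
  lab <- sub("[-_].*$", "", lab)
  list(labels = lab, data = data, rate = rate,
       subject_id = if (nzchar(subject_id)) subject_id else basename(path))
}
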