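# Recording input/output: CSV matrix + JSON sidecar, and a minimal EDF/BDF
# reader (the environment provides no EEG file reader in R or python, so the
# simple fixed-layout EDF header is parsed directly).

#' Read a recording from a matrix file with a JSON sidecar
#'
#' The matrix file is CSV (channels in rows, no header) and the sidecar is a
#' JSON object with at least `fs` and `channel_names`, optionally `label`,
#' `subject_id`, `trial_id`.
#'
#' @param matrix_path CSV path.
#' @param sidecar_path JSON path; defaults to `matrix_path` with a `.json`
#'   extension.
#' @return An [eeg_recording()].
#' @export
read_recording_csv <- function(matrix_path,
                               sidecar_path = sub("\\.[^.]+$", ".json",
                                                  matrix_path)) {
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$fs) || is.null(side$channel_names))
    stop("sidecar must contain fs and channel_names")
  x <- as.matrix(utils::read.csv(matrix_path, header = FALSE))
  eeg_recording(x, side$fs, side$channel_names,
                subject_id = side$subject_id %||% NA_character_,
                trial_id = side$trial_id %||% NA_character_,
                label = side$label %||% NA_character_)
}

#' @rdname read_recording_csv
#' @param rec an [eeg_recording()].
#' @export
write_recording_csv <- function(rec, matrix_path,
                                sidecar_path = sub("\\.[^.]+$", ".json",
                                                   matrix_path)) {
  utils::write.table(rec$data, matrix_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channel_names = rec$channel_names,
                            subject_id = rec$subject_id,
                            trial_id = rec$trial_id, label = rec$label),
                       sidecar_path, auto_unbox = TRUE, null = "null",
                       na = "null")
  invisible(matrix_path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

trim <- function(s) sub("\\s+$", "", sub("^\\s+", "", s))

#' Read an EDF or BDF file
#'
#' Minimal reader for continuous European Data Format recordings: standard
#' 256-byte header, per-signal headers, 16-bit (EDF) or 24-bit (BDF,
#' BioSemi magic) little-endian samples, digital-to-physical scaling.
#' Annotation channels and discontinuous files are not supported.
#'
#' @param path file path.
#' @param label,subject_id,trial_id metadata to stamp on the result (EDF
#'   headers carry no attention label).
#' @return An [eeg_recording()] in physical units.
#' @export
read_edf <- function(path, label = NA_character_,
                     subject_id = NA_character_, trial_id = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  is_bdf <- magic[1] == as.raw(255)
  rs <- function(n) rawToChar(readBin(con, "raw", n))
  rn <- function(n) as.numeric(trim(rs(n)))
  rs(80); rs(80); rs(8); rs(8)                    # patient/recording/date/time
  rn(8)                                           # header bytes
  rs(44)
  n_rec <- rn(8); rec_dur <- rn(8); ns <- rn(4)
  labels <- vapply(seq_len(ns), function(i) trim(rs(16)), "")
  for (i in seq_len(ns)) rs(80)                   # transducer
  for (i in seq_len(ns)) rs(8)                    # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) rn(8), 0)
  pmax_ <- vapply(seq_len(ns), function(i) rn(8), 0)
  dmin_ <- vapply(seq_len(ns), function(i) rn(8), 0)
  dmax_ <- vapply(seq_len(ns), function(i) rn(8), 0)
  for (i in seq_len(ns)) rs(80)                   # prefilter
  spr <- vapply(seq_len(ns), function(i) rn(8), 0)
  for (i in seq_len(ns)) rs(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_bdf) {
        raw3 <- readBin(con, "raw", 3L * spr[s])
        m <- matrix(as.integer(raw3), nrow = 3L)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
      } else {
        v <- readBin(con, "integer", spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      }
      phys <- (v - dmin_[s]) * (pmax_[s] - pmin_[s]) /
        (dmax_[s] - dmin_[s]) + pmin_[s]
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- phys
    }
  }
  eeg_recording(out, spr[1] / rec_dur, labels, subject_id = subject_id,
                trial_id = trial_id, label = label)
}

#' Write an EDF (16-bit) file
#'
#' Counterpart of [read_edf()] for round-trips and fixture generation; one
#' data record per second, physical range taken from the data.
#'
#' @param rec an [eeg_recording()]; `fs` must be a positive integer.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(abs(rec$fs - round(rec$fs)) < 1e-9)
  fs <- round(rec$fs)
  ns <- n_channels(rec)
  n_rec <- floor(n_samples(rec) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- floor(apply(x, 1, min)); pmax_ <- ceiling(apply(x, 1, max))
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) {
    s <- substr(s, 1, n)
    writeBin(charToRaw(formatC(s, width = -n)), con)
  }
  pad("0", 8); pad("synthetic", 80); pad("ssfgan export", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(as.character(256L * (1L + ns)), 8)
  pad("", 44); pad(as.character(n_rec), 8); pad("1", 8)
  pad(as.character(ns), 4)
  for (s in seq_len(ns)) pad(rec$channel_names[s], 16)
  for (s in seq_len(ns)) pad("", 80)
  for (s in seq_len(ns)) pad("uV", 8)
  for (s in seq_len(ns)) pad(as.character(pmin_[s]), 8)
  for (s in seq_len(ns)) pad(as.character(pmax_[s]), 8)
  for (s in seq_len(ns)) pad("-32768", 8)
  for (s in seq_len(ns)) pad("32767", 8)
  for (s in seq_len(ns)) pad("", 80)
  for (s in seq_len(ns)) pad(as.character(fs), 8)
  for (s in seq_len(ns)) pad("", 32)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- x[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - pmin_[s]) / (pmax_[s] - pmin_[s]) * 65535 - 32768)
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
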