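#' Spectro-spatial feature (SSF) map
#'
#' A 28x28 topographic image of band power for one decision window: the
#' per-electrode band powers are interpolated over the projected scalp and
#' min-max scaled to `[-1, 1]` (matching the tanh output range of the
#' generator). `scale_info` records the affine scaling so maps can be mapped
#' back to power units.
#'
#' @param grid numeric `grid_n` x `grid_n` matrix.
#' @param label `"left"`, `"right"` or `NA`.
#' @param subject_id,trial_id,window_index provenance.
#' @param scale_info list with `min`, `max` of the raw map (or NULL).
#' @param synthetic `TRUE` for GAN-generated maps.
#' @return An `ssf_map` object.
#' @export
ssf_map <- function(grid, label = NA_character_, subject_id = NA_character_,
                    trial_id = NA_character_, window_index = NA_integer_,
                    scale_info = NULL, synthetic = FALSE) {
  grid <- as.matrix(grid)
  if (nrow(grid) != ncol(grid)) stop("SSF grid must be square")
  if (!all(is.finite(grid))) stop("non-finite values in SSF grid")
  if (!is.na(label)) label <- match.arg(label, c("left", "right"))
  structure(list(grid = grid, label = label, subject_id = subject_id,
                 trial_id = trial_id, window_index = window_index,
                 scale_info = scale_info, synthetic = synthetic),
            class = "ssf_map")
}

#' @rdname ssf_map
#' @param x an `ssf_map`.
#' @param ... ignored.
#' @export
print.ssf_map <- function(x, ...) {
  cat(sprintf("<ssf_map> %dx%d  label: %s  subject: %s  trial: %s  window: %s%s\n",
              nrow(x$grid), ncol(x$grid), x$label, x$subject_id, x$trial_id,
              ifelse(is.na(x$window_index), "-", x$window_index),
              if (isTRUE(x$synthetic)) "  [synthetic]" else ""))
  invisible(x)
}

# Min-max scale a matrix to [-1, 1]; constant maps go to all zeros.
scale_minmax <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo < .Machine$double.eps) {
    list(grid = m * 0, info = list(min = lo, max = hi))
  } else {
    list(grid = 2 * (m - lo) / (hi - lo) - 1, info = list(min = lo, max = hi))
  }
}

#' Extract SSF maps from a recording
#'
#' The full feature path: cut the (already preprocessed) recording into
#' decision windows, estimate per-channel band power per window with the FFT,
#' interpolate each power vector over the azimuthal-equidistant projection of
#' the montage with the Clough-Tocher interpolant on a `grid_n` x `grid_n`
#' mesh, and min-max scale each map to `[-1, 1]`. Deterministic: identical
#' inputs give bit-identical maps.
#'
#' @param rec an [eeg_recording()] (preprocess first; this function does not
#'   filter or resample).
#' @param spec a [decision_window_spec()].
#' @param band a [frequency_band()]; default alpha 8-13 Hz.
#' @param montage an [electrode_montage()] matching the recording's channels;
#'   projected automatically if needed.
#' @param grid_n mesh resolution (default 28).
#' @param normalize min-max scale maps to `[-1, 1]` (default TRUE).
#' @return List of [ssf_map()]s in window order.
#' @export
extract_ssf <- function(rec, spec, band = frequency_band(), montage,
                        grid_n = 28, normalize = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(montage, "electrode_montage"))
  if (!identical(rec$channel_names, montage$names)) {
    idx <- match(rec$channel_names, montage$names)
    if (anyNA(idx))
      stop("montage is missing channel(s): ",
           paste(rec$channel_names[is.na(idx)], collapse = ", "))
    montage <- montage_subset(montage, rec$channel_names)
  }
  if (is.null(montage$pos2d)) montage <- project_montage(montage)
  wins <- segment_windows(rec, spec)
  powers <- vapply(wins, band_power, numeric(n_channels(rec)), band = band)
  g <- ssf_grid_axes(montage, grid_n)
  ct <- ct_interpolator_cached(montage$pos2d, g, g, fill = 0)
  lapply(seq_along(wins), function(i) {
    raw <- ct$eval(powers[, i])
    sc <- if (normalize) scale_minmax(raw) else list(grid = raw, info = NULL)
    ssf_map(sc$grid, label = rec$label, subject_id = rec$subject_id,
            trial_id = rec$trial_id, window_index = wins[[i]]$window_index,
            scale_info = sc$info)
  })
}

#' Stack a list of SSF maps into an array
#'
#' @param maps list of [ssf_map()]s of equal size.
#' @return Numeric array `n` x `grid_n` x `grid_n`.
#' @export
ssf_stack <- function(maps) {
  n <- length(maps)
  stopifnot(n > 0)
  gn <- nrow(maps[[1]]$grid)
  arr <- array(0, c(n, gn, gn))
  for (i in seq_len(n)) arr[i, , ] <- maps[[i]]$grid
  arr
}

#' @rdname ssf_stack
#' @export
ssf_labels <- function(maps) vapply(maps, function(m) m$label, character(1))

#' Write / read an SSF dataset directory
#'
#' Plain-text container for a set of SSF maps: `maps.csv` (one flattened
#' row-major map per row), `meta.csv` (label and provenance per map) and
#' `manifest.json` (grid size, count, format version). HDF5 is deliberately
#' not used: the target environment has no R HDF5 bindings and plain text
#' keeps datasets portable and diffable.
#'
#' @param maps list of [ssf_map()]s.
#' @param dir output directory (created if needed).
#' @return `write_ssf_dataset()` the directory path; `read_ssf_dataset()` the
#'   list of maps.
#' @export
write_ssf_dataset <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- ssf_stack(maps)
  flat <- matrix(arr, nrow = dim(arr)[1])    # n x (gn*gn), column-major cells
  utils::write.csv(flat, file.path(dir, "maps.csv"), row.names = FALSE)
  meta <- data.frame(
    label = ssf_labels(maps),
    subject_id = vapply(maps, function(m) as.character(m$subject_id), ""),
    trial_id = vapply(maps, function(m) as.character(m$trial_id), ""),
    window_index = vapply(maps, function(m) as.integer(m$window_index), 1L),
    synthetic = vapply(maps, function(m) isTRUE(m$synthetic), logical(1)),
    scale_min = vapply(maps, function(m)
      if (is.null(m$scale_info)) NA_real_ else m$scale_info$min, numeric(1)),
    scale_max = vapply(maps, function(m)
      if (is.null(m$scale_info)) NA_real_ else m$scale_info$max, numeric(1)))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  jsonlite::write_json(list(format = "ssfgan-dataset", version = 1L,
                            n = length(maps), grid_n = dim(arr)[2]),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_ssf_dataset
#' @export
read_ssf_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  flat <- as.matrix(utils::read.csv(file.path(dir, "maps.csv")))
  meta <- utils::read.csv(file.path(dir, "meta.csv"),
                          stringsAsFactors = FALSE)
  gn <- man$grid_n
  lapply(seq_len(nrow(flat)), function(i) {
    si <- if (is.na(meta$scale_min[i])) NULL else
      list(min = meta$scale_min[i], max = meta$scale_max[i])
    ssf_map(matrix(flat[i, ], gn, gn), label = meta$label[i],
            subject_id = meta$subject_id[i], trial_id = meta$trial_id[i],
            window_index = meta$window_index[i], scale_info = si,
            synthetic = meta$synthetic[i])
  })
}

#' Trivial hemifield-contrast baseline classifier
#'
#' Classifies a map as `"left"` or `"right"` from the sign of the difference
#' between mean intensity over the left-hemifield and right-hemifield pixel
#' columns, with the decision direction fitted on a training set (the sign
#' convention depends on the simulated boost side). Used as the separability
#' oracle for synthetic data; it has no trainable capacity beyond one sign
#' and one threshold.
#'
#' @param train_maps,train_labels maps and labels to fit sign and threshold.
#' @return A function mapping a list of maps to predicted labels.
#' @export
hemifield_classifier <- function(train_maps, train_labels) {
  contrast <- function(m) {
    gn <- ncol(m$grid)
    half <- floor(gn / 2)
    # columns follow the v (left) axis: high columns = left hemifield
    mean(m$grid[, (gn - half + 1):gn]) - mean(m$grid[, 1:half])
  }
  x <- vapply(train_maps, contrast, numeric(1))
  is_left <- train_labels == "left"
  dir <- sign(mean(x[is_left]) - mean(x[!is_left]))
  if (dir == 0) dir <- 1
  thr <- (mean(x[is_left]) + mean(x[!is_left])) / 2
  function(maps) {
    xs <- vapply(maps, contrast, numeric(1))
    ifelse(dir * (xs - thr) > 0, "left", "right")
  }
}
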