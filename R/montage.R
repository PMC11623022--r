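#' Electrode montage on the unit sphere
#'
#' Per-channel 3D electrode positions, normalized onto the unit head sphere.
#' The coordinate convention is right-handed: x toward the nasion (front),
#' y toward the left ear, z up through the vertex. The 2D coordinates `pos2d`
#' appear only after [project_montage()].
#'
#' @param names character vector of unique channel names.
#' @param pos3d numeric matrix, one `(x, y, z)` row per channel; rows are
#'   normalized to unit length.
#' @return An `electrode_montage` with elements `names`, `pos3d` and
#'   (after projection) `pos2d`.
#' @export
electrode_montage <- function(names, pos3d) {
  names <- as.character(names)
  pos3d <- as.matrix(pos3d)
  stopifnot(ncol(pos3d) == 3, nrow(pos3d) == length(names))
  if (anyDuplicated(names)) stop("electrode names must be unique")
  nrm <- sqrt(rowSums(pos3d^2))
  if (any(nrm < 1e-12)) stop("zero-norm electrode position")
  pos3d <- pos3d / nrm
  dimnames(pos3d) <- list(names, c("x", "y", "z"))
  structure(list(names = names, pos3d = pos3d, pos2d = NULL),
            class = "electrode_montage")
}

#' @rdname electrode_montage
#' @param x an `electrode_montage`.
#' @param ... ignored.
#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf("<electrode_montage> %d electrodes%s\n", length(x$names),
              if (is.null(x$pos2d)) "" else " (projected)"))
  invisible(x)
}

#' Azimuthal-equidistant projection of a montage
#'
#' Projects electrodes from the unit sphere onto the plane with the pole at
#' the vertex `(0, 0, 1)`: each electrode maps to polar coordinates
#' `(rho, theta)` with `rho` the great-circle (arc) distance from the vertex
#' and `theta = atan2(y, x)`, so distances from the pole are preserved
#' exactly.
#'
#' @param montage an [electrode_montage()].
#' @return The montage with `pos2d` filled in (columns `u`, `v`).
#' @export
project_montage <- function(montage) {
  stopifnot(inherits(montage, "electrode_montage"))
  p <- montage$pos3d
  rho <- acos(pmin(1, pmax(-1, p[, "z"])))
  theta <- atan2(p[, "y"], p[, "x"])
  pos2d <- cbind(u = rho * cos(theta), v = rho * sin(theta))
  rownames(pos2d) <- montage$names
  montage$pos2d <- pos2d
  montage
}

#' Idealized 10-10 style montage (synthetic stand-in)
#'
#' Builds a left/right symmetric 64- or 32-channel unit-sphere montage with
#' the standard 10-10 label set, by placing each electrode row on its sagittal
#' arc and rotating laterally about the nasion-inion axis. This is a synthetic
#' idealized approximation of the BioSemi-64 layout, adequate for topographic
#' mapping and simulation; it is not digitized anatomical data. The same
#' montage ships as `inst/extdata/montage64_1010_synthetic.csv`.
#'
#' @param n_channels 64 (default) or 32.
#' @return An [electrode_montage()].
#' @export
standard_montage <- function(n_channels = 64) {
  rows <- list(
    # row prefix, sagittal angle from nasion (deg), labels left-to-midline-to-right
    list("Fp", 18, c("Fp1", "Fpz", "Fp2"), c(30, 0, -30)),
    list("AF", 36, c("AF7", "AF3", "AFz", "AF4", "AF8"), c(70, 35, 0, -35, -70)),
    list("F", 54, c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
         c(90, 67.5, 45, 22.5, 0, -22.5, -45, -67.5, -90)),
    list("FC", 72, c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
         c(90, 67.5, 45, 22.5, 0, -22.5, -45, -67.5, -90)),
    list("C", 90, c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
         c(90, 67.5, 45, 22.5, 0, -22.5, -45, -67.5, -90)),
    list("CP", 108, c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
         c(90, 67.5, 45, 22.5, 0, -22.5, -45, -67.5, -90)),
    list("P", 126, c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10"),
         c(112.5, 90, 67.5, 45, 22.5, 0, -22.5, -45, -67.5, -90, -112.5)),
    list("PO", 144, c("PO7", "PO3", "POz", "PO4", "PO8"), c(70, 35, 0, -35, -70)),
    list("O", 162, c("O1", "Oz", "O2"), c(30, 0, -30)),
    list("I", 180, c("Iz"), c(0)))
  nm <- character(0); pos <- NULL
  for (r in rows) {
    t <- r[[2]] * pi / 180
    beta <- r[[4]] * pi / 180          # positive = left (+y)
    m <- cbind(x = rep(cos(t), length(beta)),
               y = sin(beta) * sin(t),
               z = cos(beta) * sin(t))
    nm <- c(nm, r[[3]]); pos <- rbind(pos, m)
  }
  mont <- electrode_montage(nm, pos)
  if (n_channels == 64) return(mont)
  if (n_channels == 32) {
    keep <- c("Fp1", "Fpz", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
              "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
              "PO3", "PO4", "O1", "O2")
    return(montage_subset(mont, keep))
  }
  stop("n_channels must be 64 or 32")
}

#' Subset a montage by channel names
#'
#' @param montage an [electrode_montage()].
#' @param names channels to keep, in the requested order.
#' @return The subset montage (2D projection dropped; re-project if needed).
#' @export
montage_subset <- function(montage, names) {
  idx <- match(names, montage$names)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(names[is.na(idx)], collapse = ", "))
  electrode_montage(montage$names[idx], montage$pos3d[idx, , drop = FALSE])
}

#' Read / write a montage CSV
#'
#' The CSV interface has columns `name,x,y,z` in the package coordinate
#' convention (x nasion, y left ear, z vertex); positions are re-normalized
#' onto the unit sphere on read.
#'
#' @param path CSV file path.
#' @return [read_montage()] returns an [electrode_montage()].
#' @export
read_montage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("montage CSV must have columns name,x,y,z")
  electrode_montage(df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' @rdname read_montage
#' @param montage an [electrode_montage()].
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(name = montage$names,
                   x = montage$pos3d[, "x"],
                   y = montage$pos3d[, "y"],
                   z = montage$pos3d[, "z"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hemisphere of each electrode
#'
#' Sign of the y coordinate: `"left"` for y > 0, `"right"` for y < 0,
#' `"midline"` within `tol` of the sagittal plane.
#'
#' @param montage an [electrode_montage()].
#' @param tol midline tolerance on y.
#' @return Character vector along channels.
#' @export
electrode_hemisphere <- function(montage, tol = 1e-9) {
  y <- montage$pos3d[, "y"]
  out <- ifelse(y > tol, "left", ifelse(y < -tol, "right", "midline"))
  names(out) <- montage$names
  out
}
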