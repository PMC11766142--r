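# Readers and writers for every file format the pipeline touches:
# CSV / PDB centre sets, PDB scatterer sets, two-column curve text,
# TIFF / plain-text detector images with JSON geometry sidecars, and
# reflection CSV exports.

#' Read oligomer centres from CSV or PDB
#'
#' CSV files need a header with columns `x`, `y`, `z` (angstroms, comma
#' separated, '.' decimal). PDB coordinates are taken verbatim (PDB is
#' angstrom-native), one centre per atom record.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"pdb"`.
#' @return A [center_set()].
#' @export
read_centers <- function(path, format = c("auto", "csv", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_centers: file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path)
    need <- c("x", "y", "z")
    if (!all(need %in% names(df)))
      stop("read_centers: CSV must have header columns x, y, z")
    for (col in need) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[col]])))))
      if (length(bad) > 0L)
        stop("read_centers: non-numeric value in column '", col,
             "' at data line ", bad[1])
      df[[col]] <- as.numeric(as.character(df[[col]]))
    }
    center_set(as.matrix(df[, need]), label = basename(path))
  } else {
    pdb <- bio3d::read.pdb(path)
    center_set(cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z),
               label = basename(path))
  }
}

#' Write oligomer centres to CSV or PDB
#'
#' PDB output stores each centre as a pseudo-atom (`CA` in residue `TRI`,
#' one residue per oligomer).
#'
#' @param centers A [center_set()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_centers <- function(centers, path, format = c("auto", "csv", "pdb")) {
  stopifnot(inherits(centers, "center_set"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "csv"
  if (format == "csv") {
    utils::write.csv(as.data.frame(centers$points), path, row.names = FALSE)
  } else {
    n <- nrow(centers$points)
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(centers$points)),
                     type = rep("ATOM", n),
                     resno = seq_len(n),
                     resid = rep("TRI", n),
                     elety = rep("CA", n))
  }
  invisible(path)
}

#' Write a scatterer set as a pseudo-atom PDB
#'
#' Convention: scattering weight in the occupancy column, Gaussian width
#' (sigma, Angstrom) in the B-factor column.
#'
#' @param scatterers A [scatterer_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scatterers <- function(scatterers, path) {
  stopifnot(inherits(scatterers, "scatterer_set"))
  n <- nrow(scatterers$sites)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(scatterers$sites)),
                   type = rep("ATOM", n),
                   resno = seq_len(n),
                   resid = rep("SCA", n),
                   elety = rep("C", n),
                   o = scatterers$weight,
                   b = scatterers$width)
  invisible(path)
}

#' Read a scatterer set from a pseudo-atom PDB
#'
#' Inverse of [write_scatterers()] (weight from occupancy, width from
#' B-factor).
#'
#' @param path PDB file path.
#' @return A [scatterer_set()].
#' @export
read_scatterers <- function(path) {
  if (!file.exists(path)) stop("read_scatterers: file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  scatterer_set(cbind(at$x, at$y, at$z),
                weight = ifelse(is.na(at$o), 1, at$o),
                width = ifelse(is.na(at$b), 0, at$b),
                label = basename(path))
}

#' Write a 1D curve as two-column text
#'
#' Whitespace-delimited `x intensity` rows with a comment header carrying
#' the abscissa unit and wavelength.
#'
#' @param curve A [curve1d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "curve1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# unit: %s", curve$unit),
               sprintf("# wavelength_angstrom: %s",
                       format(curve$wavelength, digits = 15))), con)
  utils::write.table(data.frame(x = curve$x, intensity = curve$y), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 1D curve written by [write_curve()]
#'
#' @param path File path.
#' @return A [curve1d()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("read_curve: file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  unit <- sub("^# unit:\\s*", "", grep("^# unit:", hdr, value = TRUE)[1])
  wl <- suppressWarnings(as.numeric(
    sub("^# wavelength_angstrom:\\s*", "",
        grep("^# wavelength_angstrom:", hdr, value = TRUE)[1])))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")])
  curve1d(df[[1]], df[[2]],
          unit = if (is.na(unit)) "two_theta_deg" else unit,
          wavelength = wl)
}

#' Write a detector image (TIFF or text matrix) with a JSON sidecar
#'
#' TIFF output is 32-bit float with intensities scaled to `[0, 1]`; the
#' scale factor and the full scattering geometry are stored in a JSON
#' sidecar (`<path>.json`). Plain-text output (`format = "txt"`) writes the
#' unscaled matrix.
#'
#' @param image A [detector_image()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"tiff"` or `"txt"`.
#' @return `path`, invisibly.
#' @export
write_detector_image <- function(image, path, format = c("auto", "tiff", "txt")) {
  stopifnot(inherits(image, "detector_image"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "txt"
  scale <- max(image$counts, 1e-300)
  if (format == "tiff") {
    tiff::writeTIFF(image$counts / scale, path, bits.per.sample = 32L,
                    compression = "none")
  } else {
    utils::write.table(image$counts, path, row.names = FALSE,
                       col.names = FALSE)
    scale <- 1
  }
  geo <- image$geometry
  jsonlite::write_json(
    list(wavelength = geo$wavelength,
         sample_detector_distance = geo$sample_detector_distance,
         beam_center = geo$beam_center,
         pixel_size = geo$pixel_size,
         intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a detector image written by [write_detector_image()]
#'
#' @param path Image path; the geometry sidecar `<path>.json` must exist.
#' @param format `"auto"`, `"tiff"` or `"txt"`.
#' @return A [detector_image()].
#' @export
read_detector_image <- function(path, format = c("auto", "tiff", "txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_detector_image: file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("read_detector_image: geometry sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "txt"
  counts <- if (format == "tiff") {
    tiff::readTIFF(path) * meta$intensity_scale
  } else {
    as.matrix(utils::read.table(path)) * meta$intensity_scale
  }
  dimnames(counts) <- NULL
  detector_image(counts,
                 scattering_geometry(meta$wavelength,
                                     meta$sample_detector_distance,
                                     meta$beam_center, meta$pixel_size))
}

#' Export a reflection list as CSV
#'
#' Columns `h`, `k`, `l`, `d_angstrom`, `weight`.
#'
#' @param reflections A `reflection_set` from [enumerate_reflections()] (or
#'   the `reflections` element of a `powder_pattern`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(reflections, path) {
  df <- as.data.frame(reflections)[, c("h", "k", "l", "d", "weight")]
  names(df) <- c("h", "k", "l", "d_angstrom", "weight")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a unit cell to a flat named list
#'
#' @param cell A [unit_cell()].
#' @return Named list with keys `a`, `b`, `c`, `alpha`, `beta`, `gamma`
#'   (Angstrom / degrees).
#' @export
cell_as_list <- function(cell) {
  assert_unit_cell(cell)
  unclass(cell)
}

#' Build a unit cell from a flat named list
#'
#' @param x Named list (or similar) with keys `a`, `b`, `c`, `alpha`,
#'   `beta`, `gamma`.
#' @return A [unit_cell()].
#' @export
cell_from_list <- function(x) {
  need <- c("a", "b", "c", "alpha", "beta", "gamma")
  if (!all(need %in% names(x)))
    stop("cell_from_list: keys a, b, c, alpha, beta, gamma required")
  unit_cell(x$a, x$b, x$c, x$alpha, x$beta, x$gamma)
}
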