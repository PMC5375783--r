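#' Read a radiometric sidecar file
#'
#' A flat YAML file with keys `t_min_c`, `t_max_c`, `emissivity`,
#' `distance_m`, `ifov_mrad` (the last three optional).
#'
#' @param path sidecar path.
#' @return a [radiometric_meta()].
#' @export
read_sidecar <- function(path) {
  v <- yaml::read_yaml(path)
  if (is.null(v$t_min_c) || is.null(v$t_max_c)) {
    stop_degenerate("sidecar must define t_min_c and t_max_c")
  }
  radiometric_meta(
    t_min_c = v$t_min_c, t_max_c = v$t_max_c,
    emissivity = if (is.null(v$emissivity)) 0.97 else v$emissivity,
    distance_m = if (is.null(v$distance_m)) 1.2 else v$distance_m,
    ifov_mrad = if (is.null(v$ifov_mrad)) 1.36 else v$ifov_mrad
  )
}

#' Write a radiometric sidecar file
#'
#' @param meta a [radiometric_meta()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(meta, path) {
  stopifnot(inherits(meta, "radiometric_meta"))
  yaml::write_yaml(unclass(meta), path)
  invisible(path)
}

# Collapse an image array read from disk to one gray channel in [0, 1].
flatten_gray <- function(a) {
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3L]), drop = FALSE],
                                       c(1L, 2L), mean)
  a
}

#' Read a thermogram from an image file plus radiometric metadata
#'
#' Supports 8/16-bit grayscale (or RGB, averaged) PNG and TIFF; intensities
#' are rescaled to the 0..255 range on load.
#'
#' @param path image path (`.png`, `.tif`/`.tiff`).
#' @param meta a [radiometric_meta()] or the path of a sidecar YAML.
#' @return a [thermogram()].
#' @export
read_thermogram <- function(path, meta) {
  if (is.character(meta)) meta <- read_sidecar(meta)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_degenerate(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  )
  g <- flatten_gray(a)
  thermogram(matrix(as.integer(round(g * 255)), nrow(g), ncol(g)), meta)
}

#' Read a temperature matrix CSV
#'
#' Comma-separated temperatures in degrees C, one value per pixel,
#' row-major, no header.
#'
#' @param path CSV path.
#' @param meta optional [radiometric_meta()]; defaults to the matrix's own
#'   min/max as the scene range.
#' @return a `thermal_matrix`.
#' @export
read_temperature_csv <- function(path, meta = NULL) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  if (is.null(meta)) meta <- radiometric_meta(min(m), max(m))
  structure(list(temps = m, meta = meta, tvgm = NA_integer_),
            class = "thermal_matrix")
}

#' Write a temperature matrix CSV
#'
#' @param thermal a `thermal_matrix` or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(thermal, path) {
  write.table(temps_of(thermal), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Quantize a temperature matrix to an 8-bit thermogram
#'
#' The inverse of [to_thermal()]: temperatures are mapped onto gray levels
#' 0..`levels - 1` using the scene range in `meta` (or the matrix's own
#' range).
#'
#' @param thermal a `thermal_matrix` or numeric matrix of degrees C.
#' @param meta optional [radiometric_meta()] giving the scene range.
#' @param levels gray depth (default 256).
#' @return a [thermogram()].
#' @export
thermal_to_thermogram <- function(thermal, meta = NULL, levels = 256L) {
  m <- temps_of(thermal)
  if (is.null(meta)) {
    meta <- if (inherits(thermal, "thermal_matrix")) thermal$meta
            else radiometric_meta(min(m), max(m))
  }
  g <- round((m - meta$t_min_c) / (meta$t_max_c - meta$t_min_c) * (levels - 1L))
  g <- pmin(pmax(g, 0), levels - 1L)
  thermogram(matrix(as.integer(g), nrow(m), ncol(m)), meta, levels)
}

#' Write a binary mask as a PNG
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write a thermogram as a PNG
#'
#' @param x a [thermogram()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_thermogram_png <- function(x, path) {
  stopifnot(inherits(x, "thermogram"))
  png::writePNG(x$pixels / (x$levels - 1L), path)
  invisible(path)
}
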