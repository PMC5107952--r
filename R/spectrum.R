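#' Construct a mass spectrum
#'
#' A spectrum is a pair of equal-length vectors: a strictly increasing m/z
#' axis (daltons) and non-negative intensities in arbitrary units, tagged
#' with the ionization polarity it was acquired in.
#'
#' @param mz Numeric vector of m/z values, strictly increasing.
#' @param intensity Numeric vector of non-negative intensities.
#' @param mode Ionization mode, `"positive"` or `"negative"`.
#' @return An object of class `msi_spectrum`.
#' @export
msi_spectrum <- function(mz, intensity, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("mz values must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(mz = mz, intensity = intensity, mode = mode),
            class = "msi_spectrum")
}

#' @export
length.msi_spectrum <- function(x) length(x$mz)

#' @export
print.msi_spectrum <- function(x, ...) {
  cat(sprintf("<msi_spectrum> %s mode, %d points, m/z %.2f-%.2f\n",
              x$mode, length(x$mz),
              if (length(x$mz)) min(x$mz) else NA,
              if (length(x$mz)) max(x$mz) else NA))
  invisible(x)
}

#' Construct a pixel grid
#'
#' Integer pixel positions on a regular 2-D acquisition raster.
#' Coordinates are 0-based internally; the imzML reader/writer converts
#' from and to that format's 1-based convention.
#'
#' @param x,y Integer vectors of pixel column/row indices (0-based).
#' @param spacing_um Pixel pitch in micrometers (default 100, the
#'   acquisition raster used for the lipid imaging this package targets).
#' @return An object of class `pixel_grid`: a data.frame with columns
#'   `x`, `y` and attribute `spacing_um`.
#' @export
pixel_grid <- function(x, y, spacing_um = 100) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyDuplicated(paste(x, y))) stop("pixel coordinates must be unique")
  if (!is.numeric(spacing_um) || spacing_um <= 0)
    stop("spacing_um must be > 0")
  g <- data.frame(x = x, y = y)
  attr(g, "spacing_um") <- as.numeric(spacing_um)
  class(g) <- c("pixel_grid", "data.frame")
  g
}

grid_spacing <- function(grid) attr(grid, "spacing_um")

#' Construct an MSI dataset
#'
#' One ionization mode's worth of imaging data: a pixel grid plus one
#' spectrum per pixel.
#'
#' @param grid A [pixel_grid()].
#' @param spectra List of [msi_spectrum()] objects, one per grid pixel.
#' @param mode Ionization mode; must match every spectrum's mode.
#' @param metadata Optional named list of free-form metadata.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(grid, spectra, mode = c("positive", "negative"),
                        metadata = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "pixel_grid"))
  if (length(spectra) != nrow(grid))
    stop("need exactly one spectrum per pixel (", nrow(grid), " pixels, ",
         length(spectra), " spectra)")
  modes <- vapply(spectra, function(s) s$mode, character(1))
  if (any(modes != mode))
    stop("all spectra must share the dataset polarity (", mode, ")")
  structure(list(grid = grid, spectra = spectra, mode = mode,
                 metadata = metadata),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %s mode, %d pixels, %g um pitch\n",
              x$mode, nrow(x$grid), grid_spacing(x$grid)))
  invisible(x)
}
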