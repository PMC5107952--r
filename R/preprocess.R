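#' Preprocessing configuration
#'
#' Bundles the spectral preprocessing parameters: Savitzky-Golay
#' smoothing window (points, odd) and polynomial order, the
#' signal-to-noise threshold for peak picking (3.0 in the targeted
#' workflow), the TIC normalization target (`NULL` = the dataset's
#' median raw TIC), and the m/z tolerance used to align peaks across
#' pixels.
#'
#' @param smooth_window Odd integer window length in points (default 9).
#' @param smooth_polyorder Polynomial order (default 3); must be below
#'   the window length.
#' @param snr_threshold Peak-picking signal-to-noise threshold
#'   (default 3).
#' @param tic_target Per-pixel total-ion-current target, or `NULL` to
#'   use the dataset median.
#' @param align_tolerance m/z gap (daltons) above which aligned peak
#'   groups are split (default 0.15).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(smooth_window = 9L, smooth_polyorder = 3L,
                              snr_threshold = 3.0, tic_target = NULL,
                              align_tolerance = 0.15) {
  smooth_window <- as.integer(smooth_window)
  smooth_polyorder <- as.integer(smooth_polyorder)
  if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
  if (smooth_window <= smooth_polyorder)
    stop("smooth_window must exceed smooth_polyorder")
  if (snr_threshold <= 0) stop("snr_threshold must be > 0")
  if (align_tolerance <= 0) stop("align_tolerance must be > 0")
  structure(list(smooth_window = smooth_window,
                 smooth_polyorder = smooth_polyorder,
                 snr_threshold = snr_threshold,
                 tic_target = tic_target,
                 align_tolerance = align_tolerance),
            class = "preprocess_config")
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Least-squares local-polynomial smoothing of the intensity trace; the
#' m/z axis is unchanged.  Polynomials up to the filter order are
#' reproduced exactly.
#'
#' @param s An [msi_spectrum()].
#' @param window Odd window length in points.
#' @param polyorder Polynomial order, below `window`.
#' @return The smoothed [msi_spectrum()].
#' @export
smooth_spectrum <- function(s, window = 9L, polyorder = 3L) {
  stopifnot(inherits(s, "msi_spectrum"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (length(s) < window) stop("spectrum shorter than the smoothing window")
  sm <- signal::sgolayfilt(s$intensity, p = polyorder, n = window)
  msi_spectrum(s$mz, pmax(sm, 0), mode = s$mode)
}

#' Total-ion-current normalization
#'
#' Scales a spectrum's intensities so their sum (the TIC) equals
#' `tic_target`, removing per-pixel variation in overall ion yield.
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param s An [msi_spectrum()].
#' @param tic_target Positive target total intensity (default 1).
#' @return The normalized [msi_spectrum()].
#' @export
tic_normalize <- function(s, tic_target = 1) {
  stopifnot(inherits(s, "msi_spectrum"))
  if (tic_target <= 0) stop("tic_target must be > 0")
  tic <- sum(s$intensity)
  if (tic <= 0) stop("cannot TIC-normalize an all-zero spectrum")
  msi_spectrum(s$mz, s$intensity * (tic_target / tic), mode = s$mode)
}

# running-median baseline trend; window wide relative to peak widths
.baseline_trend <- function(intensity) {
  w <- max(3L, 2L * (length(intensity) %/% 40L) + 1L)
  stats::runmed(intensity, k = min(w, .odd_at_most(length(intensity))))
}

.odd_at_most <- function(n) if (n %% 2L == 1L) n else n - 1L

#' Signal-to-noise peak picking
#'
#' Detects local intensity maxima and keeps those whose amplitude above
#' the local baseline (a running-median trend) is at least
#' `snr_threshold` times the spectrum's noise level, estimated robustly
#' as 1.4826 x the median absolute deviation of the detrended
#' intensity trace.
#'
#' @param s An [msi_spectrum()] (smoothed/normalized as configured).
#' @param snr_threshold Signal-to-noise threshold (default 3, the value
#'   used for the lipid imaging workflow this package targets).
#' @return A data.frame of class `peak_list` with columns `mz`,
#'   `intensity`, `snr` and attribute `mode`.
#' @export
pick_peaks <- function(s, snr_threshold = 3.0) {
  stopifnot(inherits(s, "msi_spectrum"))
  if (snr_threshold <= 0) stop("snr_threshold must be > 0")
  n <- length(s)
  if (n < 3L) stop("spectrum must have at least 3 points")
  y <- s$intensity
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  resid <- y - .baseline_trend(y)
  noise <- stats::mad(resid, center = 0)
  if (noise <= 0) {
    # noiseless trace: any maximum rising above the baseline counts
    keep <- which(is_max & resid > 1e-12)
    snr <- rep(Inf, length(keep))
  } else {
    snr_all <- resid / noise
    keep <- which(is_max & snr_all >= snr_threshold)
    snr <- snr_all[keep]
  }
  pl <- data.frame(mz = s$mz[keep], intensity = y[keep], snr = snr)
  attr(pl, "mode") <- s$mode
  class(pl) <- c("peak_list", "data.frame")
  pl
}

#' Align picked peaks across pixels into a peak matrix
#'
#' Pools all per-pixel peaks of one polarity and groups them by
#' single-linkage clustering along m/z: sorted peaks are split wherever
#' the gap to the next peak exceeds `tolerance`.  Each group becomes one
#' feature at the intensity-weighted mean m/z; pixels lacking a peak in
#' a group are filled with 0 (a pixel contributing several peaks to one
#' group has them summed).
#'
#' @param peaklists List of [pick_peaks()] outputs, one per pixel.
#' @param grid The [pixel_grid()] the peak lists came from.
#' @param tolerance m/z gap (daltons) splitting groups (default 0.15).
#' @param min_freq Minimum fraction of pixels a feature must appear in
#'   (default 0.25, the conventional occurrence filter that discards
#'   single-pixel noise spikes).
#' @return A [peak_matrix()].
#' @export
align_peaks <- function(peaklists, grid, tolerance = 0.15,
                        min_freq = 0.25) {
  if (length(peaklists) == 0L) stop("no peak lists supplied")
  stopifnot(inherits(grid, "pixel_grid"),
            length(peaklists) == nrow(grid))
  if (tolerance <= 0) stop("tolerance must be > 0")
  modes <- unique(unlist(lapply(peaklists, attr, "mode")))
  modes <- modes[!is.na(modes)]
  if (length(modes) > 1L) stop("peak lists mix ionization modes")
  mode <- if (length(modes)) modes else "positive"

  pix <- rep(seq_along(peaklists),
             vapply(peaklists, nrow, integer(1)))
  mz <- unlist(lapply(peaklists, `[[`, "mz"), use.names = FALSE)
  ity <- unlist(lapply(peaklists, `[[`, "intensity"), use.names = FALSE)
  if (length(mz) == 0L) stop("no peaks to align")
  o <- order(mz)
  mz <- mz[o]; ity <- ity[o]; pix <- pix[o]
  grp <- cumsum(c(1, diff(mz) > tolerance))
  # occurrence filter: a feature must be seen in enough distinct pixels
  freq <- vapply(split(pix, grp), function(p) length(unique(p)),
                 integer(1)) / length(peaklists)
  keep_grp <- which(freq >= min_freq)
  sel <- grp %in% keep_grp
  mz <- mz[sel]; ity <- ity[sel]; pix <- pix[sel]
  grp <- match(grp[sel], keep_grp)
  if (length(mz) == 0L) stop("no features pass the occurrence filter")
  centroid <- vapply(split(seq_along(mz), grp), function(i) {
    w <- ity[i]
    if (sum(w) > 0) sum(mz[i] * w) / sum(w) else mean(mz[i])
  }, numeric(1))
  values <- matrix(0, nrow = nrow(grid), ncol = length(centroid))
  idx <- cbind(pix, grp)
  for (r in seq_along(mz))
    values[idx[r, 1], idx[r, 2]] <- values[idx[r, 1], idx[r, 2]] + ity[r]
  peak_matrix(grid,
              feature_table(rep(mode, length(centroid)), centroid),
              values)
}

#' Preprocess a full MSI dataset into a peak matrix
#'
#' Applies the standard chain — Savitzky-Golay smoothing, TIC
#' normalization (to the dataset's median raw TIC unless a target is
#' configured), signal-to-noise peak picking, and cross-pixel alignment.
#' A centroided dataset (spectra already reduced to sticks, flagged via
#' `centroided = TRUE`) skips smoothing and picking and goes straight to
#' alignment.
#'
#' @param ds An [msi_dataset()].
#' @param config A [preprocess_config()].
#' @param centroided Set `TRUE` when the spectra are already centroided.
#' @return A [peak_matrix()].
#' @export
preprocess_dataset <- function(ds, config = preprocess_config(),
                               centroided = FALSE) {
  stopifnot(inherits(ds, "msi_dataset"),
            inherits(config, "preprocess_config"))
  tics <- vapply(ds$spectra, function(s) sum(s$intensity), numeric(1))
  target <- if (is.null(config$tic_target)) stats::median(tics) else
    config$tic_target
  pls <- lapply(ds$spectra, function(s) {
    if (centroided) {
      pl <- data.frame(mz = s$mz, intensity = s$intensity,
                       snr = rep(Inf, length(s$mz)))
      attr(pl, "mode") <- s$mode
      class(pl) <- c("peak_list", "data.frame")
      return(pl)
    }
    s <- smooth_spectrum(s, config$smooth_window, config$smooth_polyorder)
    s <- tic_normalize(s, target)
    pick_peaks(s, config$snr_threshold)
  })
  align_peaks(pls, ds$grid, tolerance = config$align_tolerance)
}
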