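#' Feature name from mode and m/z
#'
#' Features are named by polarity prefix and the centroid m/z printed to
#' two decimals, e.g. `POS_703.57` or `NEG_536.50`.
#'
#' @param mode `"positive"` or `"negative"` (vectorized).
#' @param mz Numeric centroid m/z (vectorized).
#' @return Character vector of feature names.
#' @export
feature_name <- function(mode, mz) {
  prefix <- ifelse(mode == "positive", "POS", "NEG")
  sprintf("%s_%.2f", prefix, mz)
}

#' Construct a feature descriptor table
#'
#' @param mode Character vector of polarities.
#' @param mz Numeric vector of centroid m/z values.
#' @return data.frame with columns `mode`, `mz`, `name`, sorted by
#'   (mode, mz).
#' @export
feature_table <- function(mode, mz) {
  stopifnot(length(mode) == length(mz),
            all(mode %in% c("positive", "negative")))
  f <- data.frame(mode = mode, mz = as.numeric(mz),
                  name = feature_name(mode, mz),
                  stringsAsFactors = FALSE)
  f <- f[order(match(f$mode, c("positive", "negative")), f$mz), ,
         drop = FALSE]
  rownames(f) <- NULL
  if (anyDuplicated(f$name)) stop("duplicate feature names")
  f
}

#' Construct a peak matrix
#'
#' The common currency of all downstream statistics: a non-negative
#' pixels-by-features intensity matrix tied to a pixel grid and a
#' feature descriptor table.
#'
#' @param grid A [pixel_grid()].
#' @param features A [feature_table()] (or mode/mz data.frame).
#' @param values Numeric matrix, `nrow(grid)` rows by `nrow(features)`
#'   columns, non-negative.
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(grid, features, values) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (is.null(features$name)) features$name <- feature_name(features$mode, features$mz)
  if (anyDuplicated(features$name)) stop("duplicate feature names")
  values <- as.matrix(values)
  if (nrow(values) != nrow(grid))
    stop("values must have one row per pixel")
  if (ncol(values) != nrow(features))
    stop("values must have one column per feature")
  if (any(values < 0)) stop("peak intensities must be non-negative")
  # keep features sorted by (mode, mz), positive mode first
  o <- order(match(features$mode, c("positive", "negative")), features$mz)
  features <- features[o, , drop = FALSE]
  rownames(features) <- NULL
  values <- values[, o, drop = FALSE]
  colnames(values) <- features$name
  structure(list(grid = grid, features = features, values = values),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d pixels x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$features$mode), collapse = "+")))
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$values)

#' Write a peak matrix to a delimited text file
#'
#' Writes a table with `x`, `y` pixel columns followed by one column per
#' feature name; [read_peak_matrix()] is its lossless inverse.
#'
#' @param pm A [peak_matrix()].
#' @param path Output file path (`.csv` or `.tsv`; comma used unless the
#'   extension is `.tsv`).
#' @return `path`, invisibly.
#' @export
save_peak_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "peak_matrix"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(x = pm$grid$x, y = pm$grid$y, check.names = FALSE)
  vals <- as.data.frame(pm$values, check.names = FALSE)
  df <- cbind(df, vals)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak matrix written by [save_peak_matrix()]
#'
#' @param path Input file path.
#' @param spacing_um Pixel pitch to attach to the restored grid.
#' @return A [peak_matrix()].
#' @export
read_peak_matrix <- function(path, spacing_um = 100) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)[1:2]))
    stop("peak matrix table must start with x,y columns")
  fn <- setdiff(names(df), c("x", "y"))
  parsed <- .parse_feature_names(fn)
  peak_matrix(pixel_grid(df$x, df$y, spacing_um = spacing_um),
              parsed,
              as.matrix(df[, fn, drop = FALSE]))
}

.parse_feature_names <- function(names) {
  m <- regmatches(names, regexec("^(POS|NEG)_([0-9.]+)$", names))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("unparseable feature name(s): ",
                     paste(names[bad], collapse = ", "))
  data.frame(
    mode = ifelse(vapply(m, `[`, character(1), 2L) == "POS",
                  "positive", "negative"),
    mz   = as.numeric(vapply(m, `[`, character(1), 3L)),
    name = names, stringsAsFactors = FALSE)
}

#' Co-register positive- and negative-mode pixel grids
#'
#' Dual-polarity acquisitions interleave the two rasters with a spatial
#' offset (50 um on a 100 um pitch in the targeted acquisitions).  Each
#' positive pixel is paired with its mutually nearest negative pixel
#' after shifting the positive raster by `offset_um`; mutual
#' nearest-neighbour pairing makes the operation symmetric under
#' swapping the arguments and negating the offset.  Unpaired pixels are
#' dropped and reported in the `dropped` attribute.
#'
#' @param pos,neg [peak_matrix()] objects for the two polarities, on
#'   grids of equal spacing.
#' @param offset_um Numeric `(dx, dy)` offset of the negative raster
#'   relative to the positive one, in micrometers; magnitude of each
#'   component must be below the pixel pitch.
#' @param normalize If `TRUE` (default), each mode is TIC-normalized
#'   per pixel (to the mode's median total intensity) before
#'   concatenation, since ionization efficiency differs between modes.
#' @return A joint [peak_matrix()] on the positive grid's paired pixels,
#'   with `POS_` features followed by `NEG_` features, and attributes
#'   `pairs` (index map, `pos` always indexing the positive-mode
#'   matrix) and `dropped` (unpaired pixel counts).
#' @export
coregister_modes <- function(pos, neg, offset_um = c(50, 50),
                             normalize = TRUE) {
  stopifnot(inherits(pos, "peak_matrix"), inherits(neg, "peak_matrix"))
  # canonicalize by polarity so the operation is symmetric under
  # swapping the arguments and negating the offset
  if (pos$features$mode[1] == "negative" &&
      neg$features$mode[1] == "positive") {
    tmp <- pos; pos <- neg; neg <- tmp
    offset_um <- -offset_um
  }
  sp <- grid_spacing(pos$grid)
  if (!isTRUE(all.equal(sp, grid_spacing(neg$grid))))
    stop("grids must share pixel spacing")
  if (any(abs(offset_um) >= sp))
    stop("offset magnitude must be below the pixel spacing")
  # physical coordinates in um; positive raster shifted by the offset
  pu <- cbind(pos$grid$x * sp + offset_um[1], pos$grid$y * sp + offset_um[2])
  nu <- cbind(neg$grid$x * sp, neg$grid$y * sp)
  nn_p <- .nearest_index(pu, nu, neg$grid)   # for each pos pixel
  d <- sqrt(rowSums((pu - nu[nn_p, , drop = FALSE])^2))
  # a pair survives if it is within one pixel pitch and its negative
  # pixel has no strictly closer positive partner
  dmin_neg <- rep(Inf, nrow(nu))
  for (i in seq_along(nn_p))
    dmin_neg[nn_p[i]] <- min(dmin_neg[nn_p[i]], d[i])
  keep <- which(d <= sp & d <= dmin_neg[nn_p] + 1e-9)
  if (length(keep) == 0L)
    stop("disjoint grids: no pixel pair within one pixel spacing")
  ip <- keep; in_ <- nn_p[keep]
  vp <- pos$values[ip, , drop = FALSE]
  vn <- neg$values[in_, , drop = FALSE]
  if (normalize) {
    vp <- .tic_scale_rows(vp)
    vn <- .tic_scale_rows(vn)
  }
  feats <- rbind(pos$features, neg$features)
  jg <- pixel_grid(pos$grid$x[ip], pos$grid$y[ip], spacing_um = sp)
  jm <- peak_matrix(jg, feats, cbind(vp, vn))
  attr(jm, "pairs") <- data.frame(pos = ip, neg = in_)
  attr(jm, "dropped") <- c(pos = nrow(pos$grid) - length(ip),
                           neg = nrow(neg$grid) - length(ip))
  jm
}

# nearest row of `to` for each row of `from` (um coordinates);
# ties broken by lowest (y, x) of the candidate pixel
.nearest_index <- function(from, to, to_grid) {
  ord <- order(to_grid$y, to_grid$x)
  vapply(seq_len(nrow(from)), function(i) {
    d2 <- (to[, 1] - from[i, 1])^2 + (to[, 2] - from[i, 2])^2
    cand <- which(d2 == min(d2))
    if (length(cand) > 1L) cand <- cand[which.min(match(cand, ord))]
    cand
  }, integer(1))
}

.tic_scale_rows <- function(v, target = NULL) {
  tic <- rowSums(v)
  if (any(tic <= 0)) stop("cannot TIC-normalize a pixel with zero total intensity")
  if (is.null(target)) target <- stats::median(tic)
  v * (target / tic)
}

#' TIC-normalize a peak matrix
#'
#' Scales every pixel row so its total intensity equals `target`
#' (default: the matrix's median row total).  Applied before
#' segmentation and classification so pixel-to-pixel ion-yield
#' variation does not drive the clustering.
#'
#' @param pm A [peak_matrix()].
#' @param target Per-pixel total-intensity target, or `NULL` for the
#'   median raw TIC.
#' @return The normalized [peak_matrix()].
#' @export
tic_normalize_matrix <- function(pm, target = NULL) {
  stopifnot(inherits(pm, "peak_matrix"))
  peak_matrix(pm$grid, pm$features, .tic_scale_rows(pm$values, target))
}
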