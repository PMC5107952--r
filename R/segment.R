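# Spatially-aware k-means segmentation of MSI peak matrices.
#
# The spatial variant maps each pixel to its feature vector concatenated
# with the Gaussian-weighted vectors of every grid neighbour within
# Chebyshev radius r (weight w(di,dj) = exp(-(di^2+dj^2)/(2*sigma^2)),
# sigma = r/2; neighbours off the tissue are zero-padded), then runs
# standard k-means on the augmented vectors.  Neighbouring pixels thus
# pull each other toward the same cluster, producing spatially coherent
# segments; r = 0 reduces exactly to plain k-means.

# squared Euclidean distances between rows of X and rows of C
.dist2 <- function(X, C) {
  outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
}

# k-means++ seeding
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- .dist2(X, centers[1, , drop = FALSE])[, 1]
  if (k > 1L) for (j in 2:k) {
    p <- pmax(d2, 0)
    idx <- if (sum(p) > 0) sample.int(n, 1L, prob = p) else sample.int(n, 1L)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, .dist2(X, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

# Lloyd iterations with empty clusters re-seeded at the farthest point
.lloyd <- function(X, centers, max_iter = 100L, tol = 1e-10) {
  k <- nrow(centers)
  assign_prev <- rep(-1L, nrow(X))
  inertia <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(X, centers)
    a <- max.col(-d2, ties.method = "first")
    for (j in which(tabulate(a, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(X)), a)])
      centers[j, ] <- X[far, ]
      a[far] <- j
    }
    inertia_new <- sum(d2[cbind(seq_len(nrow(X)), a)])
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[a == j, , drop = FALSE])
    if (all(a == assign_prev) || (inertia - inertia_new) <= tol * inertia_new) {
      assign_prev <- a; inertia <- inertia_new; break
    }
    assign_prev <- a; inertia <- inertia_new
  }
  # final inertia against the updated centers
  d2 <- .dist2(X, centers)
  a <- max.col(-d2, ties.method = "first")
  list(cluster = a, centers = centers,
       inertia = sum(d2[cbind(seq_len(nrow(X)), a)]))
}

.kmeans_pp <- function(X, k, seed, restarts = 10L) {
  best <- NULL
  set.seed(seed)
  for (r in seq_len(restarts)) {
    fit <- .lloyd(X, .kmeanspp_init(X, k))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

# Gaussian-weighted neighbourhood augmentation
.augment_spatial <- function(values, grid, r) {
  if (r == 0L) return(values)
  sigma <- r / 2
  key <- paste(grid$x, grid$y)
  lookup <- seq_len(nrow(grid))
  names(lookup) <- key
  blocks <- list()
  for (dj in -r:r) for (di in -r:r) {
    w <- exp(-(di^2 + dj^2) / (2 * sigma^2))
    if (di == 0L && dj == 0L) { blocks[[length(blocks) + 1L]] <- values; next }
    nb <- lookup[paste(grid$x + di, grid$y + dj)]
    block <- matrix(0, nrow(values), ncol(values))
    ok <- !is.na(nb)
    block[ok, ] <- values[nb[ok], , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- w * block
  }
  do.call(cbind, blocks)
}

#' Spatially-aware k-means segmentation
#'
#' Segments a peak matrix into `k` molecular clusters, using
#' neighbourhood-augmented feature vectors within pixel radius `r` so
#' that clusters form spatially coherent regions.  Intensities are
#' log-transformed (`log1p`) before clustering by default, which
#' stabilizes the multiplicative intensity variation typical of MALDI
#' data; clustering runs k-means++-seeded Lloyd iterations with the
#' best of `restarts` restarts kept (empty clusters re-seeded at the
#' farthest point).  Defaults `k = 7`, `r = 1` match the segmentation
#' settings of the lipid imaging workflow this package implements.
#'
#' @param pm A [peak_matrix()].
#' @param k Number of clusters (default 7).
#' @param r Neighbourhood pixel radius (default 1); `r = 0` is plain
#'   k-means.
#' @param seed RNG seed controlling the whole restart ensemble.
#' @param restarts Number of k-means restarts (default 10).
#' @param transform `"log1p"` (default) or `"none"`.
#' @return An object of class `segmentation_map`: list with `grid`,
#'   integer `cluster` per pixel (0-based, contiguous), `k`, `r`,
#'   `seed`, and final within-cluster sum of squares `inertia`.
#' @export
spatially_aware_segment <- function(pm, k = 7L, r = 1L, seed = 1L,
                                    restarts = 10L,
                                    transform = c("log1p", "none")) {
  stopifnot(inherits(pm, "peak_matrix"))
  transform <- match.arg(transform)
  k <- as.integer(k); r <- as.integer(r)
  if (k < 2L) stop("k must be >= 2")
  if (r < 0L) stop("r must be >= 0")
  n <- nrow(pm$values)
  if (n == 0L) stop("empty peak matrix")
  if (k > n) stop("k exceeds the number of pixels")
  X <- if (transform == "log1p") log1p(pm$values) else pm$values
  Xa <- .augment_spatial(X, pm$grid, r)
  fit <- .kmeans_pp(Xa, k, seed = seed, restarts = restarts)
  # relabel clusters contiguously by first appearance
  relabel <- match(fit$cluster, unique(fit$cluster)) - 1L
  structure(list(grid = pm$grid, cluster = relabel, k = k, r = r,
                 seed = seed, inertia = fit$inertia),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d pixels, k=%d, r=%d, inertia=%.4g\n",
              length(x$cluster), x$k, x$r, x$inertia))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Map segmentation clusters to histology labels
#'
#' Correlates a molecular segmentation with a per-pixel histology
#' annotation: each cluster is assigned the label holding the plurality
#' of its annotated pixels, with the per-cluster agreement fraction and
#' the full contingency table reported.  Clusters containing no
#' annotated pixel map to `mucin_matrix` (off-tissue by default) with
#' agreement `NA`.
#'
#' @param seg A `segmentation_map`.
#' @param annotation Character vector of histology labels (one per
#'   pixel, `NA` = unannotated), aligned with the segmentation grid.
#' @return An object of class `segment_histology_mapping`: list with
#'   `mapping` (named character: cluster id -> label), `agreement`
#'   (named numeric), and `contingency` (clusters x labels table).
#' @export
map_segments_to_histology <- function(seg, annotation) {
  stopifnot(inherits(seg, "segmentation_map"))
  if (length(annotation) != length(seg$cluster))
    stop("annotation length must match the segmentation grid")
  .assert_histology(annotation, allow_na = TRUE)
  cl <- factor(seg$cluster, levels = 0:(seg$k - 1L))
  ann <- factor(annotation, levels = histology_labels())
  tab <- table(cluster = cl, label = ann)
  mapping <- character(seg$k); agreement <- numeric(seg$k)
  for (j in seq_len(seg$k)) {
    row <- tab[j, ]
    if (sum(row) == 0L) {
      mapping[j] <- "mucin_matrix"; agreement[j] <- NA_real_
    } else {
      mapping[j] <- names(row)[which.max(row)]
      agreement[j] <- max(row) / sum(row)
    }
  }
  names(mapping) <- names(agreement) <- levels(cl)
  structure(list(mapping = mapping, agreement = agreement,
                 contingency = tab),
            class = "segment_histology_mapping")
}

#' Per-pixel histology labels implied by a segment-histology mapping
#'
#' @param seg A `segmentation_map`.
#' @param mapping A `segment_histology_mapping`.
#' @return Character vector of histology labels, one per pixel.
#' @export
segment_labels <- function(seg, mapping) {
  stopifnot(inherits(seg, "segmentation_map"),
            inherits(mapping, "segment_histology_mapping"))
  unname(mapping$mapping[as.character(seg$cluster)])
}

#' Modal (majority) spatial filter for a label map
#'
#' Replaces each pixel's label by the most frequent label in its
#' Chebyshev neighbourhood of radius `r` (the pixel included, ties
#' broken toward the first label encountered).  A standard
#' post-classification cleanup: per-pixel classification errors are
#' spatially isolated while true histology regions are contiguous, so
#' one modal pass removes most speckle.
#'
#' @param labels Character label per pixel.
#' @param grid The [pixel_grid()] the labels live on.
#' @param r Neighbourhood radius in pixels (default 1, i.e. 3x3).
#' @return The filtered label vector.
#' @export
spatial_majority_filter <- function(labels, grid, r = 1L) {
  stopifnot(inherits(grid, "pixel_grid"),
            length(labels) == nrow(grid))
  r <- as.integer(r)
  if (r < 1L) return(labels)
  key <- paste(grid$x, grid$y)
  lookup <- seq_len(nrow(grid))
  names(lookup) <- key
  lv <- unique(labels)
  counts <- matrix(0L, length(labels), length(lv))
  for (di in -r:r) for (dj in -r:r) {
    nb <- lookup[paste(grid$x + di, grid$y + dj)]
    ok <- !is.na(nb)
    idx <- cbind(which(ok), match(labels[nb[ok]], lv))
    counts[idx] <- counts[idx] + 1L
  }
  lv[max.col(counts, ties.method = "first")]
}

#' Plot a segmentation or label map
#'
#' Renders per-pixel labels as an image in the standard display palette
#' (liver blue, tumor red, necrosis purple, fibrosis grey, inflammation
#' green, mucin/matrix white).
#'
#' @param grid A [pixel_grid()].
#' @param labels Character histology labels per pixel.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_label_map <- function(grid, labels, ...) {
  .assert_histology(labels, allow_na = TRUE)
  lv <- histology_labels()
  w <- max(grid$x) + 1L; h <- max(grid$y) + 1L
  m <- matrix(NA_integer_, w, h)
  m[cbind(grid$x + 1L, grid$y + 1L)] <- match(labels, lv)
  graphics::image(x = seq_len(w), y = seq_len(h), z = m,
                  col = unname(histology_palette()), zlim = c(1, length(lv)),
                  xlab = "x", ylab = "y", useRaster = TRUE, ...)
  invisible(m)
}
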