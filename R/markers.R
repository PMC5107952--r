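# Univariate marker discovery: per-feature, per-histology ROC area and
# fold change, ranked into marker tables.

#' Rank-based ROC area under the curve
#'
#' The probability that a random target-pixel intensity exceeds a random
#' rest-pixel intensity, plus half the tie probability — the
#' Mann-Whitney concordance, computed from midranks.  1 means perfect
#' separation, 0.5 none.
#'
#' @param target,rest Non-empty numeric intensity samples.
#' @return The a.u.c. in `[0, 1]`.
#' @export
roc_auc <- function(target, rest) {
  if (length(target) == 0L || length(rest) == 0L)
    stop("both samples must be non-empty")
  r <- rank(c(target, rest))
  nt <- length(target); nr <- length(rest)
  (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (nt * nr)
}

#' Seeded stratified sample of rest-class pixels
#'
#' For a one-vs-rest comparison, draws a random subset of non-target
#' pixels of size `min(n_target, n_rest)`, stratified equally across the
#' other histologies so that no single histology dominates the rest
#' sample — markers that merely separate one other histology from the
#' remainder are thereby penalized.
#'
#' @param labels Character histology label per pixel (`NA` ignored).
#' @param target The target label.
#' @param seed RNG seed.
#' @return Integer vector of pixel indices into `labels`.
#' @export
sample_rest_pixels <- function(labels, target, seed = 1L) {
  idx_t <- which(!is.na(labels) & labels == target)
  idx_r <- which(!is.na(labels) & labels != target)
  if (length(idx_t) == 0L) stop("target class is empty")
  if (length(idx_r) == 0L) stop("no non-target pixels")
  m <- min(length(idx_t), length(idx_r))
  classes <- unique(labels[idx_r])
  set.seed(seed)
  if (m == length(idx_r)) return(sort(idx_r))
  # equal per-class quotas; classes too small to fill theirs give the
  # remainder back to the larger classes
  sizes <- vapply(classes, function(cl) sum(labels[idx_r] == cl), integer(1))
  quota <- rep(0L, length(classes))
  left <- m
  open <- rep(TRUE, length(classes))
  while (left > 0L && any(open & sizes > quota)) {
    share <- max(1L, left %/% sum(open))
    for (ci in order(sizes)) {
      if (!open[ci] || left == 0L) next
      add <- min(share, sizes[ci] - quota[ci], left)
      quota[ci] <- quota[ci] + add
      left <- left - add
      if (quota[ci] == sizes[ci]) open[ci] <- FALSE
    }
  }
  out <- integer(0)
  for (ci in seq_along(classes)) {
    pool <- which(labels == classes[ci])
    out <- c(out, if (quota[ci] >= length(pool)) pool else
      sample(pool, quota[ci]))
  }
  sort(out)
}

#' Fold change of a feature in one histology vs the rest
#'
#' Per sample, the ratio of the mean target-pixel intensity to the mean
#' rest-pixel intensity; reported as mean and standard deviation of the
#' per-sample ratios.  With one sample the sd is 0 and the result is
#' flagged via the `single_sample` attribute.
#'
#' @param pm A [peak_matrix()] (or plain intensity matrix with named
#'   columns).
#' @param labels Character histology label per pixel.
#' @param feature Feature name (column).
#' @param target Target histology label.
#' @param by_sample Optional character sample id per pixel.
#' @param rest_idx Optional explicit rest-pixel indices (defaults to all
#'   non-target pixels).
#' @return Numeric `c(mean, sd)` with attribute `single_sample`.
#' @export
fold_change <- function(pm, labels, feature, target, by_sample = NULL,
                        rest_idx = NULL) {
  vals <- if (inherits(pm, "peak_matrix")) pm$values else as.matrix(pm)
  v <- vals[, feature]
  idx_t <- which(!is.na(labels) & labels == target)
  idx_r <- if (is.null(rest_idx))
    which(!is.na(labels) & labels != target) else rest_idx
  if (length(idx_t) == 0L || length(idx_r) == 0L)
    stop("target and rest pixels must both exist")
  if (is.null(by_sample)) by_sample <- rep("sample1", length(labels))
  samples <- unique(by_sample[c(idx_t, idx_r)])
  ratios <- numeric(0)
  for (s in samples) {
    ti <- idx_t[by_sample[idx_t] == s]
    ri <- idx_r[by_sample[idx_r] == s]
    if (length(ti) == 0L || length(ri) == 0L) next
    mr <- mean(v[ri])
    if (mr == 0) stop("rest mean is zero for sample ", s)
    ratios <- c(ratios, mean(v[ti]) / mr)
  }
  if (length(ratios) == 0L) stop("no sample contains both target and rest pixels")
  out <- c(mean = mean(ratios),
           sd = if (length(ratios) > 1L) stats::sd(ratios) else 0)
  attr(out, "single_sample") <- length(ratios) == 1L
  out
}

#' Ranked discriminant-marker table
#'
#' For every feature and histology, computes the ROC a.u.c. of the
#' feature's intensity in that histology against a seeded stratified
#' rest sample ([sample_rest_pixels()]), plus the fold change vs all
#' rest pixels; per histology the `top_n` features by a.u.c. are
#' returned — the analogue of a top-marker table.
#'
#' @param pm A [peak_matrix()].
#' @param labels Character histology label per pixel.
#' @param top_n Markers per histology (default 14).
#' @param seed RNG seed for the rest subsets.
#' @param by_sample Optional sample id per pixel for the fold-change
#'   dispersion.
#' @return data.frame with columns `topography`, `feature`,
#'   `fold_change_mean`, `fold_change_sd`, `auc`, sorted by topography
#'   then descending a.u.c.
#' @export
rank_markers <- function(pm, labels, top_n = 14L, seed = 1L,
                         by_sample = NULL) {
  vals <- if (inherits(pm, "peak_matrix")) pm$values else as.matrix(pm)
  present <- unique(labels[!is.na(labels)])
  if (length(present) < 2L) stop("need at least 2 histologies")
  out <- list()
  for (hi in seq_along(present)) {
    h <- present[hi]
    rest <- sample_rest_pixels(labels, h, seed = seed + hi)
    idx_t <- which(!is.na(labels) & labels == h)
    aucs <- apply(vals, 2, function(col) roc_auc(col[idx_t], col[rest]))
    keep <- utils::head(order(aucs, decreasing = TRUE), top_n)
    fc <- vapply(colnames(vals)[keep], function(f) {
      fold_change(vals, labels, f, h, by_sample = by_sample)
    }, numeric(2))
    out[[h]] <- data.frame(
      topography = h, feature = colnames(vals)[keep],
      fold_change_mean = fc["mean", ], fold_change_sd = fc["sd", ],
      auc = aucs[keep], row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
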