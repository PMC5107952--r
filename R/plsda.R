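# PLS-DA histology classification.
#
# Labels are one-hot encoded and regressed on the (centered, optionally
# unit-scaled) peak intensities by NIPALS PLS2; pixels are assigned the
# class with the highest predicted indicator score.  With the number of
# latent components equal to the rank of X the fitted scores coincide
# with ordinary least squares on the indicator matrix; with fewer
# components the latent directions regularize the fit, which is what
# makes PLS-DA usable on strongly collinear spectral data.

#' Build a labelled spectral library
#'
#' Pools the pixels of one or more segmented samples whose cluster has a
#' histology mapping into a single labelled training matrix.  Features
#' are intersected by name across samples (order of the first sample
#' preserved).
#'
#' @param datasets List of lists, each with elements `pm`
#'   ([peak_matrix()]), `seg` (`segmentation_map`), `mapping`
#'   (`segment_histology_mapping`), and optional `sample_id`.
#'   Alternatively `pm` plus `labels` (character per pixel) is accepted.
#' @param exclude_matrix Drop `mucin_matrix` rows (default `FALSE`; the
#'   default classifier keeps the class so off-tissue pixels are
#'   recognized rather than misassigned).
#' @return An object of class `spectral_library`: list with `features`,
#'   matrix `X`, character `labels`, and `sample_id` per row.
#' @export
build_spectral_library <- function(datasets, exclude_matrix = FALSE) {
  if (length(datasets) == 0L) stop("no datasets supplied")
  feats <- lapply(datasets, function(d) d$pm$features$name)
  common <- Reduce(intersect, feats)
  if (length(common) == 0L) stop("empty intersection of feature sets")
  common <- feats[[1]][feats[[1]] %in% common]  # first sample's order
  rows <- list(); labels <- character(0); sample_id <- character(0)
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    lab <- if (!is.null(d$labels)) d$labels else
      segment_labels(d$seg, d$mapping)
    .assert_histology(lab, allow_na = TRUE)
    keep <- !is.na(lab)
    if (exclude_matrix) keep <- keep & lab != "mucin_matrix"
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <-
      d$pm$values[keep, common, drop = FALSE]
    labels <- c(labels, lab[keep])
    sid <- if (!is.null(d$sample_id)) d$sample_id else paste0("sample", i)
    sample_id <- c(sample_id, rep(sid, sum(keep)))
  }
  if (length(labels) == 0L) stop("zero labelled pixels")
  X <- do.call(rbind, rows)
  fidx <- match(common, datasets[[1]]$pm$features$name)
  structure(list(features = datasets[[1]]$pm$features[fidx, , drop = FALSE],
                 X = X, labels = labels, sample_id = sample_id),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d pixels x %d features\n",
              nrow(x$X), ncol(x$X)))
  print(table(x$labels))
  invisible(x)
}

#' Train a PLS-DA classifier
#'
#' Fits NIPALS PLS2 regression of the one-hot class indicators on the
#' column-centered (optionally unit-scaled) intensity matrix.  The fit
#' is deterministic given its inputs and invariant to row order.
#'
#' @param lib A [build_spectral_library()] result, or any list with
#'   `X`, `labels` and `features`.
#' @param n_components Number of latent components `A`; must satisfy
#'   `1 <= A <= min(n_features, n_rows - 1)`.
#' @param scale Unit-variance scaling of the columns (default `FALSE`:
#'   TIC-normalized intensities already share a scale).
#' @param transform `"none"` (default) or `"log1p"`: intensity
#'   transform applied before centering, stored in the model and
#'   re-applied at prediction time.  The log transform stabilizes the
#'   multiplicative intensity noise of MALDI data.
#' @return An object of class `plsda_model` with centering/scaling
#'   vectors, weight/loading matrices, the regression coefficients, and
#'   `class_order`.
#' @export
train_plsda <- function(lib, n_components = 2L, scale = FALSE,
                        transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  X <- as.matrix(lib$X)
  if (transform == "log1p") X <- log1p(X)
  labels <- lib$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  A <- as.integer(n_components)
  if (A < 1L || A > min(ncol(X), nrow(X) - 1L))
    stop("n_components out of rank bounds")
  Y <- outer(labels, classes, "==") * 1
  x_mean <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, stats::sd); s[s == 0] <- 1; s
  } else rep(1, ncol(X))
  y_mean <- colMeans(Y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  Yc <- sweep(Y, 2, y_mean)
  p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, A); P <- matrix(0, p, A); C <- matrix(0, q, A)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(A)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, nrow(Xd))
    for (it in seq_len(500L)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      t_ <- Xd %*% w
      cc <- crossprod(Yd, t_) / sum(t_^2)
      u <- Yd %*% cc / sum(cc^2)
      if (sum((t_ - t_old)^2) < 1e-12 * sum(t_^2)) break
      t_old <- t_
    }
    t_ <- Xd %*% w
    pp <- crossprod(Xd, t_) / sum(t_^2)
    cc <- crossprod(Yd, t_) / sum(t_^2)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc
    Xd <- Xd - t_ %*% t(pp)
    Yd <- Yd - t_ %*% t(cc)
  }
  B <- W %*% solve(crossprod(P, W), t(C))
  structure(list(n_components = A, transform = transform,
                 features = lib$features,
                 feature_names = lib$features$name,
                 x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = C,
                 coefficients = B, class_order = classes),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components, %d features, classes: %s\n",
              x$n_components, length(x$feature_names),
              paste(x$class_order, collapse = ", ")))
  invisible(x)
}

.plsda_scores <- function(model, values) {
  if (identical(model$transform, "log1p")) values <- log1p(values)
  Xc <- sweep(sweep(values, 2, model$x_mean), 2, model$x_scale, "/")
  scores <- Xc %*% model$coefficients
  scores <- sweep(scores, 2, model$y_mean, "+")
  colnames(scores) <- model$class_order
  scores
}

#' Predict per-pixel histology with a PLS-DA model
#'
#' Each pixel is assigned the class whose predicted indicator score is
#' largest; ties break toward the earlier class in `class_order`.
#'
#' @param model A [train_plsda()] model.
#' @param pm A [peak_matrix()] whose features include the model's
#'   (matched by name; extra features are ignored).
#' @return An object of class `histology_prediction`: list with
#'   character `labels` per pixel, numeric `scores` matrix, and `grid`.
#' @export
predict_histology <- function(model, pm) {
  stopifnot(inherits(model, "plsda_model"), inherits(pm, "peak_matrix"))
  missing <- setdiff(model$feature_names, pm$features$name)
  if (length(missing))
    stop("peak matrix lacks model feature(s): ",
         paste(missing, collapse = ", "))
  vals <- pm$values[, model$feature_names, drop = FALSE]
  scores <- .plsda_scores(model, vals)
  idx <- max.col(scores, ties.method = "first")
  structure(list(labels = model$class_order[idx], scores = scores,
                 grid = pm$grid),
            class = "histology_prediction")
}

#' Choose the number of PLS-DA components by cross-validation
#'
#' Stratified k-fold cross-validated accuracy for each candidate `A`;
#' the smallest candidate whose mean accuracy is within one standard
#' error of the best is chosen.
#'
#' @param lib A spectral library.
#' @param candidates Integer vector of candidate component counts
#'   (default `2:10`, clipped to the rank bound).
#' @param folds Number of folds (default 5).
#' @param seed RNG seed for the fold split.
#' @param scale,transform Passed to [train_plsda()].
#' @return List with `chosen`, and a data.frame `accuracy` of
#'   per-candidate mean/se.
#' @export
cross_validate_components <- function(lib, candidates = 2:10, folds = 5L,
                                      seed = 1L, scale = FALSE,
                                      transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  if (length(candidates) == 0L) stop("no candidates supplied")
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  n <- nrow(lib$X)
  max_a <- min(ncol(lib$X), n - ceiling(n / folds) - 1L)
  candidates <- sort(unique(pmin(as.integer(candidates), max_a)))
  if (min(table(lib$labels)) < folds)
    stop("every class needs at least `folds` rows")
  set.seed(seed)
  fold_id <- integer(n)
  for (cl in unique(lib$labels)) {
    idx <- which(lib$labels == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  acc <- matrix(NA_real_, length(candidates), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    sub <- list(X = lib$X[tr, , drop = FALSE], labels = lib$labels[tr],
                features = lib$features)
    te_pm <- list(values = lib$X[!tr, , drop = FALSE],
                  features = lib$features)
    for (ai in seq_along(candidates)) {
      m <- train_plsda(sub, n_components = candidates[ai], scale = scale,
                       transform = transform)
      sc <- .plsda_scores(m, te_pm$values[, m$feature_names, drop = FALSE])
      pred <- m$class_order[max.col(sc, ties.method = "first")]
      acc[ai, f] <- mean(pred == lib$labels[!tr])
    }
  }
  mean_acc <- rowMeans(acc)
  se_acc <- apply(acc, 1, stats::sd) / sqrt(folds)
  best <- which.max(mean_acc)
  ok <- mean_acc >= mean_acc[best] - se_acc[best]
  chosen <- candidates[min(which(ok))]
  list(chosen = chosen,
       accuracy = data.frame(n_components = candidates,
                             mean = mean_acc, se = se_acc))
}

#' Serialize / restore a PLS-DA model as portable JSON
#'
#' @param model A `plsda_model`.
#' @param path Output/input file path.
#' @return `path` invisibly for save; the model for load.
#' @export
save_plsda_model <- function(model, path) {
  stopifnot(inherits(model, "plsda_model"))
  obj <- model
  class(obj) <- NULL
  obj$features <- as.list(obj$features)
  for (nm in c("weights", "x_loadings", "y_loadings", "coefficients"))
    obj[[nm]] <- list(dim = dim(model[[nm]]), data = as.numeric(model[[nm]]))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_plsda_model
#' @export
load_plsda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("weights", "x_loadings", "y_loadings", "coefficients"))
    obj[[nm]] <- matrix(obj[[nm]]$data, obj[[nm]]$dim[1], obj[[nm]]$dim[2])
  obj$features <- as.data.frame(obj$features, stringsAsFactors = FALSE)
  obj$n_components <- as.integer(obj$n_components)
  structure(obj, class = "plsda_model")
}
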