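# toy library: two classes separated in one feature, constant elsewhere
toy_library <- function(n_per = 6L, seed = 31L) {
  set.seed(seed)
  X <- cbind(c(rep(10, n_per), rep(0, n_per)) + rnorm(2 * n_per, 0, 0.1),
             abs(rnorm(2 * n_per)), abs(rnorm(2 * n_per)))
  X <- pmax(X, 0)
  colnames(X) <- c("POS_600.10", "POS_700.10", "POS_800.10")
  list(X = X, labels = rep(c("tumor", "fibrosis"), each = n_per),
       features = feature_table(rep("positive", 3),
                                c(600.1, 700.1, 800.1)))
}

test_that("spectral library pooling preserves counts and feature intersection", {
  tb1 <- two_block_pm(noise_sd = 0.2, seed = 41)
  tb2 <- two_block_pm(noise_sd = 0.2, seed = 42)
  lab <- function(tb) c("tumor", "fibrosis")[tb$truth]
  lib <- build_spectral_library(list(
    list(pm = tb1$pm, labels = lab(tb1), sample_id = "a"),
    list(pm = tb2$pm, labels = lab(tb2), sample_id = "b")))
  expect_equal(nrow(lib$X), 288L)
  expect_equal(unname(table(lib$labels)["tumor"]),
               sum(tb1$truth == 1) + sum(tb2$truth == 1))
  expect_error(build_spectral_library(list(
    list(pm = tb1$pm, labels = rep(NA_character_, 144)))),
    "zero labelled")
})

test_that("a one-feature separable problem is solved with one component", {
  lib <- toy_library()
  m <- train_plsda(lib, n_components = 1)
  pm <- make_pm(lib$X, rep("positive", 3), c(600.1, 700.1, 800.1),
                w = 12, h = 1)
  pred <- predict_histology(m, pm)
  expect_identical(pred$labels, lib$labels)
})

test_that("full-component PLS-DA equals the least-squares oracle", {
  # 6 x 4 toy matrix of full column rank
  set.seed(32)
  X <- matrix(abs(rnorm(24, 5, 2)), 6, 4)
  colnames(X) <- feature_name(rep("positive", 4), c(500, 600, 700, 800) + 0.1)
  labels <- c("tumor", "tumor", "fibrosis", "fibrosis",
              "inflammation", "inflammation")
  lib <- list(X = X, labels = labels,
              features = feature_table(rep("positive", 4),
                                       c(500, 600, 700, 800) + 0.1))
  m <- train_plsda(lib, n_components = 4)
  got <- msigrade:::.plsda_scores(m, X)
  # oracle: normal equations on centered data
  classes <- sort(unique(labels))
  Y <- outer(labels, classes, "==") * 1
  Xc <- scale(X, scale = FALSE)
  B <- solve(crossprod(Xc), crossprod(Xc, scale(Y, scale = FALSE)))
  want <- Xc %*% B + matrix(colMeans(Y), 6, 3, byrow = TRUE)
  expect_equal(unname(got), unname(want), tolerance = 1e-8)
})

test_that("prediction is invariant to feature translation and row order", {
  lib <- toy_library()
  m1 <- train_plsda(lib, n_components = 2)
  shifted <- lib
  shifted$X[, 2] <- shifted$X[, 2] + 100
  m2 <- train_plsda(shifted, n_components = 2)
  s1 <- msigrade:::.plsda_scores(m1, lib$X)
  s2 <- msigrade:::.plsda_scores(m2, shifted$X)
  expect_equal(s1, s2, tolerance = 1e-8)

  perm <- sample(nrow(lib$X))
  permuted <- list(X = lib$X[perm, ], labels = lib$labels[perm],
                   features = lib$features)
  m3 <- train_plsda(permuted, n_components = 2)
  expect_equal(msigrade:::.plsda_scores(m3, lib$X), s1, tolerance = 1e-8)
})

test_that("PLS-DA agrees with an independent implementation on a toy problem", {
  lib <- toy_library(n_per = 10L, seed = 33L)
  m <- train_plsda(lib, n_components = 2)
  ref <- mixOmics::plsda(lib$X, factor(lib$labels), ncomp = 2,
                         scale = FALSE)
  pred_ref <- predict(ref, lib$X)$class$max.dist[, 2]
  pm <- make_pm(lib$X, rep("positive", 3), c(600.1, 700.1, 800.1),
                w = 20, h = 1)
  expect_identical(unname(predict_histology(m, pm)$labels),
                   unname(pred_ref))
})

test_that("component cross-validation applies the one-standard-error rule", {
  lib <- toy_library(n_per = 15L)
  single <- cross_validate_components(lib, candidates = 1, folds = 3,
                                      seed = 1)
  expect_equal(single$chosen, 1L)
  # separable: all candidates reach accuracy 1, so the 1-SE rule forces
  # the smallest
  cv <- cross_validate_components(lib, candidates = 1:3, folds = 3,
                                  seed = 1)
  expect_equal(cv$chosen, 1L)
  expect_true(all(cv$accuracy$mean == 1))
  cv2 <- cross_validate_components(lib, candidates = 1:3, folds = 3,
                                   seed = 1)
  expect_identical(cv$accuracy, cv2$accuracy)
})

test_that("prediction errors name missing features", {
  lib <- toy_library()
  m <- train_plsda(lib, n_components = 1)
  pm <- make_pm(lib$X[, 1:2], rep("positive", 2), c(600.1, 700.1),
                w = 12, h = 1)
  expect_error(predict_histology(m, pm), "POS_800.10")
})

test_that("necrosis subtyping separates UN from ILN at published fold changes", {
  # two-class matrix built from the signature table's UN and ILN rows
  sig <- default_signature_table()
  set.seed(34)
  n <- 400L
  labels <- rep(c("usual_necrosis", "infarct_like_necrosis"), each = n)
  base <- sig$signatures[labels, , drop = FALSE]
  X <- base * matrix(exp(rnorm(length(base), 0, 0.944)), nrow(base))
  colnames(X) <- colnames(sig$signatures)
  lib <- list(X = X, labels = labels, features = sig$features)
  m <- train_plsda(lib, n_components = 2, transform = "log1p")
  sc <- msigrade:::.plsda_scores(m, X)
  pred <- m$class_order[max.col(sc, ties.method = "first")]
  expect_gte(mean(pred == labels), 0.9)
})

test_that("the multivariate model dominates any single-feature threshold", {
  truth <- generate_phantom(48, 48, seed = 51)
  pm <- tic_normalize_matrix(generate_peak_matrix(truth, seed = 52))
  lib <- list(X = pm$values, labels = truth$labels, features = pm$features)
  m <- train_plsda(lib, n_components = 8, transform = "log1p")
  sc <- msigrade:::.plsda_scores(m, pm$values)
  acc_pls <- mean(m$class_order[max.col(sc, ties.method = "first")] ==
                    truth$labels)
  # best achievable by thresholding one feature: predict the majority
  # class on each side of the best split
  best_single <- max(apply(pm$values, 2, function(v) {
    o <- order(v)
    lab <- truth$labels[o]
    n <- length(lab)
    cums <- sapply(unique(lab), function(cl) cumsum(lab == cl))
    tots <- colSums(cums[n, , drop = FALSE])[1]
    best <- 0
    tot_per <- cums[n, ]
    for (cut in seq_len(n - 1)) {
      acc <- (max(cums[cut, ]) + max(tot_per - cums[cut, ])) / n
      best <- max(best, acc)
    }
    best
  }))
  expect_gte(acc_pls, best_single)
})

test_that("model serialization round-trips predictions exactly", {
  lib <- toy_library()
  m <- train_plsda(lib, n_components = 2)
  path <- tempfile(fileext = ".json")
  save_plsda_model(m, path)
  m2 <- load_plsda_model(path)
  expect_equal(msigrade:::.plsda_scores(m2, lib$X),
               msigrade:::.plsda_scores(m, lib$X), tolerance = 1e-12)
})
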