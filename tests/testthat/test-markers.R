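test_that("roc_auc matches forced values and the pair-count oracle", {
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3)), 1.0)
  # brute force over all 4 pairs: (3>1), (3<4), (5>1), (5>4) -> 3/4
  expect_equal(roc_auc(c(3, 5), c(1, 4)), 0.75)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("roc_auc complementarity and monotone-transform invariance", {
  set.seed(61)
  for (i in 1:5) {
    a <- rlnorm(20); b <- rlnorm(25, 0.5)
    expect_equal(roc_auc(a, b) + roc_auc(b, a), 1)
    expect_equal(roc_auc(log(a), log(b)), roc_auc(a, b))
    expect_equal(roc_auc(sqrt(a), sqrt(b)), roc_auc(a, b))
  }
})

test_that("rank-based auc agrees with an independent ROC implementation", {
  set.seed(64)
  a <- rlnorm(40, 0.8)
  b <- rlnorm(35)
  ref <- pROC::auc(pROC::roc(response = c(rep(1, 40), rep(0, 35)),
                             predictor = c(a, b), quiet = TRUE,
                             direction = "<"))
  expect_equal(roc_auc(a, b), as.numeric(ref))
})

test_that("empirical auc converges to the closed binormal form", {
  # log-normal two-class model: auc -> Phi(dmu / (sigma * sqrt(2)))
  set.seed(62)
  n <- 2000L
  sigma <- 0.944
  dmu <- log(5.62)
  target <- exp(rnorm(n, dmu, sigma))
  rest <- exp(rnorm(n, 0, sigma))
  expect_equal(roc_auc(target, rest),
               pnorm(dmu / (sigma * sqrt(2))), tolerance = 0.02)
})

test_that("rest-pixel sampling is stratified, bounded and seeded", {
  labels <- rep(c("tumor", "fibrosis", "inflammation", "adjacent_liver"),
                c(30, 100, 100, 100))
  idx <- sample_rest_pixels(labels, "tumor", seed = 3)
  expect_length(idx, 30L)
  expect_equal(as.integer(table(labels[idx])), c(10L, 10L, 10L))
  expect_identical(sample_rest_pixels(labels, "tumor", seed = 3), idx)
  # n_target >= n_rest: everything comes back
  labels2 <- rep(c("tumor", "fibrosis"), c(50, 10))
  expect_identical(sample_rest_pixels(labels2, "tumor", seed = 1),
                   51:60)
  expect_error(sample_rest_pixels(rep("tumor", 5), "tumor"), "non-target")
})

test_that("fold change follows the per-sample mean-ratio definition", {
  vals <- matrix(c(10, 10, 2, 2), ncol = 1,
                 dimnames = list(NULL, "POS_700.10"))
  labels <- c("tumor", "tumor", "fibrosis", "fibrosis")
  fc <- fold_change(vals, labels, "POS_700.10", "tumor")
  expect_equal(as.numeric(fc), c(5, 0))
  expect_true(attr(fc, "single_sample"))
  # equal class means -> 1
  vals2 <- matrix(c(3, 3, 3, 3), ncol = 1,
                  dimnames = list(NULL, "POS_700.10"))
  expect_equal(fold_change(vals2, labels, "POS_700.10", "tumor")[["mean"]], 1)
  # two samples with per-sample ratios 4 and 6 -> 5 +/- sd(c(4, 6))
  vals3 <- matrix(c(8, 2, 12, 2), ncol = 1,
                  dimnames = list(NULL, "POS_700.10"))
  labels3 <- c("tumor", "fibrosis", "tumor", "fibrosis")
  fc3 <- fold_change(vals3, labels3, "POS_700.10", "tumor",
                     by_sample = c("s1", "s1", "s2", "s2"))
  expect_equal(as.numeric(fc3), c(5, sd(c(4, 6))))
  # zero rest mean is an error, not Inf
  vals4 <- matrix(c(1, 0), ncol = 1, dimnames = list(NULL, "POS_700.10"))
  expect_error(fold_change(vals4, c("tumor", "fibrosis"),
                           "POS_700.10", "tumor"), "zero")
})

test_that("marker ranking puts constructed discriminators first", {
  set.seed(63)
  n <- 60L
  labels <- rep(c("tumor", "fibrosis", "inflammation"), each = n)
  vals <- matrix(rlnorm(3 * n * 3), ncol = 3)
  colnames(vals) <- feature_name(rep("positive", 3),
                                 c(600.1, 700.1, 800.1))
  # make POS_700.10 a perfect tumor marker
  vals[labels == "tumor", 2] <- vals[labels == "tumor", 2] + 100
  tab <- rank_markers(vals, labels, top_n = 3, seed = 5)
  top_tumor <- tab$feature[tab$topography == "tumor"][1]
  expect_identical(top_tumor, "POS_700.10")
  expect_equal(tab$auc[tab$topography == "tumor"][1], 1.0)
  # single feature: trivially the top marker of every class
  tab1 <- rank_markers(vals[, 2, drop = FALSE], labels, top_n = 5,
                       seed = 5)
  expect_true(all(tab1$feature == "POS_700.10"))
  expect_error(rank_markers(vals, rep("tumor", 3 * n)), "2 histologies")
})

test_that("the default marker report has the published table's shape", {
  truth <- generate_phantom(48, 48, seed = 71)
  pm <- tic_normalize_matrix(generate_peak_matrix(truth, seed = 72))
  tab <- rank_markers(pm$values, truth$labels, seed = 1)
  expect_named(tab, c("topography", "feature", "fold_change_mean",
                      "fold_change_sd", "auc"))
  # 14 markers per histology present in the phantom
  expect_true(all(table(tab$topography) == 14L))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$fold_change_mean > 0))
  # the strongest ILN marker feature should rank first for ILN
  iln <- tab[tab$topography == "infarct_like_necrosis", ]
  expect_identical(iln$feature[1], "POS_703.57")
})
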