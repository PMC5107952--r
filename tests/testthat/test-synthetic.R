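test_that("phantoms are deterministic and contain every tissue class", {
  a <- generate_phantom(seed = 5)
  b <- generate_phantom(seed = 5)
  expect_identical(a$labels, b$labels)
  # default phantom: every non-(unspecified-necrosis) class covers at
  # least 1% of the grid
  frac <- table(a$labels) / length(a$labels)
  want <- setdiff(histology_labels(), "necrosis_unspecified")
  expect_true(all(want %in% names(frac)))
  expect_true(all(frac[want] >= 0.01))
  # a degenerate grid collapses to a single off-tissue class
  tiny <- generate_phantom(1, 1, seed = 1)
  expect_identical(unique(tiny$labels), "mucin_matrix")
})

test_that("noise-free peak matrices equal the signature table exactly", {
  truth <- generate_phantom(16, 16, seed = 6)
  sig <- default_signature_table(n_nuisance = 4L)
  pm <- generate_peak_matrix(truth, sig, sigma_log = 0, tic_cv = 0,
                             seed = 1)
  want <- sig$signatures[truth$labels, colnames(pm$values)]
  expect_equal(unname(pm$values), unname(want))
})

test_that("generated intensities obey the log-normal calibration", {
  # 1000 + 1000 pixels: the ILN marker's mean ratio approaches its fold
  # change and its auc the closed binormal value
  sig <- default_signature_table()
  labels <- rep(c("infarct_like_necrosis", "tumor"), each = 1000)
  grid <- pixel_grid(rep(0:49, 40), rep(0:39, each = 50))
  truth <- structure(list(grid = grid, labels = labels,
                          lesion_mask = rep(TRUE, 2000), seed = 1L,
                          params = list(width = 50, height = 40)),
                     class = "phantom_truth")
  pm <- generate_peak_matrix(truth, sig, tic_cv = 0, seed = 7)
  v <- pm$values[, "POS_703.57"]
  ratio <- mean(v[labels == "infarct_like_necrosis"]) /
    mean(v[labels == "tumor"])
  expect_equal(ratio, 5.62, tolerance = 0.1)
  auc <- roc_auc(v[labels == "infarct_like_necrosis"],
                 v[labels == "tumor"])
  expect_equal(auc, pnorm(log(5.62) / (0.944 * sqrt(2))),
               tolerance = 0.02)
})

test_that("profile rendering round-trips through the preprocessing chain", {
  # noise-free single peak: picking recovers its m/z within one step
  grid <- pixel_grid(0, 0)
  pm1 <- peak_matrix(grid, feature_table("positive", 703.57),
                     matrix(5, 1, 1))
  ds1 <- generate_profile_dataset(pm1, noise_sd = 0, baseline = 0.05,
                                  seed = 1)
  pl <- pick_peaks(ds1$spectra[[1]])
  expect_equal(pl$mz[which.max(pl$intensity)], 703.57,
               tolerance = 0.25 / 4)
  expect_error(generate_profile_dataset(pm1, peak_fwhm = 0.2,
                                        mz_step = 0.3), "coarser")

  # full seeded round trip: render -> smooth -> TIC -> pick -> align
  # recovers the generating feature set one-to-one
  sig <- default_signature_table(n_nuisance = 2L)
  pos <- sig$features$mode == "positive"
  feats <- sig$features[pos, , drop = FALSE]
  truth <- generate_phantom(4, 4, class_fractions = c(tumor = 50,
                                                      fibrosis = 50),
                            seed = 8)
  sig_pos <- list(features = feats,
                  signatures = sig$signatures[, pos, drop = FALSE])
  pmx <- generate_peak_matrix(truth, sig_pos, sigma_log = 0.3,
                              tic_cv = 0.1, seed = 9)
  ds <- generate_profile_dataset(pmx, noise_sd = 0.01, seed = 10)
  ds2 <- generate_profile_dataset(pmx, noise_sd = 0.01, seed = 10)
  expect_identical(ds$spectra[[3]]$intensity, ds2$spectra[[3]]$intensity)
  back <- preprocess_dataset(ds, preprocess_config(align_tolerance = 0.15))
  matched <- vapply(feats$mz, function(m)
    any(abs(back$features$mz - m) < 0.1), logical(1))
  expect_true(all(matched))
  expect_equal(nrow(back$features), nrow(feats))
})

test_that("survival record generation matches its exponential model", {
  grades <- rep(1:5, each = 100)
  rec <- generate_survival_records(grades, censor_rate = 0,
                                   horizon = Inf, seed = 11)
  expect_true(all(rec$event == 1))
  # median event time of the partial-response group near ln 2 / rate
  g3 <- rec$time[rec$group == "partial"]
  expect_equal(median(g3), log(2) / 0.015, tolerance = 0.25)
  rec2 <- generate_survival_records(grades, censor_rate = 0,
                                    horizon = Inf, seed = 11)
  expect_identical(rec$time, rec2$time)
})

test_that("equal hazards across groups keep the log-rank near its nominal size", {
  rejections <- vapply(1:200, function(s) {
    grades <- rep(c(1, 3, 5), each = 20)
    rec <- generate_survival_records(grades,
                                     hazards = c(major = 0.02,
                                                 partial = 0.02,
                                                 minor = 0.02),
                                     censor_rate = 0.2, horizon = 60,
                                     seed = 20000 + s)
    logrank_test(rec)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
})
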