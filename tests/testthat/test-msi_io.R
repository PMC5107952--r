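test_that("spectrum and grid constructors enforce their invariants", {
  expect_error(msi_spectrum(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(msi_spectrum(c(2, 1), c(1, 1)), "strictly increasing")
  expect_error(msi_spectrum(c(1, 2), c(-1, 1)), "non-negative")
  expect_error(pixel_grid(c(0, 0), c(0, 0)), "unique")
  expect_error(pixel_grid(0, 0, spacing_um = -1), "spacing")
  expect_error(msi_dataset(pixel_grid(0:1, c(0, 0)),
                           list(msi_spectrum(1, 1)), mode = "positive"),
               "one spectrum per pixel")
})

test_that("reading a nonexistent imzML path errors", {
  expect_error(read_imzml(file.path(tempdir(), "no_such.imzML")),
               "not found")
})

test_that("imzML write/read round-trips both dialects exactly", {
  for (dialect in c("continuous", "processed")) {
    ds <- make_toy_dataset(n_pixels = 4L,
                           shared_axis = (dialect == "continuous"))
    path <- tempfile(fileext = ".imzML")
    write_imzml(ds, path, dialect = dialect)
    back <- read_imzml(path, mass_range = c(0, Inf))
    expect_identical(back$grid$x, ds$grid$x)
    expect_identical(back$grid$y, ds$grid$y)
    for (i in seq_along(ds$spectra)) {
      expect_identical(back$spectra[[i]]$mz, ds$spectra[[i]]$mz)
      expect_identical(back$spectra[[i]]$intensity,
                       ds$spectra[[i]]$intensity)
    }
    expect_identical(back$mode, ds$mode)
  }
})

test_that("mass-range filtering keeps only in-window peaks, in order", {
  ds <- msi_dataset(pixel_grid(0, 0),
                    list(msi_spectrum(c(400, 703.57, 1250), c(1, 2, 3))),
                    mode = "positive")
  path <- tempfile(fileext = ".imzML")
  write_imzml(ds, path)
  back <- read_imzml(path, mass_range = c(460, 1200))
  expect_equal(back$spectra[[1]]$mz, 703.57)
  expect_equal(back$spectra[[1]]$intensity, 2)
})

test_that("pyimzml parses a file written by the package writer", {
  path <- tempfile(fileext = ".imzML")
  ds <- make_toy_dataset(n_pixels = 4L, shared_axis = FALSE)
  write_imzml(ds, path, dialect = "processed")
  script <- sprintf(
    "from pyimzml.ImzMLParser import ImzMLParser\np = ImzMLParser(%s)\nmz, i = p.getspectrum(0)\nprint(len(p.coordinates), round(float(mz[0]), 6), round(float(i[0]), 6))",
    deparse(path))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = FALSE)
  got <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.integer(got[1]), 4L)
  expect_equal(as.numeric(got[2]), round(ds$spectra[[1]]$mz[1], 6))
  expect_equal(as.numeric(got[3]), round(ds$spectra[[1]]$intensity[1], 6))
})

test_that("peak-matrix CSV round-trip is lossless at full precision", {
  set.seed(7)
  vals <- matrix(abs(rnorm(50)), 10, 5)
  pm <- make_pm(vals, rep(c("positive", "negative"), c(3, 2)),
                c(500.123456, 600.5, 700.7, 550.25, 650.9), w = 5, h = 2)
  path <- tempfile(fileext = ".csv")
  save_peak_matrix(pm, path)
  back <- read_peak_matrix(path)
  expect_identical(back$features$name, pm$features$name)
  expect_equal(back$values, pm$values, tolerance = 0)
  expect_identical(back$grid$x, pm$grid$x)
})

test_that("single-pixel single-feature matrix writes the expected header", {
  pm <- make_pm(matrix(2.5, 1, 1), "positive", 703.57)
  path <- tempfile(fileext = ".csv")
  save_peak_matrix(pm, path)
  lines <- readLines(path)
  expect_identical(lines[1], "x,y,POS_703.57")
  expect_length(lines, 2L)
})

test_that("duplicate feature names are rejected", {
  expect_error(
    make_pm(matrix(1, 1, 2), c("positive", "positive"),
            c(703.571, 703.574)),
    "duplicate")
})

test_that("zero-offset coregistration of identical grids keeps all pixels", {
  set.seed(1)
  pos <- make_pm(matrix(abs(rnorm(8)) + 0.1, 4, 2), rep("positive", 2),
                 c(500.1, 600.1), w = 2, h = 2)
  neg <- make_pm(matrix(abs(rnorm(8)) + 0.1, 4, 2), rep("negative", 2),
                 c(510.1, 610.1), w = 2, h = 2)
  joint <- coregister_modes(pos, neg, offset_um = c(0, 0),
                            normalize = FALSE)
  expect_equal(attr(joint, "dropped"), c(pos = 0L, neg = 0L))
  expect_identical(attr(joint, "pairs")$pos, attr(joint, "pairs")$neg)
  expect_identical(colnames(joint$values),
                   c(pos$features$name, neg$features$name))
})

test_that("the 50 um dual-mode offset pairs every pixel at sqrt(2)*50 um", {
  set.seed(2)
  pos <- make_pm(matrix(abs(rnorm(18)) + 0.1, 9, 2), rep("positive", 2),
                 c(500.1, 600.1), w = 3, h = 3)
  neg <- make_pm(matrix(abs(rnorm(18)) + 0.1, 9, 2), rep("negative", 2),
                 c(510.1, 610.1), w = 3, h = 3)
  joint <- coregister_modes(pos, neg, offset_um = c(50, 50),
                            normalize = FALSE)
  pr <- attr(joint, "pairs")
  d <- sqrt((pos$grid$x[pr$pos] * 100 + 50 - neg$grid$x[pr$neg] * 100)^2 +
            (pos$grid$y[pr$pos] * 100 + 50 - neg$grid$y[pr$neg] * 100)^2)
  expect_true(all(abs(d - sqrt(2) * 50) < 1e-9))
  expect_equal(nrow(pr), 9L)
})

test_that("pairing matches a brute-force nearest-neighbour oracle", {
  set.seed(3)
  pos <- make_pm(matrix(abs(rnorm(8)) + 0.1, 4, 2), rep("positive", 2),
                 c(500.1, 600.1), w = 2, h = 2)
  neg <- make_pm(matrix(abs(rnorm(8)) + 0.1, 4, 2), rep("negative", 2),
                 c(510.1, 610.1), w = 2, h = 2)
  joint <- coregister_modes(pos, neg, offset_um = c(50, 0),
                            normalize = FALSE)
  pr <- attr(joint, "pairs")
  # oracle: exhaustive nearest-neighbour search in offset coordinates
  # (ties to the lower (y, x) pixel, matching the stated convention)
  pu <- cbind(pos$grid$x * 100 + 50, pos$grid$y * 100)
  nu <- cbind(neg$grid$x * 100, neg$grid$y * 100)
  d <- as.matrix(stats::dist(rbind(pu, nu)))[1:4, 5:8]
  nn_p <- apply(d, 1, which.min)
  keep <- which(d[cbind(1:4, nn_p)] <= 100)
  expect_setequal(paste(pr$pos, pr$neg), paste(keep, nn_p[keep]))
})

test_that("coregistration is symmetric in arguments and offset sign", {
  set.seed(4)
  pos <- make_pm(matrix(abs(rnorm(18)) + 0.1, 9, 2), rep("positive", 2),
                 c(500.1, 600.1), w = 3, h = 3)
  neg <- make_pm(matrix(abs(rnorm(18)) + 0.1, 9, 2), rep("negative", 2),
                 c(510.1, 610.1), w = 3, h = 3)
  a <- attr(coregister_modes(pos, neg, offset_um = c(50, 0),
                             normalize = FALSE), "pairs")
  # argument order is canonicalized by polarity, so `pos` always
  # indexes the positive-mode matrix
  b <- attr(coregister_modes(neg, pos, offset_um = c(-50, 0),
                             normalize = FALSE), "pairs")
  expect_setequal(paste(a$pos, a$neg), paste(b$pos, b$neg))
})
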