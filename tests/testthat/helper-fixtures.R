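# Small in-code fixtures shared across the suite.

# peak matrix on a w x h full grid with given feature table and values
make_pm <- function(values, modes, mzs, w = NULL, h = NULL,
                    spacing_um = 100) {
  n <- nrow(values)
  if (is.null(w)) { w <- n; h <- 1L }
  grid <- pixel_grid(rep(0:(w - 1), h), rep(0:(h - 1), each = w),
                     spacing_um = spacing_um)
  peak_matrix(grid, feature_table(modes, mzs), values)
}

# tiny two-mode dataset used by the imzML round-trip tests
make_toy_dataset <- function(mode = "positive", n_pixels = 4L,
                             shared_axis = TRUE, seed = 42L) {
  set.seed(seed)
  axis <- seq(500, 510, by = 0.5)
  w <- ceiling(sqrt(n_pixels))
  xs <- (seq_len(n_pixels) - 1L) %% w
  ys <- (seq_len(n_pixels) - 1L) %/% w
  spectra <- lapply(seq_len(n_pixels), function(i) {
    mz <- if (shared_axis) axis else sort(runif(15, 500, 510))
    msi_spectrum(mz, abs(rnorm(length(mz))), mode = mode)
  })
  msi_dataset(pixel_grid(xs, ys), spectra, mode = mode)
}

# do two clusterings define the same partition of the indices?
same_partition <- function(a, b) {
  ta <- table(a, b)
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}

# two-block phantom: left half one signature, right half another
two_block_pm <- function(w = 12L, h = 12L, noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  grid <- pixel_grid(rep(0:(w - 1), h), rep(0:(h - 1), each = w))
  block <- rep(rep(c(1L, 2L), each = w / 2), h)
  mu <- rbind(c(5, 1, 1), c(1, 5, 1))
  vals <- pmax(mu[block, ] + matrix(rnorm(w * h * 3, 0, noise_sd),
                                    ncol = 3), 0)
  list(pm = peak_matrix(grid,
                        feature_table(rep("positive", 3),
                                      c(600.1, 700.1, 800.1)),
                        vals),
       truth = block)
}
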