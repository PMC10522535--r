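test_that("upsampling preserves constants, corners and linear ramps", {
  expect_equal(upsample_grid(matrix(5, 4, 4)), matrix(5, 20, 20))
  W <- matrix(runif(16), 4, 4)
  up <- upsample_grid(W)
  expect_equal(up[1, 1], W[1, 1])
  expect_equal(up[20, 20], W[4, 4])
  expect_equal(up[1, 20], W[1, 4])
  expect_equal(up[20, 1], W[4, 1])
  # a natural cubic spline through linear data is linear: midpoints of a
  # ramp equal the mean of their neighbours (interpolation oracle)
  ramp <- outer(1:4, 1:4, function(a, b) 2 * a + 3 * b)
  upr <- upsample_grid(ramp)
  xs <- seq(1, 4, length.out = 20)
  expect_equal(upr, outer(xs, xs, function(a, b) 2 * a + 3 * b),
               tolerance = 1e-9)
  expect_error(upsample_grid(matrix(c(NA, runif(15)), 4, 4)), "NaN")
})

test_that("Laplace extrapolation keeps known cells and obeys the maximum principle", {
  # constant block fills constant
  ex <- extrapolate_pde(matrix(3, 4, 4), frame_n = 8)
  expect_equal(ex, matrix(3, 8, 8))
  known <- outer(1:4, 1:4, function(a, b) sin(a) + cos(b))
  ex2 <- extrapolate_pde(known, frame_n = 10)
  expect_equal(ex2[4:7, 4:7], known, ignore_attr = TRUE)
  expect_gte(min(ex2), min(known))
  expect_lte(max(ex2), max(known))
})

test_that("sparse Laplace solve matches a dense direct solve on a toy grid", {
  set.seed(3)
  for (frame_n in c(8, 12)) {
    known <- matrix(runif(16), 4, 4)
    ex <- extrapolate_pde(known, frame_n = frame_n)
    expect_equal(ex, laplace_dense_oracle(known, frame_n), tolerance = 1e-9)
  }
})

test_that("the coverage chain preserves the native argmax for unimodal fields", {
  pm <- rbind(c(d0 = 2, pd0 = 3, sigma_d = 0.7, sigma_pd = 1.1,
                peak_delay = 5, under_delay = 15, dispersion = 1,
                ratio = 0.15, amplitude = 2))
  colnames(pm) <- c("d0", "pd0", "sigma_d", "sigma_pd", "peak_delay",
                    "under_delay", "dispersion", "ratio", "amplitude")
  maps <- coverage_from_params(pm, "gaussian2d")
  pk <- which(maps[[1]] == max(maps[[1]]), arr.ind = TRUE)[1, ]
  # native cell (2, 3) maps into the 20x20 block placed at rows/cols 21:40
  native_pk <- 21 + round((c(2, 3) - 1) / 3 * 19)
  expect_true(all(abs(pk - native_pk) <= 1))
})

test_that("PCA averaging recovers shared structure with equal subject weight", {
  base <- extrapolate_pde(upsample_grid(eval_weights(
    prf_model("gaussian2d", c(d0 = 2, pd0 = 2, sigma_d = 1,
                              sigma_pd = 1)))))
  # all voxels identical -> PC1 explains everything, average equals the map
  maps <- rep(list(base), 5)
  out <- pca_average(maps)
  expect_equal(out$average, base, tolerance = 1e-9)
  expect_gt(out$explained_variance[1], 1 - 1e-9)
  # rank-3 generator -> 3 components explain > 99 %
  set.seed(6)
  b1 <- base
  b2 <- base[, c(2:60, 1)]
  b3 <- base[c(2:60, 1), ]
  maps3 <- lapply(1:12, function(i) {
    a <- runif(3)
    a[1] * b1 + a[2] * b2 + a[3] * b3
  })
  out3 <- pca_average(maps3)
  expect_gt(sum(out3$explained_variance), 0.99)
  expect_true(all(diff(out3$explained_variance) <= 1e-12))
  # equal subject weighting: a subject with many voxels does not dominate
  subj <- c(rep(1, 10), rep(2, 2))
  mapsw <- c(rep(list(b1), 10), rep(list(b2), 2))
  outw <- pca_average(mapsw, subject_ids = subj, n_components = 2)
  direct <- (b1 + b2) / 2
  expect_lt(max(abs(outw$average - direct)), 0.05 * max(abs(direct)))
  # fewer maps than components reduces the rank with a warning
  expect_warning(pca_average(rep(list(b1), 2)), "fewer maps")
})

test_that("peak alignment centres peaks and undoes planted shifts", {
  base <- extrapolate_pde(upsample_grid(eval_weights(
    prf_model("gaussian2d", c(d0 = 2.5, pd0 = 2.5, sigma_d = 0.8,
                              sigma_pd = 0.8)))))
  centre <- (dim(base) + 1L) %/% 2L
  # already-centred maps are unchanged on the full frame
  pk <- which(base == max(base), arr.ind = TRUE)[1, ]
  shift0 <- peak_align(list(base, base), axis = "both")
  pk0 <- which(shift0 == max(shift0, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk0), unname(centre))
  # shifted copies realign to the original on the common support
  shifted <- base * 0
  shifted[1:55, ] <- base[6:60, ]          # shift up by 5 rows
  al <- peak_align(list(base, shifted), axis = "digit")
  pal <- which(al == max(al, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(pal[["row"]], centre[[1]])
  # flat maps are excluded with a warning
  expect_warning(peak_align(list(base, matrix(1, 60, 60)), axis = "both"),
                 "flat")
  expect_error(suppressWarnings(peak_align(list(matrix(1, 6, 6)), "both")),
               "no usable")
})

test_that("wider planted pRFs give wider peak-aligned coverage maps", {
  mk <- function(sig) {
    extrapolate_pde(upsample_grid(eval_weights(
      prf_model("gaussian2d", c(d0 = 2.5, pd0 = 2.5, sigma_d = sig,
                                sigma_pd = 1.5 * sig)))))
  }
  narrow <- peak_align(lapply(c(0.6, 0.7), mk), axis = "both")
  wide <- peak_align(lapply(c(1.2, 1.4), mk), axis = "both")
  wn <- coverage_width(narrow[21:40, 21:40])
  ww <- coverage_width(wide[21:40, 21:40])
  expect_gt(ww[["width_digit"]], wn[["width_digit"]])
  expect_gt(ww[["width_pd"]], wn[["width_pd"]])
})
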