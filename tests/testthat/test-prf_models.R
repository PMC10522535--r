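test_that("2D Gaussian weights match the closed form", {
  m <- prf_model("gaussian2d", c(d0 = 2, pd0 = 3, sigma_d = 1,
                                 sigma_pd = 1))
  W <- eval_weights(m)
  expect_equal(unname(W[2, 3]), 1)                  # centre weight
  expect_equal(unname(W[1, 3]), unname(W[3, 3]))    # symmetry about d0
  # hand-evaluated off-centre weight
  m2 <- prf_model("gaussian2d", c(d0 = 2.5, pd0 = 2.5, sigma_d = 1,
                                  sigma_pd = 2))
  expect_equal(unname(eval_weights(m2)[1, 1]), exp(-(1.125 + 0.28125)),
               tolerance = 1e-12)
  # separability: the weight grid is the outer product of its profiles
  W2 <- eval_weights(m2)
  expect_equal(W2, outer(W2[, 1], W2[1, ]) / W2[1, 1],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("1D profiles agree with the 2D model slice at matched parameters", {
  sig <- 0.8
  m2 <- prf_model("gaussian2d", c(d0 = 2, pd0 = 1, sigma_d = sig,
                                  sigma_pd = 1))
  mb <- prf_model("gaussian1d_bd",
                  c(setNames(rep(2, 4), paste0("d0_pd", 1:4)),
                    setNames(rep(sig, 4), paste0("sigma_pd", 1:4)),
                    setNames(rep(1, 3), paste0("k_pd", 2:4))))
  # PD1 row of the 2D model (pd0 = 1) equals the BD model's PD1 profile
  expect_equal(eval_weights(m2)[, 1], eval_weights(mb)[, 1],
               tolerance = 1e-12)
})

test_that("invalid sigma is rejected", {
  expect_error(prf_model("gaussian2d", c(d0 = 2, pd0 = 2, sigma_d = -1,
                                         sigma_pd = 1)), "sigma")
})

test_that("preferred location follows each family's extraction rule", {
  m2 <- prf_model("gaussian2d", c(d0 = 2.2, pd0 = 3.1, sigma_d = 0.7,
                                  sigma_pd = 1.3))
  loc <- preferred_location(m2)
  expect_equal(loc$digit, 2.2)
  expect_equal(loc$pd, 3.1)
  expect_equal(loc$size, c(sigma_d = 0.7, sigma_pd = 1.3))

  mb <- prf_model("gaussian1d_bd",
                  c(setNames(c(1.5, 2.5, 3.5, 4.2), paste0("d0_pd", 1:4)),
                    setNames(c(0.5, 0.7, 0.9, 1.1), paste0("sigma_pd", 1:4)),
                    c(k_pd2 = 3, k_pd3 = 2, k_pd4 = 1)))
  locb <- preferred_location(mb)
  expect_equal(locb$pd, 2)               # k = (1, 3, 2, 1): argmax row 2
  expect_equal(locb$digit, 2.5)          # that row's centre
  expect_equal(locb$size, c(sigma_d = 0.7))

  # tie in maximal scale breaks to the lowest index with a warning
  mt <- prf_model("gaussian1d_bd",
                  c(setNames(1:4, paste0("d0_pd", 1:4)),
                    setNames(rep(1, 4), paste0("sigma_pd", 1:4)),
                    c(k_pd2 = 1, k_pd3 = 1, k_pd4 = 1)))
  expect_warning(loct <- preferred_location(mt), "tie")
  expect_equal(loct$pd, 1)

  # one-hot unconstrained weight: argmax site, size undefined
  w <- setNames(numeric(16), paste0("w", 1:16))
  w[site_index(3, 1)] <- 1
  locu <- preferred_location(prf_model("unconstrained", w))
  expect_equal(locu$digit, 3)
  expect_equal(locu$pd, 1)
  expect_true(is.na(locu$size))
})

test_that("free-parameter totals include the 5 HRF parameters", {
  expect_equal(count_free_parameters("gaussian2d"), 9L)
  expect_equal(count_free_parameters("gaussian1d_bd"), 16L)
  expect_equal(count_free_parameters("gaussian1d_wd"), 16L)
  expect_equal(count_free_parameters("unconstrained"), 21L)
  expect_error(count_free_parameters("cortical_magnification"))
})

test_that("HRF kernel is linear in amplitude and peaks later with delay", {
  k1 <- evaluate_hrf(hrf_params(amplitude = 1), tr = 2)
  k2 <- evaluate_hrf(hrf_params(amplitude = 2), tr = 2)
  expect_equal(2 * k1, k2)
  expect_length(k1, floor(30 / 2) + 1L)
  # peak time strictly increases with the peak-delay parameter
  peaks <- sapply(seq(3, 8, by = 1), function(tp) {
    k <- evaluate_hrf(hrf_params(peak_delay = tp), tr = 0.1)
    which.max(k)
  })
  expect_true(all(diff(peaks) > 0))
  expect_error(evaluate_hrf(hrf_params(), tr = 2, duration = 1), "duration")
  h <- hrf_params(); h[["dispersion"]] <- -1
  expect_error(evaluate_hrf(h, tr = 2), "dispersion")
})

test_that("predicted time course is the HRF under a one-hot delta stimulus", {
  g <- grid_spec()
  m <- prf_model("gaussian2d", c(d0 = 2, pd0 = 3, sigma_d = 1,
                                 sigma_pd = 1))
  mat <- matrix(0, 40, 16)
  mat[1, site_index(2, 3)] <- 1          # delta at the pRF centre site
  seq1 <- somatoprf:::new_stim_sequence(mat, tr = 2, cycle_len = 80,
                                        n_cycles = 1, paradigm = "between",
                                        direction = "forward")
  pred <- predict_timecourse(m, hrf_params(amplitude = 1.7), seq1)
  kern <- evaluate_hrf(hrf_params(amplitude = 1.7), tr = 2)
  expect_equal(pred[seq_along(kern)], kern)     # centre weight is 1
  expect_equal(pred[(length(kern) + 1):40], rep(0, 40 - length(kern)))
  # all-zero stimulus predicts zero
  seq0 <- somatoprf:::new_stim_sequence(matrix(0, 20, 16), tr = 2,
                                        cycle_len = 40, n_cycles = 1,
                                        paradigm = "between",
                                        direction = "forward")
  expect_equal(predict_timecourse(m, hrf_params(), seq0), rep(0, 20))
})

test_that("prediction is periodic at the stimulus frequency after the onset transient", {
  m <- prf_model("gaussian2d", c(d0 = 3, pd0 = 2, sigma_d = 0.8,
                                 sigma_pd = 1))
  bd <- build_tw_sequence("between", "forward", n_cycles = 12)
  pred <- predict_timecourse(m, hrf_params(), bd)
  per <- 8                                # 16 s cycle / 2 s TR
  steady <- matrix(pred[(3 * per + 1):(12 * per)], nrow = per)
  expect_lt(max(apply(steady, 1, function(x) diff(range(x)))), 1e-10)
  # peak lag: digit-3 epoch (samples 5-6 of the cycle) plus HRF delay
  cyc <- rowMeans(steady)
  expect_equal(which.max(cyc), 8L)        # 4 s ON midpoint + ~5 s HRF peak
})

test_that("convolution respects run boundaries", {
  m <- prf_model("gaussian2d", c(d0 = 2, pd0 = 2, sigma_d = 1,
                                 sigma_pd = 1))
  bd <- build_tw_sequence("between", "forward", n_cycles = 2)
  two <- concatenate_sequences(list(bd, bd))
  p1 <- predict_timecourse(m, hrf_params(), bd)
  p2 <- predict_timecourse(m, hrf_params(), two)
  expect_equal(p2, c(p1, p1))             # no bleed across the boundary
})
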