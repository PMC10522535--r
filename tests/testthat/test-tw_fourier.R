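test_that("fourier analysis recovers amplitude, phase and coherence of a sinusoid", {
  n <- 96; cyc <- 8; n_cycles <- n / cyc
  t <- 0:(n - 1)
  w <- 2 * pi * n_cycles / n
  for (phi in c(0, 0.7, pi, 5.1)) {
    x <- 3.2 * cos(w * t - phi)
    fa <- fourier_analysis(x, cyc)
    expect_equal(fa$coherence, 1, tolerance = 1e-9)
    expect_equal(fa$phase %% (2 * pi), phi %% (2 * pi), tolerance = 1e-9)
    expect_equal(fa$amplitude, 3.2, tolerance = 1e-9)
  }
  # direct DFT oracle for the phase of an arbitrary series
  set.seed(4)
  x <- rnorm(n)
  fa <- fourier_analysis(x, cyc)
  X <- sum(x * exp(-2i * pi * n_cycles * t / n))
  expect_equal(fa$phase, (-Arg(X)) %% (2 * pi), tolerance = 1e-9)
  expect_error(fourier_analysis(rnorm(95), 8), "whole number")
})

test_that("coherence is scale-invariant and its square averages 1/K on noise", {
  set.seed(9)
  x <- rnorm(96)
  f1 <- fourier_analysis(x, 8)
  f2 <- fourier_analysis(10 * x, 8)
  expect_equal(f1$coherence, f2$coherence, tolerance = 1e-12)
  # E[c^2] = 1/K under white Gaussian noise
  Y <- matrix(rnorm(96 * 4000), 96)
  fa <- fourier_analysis(Y, 8)
  K <- attr(fa, "n_freq_bins")
  expect_equal(mean(fa$coherence^2), 1 / K, tolerance = 0.05)
})

test_that("coherence-to-p conversion is calibrated under the null", {
  expect_equal(coherence_to_p(0, 47), 1)
  expect_equal(coherence_to_p(1, 47), 0)
  cs <- seq(0, 1, by = 0.1)
  expect_true(all(diff(coherence_to_p(cs, 47)) <= 0))
  expect_error(coherence_to_p(0.5, 1), "bins")
  # Monte-Carlo type-I error at alpha = 0.05
  set.seed(21)
  Y <- matrix(rnorm(96 * 10000), 96)
  fa <- fourier_analysis(Y, 8)
  p <- coherence_to_p(fa$coherence, attr(fa, "n_freq_bins"))
  typeI <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(typeI - 0.05), 3 * se)
})

test_that("Hommel correction matches the closed-testing oracle for m <= 6", {
  # hommel_oracle (exhaustive closed testing with Simes local tests) is
  # defined in helper-fixtures.R
  expect_equal(correct_pvalues(0.03), 0.03)          # single p unchanged
  # m identical p's are left unchanged: every subset's Simes combination of
  # equal p's is p itself, so the closed-testing maximum is p
  expect_equal(correct_pvalues(rep(0.01, 5)), rep(0.01, 5))
  expect_equal(correct_pvalues(rep(0.3, 4)), rep(0.3, 4))
  set.seed(5)
  for (m in 2:6) {
    for (rep in 1:5) {
      p <- round(runif(m), 3)
      adj <- correct_pvalues(p)
      expect_equal(adj, hommel_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p))
    }
  }
  expect_error(correct_pvalues(numeric(0)), "empty")
})

test_that("phase bins partition the cycle into 4 contiguous labels", {
  centres <- (0:3) * pi / 2 + pi / 4
  expect_equal(phase_to_label(centres), 1:4)
  # exact bin edges belong to the upper bin (half-open convention)
  expect_equal(phase_to_label(0), 1L)
  expect_equal(phase_to_label(pi / 2), 2L)
  # every phase gets exactly one label and the partition tiles [0, 2pi)
  ph <- seq(0, 2 * pi - 1e-9, length.out = 997)
  lab <- phase_to_label(ph)
  expect_true(all(lab %in% 1:4))
  expect_equal(as.numeric(table(lab)), rep(997 / 4, 4), tolerance = 0.01)
  # offset shifts the partition
  expect_equal(phase_to_label(0.1, offset = 0.2), 4L)
})

test_that("forward/reverse combination removes the haemodynamic lag from phase", {
  # identity case: fwd equal to the time-flip of rev, zero lag
  x <- sin(2 * pi * 12 * (0:95) / 96)
  expect_equal(combine_forward_reverse(x, rev(x), lag = 0), x)
  expect_error(combine_forward_reverse(x, x[1:50]), "mismatch")
  # simulated voxels: combined phase approximates the stimulus phase of the
  # voxel's preferred epoch, free of HRF delay
  sim <- noiseless_session()
  runs <- sim$seq$runs
  fwd_idx <- with(runs, start[paradigm == "between" &
                                direction == "forward"]):
    with(runs, end[paradigm == "between" & direction == "forward"])
  rev_idx <- with(runs, start[paradigm == "between" &
                                direction == "reverse"]):
    with(runs, end[paradigm == "between" & direction == "reverse"])
  # stimulus-phase oracle: Fourier phase of the unconvolved neural signal
  for (v in c(6, 7, 10)) {
    m <- prf_model("gaussian2d",
                   c(d0 = sim$truth$d0[v], pd0 = sim$truth$pd0[v],
                     sigma_d = sim$truth$sigma_d[v],
                     sigma_pd = sim$truth$sigma_pd[v]))
    neural <- as.numeric(
      sim$seq$matrix[fwd_idx, ] %*% weights_vector(m))
    true_phase <- fourier_analysis(neural, 8)$phase
    comb <- combine_forward_reverse(sim$Ypsc[fwd_idx, v],
                                    sim$Ypsc[rev_idx, v])
    est_phase <- fourier_analysis(comb, 8)$phase
    dphi <- abs(((est_phase - true_phase + pi) %% (2 * pi)) - pi)
    expect_lt(dphi, 0.1)
  }
})

test_that("averaging forward and reverse halves independent noise variance", {
  set.seed(31)
  n <- 96; reps <- 2000
  F <- matrix(rnorm(n * reps), n)
  R <- matrix(rnorm(n * reps), n)
  comb <- combine_forward_reverse(F, R, lag = 4, tr = 2)
  expect_equal(mean(apply(comb, 2, var)), 0.5, tolerance = 0.05)
})

test_that("travelling-wave labels recover the planted digit ordering", {
  sim <- noisy_session()
  twb <- tw_analysis(sim$Ypsc, sim$seq, "between")
  expect_true(all(twb$coherence >= 0 & twb$coherence <= 1))
  expect_true(all(twb$p_corrected >= twb$p_raw))
  # orderly gradient: mean phase increases with the true digit
  mph <- tapply(twb$phase, sim$truth$digit, mean)
  expect_true(all(diff(mph) > 0))
  # labels match the true digit for the well-identified middle digits and
  # never invert the ordering
  expect_true(all(tapply(twb$label, sim$truth$digit, stats::median) ==
                    sort(tapply(twb$label, sim$truth$digit,
                                stats::median))))
  agree <- mean(twb$label == sim$truth$digit)
  expect_gt(agree, 0.6)
})
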