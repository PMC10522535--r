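test_that("preprocessing removes offsets, trends and slow drift", {
  n <- 96
  t <- seq_len(n)
  # constant series -> all-zero PSC
  expect_equal(preprocess_timeseries(rep(7, n), tr = 2), rep(0, n))
  # pure linear drift removed to numerical zero
  drift <- 100 + 0.05 * t
  expect_lt(max(abs(preprocess_timeseries(drift, tr = 2))), 1e-10)
  # gain changes cancel in percent signal change; offsets leave only the
  # mean normalisation
  x <- 100 + sin(2 * pi * 12 * t / n)
  p1 <- preprocess_timeseries(x, tr = 2)
  expect_equal(preprocess_timeseries(3.7 * x, tr = 2), p1, tolerance = 1e-9)
  p2 <- preprocess_timeseries(x + 50, tr = 2)
  expect_equal(p1 * mean(x), p2 * mean(x + 50), tolerance = 1e-9)
  expect_lt(abs(mean(p1)), 1e-12)
  # slow sine below the 0.01 Hz cut-off is attenuated, stimulus band is not
  slow <- 100 + sin(2 * pi * (1 / 200) * (t * 2))      # 0.005 Hz
  fast <- 100 + sin(2 * pi * (1 / 16) * (t * 2))       # 0.0625 Hz
  expect_lt(sd(preprocess_timeseries(slow, tr = 2)),
            0.3 * sd(preprocess_timeseries(fast, tr = 2)))
  # short-run fallback warns and detrends only
  expect_warning(preprocess_timeseries(rnorm(10) + 100, tr = 2), "detrend")
})

test_that("adjusted r2 follows its formula and penalises parameters", {
  expect_equal(adjusted_r2(1, 96, 9), 1)
  expect_equal(adjusted_r2(0, 96, 9), 1 - 95 / 86)   # -0.10465...
  expect_equal(adjusted_r2(0, 96, 9), -0.10465116, tolerance = 1e-7)
  r2 <- 0.7
  vals <- sapply(c(5, 9, 16, 21), function(p) adjusted_r2(r2, 96, p))
  expect_true(all(diff(vals) < 0))
  expect_error(adjusted_r2(0.5, 10, 9), "undefined")
})

test_that("least-squares AIC follows its formula", {
  expect_equal(aic_ls(96, 96, 9), 18)                 # rss = n -> 2k
  expect_equal(as.numeric(aic_ls(48, 96, 9)), 96 * log(0.5) + 18)
  expect_equal(as.numeric(aic_ls(48, 96, 9)), -48.54239, tolerance = 1e-5)
  expect_lt(aic_ls(40, 96, 9), aic_ls(48, 96, 9))     # lower rss wins
  a0 <- aic_ls(0, 96, 9)
  expect_equal(as.numeric(a0), -Inf)
  expect_true(attr(a0, "exact_fit"))
})

test_that("grid search returns the generating lattice point on noiseless data", {
  sim <- noiseless_session()
  seqs <- sim$seq
  # voxel generated exactly at a lattice point
  m <- prf_model("gaussian2d", c(d0 = 3, pd0 = 2, sigma_d = 1,
                                 sigma_pd = 2))
  y0 <- predict_timecourse(m, hrf_params(amplitude = 2), seqs)
  proj <- run_projector(length(y0), seqs$runs, seqs$tr)
  y <- proj(y0)
  init <- grid_search_init(y, "gaussian2d", seqs)
  expect_equal(unname(init$params[c("d0", "pd0", "sigma_d", "sigma_pd")]),
               c(3, 2, 1, 2))
  # argmin contract: returned rss is no worse than any lattice point
  lat <- default_search_lattice()
  cand <- expand.grid(d0 = lat$centres, pd0 = lat$centres,
                      sigma_d = lat$sigmas, sigma_pd = lat$sigmas)
  design <- apply(somatoprf:::convolved_design(seqs), 2L, proj)
  rss_all <- apply(cand, 1, function(p) {
    w <- weights_vector(prf_model("gaussian2d", p))
    pr <- design %*% w
    s <- max(sum(pr * y) / sum(pr^2), 1e-6)
    sum((y - s * pr)^2)
  })
  expect_lte(init$rss, min(rss_all) + 1e-8)
  expect_error(grid_search_init(rep(NA_real_, length(y)), "gaussian2d",
                                seqs), "NaN")
})

test_that("noiseless voxels are recovered to solver tolerance", {
  sim <- noiseless_session()
  truth <- sim$truth
  ft <- fit_patch(sim$Ypsc[, 1:6], "gaussian2d", sim$seq)
  expect_true(all(abs(ft$pref_digit - truth$d0[1:6]) < 1e-3))
  expect_true(all(abs(ft$pref_pd - truth$pd0[1:6]) < 1e-3))
  expect_true(all(abs(ft$sigma_d - truth$sigma_d[1:6]) < 1e-2))
  expect_true(all(abs(ft$sigma_pd - truth$sigma_pd[1:6]) < 1e-2))
  # essentially perfect fits
  expect_true(all(ft$adjusted_r2 > 1 - 1e-6))
})

test_that("the LM fit never ends above its grid-search start", {
  sim <- noisy_session()
  for (v in c(1, 17, 40)) {
    for (fam in c("gaussian2d", "gaussian1d_wd")) {
      init <- grid_search_init(sim$Ypsc[, v], fam, sim$seq)
      fit <- fit_voxel(sim$Ypsc[, v], fam, sim$seq, init = init)
      expect_lte(fit$rss, init$rss + 1e-10)
      expect_lte(fit$adjusted_r2, fit$r2)
    }
  }
})

test_that("fit_patch tabulates every family with sizes where defined", {
  sim <- noisy_session()
  ft <- fit_patch(sim$Ypsc[, 1:3],
                  c("gaussian2d", "gaussian1d_bd", "gaussian1d_wd",
                    "unconstrained"), sim$seq)
  expect_equal(nrow(ft), 12L)
  expect_true(all(!is.na(ft$sigma_d[ft$family == "gaussian2d"])))
  expect_true(all(is.na(ft$sigma_pd[ft$family == "gaussian1d_bd"])))
  expect_true(all(is.na(ft$sigma_d[ft$family == "gaussian1d_wd"])))
  expect_true(all(is.na(ft$sigma_d[ft$family == "unconstrained"])))
  expect_true(all(ft$rss >= 0))
  expect_true(all(ft$pref_digit >= 0.5 & ft$pref_digit <= 4.5))
})
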