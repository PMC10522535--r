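# Synthetic somatotopic patches and simulated fMRI sessions.
#
# The generator emulates the qualitative structure of hand somatotopy in
# S1: a smooth digit gradient (D2..D5) along one lattice axis, mirrored
# tip-base-tip proximal-distal gradients across four parallel area bands
# (emulating the reversals at areal borders between 3a, 3b, 1 and 2),
# band-dependent pRF sizes (largest in the area-2-like band), elongated
# pRFs (within-digit sigma > between-digit sigma), and sizes growing from
# D2 to D5 and from tip to base. Voxel time series are generated with the
# same forward model the analysis fits (site weights -> stimulus dot
# product -> HRF convolution per run) plus optional drift and noise.

#' Simulation configuration
#'
#' @param tr Repetition time (s).
#' @param n_cycles Cycles per run.
#' @param s_on Seconds per stimulation line.
#' @param run_spec Named list giving forward/reverse run counts per
#'   paradigm. The default reproduces the study session: one
#'   forward + reverse between-digit pair, two within-digit pairs, one
#'   diagonal pair.
#' @param hrf True HRF parameters (without amplitude; each voxel's
#'   amplitude comes from the patch).
#' @param noise_sd White-noise standard deviation in raw signal units.
#'   With `baseline = 100` the temporal SNR is `baseline / noise_sd`; the
#'   default 2 gives tSNR 50.
#' @param ar1 AR(1) coefficient of the noise (0 = white; 0.3 emulates
#'   mildly autocorrelated BOLD noise).
#' @param drift_amplitude Peak-to-peak amplitude of a per-run random linear
#'   drift, percent of baseline (0 disables).
#' @param baseline Raw-signal baseline (arbitrary scanner units).
#' @param seed Random seed for noise and drift.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(tr = 2, n_cycles = 12L, s_on = 4,
                              run_spec = list(
                                between = c(forward = 1L, reverse = 1L),
                                within = c(forward = 2L, reverse = 2L),
                                diagonal = c(forward = 1L, reverse = 1L)),
                              hrf = hrf_params(),
                              noise_sd = 2, ar1 = 0, drift_amplitude = 0,
                              baseline = 100, seed = 1L) {
  structure(list(tr = tr, n_cycles = as.integer(n_cycles), s_on = s_on,
                 run_spec = run_spec, hrf = hrf, noise_sd = noise_sd,
                 ar1 = ar1, drift_amplitude = drift_amplitude,
                 baseline = baseline, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a ground-truth somatotopic patch
#'
#' @param nx,ny Lattice size (default 40 x 40). The digit gradient runs
#'   along x; the four area bands are strips along y.
#' @param n_subjects Number of subjects; each gets an independent centre
#'   jitter but the same underlying gradients.
#' @param sigma_base Baseline between-digit pRF size (grid units).
#' @param band_mults Named size multipliers for the four area bands, in
#'   band order along y.
#' @param elongation Ratio `sigma_pd / sigma_d` (within-digit pRFs are
#'   wider; > 1 plants Hypothesis-1 structure).
#' @param digit_slope,pd_slope Fractional size increase from D2 to D5 and
#'   tip to base (Hypotheses 2 and 4).
#' @param jitter SD of Gaussian jitter on the centres (grid units).
#' @param amplitude Response amplitude (percent signal change).
#' @param family Generating model family (default `"gaussian2d"`).
#' @param seed Seed for the centre jitter (ground truth is fully
#'   reproducible from this seed, independent of the noise seed).
#' @return Data frame of class `gt_patch`: one row per voxel and subject
#'   with columns `voxel`, `subject`, `x`, `y`, `d0`, `pd0`, `sigma_d`,
#'   `sigma_pd`, `amplitude`, `area`, `digit`, `pd`, `family`.
#' @export
generate_patch <- function(nx = 40L, ny = 40L, n_subjects = 1L,
                           sigma_base = 0.7,
                           band_mults = c("3a" = 1, "3b" = 0.85,
                                          "1" = 1.15, "2" = 1.5),
                           elongation = 1.5, digit_slope = 0.5,
                           pd_slope = 0.5, jitter = 0.1, amplitude = 2,
                           family = "gaussian2d", seed = 42L) {
  family <- match.arg(family, PRF_FAMILIES)
  n_bands <- length(band_mults)
  set.seed(seed)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    g <- expand.grid(x = seq_len(nx), y = seq_len(ny),
                     KEEP.OUT.ATTRS = FALSE)
    band <- pmin(ceiling(n_bands * g$y / ny), n_bands)
    # position within band, 0..1
    band_len <- ny / n_bands
    upos <- (g$y - (band - 1) * band_len - 0.5) / band_len
    upos <- pmin(pmax(upos, 0), 1)
    # mirrored gradients: odd bands tip->base, even bands base->tip
    pd0 <- ifelse(band %% 2L == 1L, 1 + 3 * upos, 4 - 3 * upos)
    d0 <- 1 + 3 * (g$x - 1) / (nx - 1)
    d0 <- pmin(pmax(d0 + stats::rnorm(nrow(g), 0, jitter), 0.6), 4.4)
    pd0 <- pmin(pmax(pd0 + stats::rnorm(nrow(g), 0, jitter), 0.6), 4.4)
    sigma_d <- sigma_base * unname(band_mults[band]) *
      (1 + digit_slope * (d0 - 1) / 3) * (1 + pd_slope * (pd0 - 1) / 3)
    out[[s]] <- data.frame(
      voxel = seq_len(nrow(g)) + (s - 1L) * nrow(g),
      subject = s, x = g$x, y = g$y, d0 = d0, pd0 = pd0,
      sigma_d = sigma_d, sigma_pd = elongation * sigma_d,
      amplitude = amplitude, area = names(band_mults)[band],
      digit = location_to_label(d0), pd = location_to_label(pd0),
      family = family, stringsAsFactors = FALSE
    )
  }
  patch <- do.call(rbind, out)
  class(patch) <- c("gt_patch", class(patch))
  patch
}

#' Session stimulus layout from a configuration
#'
#' @param config A [simulation_config()].
#' @param grid A [grid_spec()].
#' @return Concatenated `stim_sequence` for the whole session, forward runs
#'   before reverse runs within each paradigm.
#' @export
session_sequence <- function(config, grid = grid_spec()) {
  seqs <- list()
  for (par in names(config$run_spec)) {
    counts <- config$run_spec[[par]]
    for (dir in c("forward", "reverse")) {
      k <- if (dir %in% names(counts)) counts[[dir]] else 0L
      for (i in seq_len(k)) {
        seqs[[length(seqs) + 1L]] <- build_tw_sequence(
          par, dir, n_cycles = config$n_cycles, s_on = config$s_on,
          tr = config$tr, grid = grid)
      }
    }
  }
  concatenate_sequences(seqs)
}

prf_model_from_truth <- function(row) {
  switch(row$family,
    gaussian2d = prf_model("gaussian2d",
      c(d0 = row$d0, pd0 = row$pd0,
        sigma_d = row$sigma_d, sigma_pd = row$sigma_pd)),
    unconstrained = {
      # one-hot-ish truth for the unconstrained family: the 2D Gaussian
      # evaluated on the grid, used verbatim as the 16 weights
      w <- weights_vector(prf_model("gaussian2d",
        c(d0 = row$d0, pd0 = row$pd0,
          sigma_d = row$sigma_d, sigma_pd = row$sigma_pd)))
      prf_model("unconstrained", stats::setNames(w, paste0("w", 1:16)))
    },
    stop("unsupported generating family: ", row$family)
  )
}

#' Simulate a full fMRI session from a ground-truth patch
#'
#' For every voxel the true pRF model predicts the percent-signal-change
#' response to the session's stimulus sequence (HRF convolution run-wise),
#' then optional linear drift and (optionally AR(1)) Gaussian noise are
#' added and the series is placed on the raw-signal baseline:
#' `raw = baseline * (1 + (signal + drift + noise_psc) / 100)`.
#'
#' @param patch A [generate_patch()] truth table.
#' @param config A [simulation_config()].
#' @param grid A [grid_spec()].
#' @return List with `Y` (time-points x voxels raw-signal matrix), `seq`
#'   (the session `stim_sequence`), `truth` (the patch), and `config`.
#' @export
simulate_session <- function(patch, config = simulation_config(),
                             grid = grid_spec()) {
  seq <- session_sequence(config, grid)
  n <- nrow(seq$matrix)
  nv <- nrow(patch)
  W <- vapply(seq_len(nv), function(v) {
    weights_vector(prf_model_from_truth(patch[v, ]), grid)
  }, numeric(grid$n_sites))
  neural <- seq$matrix %*% W
  kern <- evaluate_hrf(config$hrf, config$tr)
  sig <- matrix(0, n, nv)
  for (v in seq_len(nv)) {
    sig[, v] <- patch$amplitude[v] *
      convolve_runs(neural[, v], kern, seq$runs)
  }
  # express the response as percent signal change about each run's mean, so
  # the raw run mean equals the baseline exactly
  for (i in seq_len(nrow(seq$runs))) {
    idx <- seq$runs$start[i]:seq$runs$end[i]
    sig[idx, ] <- sweep(sig[idx, , drop = FALSE], 2L,
                        colMeans(sig[idx, , drop = FALSE]))
  }
  set.seed(config$seed)
  noise_psc <- matrix(stats::rnorm(n * nv), n, nv)
  if (config$ar1 != 0) {
    for (i in seq_len(nrow(seq$runs))) {
      idx <- seq$runs$start[i]:seq$runs$end[i]
      sub <- noise_psc[idx, , drop = FALSE]
      for (t in 2:nrow(sub)) {
        sub[t, ] <- config$ar1 * sub[t - 1, ] +
          sqrt(1 - config$ar1^2) * sub[t, ]
      }
      noise_psc[idx, ] <- sub
    }
  }
  noise_psc <- noise_psc * (100 * config$noise_sd / config$baseline)
  drift <- matrix(0, n, nv)
  if (config$drift_amplitude > 0) {
    for (i in seq_len(nrow(seq$runs))) {
      idx <- seq$runs$start[i]:seq$runs$end[i]
      ramp <- seq(-0.5, 0.5, length.out = length(idx))
      slopes <- stats::runif(nv, -1, 1) * config$drift_amplitude
      drift[idx, ] <- outer(ramp, slopes)
    }
  }
  Y <- config$baseline * (1 + (sig + drift + noise_psc) / 100)
  list(Y = Y, seq = seq, truth = patch, config = config)
}

#' Score parameter recovery against ground truth
#'
#' @param truth A [generate_patch()] table.
#' @param fit_table A [fit_patch()] table (one family) on the same voxels.
#' @return List with `per_parameter` (bias, RMSE, truth-estimate
#'   correlation for the centre and size parameters available in the fit)
#'   and `dice_digit` / `dice_pd` (mean diagonal Dice between true and
#'   estimated discrete label maps).
#' @export
score_recovery <- function(truth, fit_table) {
  fams <- unique(fit_table$family)
  if (length(fams) != 1L) stop("pass a single-family fit table")
  m <- merge(truth, fit_table, by = "voxel",
             suffixes = c("_true", "_est"))
  if (nrow(m) == 0) stop("no matching voxels between truth and fits")
  pairs <- list(
    d0 = c("d0", "pref_digit"), pd0 = c("pd0", "pref_pd"),
    sigma_d = c("sigma_d_true", "sigma_d_est"),
    sigma_pd = c("sigma_pd_true", "sigma_pd_est")
  )
  rows <- lapply(names(pairs), function(pn) {
    tv <- m[[pairs[[pn]][1]]]
    ev <- m[[pairs[[pn]][2]]]
    if (is.null(ev) || all(is.na(ev))) return(NULL)
    err <- ev - tv
    data.frame(parameter = pn, bias = mean(err, na.rm = TRUE),
               rmse = sqrt(mean(err^2, na.rm = TRUE)),
               correlation = suppressWarnings(
                 stats::cor(tv, ev, use = "complete.obs")),
               median_abs_error = stats::median(abs(err), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  per_parameter <- do.call(rbind, rows)
  dd <- dice_matrix(m$digit, location_to_label(m$pref_digit))
  dp <- dice_matrix(m$pd, location_to_label(m$pref_pd))
  list(per_parameter = per_parameter,
       dice_digit = mean(diag(dd), na.rm = TRUE),
       dice_pd = mean(diag(dp), na.rm = TRUE))
}
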