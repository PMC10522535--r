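# Voxel-wise preprocessing and nonlinear least-squares pRF estimation.
#
# Fitting works on the full parameter vector: spatial parameters of the
# chosen family followed by the five HRF parameters. Starting values come
# from a coarse grid search (centres x sigmas at a canonical HRF, with the
# response scale solved linearly), then minpack.lm's Levenberg-Marquardt
# refines all parameters under box bounds. Centres are bounded to
# [0.5, 4.5] grid units and sigmas to [0.1, 10].

CENTRE_BOUNDS <- c(0.5, 4.5)
SIGMA_BOUNDS <- c(0.1, 10)

# ---- preprocessing ---------------------------------------------------------

#' Preprocess raw BOLD time series to percent signal change
#'
#' Per run: the run mean is recorded, a linear trend and slow
#' discrete-cosine components below the high-pass cut-off are projected out,
#' and the residual is scaled to percent signal change using the
#' pre-detrend run mean. Output is zero-mean within each run. Runs shorter
#' than one cut-off period are detrended only (with a warning).
#'
#' @param ts Numeric vector (one voxel) or time-points x voxels matrix of
#'   raw signal.
#' @param tr Repetition time (seconds).
#' @param highpass_hz High-pass cut-off frequency (Hz, default 0.01).
#' @param runs Optional run-boundary data frame with `start`/`end` columns
#'   (as in `stim_sequence$runs`); default treats the whole series as one
#'   run.
#' @return Percent-signal-change series with the same shape as `ts`.
#' @export
preprocess_timeseries <- function(ts, tr, highpass_hz = 0.01, runs = NULL) {
  vec_in <- is.null(dim(ts))
  Y <- if (vec_in) matrix(ts, ncol = 1L) else as.matrix(ts)
  n <- nrow(Y)
  if (is.null(runs)) runs <- data.frame(start = 1L, end = n)
  stopifnot(max(runs$end) <= n)
  out <- Y
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    nr <- length(idx)
    m <- colMeans(Y[idx, , drop = FALSE])
    if (any(m == 0)) stop("zero run mean: cannot form percent signal change")
    X <- cbind(1, seq_len(nr))
    if (nr * tr >= 1 / highpass_hz) {
      K <- floor(2 * nr * tr * highpass_hz)
      if (K >= 1L) {
        t0 <- seq_len(nr) - 0.5
        X <- cbind(X, sapply(seq_len(K), function(k) cos(pi * k * t0 / nr)))
      }
    } else {
      warning("run ", i, " shorter than one high-pass period; detrend only")
    }
    resid <- qr.resid(qr(X), Y[idx, , drop = FALSE])
    out[idx, ] <- 100 * sweep(resid, 2L, m, "/")
  }
  if (vec_in) drop(out) else out
}

# ---- fit statistics --------------------------------------------------------

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`; penalises r-squared for the number
#' of fitted parameters and can be negative. Voxel maps are conventionally
#' thresholded at adjusted r-squared > 0.
#'
#' @param r2 Unadjusted r-squared.
#' @param n Number of time points.
#' @param p Number of fitted parameters (see [count_free_parameters()]).
#' @return Scalar adjusted r-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted r2 undefined: n must exceed p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Least-squares Akaike information criterion
#'
#' `n * log(rss / n) + 2 k`, the AIC of a Gaussian-noise least-squares fit up
#' to an additive constant shared by all models on the same data. A perfect
#' fit (`rss = 0`) returns `-Inf` with attribute `exact_fit = TRUE`.
#'
#' @param rss Residual sum of squares.
#' @param n Number of time points.
#' @param k Number of fitted parameters.
#' @return Scalar AIC.
#' @export
aic_ls <- function(rss, n, k) {
  stopifnot(rss >= 0, n > 0)
  if (rss == 0) return(structure(-Inf, exact_fit = TRUE))
  n * log(rss / n) + 2 * k
}

# ---- parameter packing -----------------------------------------------------

HRF_NAMES <- c("peak_delay", "under_delay", "dispersion", "ratio",
               "amplitude")

full_param_names <- function(family) c(spatial_param_names(family), HRF_NAMES)

param_bounds <- function(family) {
  nm <- full_param_names(family)
  lower <- upper <- stats::setNames(numeric(length(nm)), nm)
  for (i in seq_along(nm)) {
    b <- if (grepl("^(d0|pd0)", nm[i])) {
      CENTRE_BOUNDS
    } else if (grepl("^sigma", nm[i])) {
      SIGMA_BOUNDS
    } else if (grepl("^k_", nm[i])) {
      c(0, 20)
    } else if (grepl("^w", nm[i])) {
      c(-20, 20)
    } else {
      switch(nm[i],
        peak_delay = c(2, 10), under_delay = c(8, 25),
        dispersion = c(0.25, 3), ratio = c(0, 0.6),
        amplitude = if (family == "unconstrained") c(1e-3, 100) else c(0, 100))
    }
    lower[i] <- b[1]
    upper[i] <- b[2]
  }
  list(lower = lower, upper = upper)
}

split_params <- function(theta, family) {
  sp <- theta[spatial_param_names(family)]
  hp <- theta[HRF_NAMES]
  list(model = prf_model(family, pmax(sp,
         ifelse(grepl("^sigma", names(sp)), 1e-6, -Inf))),
       hrf = do.call(hrf_params, as.list(hp)))
}

# ---- run-wise projection ---------------------------------------------------

#' Per-run drift/high-pass projector
#'
#' Returns a function that removes, run-wise, the same nuisance subspace
#' (intercept, linear trend, slow discrete-cosine components) that
#' [preprocess_timeseries()] removes from the data. Fitted model
#' predictions are passed through this projector so that model and data see
#' identical filtering.
#'
#' @param n Series length.
#' @param runs Run-boundary data frame (`start`, `end`).
#' @param tr Repetition time (seconds).
#' @param highpass_hz High-pass cut-off (Hz).
#' @return Function mapping a length-`n` vector to its filtered version.
#' @export
run_projector <- function(n, runs, tr, highpass_hz = 0.01) {
  mats <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    nr <- length(idx)
    X <- cbind(1, seq_len(nr))
    if (nr * tr >= 1 / highpass_hz) {
      K <- floor(2 * nr * tr * highpass_hz)
      if (K >= 1L) {
        t0 <- seq_len(nr) - 0.5
        X <- cbind(X, sapply(seq_len(K), function(k) cos(pi * k * t0 / nr)))
      }
    }
    # dense residual-maker P = I - X (X'X)^-1 X', cheap at run length
    P <- diag(nr) - X %*% solve(crossprod(X), t(X))
    list(idx = idx, P = P)
  })
  function(x) {
    for (m in mats) x[m$idx] <- m$P %*% x[m$idx]
    x
  }
}

# ---- fast evaluation path --------------------------------------------------
# Validation-free versions of eval_weights / evaluate_hrf used inside the
# optimiser's residual function; theta is the full named parameter vector.

fast_weights <- function(theta, family, grid) {
  d <- seq_len(grid$n_digits)
  pd <- seq_len(grid$n_pd)
  switch(family,
    gaussian2d = {
      gd <- exp(-(theta[1L] - d)^2 / (2 * theta[3L]^2))
      gp <- exp(-(theta[2L] - pd)^2 / (2 * theta[4L]^2))
      rep(gd, each = grid$n_pd) * rep(gp, times = grid$n_digits)
    },
    gaussian1d_bd = {
      # theta: d0_pd1..4, sigma_pd1..4, k_pd2..4
      k <- c(1, theta[9:11])
      w <- numeric(grid$n_sites)
      for (j in pd) {
        idx <- (d - 1L) * grid$n_pd + j
        w[idx] <- k[j] * exp(-(theta[j] - d)^2 / (2 * theta[4L + j]^2))
      }
      w
    },
    gaussian1d_wd = {
      k <- c(1, theta[9:11])
      w <- numeric(grid$n_sites)
      for (i in d) {
        idx <- (i - 1L) * grid$n_pd + pd
        w[idx] <- k[i] * exp(-(theta[i] - pd)^2 / (2 * theta[4L + i]^2))
      }
      w
    },
    unconstrained = theta[seq_len(grid$n_sites)]
  )
}

fast_kernel <- function(htheta, tr, duration = 30) {
  t <- seq(0, by = tr, length.out = floor(duration / tr) + 1L)
  htheta[5L] * (gamma_bump(t, htheta[1L], htheta[3L]) -
                  htheta[4L] * gamma_bump(t, htheta[2L], htheta[3L]))
}

make_resid_fn <- function(y, family, seq, grid, projector = NULL) {
  S <- seq$matrix
  runs <- seq$runs
  tr <- seq$tr
  nsp <- length(spatial_param_names(family))
  function(theta) {
    w <- fast_weights(theta, family, grid)
    neural <- as.numeric(S %*% w)
    kern <- fast_kernel(theta[nsp + 1:5], tr)
    pred <- convolve_runs(neural, kern, runs)
    if (!is.null(projector)) pred <- projector(pred)
    y - pred
  }
}

# ---- grid search -----------------------------------------------------------

#' Default grid-search lattice
#'
#' Centres at the integer grid positions 1..4 on each axis and sigmas of
#' 0.5, 1 and 2 grid units; the HRF is held at its canonical values during
#' the search and the response scale is solved linearly per lattice point.
#'
#' @return List with `centres` and `sigmas` vectors.
#' @export
default_search_lattice <- function() {
  list(centres = c(1, 2, 3, 4), sigmas = c(0.5, 1, 2))
}

#' Convolved stimulus design matrix under a fixed HRF
#'
#' Column s is the predicted response to stimulation of site s alone, so
#' any site-weight vector `w` predicts `design %*% w`. Used by the grid
#' search (and OLS initialisation of the linear families) with the HRF held
#' canonical.
#'
#' @param seq A `stim_sequence`.
#' @param hrf An [hrf_params()] vector (default canonical).
#' @param grid A [grid_spec()].
#' @return Numeric time-points x sites matrix.
#' @export
convolved_design <- function(seq, hrf = hrf_params(), grid = grid_spec()) {
  kern <- evaluate_hrf(hrf, seq$tr)
  apply(seq$matrix, 2L, convolve_runs, kern = kern, runs = seq$runs)
}

# Candidate weight vectors for the lattice of a family. Returns list(W =
# sites x L weight matrix, pars = L-row data.frame of lattice coordinates).
lattice_weights_2d <- function(lattice, grid = grid_spec()) {
  pars <- expand.grid(d0 = lattice$centres, pd0 = lattice$centres,
                      sigma_d = lattice$sigmas, sigma_pd = lattice$sigmas,
                      KEEP.OUT.ATTRS = FALSE)
  W <- vapply(seq_len(nrow(pars)), function(i) {
    weights_vector(prf_model("gaussian2d", unlist(pars[i, ])), grid)
  }, numeric(grid$n_sites))
  list(W = W, pars = pars)
}

#' Grid-search initialisation for one or many voxels
#'
#' Evaluates the family's prediction on a coarse lattice (canonical HRF,
#' response scale solved linearly) and returns the lattice point with the
#' smallest residual sum of squares; ties break to the lowest lattice index.
#' For the 1D families the lattice is a shared (centre, sigma) over all four
#' profiles with the four scales solved by ordinary least squares; for the
#' unconstrained family the 16 weights are solved directly by OLS.
#'
#' @param ts Numeric vector, one preprocessed voxel time series.
#' @param family Model family name.
#' @param seq A `stim_sequence`.
#' @param lattice Search lattice, see [default_search_lattice()].
#' @param grid A [grid_spec()].
#' @param design Optional precomputed [convolved_design()] matrix, already
#'   passed through `projector` (reused across voxels by [fit_patch()]).
#' @param projector Optional [run_projector()] applying the data's
#'   detrend/high-pass filtering to model predictions; built to match
#'   [preprocess_timeseries()] defaults when `NULL`.
#' @return List with `params` (full named start vector including HRF),
#'   `rss`, and `family`.
#' @export
grid_search_init <- function(ts, family, seq,
                             lattice = default_search_lattice(),
                             grid = grid_spec(), design = NULL,
                             projector = NULL) {
  if (all(is.na(ts))) stop("all-NaN voxel: skip")
  family <- match.arg(family, PRF_FAMILIES)
  if (is.null(projector)) {
    projector <- run_projector(nrow(seq$matrix), seq$runs, seq$tr)
  }
  if (is.null(design)) {
    design <- apply(convolved_design(seq, grid = grid), 2L, projector)
  }
  y <- as.numeric(ts)
  hrf0 <- hrf_params()
  bounds <- param_bounds(family)

  if (family == "gaussian2d") {
    lw <- lattice_weights_2d(lattice, grid)
    P <- design %*% lw$W
    pp <- colSums(P^2)
    num <- as.numeric(crossprod(P, y))
    scale <- pmax(num / pp, 1e-6)
    rss <- sum(y^2) - 2 * scale * num + scale^2 * pp
    best <- which.min(rss)
    theta <- c(unlist(lw$pars[best, ]),
               stats::setNames(as.numeric(hrf0), HRF_NAMES))
    theta[["amplitude"]] <- scale[best]
  } else if (family %in% c("gaussian1d_bd", "gaussian1d_wd")) {
    cand <- expand.grid(c0 = lattice$centres, s0 = lattice$sigmas,
                        KEEP.OUT.ATTRS = FALSE)
    best_rss <- Inf
    best <- NULL
    for (i in seq_len(nrow(cand))) {
      R <- profile_regressors(cand$c0[i], cand$s0[i], family, design, grid)
      fit <- stats::lm.fit(R, y)
      rss <- sum(fit$residuals^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- list(c0 = cand$c0[i], s0 = cand$s0[i], coef = fit$coefficients)
      }
    }
    k <- best$coef
    k[!is.finite(k)] <- 0
    amp <- if (k[1] > 1e-3) k[1] else max(max(abs(k)), 1e-3)
    krel <- pmin(pmax(k / amp, 0), 20)
    theta <- stats::setNames(numeric(0), character(0))
    pre <- if (family == "gaussian1d_bd") {
      c(stats::setNames(rep(best$c0, 4), paste0("d0_pd", 1:4)),
        stats::setNames(rep(best$s0, 4), paste0("sigma_pd", 1:4)),
        stats::setNames(krel[2:4], paste0("k_pd", 2:4)))
    } else {
      c(stats::setNames(rep(best$c0, 4), paste0("pd0_d", 1:4)),
        stats::setNames(rep(best$s0, 4), paste0("sigma_d", 1:4)),
        stats::setNames(krel[2:4], paste0("k_d", 2:4)))
    }
    theta <- c(pre, stats::setNames(as.numeric(hrf0), HRF_NAMES))
    theta[["amplitude"]] <- amp
  } else {
    fit <- stats::lm.fit(design, y)
    w <- fit$coefficients
    w[!is.finite(w)] <- 0
    w <- pmin(pmax(w, -20), 20)
    theta <- c(stats::setNames(w, paste0("w", seq_len(grid$n_sites))),
               stats::setNames(as.numeric(hrf0), HRF_NAMES))
  }
  theta <- pmin(pmax(theta, bounds$lower), bounds$upper)
  resid_fn <- make_resid_fn(y, family, seq, grid, projector)
  list(params = theta, rss = sum(resid_fn(theta)^2), family = family)
}

profile_regressors <- function(c0, s0, family, design, grid) {
  n <- grid$n_pd
  sapply(seq_len(n), function(j) {
    w <- numeric(grid$n_sites)
    if (family == "gaussian1d_bd") {
      idx <- site_index(seq_len(grid$n_digits), rep(j, grid$n_digits), grid)
      w[idx] <- exp(-(c0 - seq_len(grid$n_digits))^2 / (2 * s0^2))
    } else {
      idx <- site_index(rep(j, grid$n_pd), seq_len(grid$n_pd), grid)
      w[idx] <- exp(-(c0 - seq_len(grid$n_pd))^2 / (2 * s0^2))
    }
    as.numeric(design %*% w)
  })
}

# ---- voxel fit -------------------------------------------------------------

#' Fit one voxel by bounded Levenberg--Marquardt least squares
#'
#' Refines a grid-search start with `minpack.lm::nls.lm` under box bounds
#' and returns the best-fit parameters with residual statistics. If the
#' optimiser fails to improve on the start, the start is returned with
#' `converged = FALSE`. When a fitted centre lands on a bound -- the
#' signature of a boundary local minimum for broad receptive fields near
#' the grid edge -- the fit is retried once from the same start with the
#' sigmas flipped to the opposite end of the search lattice, and the
#' better of the two solutions is kept.
#'
#' @param ts Preprocessed voxel time series (percent signal change).
#' @param family Model family name.
#' @param seq A `stim_sequence`.
#' @param init Start values from [grid_search_init()]; computed on the fly
#'   when `NULL`.
#' @param grid A [grid_spec()].
#' @param projector Optional [run_projector()]; built to match
#'   [preprocess_timeseries()] defaults when `NULL`, so the model
#'   prediction is filtered exactly like the data.
#' @param control An [minpack.lm::nls.lm.control()] list.
#' @param boundary_retry Retry once from an alternate-sigma start when a
#'   centre sticks to a bound (default TRUE).
#' @return An object of class `prf_fit`: list with `family`, `params`
#'   (full vector), `model`, `hrf`, `rss`, `r2`, `adjusted_r2`, `aic`, `n`,
#'   `converged`, and `init`.
#' @export
fit_voxel <- function(ts, family, seq, init = NULL, grid = grid_spec(),
                      projector = NULL,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 100, ftol = 1e-8, ptol = 1e-8),
                      boundary_retry = TRUE) {
  family <- match.arg(family, PRF_FAMILIES)
  y <- as.numeric(ts)
  if (is.null(projector)) {
    projector <- run_projector(nrow(seq$matrix), seq$runs, seq$tr)
  }
  if (is.null(init)) {
    init <- grid_search_init(y, family, seq, grid = grid,
                             projector = projector)
  }
  bounds <- param_bounds(family)
  resid_fn <- make_resid_fn(y, family, seq, grid, projector)
  run_lm <- function(start) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = start, lower = bounds$lower,
                           upper = bounds$upper, fn = resid_fn,
                           control = control)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(list(theta = start, rss = sum(resid_fn(start)^2),
                  converged = FALSE))
    }
    theta <- stats::setNames(coef(fit), names(start))
    list(theta = theta, rss = sum(resid_fn(theta)^2),
         converged = fit$info %in% 1:4)
  }
  best <- run_lm(init$params)
  centre_idx <- grep("^(d0|pd0)", names(init$params))
  at_bound <- function(theta) {
    length(centre_idx) &&
      any(abs(theta[centre_idx] - bounds$lower[centre_idx]) < 1e-6 |
            abs(theta[centre_idx] - bounds$upper[centre_idx]) < 1e-6)
  }
  if (boundary_retry && at_bound(best$theta)) {
    sg <- grep("^sigma", names(init$params))
    # broad pRFs near the grid edge stick centres to the bound when started
    # too narrow; retry wide first, then narrow
    for (s_alt in c(2, 0.5)) {
      alt <- init$params
      alt[sg] <- s_alt
      retry <- run_lm(alt)
      if (retry$rss < best$rss) best <- retry
      if (!at_bound(best$theta)) break
    }
  }
  theta <- best$theta
  rss <- best$rss
  converged <- best$converged
  if (rss > init$rss) {        # descent contract: never worse than the start
    theta <- init$params
    rss <- init$rss
    converged <- FALSE
  }
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  p <- count_free_parameters(family)
  sp <- split_params(theta, family)
  structure(
    list(family = family, params = theta, model = sp$model, hrf = sp$hrf,
         rss = rss, r2 = r2,
         adjusted_r2 = if (is.na(r2)) NA_real_ else adjusted_r2(r2, n, p),
         aic = aic_ls(rss, n, p), n = n, converged = converged,
         init = init$params),
    class = "prf_fit"
  )
}

#' @export
print.prf_fit <- function(x, ...) {
  cat(sprintf("<prf_fit> %s: rss=%.4g adjR2=%.3f aic=%.2f%s\n", x$family,
              x$rss, x$adjusted_r2, x$aic,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit many voxels and tabulate the results
#'
#' Runs [grid_search_init()] (sharing one convolved design across voxels)
#' and [fit_voxel()] for every voxel and model family, and collects per-voxel
#' preferred locations, sizes and fit statistics in one flat table.
#'
#' @param Y Time-points x voxels matrix of preprocessed series.
#' @param families Character vector of model families to fit.
#' @param seq A `stim_sequence`.
#' @param grid A [grid_spec()].
#' @param lattice Search lattice for initialisation.
#' @param voxel_ids Optional voxel identifiers (default column index).
#' @return Data frame with one row per voxel x family: `voxel`, `family`,
#'   `pref_digit`, `pref_pd`, `sigma_d`, `sigma_pd`, `amplitude`, `rss`,
#'   `r2`, `adjusted_r2`, `aic`, `converged`. The full parameter vectors are
#'   attached as attribute `params` (a list of matrices, one per family).
#' @export
fit_patch <- function(Y, families = "gaussian2d", seq, grid = grid_spec(),
                      lattice = default_search_lattice(),
                      voxel_ids = NULL) {
  Y <- as.matrix(Y)
  nv <- ncol(Y)
  if (is.null(voxel_ids)) voxel_ids <- seq_len(nv)
  projector <- run_projector(nrow(seq$matrix), seq$runs, seq$tr)
  design <- apply(convolved_design(seq, grid = grid), 2L, projector)
  rows <- vector("list", nv * length(families))
  par_store <- stats::setNames(vector("list", length(families)), families)
  ri <- 0L
  for (fam in families) {
    pmat <- matrix(NA_real_, nv, length(full_param_names(fam)),
                   dimnames = list(NULL, full_param_names(fam)))
    for (v in seq_len(nv)) {
      init <- grid_search_init(Y[, v], fam, seq, lattice = lattice,
                               grid = grid, design = design,
                               projector = projector)
      fit <- fit_voxel(Y[, v], fam, seq, init = init, grid = grid,
                       projector = projector)
      loc <- suppressWarnings(preferred_location(fit$model, grid))
      pmat[v, ] <- fit$params
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        voxel = voxel_ids[v], family = fam,
        pref_digit = loc$digit, pref_pd = loc$pd,
        sigma_d = if ("sigma_d" %in% names(loc$size))
          unname(loc$size[["sigma_d"]]) else NA_real_,
        sigma_pd = if ("sigma_pd" %in% names(loc$size))
          unname(loc$size[["sigma_pd"]]) else NA_real_,
        amplitude = unname(fit$params[["amplitude"]]),
        rss = fit$rss, r2 = fit$r2, adjusted_r2 = fit$adjusted_r2,
        aic = as.numeric(fit$aic), converged = fit$converged,
        stringsAsFactors = FALSE
      )
    }
    par_store[[fam]] <- pmat
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- par_store
  out
}
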