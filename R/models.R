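# pRF model families.
#
# Four families describe how a voxel weights the 16 stimulation sites:
#   gaussian2d    - one separable 2D Gaussian over (digit, pd):
#                   w(d, p) = exp(-[(d0-d)^2/(2 s_d^2) + (pd0-p)^2/(2 s_pd^2)])
#   gaussian1d_bd - four independently scaled 1D Gaussians over digits, one
#                   per PD row; the PD1 row's scale is fixed to 1
#   gaussian1d_wd - four independently scaled 1D Gaussians over PD, one per
#                   digit; the D2 column's scale is fixed to 1
#   unconstrained - one free weight per site, no shape constraint
# Response amplitude is carried by the HRF amplitude parameter, so the 2D
# Gaussian itself has no scale factor and peaks at exactly 1 at its centre.

#' The four pRF model family names
#'
#' `"gaussian2d"`, `"gaussian1d_bd"`, `"gaussian1d_wd"`, `"unconstrained"`.
#' @export
PRF_FAMILIES <- c("gaussian2d", "gaussian1d_bd", "gaussian1d_wd",
                  "unconstrained")

#' Construct a pRF model
#'
#' @param family One of `"gaussian2d"`, `"gaussian1d_bd"`, `"gaussian1d_wd"`,
#'   `"unconstrained"`.
#' @param params Named numeric vector of spatial parameters:
#'   * `gaussian2d`: `d0`, `pd0` (centre, grid units), `sigma_d`, `sigma_pd`
#'     (sizes, grid units);
#'   * `gaussian1d_bd`: `d0_pd1..d0_pd4`, `sigma_pd1..sigma_pd4`,
#'     `k_pd2..k_pd4` (PD1 scale fixed to 1);
#'   * `gaussian1d_wd`: `pd0_d1..pd0_d4`, `sigma_d1..sigma_d4`,
#'     `k_d2..k_d4` (D2 scale fixed to 1; digit index 1 = D2);
#'   * `unconstrained`: `w1..w16`, one per linear site index.
#' @return An object of class `prf_model`.
#' @export
prf_model <- function(family, params) {
  family <- match.arg(family, PRF_FAMILIES)
  params <- unlist(params)
  need <- spatial_param_names(family)
  if (!all(need %in% names(params))) {
    stop("missing parameters for ", family, ": ",
         paste(setdiff(need, names(params)), collapse = ", "))
  }
  params <- params[need]
  sig <- grep("^sigma", names(params))
  if (length(sig) && any(params[sig] <= 0)) {
    stop("invalid parameter: sigma must be > 0")
  }
  structure(list(family = family, params = params), class = "prf_model")
}

spatial_param_names <- function(family) {
  switch(family,
    gaussian2d = c("d0", "pd0", "sigma_d", "sigma_pd"),
    gaussian1d_bd = c(paste0("d0_pd", 1:4), paste0("sigma_pd", 1:4),
                      paste0("k_pd", 2:4)),
    gaussian1d_wd = c(paste0("pd0_d", 1:4), paste0("sigma_d", 1:4),
                      paste0("k_d", 2:4)),
    unconstrained = paste0("w", 1:16),
    stop("unknown model family: ", family)
  )
}

#' Evaluate model weights on the stimulation grid
#'
#' @param model A [prf_model()].
#' @param grid A [grid_spec()] (4 x 4 for every Gaussian family).
#' @return Numeric `n_digits x n_pd` matrix of site weights; rows index
#'   digits (1 = D2), columns PD locations (1 = tip).
#' @export
#' @examples
#' m <- prf_model("gaussian2d", c(d0 = 2, pd0 = 3, sigma_d = 1, sigma_pd = 1))
#' eval_weights(m)[2, 3]   # 1 at the centre
eval_weights <- function(model, grid = grid_spec()) {
  stopifnot(inherits(model, "prf_model"))
  p <- model$params
  d <- seq_len(grid$n_digits)
  pd <- seq_len(grid$n_pd)
  W <- switch(model$family,
    gaussian2d = {
      gd <- exp(-(p[["d0"]] - d)^2 / (2 * p[["sigma_d"]]^2))
      gp <- exp(-(p[["pd0"]] - pd)^2 / (2 * p[["sigma_pd"]]^2))
      outer(gd, gp)
    },
    gaussian1d_bd = {
      k <- c(1, p[paste0("k_pd", 2:4)])
      sapply(pd, function(j) {
        k[j] * exp(-(p[[paste0("d0_pd", j)]] - d)^2 /
                     (2 * p[[paste0("sigma_pd", j)]]^2))
      })
    },
    gaussian1d_wd = {
      k <- c(1, p[paste0("k_d", 2:4)])
      t(sapply(d, function(i) {
        k[i] * exp(-(p[[paste0("pd0_d", i)]] - pd)^2 /
                     (2 * p[[paste0("sigma_d", i)]]^2))
      }))
    },
    unconstrained = {
      w <- matrix(NA_real_, grid$n_digits, grid$n_pd)
      w[cbind(grid$sites$digit, grid$sites$pd)] <- p[paste0("w",
                                                            grid$sites$site)]
      w
    }
  )
  dimnames(W) <- list(digit = paste0("D", d + 1L), pd = paste0("PD", pd))
  W
}

#' Model weights as a site vector
#'
#' @inheritParams eval_weights
#' @return Numeric vector of length `grid$n_sites`, ordered by linear site
#'   index (see [site_index()]).
#' @export
weights_vector <- function(model, grid = grid_spec()) {
  W <- eval_weights(model, grid)
  W[cbind(grid$sites$digit, grid$sites$pd)]
}

#' Preferred stimulus location and pRF size of a fitted model
#'
#' For the 2D Gaussian the preferred location is the model centre and the
#' size its two sigmas. For the 1D families the profile with the largest
#' scale factor selects the preferred row/column; its centre gives the
#' location along the other axis and its sigma the size. For the
#' unconstrained model the argmax site gives the location and no size is
#' defined.
#'
#' @param model A fitted [prf_model()].
#' @param grid A [grid_spec()].
#' @return List with `digit`, `pd` (grid units) and `size` (named numeric,
#'   `NA` for the unconstrained family).
#' @export
preferred_location <- function(model, grid = grid_spec()) {
  stopifnot(inherits(model, "prf_model"))
  p <- model$params
  argmax_scale <- function(k, what) {
    top <- which(k == max(k))
    if (length(top) > 1L) {
      warning("tie in maximal ", what, " scale; taking lowest index")
    }
    top[1L]
  }
  switch(model$family,
    gaussian2d = list(digit = unname(p[["d0"]]), pd = unname(p[["pd0"]]),
                      size = c(sigma_d = unname(p[["sigma_d"]]),
                               sigma_pd = unname(p[["sigma_pd"]]))),
    gaussian1d_bd = {
      k <- c(1, unname(p[paste0("k_pd", 2:4)]))
      j <- argmax_scale(k, "PD-row")
      list(digit = unname(p[[paste0("d0_pd", j)]]), pd = j,
           size = c(sigma_d = unname(p[[paste0("sigma_pd", j)]])))
    },
    gaussian1d_wd = {
      k <- c(1, unname(p[paste0("k_d", 2:4)]))
      i <- argmax_scale(k, "digit")
      list(digit = i, pd = unname(p[[paste0("pd0_d", i)]]),
           size = c(sigma_pd = unname(p[[paste0("sigma_d", i)]])))
    },
    unconstrained = {
      w <- unname(p[paste0("w", seq_len(grid$n_sites))])
      s <- which(w == max(w))
      if (length(s) > 1L) {
        warning("tie in maximal site weight; taking lowest index")
      }
      xy <- site_coords(s[1L], grid)
      list(digit = xy$digit, pd = xy$pd, size = NA_real_)
    }
  )
}

#' Total number of fitted parameters per model family
#'
#' Includes the five HRF parameters fitted alongside every family:
#' 2D Gaussian 9, each 1D Gaussian 16, unconstrained 21.
#'
#' @param family Model family name.
#' @return Integer count.
#' @export
count_free_parameters <- function(family) {
  family <- match.arg(family, PRF_FAMILIES)
  length(spatial_param_names(family)) + 5L
}

#' Predict the BOLD time course of a pRF model
#'
#' The neural response at each volume is the dot product of the model's site
#' weights with the stimulus row; the neural series is convolved with the
#' HRF kernel independently within each run (convolution never crosses a
#' scan boundary) and the per-run predictions are concatenated.
#'
#' @param model A [prf_model()].
#' @param hrf An [hrf_params()] vector.
#' @param seq A `stim_sequence` (see [build_tw_sequence()]).
#' @param grid A [grid_spec()].
#' @return Numeric predicted time series, same length as `nrow(seq$matrix)`,
#'   in the units of the HRF amplitude (percent signal change for the
#'   fitted models).
#' @export
predict_timecourse <- function(model, hrf, seq, grid = grid_spec()) {
  stopifnot(inherits(seq, "stim_sequence"))
  if (ncol(seq$matrix) != grid$n_sites) {
    stop("sequence/grid mismatch: ", ncol(seq$matrix), " columns vs ",
         grid$n_sites, " sites")
  }
  w <- weights_vector(model, grid)
  neural <- as.numeric(seq$matrix %*% w)
  kern <- evaluate_hrf(hrf, seq$tr)
  convolve_runs(neural, kern, seq$runs)
}

# Causal convolution applied independently per run.
convolve_runs <- function(x, kern, runs) {
  out <- numeric(length(x))
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    seg <- x[idx]
    n <- length(seg)
    full <- stats::convolve(seg, rev(kern), type = "open")
    out[idx] <- full[seq_len(n)]
  }
  out
}

#' @export
print.prf_model <- function(x, ...) {
  cat(sprintf("<prf_model> %s\n", x$family))
  print(round(x$params, 4))
  invisible(x)
}
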