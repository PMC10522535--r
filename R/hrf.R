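# Haemodynamic response function.
#
# Double-gamma kernel with five parameters: a positive lobe peaking at
# `peak_delay` seconds, an undershoot lobe peaking at `under_delay` seconds,
# a shared dispersion (width) parameter, the undershoot:peak ratio, and an
# overall amplitude. Each lobe is a gamma-shaped bump written in unit-peak
# form, (t/tp)^(tp/disp) * exp(-(t - tp)/disp), so that `peak_delay` is
# exactly the mode of the positive lobe and `amplitude` scales the kernel
# linearly.

#' Haemodynamic response function parameters
#'
#' @param peak_delay Time to peak of the positive lobe (s, default 5).
#' @param under_delay Time to peak of the undershoot lobe (s, default 15).
#' @param dispersion Width parameter shared by both lobes (s, default 1).
#' @param ratio Undershoot amplitude relative to the peak (default 0.15).
#' @param amplitude Overall scale of the kernel (response units, default 1).
#' @return Named numeric vector of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 5, under_delay = 15, dispersion = 1,
                       ratio = 0.15, amplitude = 1) {
  stopifnot(peak_delay > 0, under_delay > 0, dispersion > 0,
            is.finite(amplitude))
  structure(c(peak_delay = peak_delay, under_delay = under_delay,
              dispersion = dispersion, ratio = ratio, amplitude = amplitude),
            class = "hrf_params")
}

# unit-peak gamma bump with mode tp and width disp
gamma_bump <- function(t, tp, disp) {
  a <- tp / disp
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(a * (log(t[pos]) - log(tp)) - (t[pos] - tp) / disp)
  out
}

#' Sample the HRF kernel
#'
#' @param hrf An [hrf_params()] vector (a plain named numeric vector with the
#'   same names also works).
#' @param tr Sampling interval (seconds).
#' @param duration Kernel support (seconds, default 30).
#' @return Numeric kernel of length `floor(duration / tr) + 1`, sampled at
#'   `0, tr, 2 tr, ...`.
#' @export
#' @examples
#' k <- evaluate_hrf(hrf_params(), tr = 2)
#' length(k)   # 16
evaluate_hrf <- function(hrf, tr, duration = 30) {
  stopifnot(duration >= tr, tr > 0)
  h <- as.numeric(hrf)
  names(h) <- names(unclass(hrf))
  if (h[["dispersion"]] <= 0) stop("non-positive dispersion")
  if (h[["peak_delay"]] <= 0 || h[["under_delay"]] <= 0) {
    stop("HRF delays must be positive")
  }
  t <- seq(0, by = tr, length.out = floor(duration / tr) + 1L)
  h[["amplitude"]] *
    (gamma_bump(t, h[["peak_delay"]], h[["dispersion"]]) -
       h[["ratio"]] * gamma_bump(t, h[["under_delay"]], h[["dispersion"]]))
}
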