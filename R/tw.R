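# Fourier travelling-wave analysis.
#
# The reference phase-encoding analysis: a voxel driven by the travelling
# wave responds periodically at the stimulation frequency, and its response
# phase encodes the preferred stimulus location. Phase here follows the
# delay convention: a series cos(w t - phi) returns phase phi, so voxels
# preferring later stimulation epochs get larger phases. Averaging a
# forward run with the time-flipped reverse run (each shifted by the
# haemodynamic lag) cancels the HRF delay from the phase estimate.

#' Combine forward and time-reversed reverse runs
#'
#' The reverse run is flipped in time, the forward run is advanced and the
#' flipped reverse run delayed by the haemodynamic lag (circular shifts; the
#' series are periodic), and the two are averaged. The phase of the result
#' estimates the stimulus phase free of haemodynamic-lag bias.
#'
#' @param fwd_ts,rev_ts Forward- and reverse-run time series: numeric
#'   vectors or time-points x voxels matrices of equal size.
#' @param lag Haemodynamic lag in seconds (default 4, i.e. 2 TRs at TR 2 s).
#' @param tr Repetition time (seconds).
#' @return Combined series, same shape as the inputs.
#' @export
combine_forward_reverse <- function(fwd_ts, rev_ts, lag = 4, tr = 2) {
  vec_in <- is.null(dim(fwd_ts))
  F <- if (vec_in) matrix(fwd_ts, ncol = 1L) else as.matrix(fwd_ts)
  R <- if (vec_in) matrix(rev_ts, ncol = 1L) else as.matrix(rev_ts)
  if (!all(dim(F) == dim(R))) stop("forward/reverse length mismatch")
  n <- nrow(F)
  L <- as.integer(round(lag / tr)) %% n
  advance <- function(M, k) {          # y(t) <- y(t + k), circular
    if (k == 0L) return(M)
    M[c((k + 1L):n, 1:k), , drop = FALSE]
  }
  Rf <- R[rev(seq_len(n)), , drop = FALSE]
  out <- (advance(F, L) + advance(Rf, (n - L) %% n)) / 2
  if (vec_in) drop(out) else out
}

#' Fourier analysis at the stimulation frequency
#'
#' Extracts amplitude, phase (delay convention, radians in `[0, 2 pi)`) and
#' coherence of the discrete Fourier component at the stimulus frequency
#' (the `n_cycles`-th harmonic). Coherence is the amplitude at the stimulus
#' frequency divided by the root sum of squared amplitudes over all
#' frequencies strictly between DC and Nyquist, so a pure sinusoid at the
#' stimulus frequency has coherence 1.
#'
#' @param ts Numeric vector or time-points x voxels matrix (the series
#'   length must be a whole number of cycles).
#' @param cycle_len_tp Stimulation cycle length in time points.
#' @return Data frame with one row per voxel: `coherence`, `phase`,
#'   `amplitude`; the number of non-DC frequency bins is attached as
#'   attribute `n_freq_bins`.
#' @export
fourier_analysis <- function(ts, cycle_len_tp) {
  Y <- if (is.null(dim(ts))) matrix(ts, ncol = 1L) else as.matrix(ts)
  n <- nrow(Y)
  if (n %% cycle_len_tp != 0) {
    stop("series length ", n, " is not a whole number of ", cycle_len_tp,
         "-point cycles")
  }
  n_cycles <- n %/% cycle_len_tp
  X <- stats::mvfft(Y)
  K <- (n - 1L) %/% 2L                      # bins strictly between DC/Nyquist
  if (n_cycles > K) stop("stimulus frequency at or above Nyquist")
  bins <- 2:(K + 1L)
  amps <- Mod(X[bins, , drop = FALSE])
  denom <- sqrt(colSums(amps^2))
  a_stim <- amps[n_cycles, ]
  coherence <- ifelse(denom > 0, a_stim / denom, 0)
  phase <- (-Arg(X[n_cycles + 1L, ])) %% (2 * pi)
  structure(
    data.frame(coherence = coherence, phase = phase,
               amplitude = 2 * a_stim / n),
    n_freq_bins = K
  )
}

#' Convert coherence to a p-value
#'
#' Under independent Gaussian noise the squared coherence over `K` non-DC
#' frequency bins is Beta(1, K - 1), giving the exceedance probability
#' `p = (1 - c^2)^(K - 1)`.
#'
#' @param coherence Coherence value(s) in `[0, 1]`.
#' @param n_freq_bins Number of non-DC frequency bins `K` (attribute of
#'   [fourier_analysis()] output).
#' @return p-value(s), monotone decreasing in coherence.
#' @export
coherence_to_p <- function(coherence, n_freq_bins) {
  if (n_freq_bins < 2) stop("need at least 2 frequency bins")
  stopifnot(all(coherence >= 0 & coherence <= 1))
  (1 - coherence^2)^(n_freq_bins - 1)
}

#' Hommel multiple-comparison correction
#'
#' Stagewise-Bonferroni (Hommel) adjusted p-values across voxels, via
#' `stats::p.adjust(method = "hommel")`.
#'
#' @param p_list Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, never smaller than the raw ones.
#' @export
correct_pvalues <- function(p_list) {
  if (length(p_list) == 0) stop("empty p-value list")
  stopifnot(all(p_list >= 0 & p_list <= 1))
  stats::p.adjust(p_list, method = "hommel")
}

#' Discretise response phase into location labels
#'
#' Partitions `[0, 2 pi)` into `n_bins` contiguous half-open bins of equal
#' width starting at `offset`, so the between-digit phases map to digits
#' D2--D5 and the within-digit phases to PD1--PD4.
#'
#' @param phase Phase(s) in radians (wrapped automatically).
#' @param n_bins Number of labels (default 4).
#' @param offset Phase of the first bin edge (radians, default 0).
#' @return Integer label(s) in `1..n_bins`.
#' @export
phase_to_label <- function(phase, n_bins = 4L, offset = 0) {
  wrapped <- (phase - offset) %% (2 * pi)
  lab <- floor(wrapped / (2 * pi / n_bins)) + 1L
  as.integer(pmin(lab, n_bins))   # guard against 2*pi wrap at the boundary
}

#' Travelling-wave analysis of one paradigm across voxels
#'
#' Pairs the forward and reverse runs of a paradigm within a preprocessed
#' session, combines each pair with [combine_forward_reverse()], averages
#' the pairs, and derives coherence, phase, amplitude, raw and
#' Hommel-corrected p-values, and discrete location labels.
#'
#' @param Y Time-points x voxels matrix of preprocessed (percent signal
#'   change) data for the whole session.
#' @param seq The session `stim_sequence` whose `runs` table locates the
#'   paradigm's runs.
#' @param paradigm `"between"`, `"within"` or `"diagonal"`.
#' @param lag Haemodynamic lag passed to [combine_forward_reverse()].
#' @param phase_offset Offset passed to [phase_to_label()]. The default
#'   `-pi/8` centres the discrete stimulation-epoch phases (each line's ON
#'   block straddles the first samples of its quarter-cycle) in their bins.
#' @return Data frame with one row per voxel: `voxel`, `coherence`, `phase`,
#'   `amplitude`, `p_raw`, `p_corrected`, `label`.
#' @export
tw_analysis <- function(Y, seq, paradigm = "between", lag = 4,
                        phase_offset = -pi / 8) {
  Y <- as.matrix(Y)
  runs <- seq$runs[seq$runs$paradigm == paradigm, , drop = FALSE]
  if (nrow(runs) == 0) stop("no runs of paradigm '", paradigm, "'")
  fwd <- runs[runs$direction == "forward", , drop = FALSE]
  rev_ <- runs[runs$direction == "reverse", , drop = FALSE]
  cycle_tp <- as.integer(round(runs$cycle_len[1] / seq$tr))
  n_pairs <- min(nrow(fwd), nrow(rev_))
  if (n_pairs >= 1L) {
    acc <- 0
    for (i in seq_len(n_pairs)) {
      Ff <- Y[fwd$start[i]:fwd$end[i], , drop = FALSE]
      Rr <- Y[rev_$start[i]:rev_$end[i], , drop = FALSE]
      acc <- acc + combine_forward_reverse(Ff, Rr, lag = lag, tr = seq$tr)
    }
    comb <- acc / n_pairs
  } else {
    # forward-only fallback: phase retains the haemodynamic delay
    comb <- Y[fwd$start[1]:fwd$end[1], , drop = FALSE]
    warning("no forward/reverse pair for '", paradigm,
            "'; phase includes haemodynamic delay")
  }
  fa <- fourier_analysis(comb, cycle_tp)
  K <- attr(fa, "n_freq_bins")
  p_raw <- coherence_to_p(fa$coherence, K)
  data.frame(
    voxel = seq_len(ncol(Y)),
    coherence = fa$coherence, phase = fa$phase, amplitude = fa$amplitude,
    p_raw = p_raw, p_corrected = correct_pvalues(p_raw),
    label = phase_to_label(fa$phase, offset = phase_offset)
  )
}
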