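# Sensory grid geometry.
#
# The stimulation array is a 4 x 4 grid of vibrotactile sites: four digits
# (D2..D5, coded 1..4 on the digit axis, 1 = index finger D2) by four
# proximal-distal (PD) locations along each digit (PD1 = tip .. PD4 = base).
# Site linear index = (digit - 1) * 4 + pd, i.e. sites 1..4 are D2 tip..base,
# sites 5..8 are D3 tip..base, and so on (column-major in digit).

#' Create a sensory grid specification
#'
#' Describes the digit-by-phalanx stimulation grid. The default (and the only
#' layout used by the vibrotactile protocol implemented here) is 4 digits
#' (D2--D5) by 4 proximal--distal (PD) sites (tip to base), i.e. 16 sites.
#'
#' @param n_digits Number of digits covered by the array (default 4, D2--D5).
#' @param n_pd Number of proximal--distal sites per digit (default 4,
#'   PD1 = tip to PD4 = base).
#'
#' @return An object of class `grid_spec`: a list with `n_digits`, `n_pd`,
#'   `n_sites`, and a `sites` data frame giving, for every linear site index,
#'   its digit and PD coordinates in grid units (1..4 on each axis).
#' @export
#' @examples
#' g <- grid_spec()
#' g$n_sites       # 16
#' head(g$sites)
grid_spec <- function(n_digits = 4L, n_pd = 4L) {
  n_digits <- as.integer(n_digits)
  n_pd <- as.integer(n_pd)
  stopifnot(n_digits >= 1L, n_pd >= 1L)
  sites <- data.frame(
    site = seq_len(n_digits * n_pd),
    digit = rep(seq_len(n_digits), each = n_pd),
    pd = rep(seq_len(n_pd), times = n_digits)
  )
  structure(
    list(n_digits = n_digits, n_pd = n_pd,
         n_sites = n_digits * n_pd, sites = sites),
    class = "grid_spec"
  )
}

#' Linear site index from grid coordinates
#'
#' @param digit Digit coordinate (1 = D2 .. 4 = D5).
#' @param pd Proximal--distal coordinate (1 = tip .. 4 = base).
#' @param grid A [grid_spec()].
#' @return Integer linear site index in `1..grid$n_sites`. Vectorised.
#' @export
site_index <- function(digit, pd, grid = grid_spec()) {
  stopifnot(all(digit >= 1 & digit <= grid$n_digits),
            all(pd >= 1 & pd <= grid$n_pd))
  as.integer((digit - 1L) * grid$n_pd + pd)
}

#' Grid coordinates from linear site index
#'
#' @param site Linear site index (1-based).
#' @param grid A [grid_spec()].
#' @return Data frame with columns `digit` and `pd`. Vectorised.
#' @export
site_coords <- function(site, grid = grid_spec()) {
  stopifnot(all(site >= 1 & site <= grid$n_sites))
  site <- as.integer(site)
  data.frame(digit = (site - 1L) %/% grid$n_pd + 1L,
             pd = (site - 1L) %% grid$n_pd + 1L)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d digits x %d PD sites (%d sites)\n",
              x$n_digits, x$n_pd, x$n_sites))
  invisible(x)
}
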