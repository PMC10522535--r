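# Map agreement and model comparison.

#' Dice coefficient between two label maps
#'
#' `2 |A n B| / (|A| + |B|)` where A and B are the voxel sets carrying
#' `label_value` in each map. Returns `NA` when both sets are empty.
#'
#' @param labels_a,labels_b Integer label vectors over a common voxel set.
#' @param label_value The label whose supports are compared.
#' @return Scalar in `[0, 1]`, or `NA` if the label is absent from both.
#' @export
dice_coefficient <- function(labels_a, labels_b, label_value) {
  if (length(labels_a) != length(labels_b)) {
    stop("label maps must cover the same voxels")
  }
  a <- labels_a == label_value
  b <- labels_b == label_value
  denom <- sum(a, na.rm = TRUE) + sum(b, na.rm = TRUE)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b, na.rm = TRUE) / denom
}

#' Full Dice matrix over label pairs
#'
#' Entry (i, j) is the Dice coefficient between the voxels labelled `i` in
#' the first map and `j` in the second, computed as the overlap statistic
#' `2 |A_i n B_j| / (|A_i| + |B_j|)`. The diagonal reproduces
#' [dice_coefficient()] per label.
#'
#' @inheritParams dice_coefficient
#' @param n_labels Number of labels (default 4).
#' @return `n_labels x n_labels` numeric matrix.
#' @export
dice_matrix <- function(labels_a, labels_b, n_labels = 4L) {
  out <- matrix(NA_real_, n_labels, n_labels)
  for (i in seq_len(n_labels)) {
    for (j in seq_len(n_labels)) {
      a <- labels_a == i
      b <- labels_b == j
      denom <- sum(a, na.rm = TRUE) + sum(b, na.rm = TRUE)
      out[i, j] <- if (denom == 0) NA_real_ else
        2 * sum(a & b, na.rm = TRUE) / denom
    }
  }
  dimnames(out) <- list(paste0("a", seq_len(n_labels)),
                        paste0("b", seq_len(n_labels)))
  out
}

#' Round continuous preferred locations to grid labels
#'
#' @param x Continuous preferred locations in grid units.
#' @param n_labels Number of grid positions (default 4).
#' @return Integer labels in `1..n_labels` (nearest integer, clamped).
#' @export
location_to_label <- function(x, n_labels = 4L) {
  as.integer(pmin(pmax(round(x), 1L), n_labels))
}

#' AIC preference matrix across model families
#'
#' Entry (A, B) is the percentage of voxels where family A's AIC is lower
#' than family B's; ties are split evenly between the two and the diagonal
#' is reported as 50, so `P(A,B) + P(B,A) = 100` always.
#'
#' @param fit_table A [fit_patch()] table (or any data frame with `voxel`,
#'   `family`, `aic` columns) covering the same voxels for every family.
#' @return Numeric matrix of percentages with family dimnames.
#' @export
aic_preference_matrix <- function(fit_table) {
  fams <- unique(fit_table$family)
  vox <- sort(unique(fit_table$voxel))
  aic <- sapply(fams, function(f) {
    sub <- fit_table[fit_table$family == f, ]
    if (!identical(sort(sub$voxel), vox)) {
      stop("voxel sets differ across families")
    }
    sub$aic[match(vox, sub$voxel)]
  })
  n <- length(fams)
  out <- matrix(50, n, n, dimnames = list(fams, fams))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      wins <- sum(aic[, i] < aic[, j]) + 0.5 * sum(aic[, i] == aic[, j])
      out[i, j] <- 100 * wins / length(vox)
    }
  }
  out
}
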