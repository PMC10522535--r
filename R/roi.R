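# ROI aggregation of pRF sizes and group comparisons.
#
# Voxels are aggregated into 16 regions of interest per scheme: functionally
# by proximal-distal location x digit, or anatomically by area band x digit.
# The observational unit for the group statistics is the subject-wise ROI
# mean.

#' Build a voxel ROI label table
#'
#' @param voxel Voxel identifiers.
#' @param subject Subject identifiers.
#' @param digit Digit label 1..4 (D2..D5).
#' @param pd Proximal--distal label 1..4 (tip..base).
#' @param area Area-band label (e.g. `"3a"`, `"3b"`, `"1"`, `"2"`).
#' @return Data frame of class `roi_labels`.
#' @export
roi_labels <- function(voxel, subject, digit, pd, area) {
  out <- data.frame(voxel = voxel, subject = subject,
                    digit = as.integer(digit), pd = as.integer(pd),
                    area = as.character(area), stringsAsFactors = FALSE)
  stopifnot(all(out$digit %in% 1:4), all(out$pd %in% 1:4))
  class(out) <- c("roi_labels", class(out))
  out
}

#' Aggregate pRF sizes over ROIs
#'
#' Joins a [fit_patch()] table with ROI labels, keeps voxels passing the
#' adjusted r-squared threshold, and computes subject-wise mean pRF sizes
#' per ROI (scheme label x digit) plus the group mean per ROI. Empty ROIs
#' are omitted with a warning.
#'
#' @param fit_table A [fit_patch()] result (one family).
#' @param labels A [roi_labels()] table covering the fitted voxels.
#' @param scheme `"pd"` (functional) or `"area"` (anatomical).
#' @param r2_threshold Keep voxels with `adjusted_r2 >` this (default 0).
#' @return List with `by_subject` (roi, scheme label, digit, subject,
#'   sigma_d, sigma_pd, n_voxels) and `by_roi` (group means per ROI).
#' @export
aggregate_prf_size <- function(fit_table, labels, scheme = c("pd", "area"),
                               r2_threshold = 0) {
  scheme <- match.arg(scheme)
  fams <- unique(fit_table$family)
  if (length(fams) != 1L) stop("pass a single-family fit table")
  keep <- !is.na(fit_table$adjusted_r2) &
    fit_table$adjusted_r2 > r2_threshold
  tab <- merge(fit_table[keep, ], labels, by = "voxel")
  if (nrow(tab) == 0) stop("no voxels pass the adjusted r2 threshold")
  tab$roi <- paste0(scheme, tab[[scheme]], "_D", tab$digit + 1L)
  agg <- function(x) stats::aggregate(
    cbind(sigma_d, sigma_pd) ~ roi + subject,
    data = x, FUN = mean, na.action = stats::na.pass)
  by_subject <- agg(tab)
  n_vox <- stats::aggregate(voxel ~ roi + subject, data = tab, FUN = length)
  names(n_vox)[3] <- "n_voxels"
  by_subject <- merge(by_subject, n_vox, by = c("roi", "subject"))
  by_roi <- stats::aggregate(cbind(sigma_d, sigma_pd) ~ roi,
                             data = by_subject, FUN = mean,
                             na.action = stats::na.pass)
  all_rois <- paste0(scheme, rep(sort(unique(labels[[scheme]])), each = 4),
                     "_D", 2:5)
  missing <- setdiff(all_rois, by_roi$roi)
  if (length(missing)) {
    warning("empty ROI(s) omitted: ", paste(missing, collapse = ", "))
  }
  list(by_subject = by_subject, by_roi = by_roi)
}

#' ROI volumes from voxel counts
#'
#' @param labels A [roi_labels()] table.
#' @param voxel_volume Volume of one voxel in mm^3 (1.25 mm isotropic
#'   voxels give 1.953125 mm^3).
#' @param scheme `"pd"` or `"area"`.
#' @return Data frame: `roi`, `n_voxels`, `volume_mm3`.
#' @export
roi_volume <- function(labels, voxel_volume, scheme = c("pd", "area")) {
  scheme <- match.arg(scheme)
  stopifnot(voxel_volume > 0)
  roi <- paste0(scheme, labels[[scheme]], "_D", labels$digit + 1L)
  cnt <- as.data.frame(table(roi), stringsAsFactors = FALSE)
  names(cnt) <- c("roi", "n_voxels")
  cnt$volume_mm3 <- cnt$n_voxels * voxel_volume
  cnt
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Compares per-subject ROI values across the levels of a grouping factor
#' (digit, PD location, or area band): single-factor ANOVA F and p plus
#' Tukey honest-significant-difference adjusted pairwise comparisons.
#'
#' @param values Numeric response (e.g. subject-wise mean pRF size).
#' @param group Grouping factor, at least 2 levels with at least 2 values
#'   each.
#' @return List with `F`, `p`, `anova` (the `aov` fit), `tukey` (data frame
#'   of pairwise differences and adjusted p-values), and `degenerate`
#'   (TRUE when the residual variance is zero).
#' @export
compare_groups <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("each group needs at least 2 values")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  degenerate <- tab["Residuals", "Sum Sq"] < .Machine$double.eps *
    max(1, sum(values^2))
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = tab["group", "F value"], p = tab["group", "Pr(>F)"],
       anova = fit, tukey = tukey, degenerate = degenerate)
}
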