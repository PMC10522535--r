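# pRF coverage maps.
#
# A voxel's coverage of sensory space is its 4x4 weight grid. Per ROI the
# maps are (1) upsampled to 20x20 by separable cubic-spline (bicubic)
# interpolation, (2) placed centrally in a 60x60 frame whose surround is
# filled by solving the discrete Laplace equation with the known block as
# Dirichlet data, (3) summarised across voxels by PCA with subject-wise
# equal weighting, and (4) optionally peak-aligned before averaging.
# Rows index the digit axis, columns the proximal-distal axis throughout.

#' Upsample a native 4x4 weight grid to 20x20
#'
#' Separable (bicubic) natural cubic-spline interpolation: each row is
#' interpolated from 4 to 20 samples over the native coordinate range, then
#' each resulting column. Native lattice values are reproduced wherever a
#' target sample coincides with a native position (the four corners always
#' do).
#'
#' @param native Numeric 4x4 matrix (any square size works).
#' @param out_n Output side length (default 20).
#' @return `out_n x out_n` numeric matrix.
#' @export
upsample_grid <- function(native, out_n = 20L) {
  native <- as.matrix(native)
  if (any(!is.finite(native))) stop("NaN/Inf in native grid")
  n <- nrow(native)
  stopifnot(ncol(native) == n, n >= 2L)
  xs <- seq(1, n, length.out = out_n)
  interp1 <- function(y) {
    stats::spline(seq_len(n), y, xout = xs, method = "natural")$y
  }
  half <- t(apply(native, 1L, interp1))   # n x out_n
  apply(half, 2L, interp1)                # out_n x out_n
}

# Cached sparse Laplace factorisation per (frame, block) geometry.
.laplace_cache <- new.env(parent = emptyenv())

laplace_system <- function(frame_n, block_idx) {
  key <- paste(frame_n, min(block_idx), max(block_idx), sep = "_")
  if (!is.null(.laplace_cache[[key]])) return(.laplace_cache[[key]])
  known <- matrix(FALSE, frame_n, frame_n)
  known[block_idx, block_idx] <- TRUE
  idx <- matrix(seq_len(frame_n^2), frame_n, frame_n)
  unk <- which(!known)
  pos <- integer(frame_n^2)
  pos[unk] <- seq_along(unk)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  # rhs is assembled per map later; record which known neighbour feeds which
  # unknown equation
  rk_rows <- integer(0); rk_known <- integer(0)
  nbr_shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (u in seq_along(unk)) {
    lin <- unk[u]
    r <- (lin - 1L) %% frame_n + 1L
    c <- (lin - 1L) %/% frame_n + 1L
    deg <- 0L
    for (s in nbr_shifts) {
      rr <- r + s[1]; cc <- c + s[2]
      if (rr < 1 || rr > frame_n || cc < 1 || cc > frame_n) next
      deg <- deg + 1L
      nlin <- idx[rr, cc]
      if (known[nlin]) {
        rk_rows <- c(rk_rows, u); rk_known <- c(rk_known, nlin)
      } else {
        rows <- c(rows, u); cols <- c(cols, pos[nlin]); vals <- c(vals, -1)
      }
    }
    rows <- c(rows, u); cols <- c(cols, u); vals <- c(vals, deg)
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(length(unk), length(unk)))
  sys <- list(chol = Matrix::Cholesky(Matrix::forceSymmetric(A)),
              unk = unk, rk_rows = rk_rows, rk_known = rk_known,
              n_unk = length(unk))
  .laplace_cache[[key]] <- sys
  sys
}

#' Extrapolate a known block into a larger frame by Laplace's equation
#'
#' The known grid is placed centrally in an `frame_n x frame_n` frame and
#' every surrounding cell is filled so that it equals the mean of its
#' in-frame neighbours (discrete Laplace equation, Dirichlet data on the
#' known block, zero-flux at the frame edge). Known cells are never
#' altered and filled values obey the maximum principle.
#'
#' @param known Numeric matrix (typically the 20x20 upsampled grid; must be
#'   square and no larger than `frame_n`).
#' @param frame_n Output frame side length (default 60).
#' @return `frame_n x frame_n` matrix agreeing with `known` on the central
#'   block.
#' @export
extrapolate_pde <- function(known, frame_n = 60L) {
  known <- as.matrix(known)
  kb <- nrow(known)
  stopifnot(ncol(known) == kb, kb <= frame_n)
  off <- (frame_n - kb) %/% 2L
  block_idx <- off + seq_len(kb)
  out <- matrix(NA_real_, frame_n, frame_n)
  out[block_idx, block_idx] <- known
  if (kb == frame_n) return(out)
  sys <- laplace_system(frame_n, block_idx)
  b <- numeric(sys$n_unk)
  vals <- out[sys$rk_known]
  for (i in seq_along(sys$rk_rows)) {
    b[sys$rk_rows[i]] <- b[sys$rk_rows[i]] + vals[i]
  }
  x <- as.numeric(Matrix::solve(sys$chol, b))
  out[sys$unk] <- x
  out
}

#' Build extrapolated coverage maps for a set of voxel models
#'
#' Evaluates each voxel's native 4x4 weight grid, upsamples it and fills
#' the 60x60 frame; the Laplace system is factorised once and solved for
#' all voxels together.
#'
#' @param pmat Parameter matrix (voxels x parameters) as stored by
#'   [fit_patch()] in its `params` attribute.
#' @param family Model family of `pmat`.
#' @param grid A [grid_spec()].
#' @param up_n,frame_n Upsampled and frame side lengths (20 and 60).
#' @return List of `frame_n x frame_n` matrices, one per voxel row.
#' @export
coverage_from_params <- function(pmat, family, grid = grid_spec(),
                                 up_n = 20L, frame_n = 60L) {
  nv <- nrow(pmat)
  off <- (frame_n - up_n) %/% 2L
  block_idx <- off + seq_len(up_n)
  sys <- laplace_system(frame_n, block_idx)
  spn <- spatial_param_names(family)
  maps <- vector("list", nv)
  B <- matrix(0, sys$n_unk, nv)
  for (v in seq_len(nv)) {
    m <- prf_model(family, pmat[v, spn])
    up <- upsample_grid(eval_weights(m, grid), up_n)
    out <- matrix(NA_real_, frame_n, frame_n)
    out[block_idx, block_idx] <- up
    vals <- out[sys$rk_known]
    b <- numeric(sys$n_unk)
    for (i in seq_along(sys$rk_rows)) {
      b[sys$rk_rows[i]] <- b[sys$rk_rows[i]] + vals[i]
    }
    B[, v] <- b
    maps[[v]] <- out
  }
  X <- as.matrix(Matrix::solve(sys$chol, B))
  for (v in seq_len(nv)) maps[[v]][sys$unk] <- X[, v]
  maps
}

#' PCA-summarised average coverage map
#'
#' Flattens the voxel maps, performs PCA across voxels, reconstructs every
#' map from the first `n_components` components, averages the
#' reconstructions within each subject and then across subjects with equal
#' subject weight (so no subject dominates through voxel count). With
#' `mode = "per_subject"` the PCA itself is computed within each subject
#' before reconstruction; the default pools voxels in one PCA.
#'
#' @param maps List of equally sized numeric matrices, one per voxel.
#' @param subject_ids Vector assigning each map to a subject (default: all
#'   one subject).
#' @param n_components Number of principal components kept (default 3;
#'   reduced with a warning when fewer maps are available).
#' @param mode `"pooled"` (one PCA over all voxels) or `"per_subject"`.
#' @return List with `average` (matrix), `explained_variance` (proportion
#'   per kept component; pooled mode only), `n_components`, `mode`.
#' @export
pca_average <- function(maps, subject_ids = NULL, n_components = 3L,
                        mode = c("pooled", "per_subject")) {
  mode <- match.arg(mode)
  nv <- length(maps)
  stopifnot(nv >= 1L)
  if (is.null(subject_ids)) subject_ids <- rep(1L, nv)
  stopifnot(length(subject_ids) == nv)
  dm <- dim(maps[[1L]])
  M <- t(vapply(maps, as.numeric, numeric(prod(dm))))
  reconstruct <- function(M, k) {
    k <- min(k, nrow(M) - 1L, ncol(M))
    if (k < 1L) {
      return(list(R = M, ev = NULL, k = 0L))   # too few maps: identity
    }
    pc <- stats::prcomp(M, center = TRUE, rank. = k)
    R <- pc$x %*% t(pc$rotation)
    R <- sweep(R, 2L, pc$center, "+")
    tot <- sum(pc$sdev^2)
    ev <- if (tot > 0) (pc$sdev^2 / tot)[seq_len(k)] else
      c(1, rep(0, k - 1L))    # identical maps: PC1 trivially explains all
    list(R = R, ev = ev, k = k)
  }
  subjects <- unique(subject_ids)
  if (mode == "pooled") {
    if (nv - 1L < n_components) {
      warning("fewer maps than components; reducing to ", max(nv - 1L, 0L))
    }
    rec <- reconstruct(M, n_components)
    subj_means <- vapply(subjects, function(s) {
      colMeans(rec$R[subject_ids == s, , drop = FALSE])
    }, numeric(prod(dm)))
    ev <- rec$ev
    k <- rec$k
  } else {
    subj_means <- vapply(subjects, function(s) {
      rec <- reconstruct(M[subject_ids == s, , drop = FALSE], n_components)
      colMeans(rec$R)
    }, numeric(prod(dm)))
    ev <- NULL
    k <- n_components
  }
  avg <- matrix(rowMeans(subj_means), dm[1], dm[2])
  list(average = avg, explained_variance = ev, n_components = k, mode = mode)
}

#' Peak-aligned average of coverage maps
#'
#' Shifts each map by whole cells so that its peak lands on the frame
#' centre along the chosen axis (or both), then averages; cells shifted out
#' of frame are dropped and the average at each cell is normalised by the
#' number of maps contributing there. Maps without a unique-valued peak
#' (constant maps) are excluded with a warning.
#'
#' @param maps List of equally sized matrices (rows = digit axis,
#'   columns = PD axis).
#' @param axis `"digit"` (align rows), `"pd"` (align columns) or `"both"`.
#' @return The aligned average matrix (`NA` where no map contributed).
#' @export
peak_align <- function(maps, axis = c("digit", "pd", "both")) {
  axis <- match.arg(axis)
  dm <- dim(maps[[1L]])
  centre <- (dm + 1L) %/% 2L
  acc <- matrix(0, dm[1], dm[2])
  cnt <- matrix(0L, dm[1], dm[2])
  used <- 0L
  for (m in maps) {
    rng <- range(m)
    if (rng[1] == rng[2]) {
      warning("flat map excluded from peak alignment")
      next
    }
    pk <- which(m == rng[2], arr.ind = TRUE)[1L, ]
    dr <- if (axis %in% c("digit", "both")) centre[1] - pk[1] else 0L
    dc <- if (axis %in% c("pd", "both")) centre[2] - pk[2] else 0L
    src_r <- seq_len(dm[1]) - dr
    src_c <- seq_len(dm[2]) - dc
    ok_r <- src_r >= 1L & src_r <= dm[1]
    ok_c <- src_c >= 1L & src_c <= dm[2]
    acc[ok_r, ok_c] <- acc[ok_r, ok_c] + m[src_r[ok_r], src_c[ok_c]]
    cnt[ok_r, ok_c] <- cnt[ok_r, ok_c] + 1L
    used <- used + 1L
  }
  if (used == 0L) stop("no usable maps for peak alignment")
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Second-moment width of a coverage map
#'
#' Weight-variance summary used to compare how diffuse two coverage maps
#' are: the weighted standard deviation of cell positions around the map's
#' centre of mass, computed on the positive part of the map.
#'
#' @param map Numeric matrix.
#' @return Named numeric: `width_digit`, `width_pd` (in cells).
#' @export
coverage_width <- function(map) {
  w <- pmax(map, 0)
  w[is.na(w)] <- 0
  tot <- sum(w)
  if (tot == 0) return(c(width_digit = NA_real_, width_pd = NA_real_))
  r <- row(map); c_ <- col(map)
  mr <- sum(w * r) / tot
  mc <- sum(w * c_) / tot
  c(width_digit = sqrt(sum(w * (r - mr)^2) / tot),
    width_pd = sqrt(sum(w * (c_ - mc)^2) / tot))
}
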