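#' Dice volume-overlap score of two masks
#'
#' \code{DS = 2 |A intersect B| / (|A| + |B|)} on voxel counts, in [0, 1].
#'
#' @param A,B \code{binary_mask}s on identical grids, not both empty.
#' @return scalar Dice score.
#' @export
dice <- function(A, B) {
  stopifnot(is_binary_mask(A), is_binary_mask(B))
  if (!same_grid(A, B)) stop("grid mismatch")
  na <- sum(A$data); nb <- sum(B$data)
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(A$data & B$data) / (na + nb)
}

# 2D boundary voxel centres of one axial slice of a mask, in-plane mm.
# A mask voxel is boundary if any 4-neighbour (or the slice border) is
# outside the mask.
slice_boundary_points <- function(mask, k) {
  sl <- mask$data[, , k, drop = TRUE]
  if (!any(sl)) return(NULL)
  d <- dim(sl)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- sl
  inner <- pad[1:d[1], 2:(d[2] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1)] &
    pad[2:(d[1] + 1), 1:d[2]] & pad[2:(d[1] + 1), 3:(d[2] + 2)]
  bnd <- which(sl & !inner, arr.ind = TRUE)
  cbind(mask$origin[1] + (bnd[, 1] - 1) * mask$spacing[1],
        mask$origin[2] + (bnd[, 2] - 1) * mask$spacing[2])
}

# 3D boundary voxel centres (6-connectivity) of a mask, world mm
boundary_points_3d <- function(mask) {
  m <- mask$data
  if (!any(m)) return(NULL)
  inner <- shift_array(m, 1, 0, 0, FALSE) & shift_array(m, -1, 0, 0, FALSE) &
    shift_array(m, 0, 1, 0, FALSE) & shift_array(m, 0, -1, 0, FALSE) &
    shift_array(m, 0, 0, 1, FALSE) & shift_array(m, 0, 0, -1, FALSE)
  idx <- arrayInd(which(m & !inner), dim(m)) - 1L
  index_to_world(mask, idx)
}

directed_hausdorff <- function(a, b) {
  # max over a of the min distance to b; both are point matrices
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(max(pmax(apply(d2, 1, min), 0)))
}

#' Symmetric Hausdorff distance between two in-plane boundaries
#'
#' The boundary of each mask slice is represented by its boundary voxel
#' centres; the symmetric Hausdorff distance is the larger of the two
#' directed maximum-minimum distances, in in-plane mm.
#'
#' @param a,b two-column matrices of in-plane boundary points (mm), both
#'   non-empty (as produced internally per slice, or any point sets).
#' @return scalar distance in mm.
#' @export
slice_hausdorff <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = ncol(as.matrix(a)))
  b <- matrix(as.numeric(b), ncol = ncol(as.matrix(b)))
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty boundary")
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

#' Mean slicewise Hausdorff distance (MSHD)
#'
#' The symmetric Hausdorff distance is computed on every axial slice where
#' the expert mask is present and averaged over those slices. On expert
#' slices where the propagated mask is absent, the slice value is the
#' directed maximum-minimum distance from the expert boundary points on
#' that slice to the propagated mask's full 3D boundary, so gross
#' under-propagation is penalized rather than silently skipped.
#'
#' @param propagated,expert \code{binary_mask}s on identical grids;
#'   \code{expert} selects the slices and neither may be empty.
#' @return list with \code{mshd_mm} and \code{slice_count_used}.
#' @export
mshd <- function(propagated, expert) {
  stopifnot(is_binary_mask(propagated), is_binary_mask(expert))
  if (!same_grid(propagated, expert)) stop("grid mismatch")
  if (!any(expert$data)) stop("expert mask is empty")
  if (!any(propagated$data)) stop("propagated mask is empty")
  ks <- which(apply(expert$data, 3, any))
  b3d <- NULL
  vals <- vapply(ks, function(k) {
    be <- slice_boundary_points(expert, k)
    bp <- slice_boundary_points(propagated, k)
    if (is.null(bp)) {
      if (is.null(b3d)) b3d <<- boundary_points_3d(propagated)
      ke <- cbind(be, expert$origin[3] + (k - 1) * expert$spacing[3])
      directed_hausdorff(ke, b3d)
    } else {
      slice_hausdorff(be, bp)
    }
  }, numeric(1))
  list(mshd_mm = mean(vals), slice_count_used = length(ks))
}

#' Centre-of-mass displacement between two masks
#'
#' The COM of each mask is the unweighted mean of its member-voxel world
#' centres; the displacement is \code{COM(A) - COM(B)} with Euclidean
#' magnitude in mm.
#'
#' @param A,B non-empty \code{binary_mask}s (grids may differ).
#' @return list with \code{vector_mm} (length 3) and \code{magnitude_mm}.
#' @export
com_displacement <- function(A, B) {
  stopifnot(is_binary_mask(A), is_binary_mask(B))
  com <- function(m) {
    w <- which(m$data)
    if (!length(w)) stop("empty mask")
    colMeans(index_to_world(m, arrayInd(w, vol_dim(m)) - 1L))
  }
  v <- com(A) - com(B)
  list(vector_mm = as.numeric(v), magnitude_mm = sqrt(sum(v^2)))
}

#' Per-ROI agreement report between a propagated and an expert mask
#'
#' Bundles the three agreement measures used for contour propagation QA:
#' Dice score, mean slicewise Hausdorff distance and (by convention
#' reported for GTVs) the centre-of-mass shift.
#'
#' @param propagated,expert \code{binary_mask}s on identical grids.
#' @return one-row data.frame: roi_label, dice, mshd_mm, com_dx, com_dy,
#'   com_dz, com_mag_mm, slice_count_used.
#' @export
metric_report <- function(propagated, expert) {
  ds <- dice(propagated, expert)
  h <- mshd(propagated, expert)
  cm <- com_displacement(propagated, expert)
  data.frame(roi_label = expert$label, dice = ds, mshd_mm = h$mshd_mm,
             com_dx = cm$vector_mm[1], com_dy = cm$vector_mm[2],
             com_dz = cm$vector_mm[3], com_mag_mm = cm$magnitude_mm,
             slice_count_used = h$slice_count_used)
}
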