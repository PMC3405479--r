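#' Parameters for salient-feature-based registration
#'
#' @param reliability_threshold minimum local correlation for a feature
#'   match to be retained (default 0.80).
#' @param search_radius_mm half-extent of the exhaustive displacement
#'   search around each feature, mm (default 15).
#' @param target_anchor_count maximum number of detected features kept,
#'   strongest first (default 1500; typical head-and-neck registrations use
#'   1000-2000 reliable anchors).
#' @param scale_levels_mm detector Gaussian scales in mm, ascending
#'   (default 4 levels geometrically spanning 2-12 mm).
#' @param tps_lambda thin-plate-spline regularization (0 = exact
#'   interpolation of the anchors).
#' @param min_contrast_mad contrast cut: candidate extrema whose |response|
#'   is below this multiple of the DoG level's median absolute deviation
#'   (a robust noise-floor estimate) are rejected as noise blobs. 0
#'   disables.
#' @param consistency_tol_mm anchor displacements are assumed to sample a
#'   smooth deformation; a retained correspondence whose displacement
#'   deviates from the componentwise median of its 8 nearest anchors by
#'   more than this (mm) is rejected as an outlier. Inf disables.
#' @param second_peak_ratio distinctiveness cut: a match is discarded when
#'   the correlation surface has a second peak (more than 2 voxels from
#'   the best displacement) exceeding this fraction of the best
#'   correlation — such correspondences are ambiguous, typically from
#'   structures that are self-similar along a direction. 1 disables.
#' @param min_hessian_ratio blob-ness cut: candidate extrema whose DoG
#'   Hessian eigenvalue ratio min|lambda|/max|lambda| falls below this are
#'   rejected as ridge/edge responses (the 3D analogue of the classic DoG
#'   edge-rejection test); such points are not point-like and match
#'   ambiguously along the structure. 0 disables the test.
#' @return an object of class \code{sfbr_params}.
#' @export
sfbr_params <- function(reliability_threshold = 0.80,
                        search_radius_mm = 15,
                        target_anchor_count = 1500,
                        scale_levels_mm = 2 * (12 / 2)^((0:3) / 3),
                        tps_lambda = 0,
                        min_contrast_mad = 3,
                        consistency_tol_mm = 6,
                        second_peak_ratio = 0.95,
                        min_hessian_ratio = 0.1) {
  if (reliability_threshold <= 0 || reliability_threshold >= 1)
    stop("'reliability_threshold' must be in (0, 1)")
  if (search_radius_mm <= 0) stop("'search_radius_mm' must be > 0")
  if (length(scale_levels_mm) < 2 || any(diff(scale_levels_mm) <= 0))
    stop("'scale_levels_mm' must be ascending with >= 2 levels")
  structure(list(reliability_threshold = reliability_threshold,
                 search_radius_mm = search_radius_mm,
                 target_anchor_count = as.integer(target_anchor_count),
                 scale_levels_mm = as.numeric(scale_levels_mm),
                 tps_lambda = tps_lambda,
                 min_contrast_mad = min_contrast_mad,
                 consistency_tol_mm = consistency_tol_mm,
                 second_peak_ratio = second_peak_ratio,
                 min_hessian_ratio = min_hessian_ratio),
            class = "sfbr_params")
}

# shift a 3D array by integer offsets, padding with `fill`
shift_array <- function(a, dx, dy, dz, fill) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(sx) < 1 || length(sy) < 1 || length(sz) < 1) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# min|lambda|/max|lambda| of the finite-difference Hessian (mm^-2) of the
# DoG volume at interior candidate voxel indices (0-based). Ridge-like
# structures have one near-zero eigenvalue along the ridge and score ~0;
# isotropic blobs score ~1.
hessian_blobness <- function(a, idx, spacing) {
  d <- dim(a)
  i <- idx[, 1] + 1L; j <- idx[, 2] + 1L; k <- idx[, 3] + 1L
  at <- function(di, dj, dk)
    a[cbind(i + di, j + dj, k + dk)]
  c0 <- at(0, 0, 0)
  hxx <- (at(1, 0, 0) - 2 * c0 + at(-1, 0, 0)) / spacing[1]^2
  hyy <- (at(0, 1, 0) - 2 * c0 + at(0, -1, 0)) / spacing[2]^2
  hzz <- (at(0, 0, 1) - 2 * c0 + at(0, 0, -1)) / spacing[3]^2
  hxy <- (at(1, 1, 0) - at(1, -1, 0) - at(-1, 1, 0) + at(-1, -1, 0)) /
    (4 * spacing[1] * spacing[2])
  hxz <- (at(1, 0, 1) - at(1, 0, -1) - at(-1, 0, 1) + at(-1, 0, -1)) /
    (4 * spacing[1] * spacing[3])
  hyz <- (at(0, 1, 1) - at(0, 1, -1) - at(0, -1, 1) + at(0, -1, -1)) /
    (4 * spacing[2] * spacing[3])
  vapply(seq_along(c0), function(q) {
    H <- matrix(c(hxx[q], hxy[q], hxz[q],
                  hxy[q], hyy[q], hyz[q],
                  hxz[q], hyz[q], hzz[q]), 3, 3)
    ev <- abs(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    if (max(ev) == 0) 0 else min(ev) / max(ev)
  }, numeric(1))
}

# max / min over the 26-neighbourhood (excluding centre), borders padded
neighborhood_extrema <- function(a) {
  mx <- array(-Inf, dim(a)); mn <- array(Inf, dim(a))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    s <- shift_array(a, dx, dy, dz, NA)
    mx <- pmax(mx, s, na.rm = TRUE)
    mn <- pmin(mn, s, na.rm = TRUE)
  }
  list(max = mx, min = mn)
}

# including the centre (for cross-scale comparison)
neighborhood_extrema27 <- function(a) {
  e <- neighborhood_extrema(a)
  list(max = pmax(e$max, a), min = pmin(e$min, a))
}

#' Detect scale-attributed salient features
#'
#' Scale-normalized difference-of-Gaussians extrema: the volume is smoothed
#' at each configured scale (mm, converted per-axis to voxels), adjacent
#' smoothed volumes are differenced and normalized by the scale ratio, and
#' voxels that are strict extrema over the 26-neighbourhood in their own
#' DoG level and over the 27-neighbourhoods of the available adjacent
#' levels become features. Each feature carries a centre (world mm), a
#' scale (geometric mean of the bracketing sigmas, mm) and the signed
#' detector response. Features are ordered by |response| descending with
#' lexicographic centre tie-break and truncated to
#' \code{target_anchor_count}; the ordering is fully deterministic.
#'
#' @param volume an \code{image_volume}.
#' @param params an \code{sfbr_params}.
#' @return data.frame with columns x, y, z (mm), scale (mm), response.
#' @export
detect_salient_features <- function(volume, params = sfbr_params()) {
  stopifnot(is_image_volume(volume))
  if (stats::sd(volume$data) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      scale = numeric(0), response = numeric(0)))
  sig <- params$scale_levels_mm
  sm <- lapply(sig, function(s)
    gaussian_smooth_volume(volume, s / volume$spacing)$data)
  nl <- length(sig) - 1L
  dog <- vector("list", nl)
  for (i in seq_len(nl))
    dog[[i]] <- (sm[[i + 1]] - sm[[i]]) / (sig[i + 1] / sig[i] - 1)
  ex_in <- lapply(dog, neighborhood_extrema)
  ex27 <- lapply(dog, neighborhood_extrema27)
  d <- vol_dim(volume)
  feats <- list()
  for (i in seq_len(nl)) {
    a <- dog[[i]]
    ismax <- a > ex_in[[i]]$max
    ismin <- a < ex_in[[i]]$min
    if (i > 1L) {
      ismax <- ismax & (a > ex27[[i - 1]]$max)
      ismin <- ismin & (a < ex27[[i - 1]]$min)
    }
    if (i < nl) {
      ismax <- ismax & (a > ex27[[i + 1]]$max)
      ismin <- ismin & (a < ex27[[i + 1]]$min)
    }
    cand <- which(ismax | ismin)
    if (!length(cand)) next
    if ((params$min_contrast_mad %||% 0) > 0) {
      floor_i <- params$min_contrast_mad * stats::mad(a)
      cand <- cand[abs(a[cand]) >= floor_i]
      if (!length(cand)) next
    }
    idx <- arrayInd(cand, d) - 1L
    # exclude the outermost voxel shell (one-sided neighbourhoods)
    keep <- idx[, 1] > 0 & idx[, 1] < d[1] - 1 &
      idx[, 2] > 0 & idx[, 2] < d[2] - 1 &
      idx[, 3] > 0 & idx[, 3] < d[3] - 1
    if (!any(keep)) next
    idx <- idx[keep, , drop = FALSE]
    if (params$min_hessian_ratio > 0) {
      blob <- hessian_blobness(a, idx, volume$spacing) >=
        params$min_hessian_ratio
      if (!any(blob)) next
      keep[keep] <- blob
      idx <- idx[blob, , drop = FALSE]
    }
    w <- index_to_world(volume, idx)
    feats[[i]] <- data.frame(x = w[, 1], y = w[, 2], z = w[, 3],
                             scale = sqrt(sig[i] * sig[i + 1]),
                             response = a[cand[keep]])
  }
  if (!length(feats))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      scale = numeric(0), response = numeric(0)))
  f <- do.call(rbind, feats)
  f <- f[order(-abs(f$response), f$x, f$y, f$z), , drop = FALSE]
  rownames(f) <- NULL
  utils::head(f, params$target_anchor_count)
}

match_features_batch <- function(features, source, target, params) {
  stopifnot(same_grid(source, target))
  n <- nrow(features)
  d <- vol_dim(source)
  centers <- round(world_to_index(source, cbind(features$x, features$y,
                                                features$z)))
  storage.mode(centers) <- "integer"
  hw <- t(vapply(features$scale, function(s)
    pmax(1L, as.integer(ceiling(2 * s / source$spacing))), integer(3)))
  srange <- as.integer(ceiling(params$search_radius_mm / source$spacing))
  m <- cpp_match_search(as.numeric(source$data), as.numeric(target$data),
                        d, centers, hw, srange, 2L,
                        params$second_peak_ratio %||% 1)
  disp <- sweep(m[, 1:3, drop = FALSE], 2, source$spacing, "*")
  data.frame(x_source = features$x, y_source = features$y,
             z_source = features$z,
             x_target = features$x + disp[, 1],
             y_target = features$y + disp[, 2],
             z_target = features$z + disp[, 3],
             correlation = m[, 4],
             ok = m[, 5] > 0 & m[, 4] >= params$reliability_threshold)
}

#' Match one salient feature by local correlation
#'
#' The intensity window of half-width 2 x scale around the feature in the
#' source image is correlated (zero-mean NCC) against target windows at
#' every integer-voxel displacement within the search radius; the best
#' displacement is refined to sub-voxel precision by a separable quadratic
#' fit. The match is discarded (NULL) if the window leaves the source grid,
#' no candidate window fits the target, or the best correlation falls
#' below the reliability threshold.
#'
#' @param feature a one-row data.frame as returned by
#'   \code{detect_salient_features} (columns x, y, z, scale).
#' @param source,target \code{image_volume}s on a common grid.
#' @param params an \code{sfbr_params}.
#' @return a one-row data.frame (source point, target point, correlation)
#'   or \code{NULL} if discarded.
#' @export
match_feature <- function(feature, source, target,
                          params = sfbr_params()) {
  m <- match_features_batch(feature[1, , drop = FALSE], source, target,
                            params)
  if (!m$ok[1]) return(NULL)
  m[1, c("x_source", "y_source", "z_source",
         "x_target", "y_target", "z_target", "correlation")]
}

# reject correspondences whose displacement disagrees with the
# componentwise median displacement of their k nearest anchors (the true
# deformation is smooth, so neighbouring anchors must move coherently)
filter_consistent <- function(keep, tol_mm, k = 8) {
  n <- nrow(keep)
  if (!is.finite(tol_mm) || n <= k + 1) return(keep)
  src <- as.matrix(keep[, 1:3])
  disp <- as.matrix(keep[, 4:6]) - src
  D <- as.matrix(stats::dist(src))
  dev <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[2:(k + 1)]
    sqrt(sum((disp[i, ] - apply(disp[nb, , drop = FALSE], 2,
                                stats::median))^2))
  }, numeric(1))
  keep[dev <= tol_mm, , drop = FALSE]
}

#' Fit a 3D thin-plate-spline transform to point correspondences
#'
#' Solves the standard TPS linear system per output component with the 3D
#' biharmonic kernel U(r) = r: kernel block K + lambda I bordered by the
#' affine polynomial block. With \code{lambda = 0} the transform
#' interpolates every anchor exactly; the spline weights satisfy the
#' polynomial orthogonality side conditions by construction.
#'
#' @param correspondences data.frame with columns x_source..z_source and
#'   x_target..z_target (as produced by the matching step), >= 4 rows, not
#'   all coplanar.
#' @param lambda regularization weight, >= 0.
#' @return an object of class \code{tps_transform}.
#' @export
fit_tps <- function(correspondences, lambda = 0) {
  src <- as.matrix(correspondences[, c("x_source", "y_source", "z_source")])
  tgt <- as.matrix(correspondences[, c("x_target", "y_target", "z_target")])
  n <- nrow(src)
  if (n < 4) stop("need at least 4 correspondences")
  if (lambda < 0) stop("'lambda' must be >= 0")
  P <- cbind(1, src)
  if (qr(P)$rank < 4)
    stop("degenerate anchors: rank ", qr(P)$rank,
         " < 4 (anchors are coplanar or collinear)")
  K <- as.matrix(stats::dist(src))           # U(r) = r
  A <- rbind(cbind(K + diag(lambda, n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(tgt, matrix(0, 4, 3))
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) stop("TPS system is singular: ",
                                           conditionMessage(e)))
  w <- sol[seq_len(n), , drop = FALSE]
  aff <- sol[n + 1:4, , drop = FALSE]
  side <- max(abs(t(P) %*% w))
  structure(list(anchors = src, weights = w, affine = aff,
                 kernel = "r", lambda = lambda,
                 side_condition_residual = side),
            class = "tps_transform")
}

#' Evaluate a thin-plate-spline transform at points
#' @param t a \code{tps_transform}.
#' @param points n x 3 matrix (or length-3 vector) of world-mm points.
#' @return n x 3 matrix of mapped world-mm points.
#' @export
apply_tps <- function(t, points) {
  p <- rbind2mat(points)
  out <- cbind(1, p) %*% t$affine
  # kernel sum in chunks to bound memory on large meshes
  n <- nrow(p)
  chunk <- max(1L, as.integer(2e6 / nrow(t$anchors)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    dx <- outer(p[s:e, 1], t$anchors[, 1], "-")
    dy <- outer(p[s:e, 2], t$anchors[, 2], "-")
    dz <- outer(p[s:e, 3], t$anchors[, 3], "-")
    U <- sqrt(dx * dx + dy * dy + dz * dz)
    out[s:e, ] <- out[s:e, ] + U %*% t$weights
  }
  out
}

#' Salient-feature-based registration
#'
#' Detects scale-attributed interest points on the planning image, matches
#' each one into the per-treatment image by local correlation (discarding
#' matches below the reliability threshold), and interpolates the retained
#' anchor correspondences with a thin-plate spline. The returned transform
#' maps planning-image points forward into per-treatment geometry, as
#' needed to push ROI surface meshes onto the new anatomy.
#'
#' @param planning,per_treatment \code{image_volume}s on a common grid
#'   (rigidly pre-aligned).
#' @param params an \code{sfbr_params}.
#' @return list with \code{transform} (a \code{tps_transform}),
#'   \code{retained_count}, and \code{correspondences} (the retained
#'   anchor table).
#' @export
sfbr_register <- function(planning, per_treatment,
                          params = sfbr_params()) {
  feats <- detect_salient_features(planning, params)
  if (nrow(feats) < 10)
    stop("insufficient anchors: only ", nrow(feats), " features detected")
  m <- match_features_batch(feats, planning, per_treatment, params)
  keep <- m[m$ok, c("x_source", "y_source", "z_source",
                    "x_target", "y_target", "z_target", "correlation")]
  if (nrow(keep) < 10)
    stop("insufficient anchors: only ", nrow(keep),
         " reliable correspondences (threshold ",
         params$reliability_threshold, ")")
  keep <- filter_consistent(keep, params$consistency_tol_mm %||% Inf)
  if (nrow(keep) < 10)
    stop("insufficient anchors: only ", nrow(keep),
         " correspondences survive the consistency filter")
  tps <- fit_tps(keep, lambda = params$tps_lambda)
  list(transform = tps, retained_count = nrow(keep),
       correspondences = keep)
}

#' Write retained correspondences to CSV
#' @param correspondences the anchor table from \code{sfbr_register}.
#' @param path output CSV path.
#' @export
write_correspondences_csv <- function(correspondences, path) {
  utils::write.csv(correspondences, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a TPS transform as JSON
#' @param t a \code{tps_transform}.
#' @param path file path.
#' @return \code{read_tps_json} returns a \code{tps_transform}.
#' @export
write_tps_json <- function(t, path) {
  jsonlite::write_json(list(kernel = t$kernel, lambda = t$lambda,
                            anchors = t$anchors, weights = t$weights,
                            affine = t$affine),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_tps_json
#' @export
read_tps_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(anchors = as.matrix(j$anchors),
                 weights = as.matrix(j$weights),
                 affine = as.matrix(j$affine),
                 kernel = j$kernel[1], lambda = j$lambda[1],
                 side_condition_residual = NA_real_),
            class = "tps_transform")
}
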