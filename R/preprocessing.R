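#' Rigid (translation + rotation) transform
#'
#' Six-parameter rigid body transform: rotation in degrees about the centre
#' of a reference volume, applied in fixed axis order x, then y, then z,
#' followed by translation in mm. The transform maps points of the moving
#' image's space into the fixed image's space; \code{apply_rigid} resamples
#' an image through the inverse, so a transform with translation \code{t}
#' moves image content by \code{+t}.
#'
#' @param translation length-3 numeric, mm.
#' @param rotation length-3 numeric, degrees about (x, y, z).
#' @param center length-3 numeric, rotation centre in world mm.
#' @return an object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(center) == 3)
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rotation_matrix <- function(rotation) {
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points (forward map)
#' @param t a \code{rigid_transform}.
#' @param points n x 3 matrix or length-3 vector of world-mm points.
#' @return transformed points (n x 3 matrix).
#' @export
rigid_apply_points <- function(t, points) {
  p <- rbind2mat(points)
  R <- rotation_matrix(t$rotation)
  sweep(sweep(p, 2, t$center, "-") %*% t(R), 2,
        t$center + t$translation, "+")
}

#' Invert a rigid transform
#' @param t a \code{rigid_transform}.
#' @return the inverse \code{rigid_transform} expressed with the same
#'   rotation centre (as a general rotation + translation; the rotation
#'   angles of the inverse are the negated angles applied in reverse order,
#'   represented here by the transpose matrix).
#' @export
rigid_invert <- function(t) {
  R <- rotation_matrix(t$rotation)
  # inverse map: p -> R^T (p - c - trans) + c ; re-express as rotation
  # about the same centre plus a translation
  Rt <- t(R)
  inv <- structure(list(translation = as.numeric(-Rt %*% t$translation),
                        rotation = NULL, center = t$center,
                        matrix = Rt),
                   class = "rigid_transform")
  inv
}

transform_matrix_of <- function(t) {
  if (!is.null(t$matrix)) t$matrix else rotation_matrix(t$rotation)
}

rigid_map <- function(t, p) {
  R <- transform_matrix_of(t)
  sweep(sweep(rbind2mat(p), 2, t$center, "-") %*% t(R), 2,
        t$center + t$translation, "+")
}

rigid_map_inverse <- function(t, p) {
  R <- transform_matrix_of(t)
  # q = R (p - c) + c + trans  =>  p = R^T (q - c - trans) + c
  sweep(sweep(rbind2mat(p), 2, t$center + t$translation, "-") %*% R, 2,
        t$center, "+")
}

#' Resample a volume through a rigid transform
#'
#' Samples \code{volume} at the inverse-transformed voxel centres of
#' \code{reference_grid}, so image content moves by the forward transform.
#'
#' @param volume an \code{image_volume} to resample.
#' @param t a \code{rigid_transform}.
#' @param reference_grid an \code{image_volume} (or mask) whose grid defines
#'   the output; defaults to \code{volume}'s own grid.
#' @param nearest logical; nearest-neighbour sampling (for label images).
#' @return an \code{image_volume} on the reference grid.
#' @export
apply_rigid <- function(volume, t, reference_grid = volume,
                        nearest = FALSE) {
  d <- vol_dim(reference_grid)
  g <- grid_index_arrays(d)
  w <- cbind(reference_grid$origin[1] + g$i * reference_grid$spacing[1],
             reference_grid$origin[2] + g$j * reference_grid$spacing[2],
             reference_grid$origin[3] + g$k * reference_grid$spacing[3])
  src <- rigid_map_inverse(t, w)
  idx <- world_to_index(volume, src)
  if (nearest) idx <- round(idx)
  v <- cpp_trilinear(as.numeric(volume$data), dim(volume$data), idx)
  image_volume(array(v, d), reference_grid$spacing, reference_grid$origin)
}

ncc <- function(a, b) {
  a <- as.numeric(a) - mean(a)
  b <- as.numeric(b) - mean(b)
  den <- sqrt(sum(a * a) * sum(b * b))
  if (den == 0) stop("NCC undefined: constant image")
  sum(a * b) / den
}

#' Rigid registration by normalized cross-correlation
#'
#' Finds the 6-parameter rigid transform (translation mm, rotation degrees
#' about the fixed-volume centre) maximizing the zero-mean normalized
#' cross-correlation between \code{fixed} and the resampled \code{moving}
#' image. Deterministic coarse-to-fine search: a translation grid at the
#' coarsest pyramid level followed by coordinate-descent refinement of all
#' six parameters across pyramid levels; the returned transform never
#' scores below the identity.
#'
#' Aligning the moving image is then \code{apply_rigid(moving, t, fixed)}.
#'
#' @param fixed,moving \code{image_volume}s with overlapping extent.
#' @param max_translation search extent per axis, mm (default 20).
#' @param max_rotation search extent per axis, degrees (default 10).
#' @return a \code{rigid_transform} with attribute \code{"ncc"}.
#' @export
rigid_register <- function(fixed, moving, max_translation = 20,
                           max_rotation = 10) {
  stopifnot(is_image_volume(fixed), is_image_volume(moving))
  if (stats::sd(fixed$data) == 0 || stats::sd(moving$data) == 0)
    stop("NCC undefined: constant image")
  center <- fixed$origin + (vol_dim(fixed) - 1) * fixed$spacing / 2
  score <- function(par, fx, mv) {
    t <- rigid_transform(par[1:3], par[4:6], center)
    ncc(fx$data, apply_rigid(mv, t, fx)$data)
  }
  factors <- c(4L, 2L, 1L)
  par <- rep(0, 6)
  for (li in seq_along(factors)) {
    f <- factors[li]
    fx <- downsample(fixed, f); mv <- downsample(moving, f)
    if (li == 1L) {
      # translation-only global grid at the coarsest level
      step <- max(min(fixed$spacing) * f, max_translation / 5)
      tr <- seq(-max_translation, max_translation, by = step)
      best <- score(par, fx, mv); bpar <- par
      for (tz in tr) for (ty in tr) for (tx in tr) {
        s <- score(c(tx, ty, tz, 0, 0, 0), fx, mv)
        if (s > best + 1e-12) { best <- s; bpar <- c(tx, ty, tz, 0, 0, 0) }
      }
      par <- bpar
    }
    # coordinate descent, halving steps
    step_t <- min(fixed$spacing) * f
    step_r <- max_rotation / 4 * f / factors[1]
    steps <- c(rep(step_t, 3), rep(step_r, 3))
    best <- score(par, fx, mv)
    for (pass in 1:12) {
      improved <- FALSE
      for (a in 1:6) {
        for (dir in c(-1, 1)) {
          cand <- par
          cand[a] <- cand[a] + dir * steps[a]
          if (a <= 3 && abs(cand[a]) > max_translation) next
          if (a > 3 && abs(cand[a]) > max_rotation) next
          s <- score(cand, fx, mv)
          if (s > best + 1e-12) { best <- s; par <- cand; improved <- TRUE }
        }
      }
      if (!improved) {
        steps <- steps / 2
        if (max(steps[1:3]) < 0.05 && max(steps[4:6]) < 0.05) break
      }
    }
  }
  out <- rigid_transform(par[1:3], par[4:6], center)
  s_final <- score(par, fixed, moving)
  s_id <- score(rep(0, 6), fixed, moving)
  if (s_final < s_id) { # never worse than the identity
    out <- rigid_transform(center = center)
    s_final <- s_id
  }
  attr(out, "ncc") <- s_final
  out
}

#' Histogram matching by interior quantile mapping
#'
#' Fits a monotone piecewise-linear intensity map taking the source
#' quantiles at \code{n_match_points} equally spaced interior quantile
#' levels (levels l/(m+1), never pinning the extremes) onto the reference
#' quantiles at the same levels. Quantiles are read off \code{n_bins}-bin
#' histogram CDFs, so the map is accurate to about one bin width. The
#' defaults (64 bins, 7 match points) are the standard CT pre-registration
#' setting.
#'
#' @param source \code{image_volume} whose intensities are remapped.
#' @param reference \code{image_volume} providing the target histogram.
#' @param n_bins number of histogram bins (>= 2).
#' @param n_match_points number of interior quantile match points.
#' @return the remapped \code{image_volume} on the source grid.
#' @export
histogram_match <- function(source, reference, n_bins = 64,
                            n_match_points = 7) {
  stopifnot(is_image_volume(source), is_image_volume(reference))
  n_bins <- as.integer(n_bins); n_match_points <- as.integer(n_match_points)
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  if (n_match_points < 1L || n_match_points > n_bins)
    stop("'n_match_points' must be in [1, n_bins]")
  if (stats::sd(source$data) == 0) stop("constant source image")
  if (stats::sd(reference$data) == 0) stop("constant reference image")
  lev <- seq_len(n_match_points) / (n_match_points + 1)
  qs <- hist_quantile(as.numeric(source$data), n_bins, lev)
  qr <- hist_quantile(as.numeric(reference$data), n_bins, lev)
  # enforce strict monotonicity of the knots for a well-defined inverse
  eps <- 1e-9 * max(diff(range(source$data)), 1)
  qs <- cummax(qs + seq_along(qs) * eps)
  mapped <- lin_extrap(as.numeric(source$data), qs, qr)
  image_volume(array(mapped, vol_dim(source)), source$spacing,
               source$origin)
}

# quantiles from an n-bin histogram CDF, linear within bins
hist_quantile <- function(v, n_bins, levels) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- hist(v, breaks = br, plot = FALSE)
  cdf <- c(0, cumsum(h$counts)) / length(v)
  vapply(levels, function(q) {
    i <- findInterval(q, cdf, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n_bins)
    c0 <- cdf[i]; c1 <- cdf[i + 1]
    f <- if (c1 > c0) (q - c0) / (c1 - c0) else 0.5
    br[i] + f * (br[i + 1] - br[i])
  }, numeric(1))
}

# piecewise-linear map through (xs, ys) with linear end extension
lin_extrap <- function(x, xs, ys) {
  n <- length(xs)
  out <- stats::approx(xs, ys, xout = pmin(pmax(x, xs[1]), xs[n]),
                       ties = "ordered")$y
  lo <- x < xs[1]; hi <- x > xs[n]
  if (any(lo)) {
    sl <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    out[lo] <- ys[1] + sl * (x[lo] - xs[1])
  }
  if (any(hi)) {
    sl <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    out[hi] <- ys[n] + sl * (x[hi] - xs[n])
  }
  out
}

#' Serialize / deserialize a rigid transform as JSON
#' @param t a \code{rigid_transform}.
#' @param path file path.
#' @return \code{read_rigid_json} returns a \code{rigid_transform}.
#' @export
write_rigid_json <- function(t, path) {
  jsonlite::write_json(
    list(convention = "translation mm + rotation deg about center, order x-y-z, forward map",
         translation = t$translation, rotation = t$rotation,
         center = t$center),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rigid_json
#' @export
read_rigid_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(j$translation, j$rotation, j$center)
}
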