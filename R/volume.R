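#' Construct a 3D scalar image volume
#'
#' The basic container for planning and per-treatment scans: a 3D array of
#' CT-number-like intensities on an axis-aligned grid with voxel spacing and
#' origin in millimetres. Voxel indices are 0-based; the world position of
#' voxel \code{(i,j,k)} is \code{origin + c(i,j,k) * spacing}, with the third
#' axis the slice (z) axis.
#'
#' @param data numeric 3D array of intensities (x, y, z order).
#' @param spacing positive length-3 numeric, mm per voxel along each axis.
#' @param origin length-3 numeric, world position (mm) of voxel (0,0,0).
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (mm)")
  if (any(!is.finite(data)))
    stop("all intensities must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = "/"),
      " mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' @rdname image_volume
#' @param x an object.
#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

#' Grid dimensions of a volume, field or mask
#' @param x an \code{image_volume}, \code{displacement_field} or
#'   \code{binary_mask}.
#' @return integer length-3 vector of voxel counts.
#' @export
vol_dim <- function(x) dim(if (is_displacement_field(x)) x$vx else x$data)

same_grid <- function(a, b, tol = 1e-9) {
  identical(vol_dim(a), vol_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert between voxel indices and world coordinates
#'
#' @param vol an \code{image_volume} (or anything with spacing/origin).
#' @param index numeric matrix (n x 3) of 0-based voxel indices.
#' @param world numeric matrix (n x 3) of world positions in mm.
#' @return a matrix of the converted coordinates.
#' @export
index_to_world <- function(vol, index) {
  index <- rbind2mat(index)
  sweep(sweep(index, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname index_to_world
#' @export
world_to_index <- function(vol, world) {
  world <- rbind2mat(world)
  sweep(sweep(world, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

rbind2mat <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 3) else
    matrix(as.numeric(p), ncol = 3, dimnames = NULL)
}

#' Construct a per-voxel displacement field
#'
#' Displacements live on the grid of a reference (target) image and are
#' expressed in mm, pull-back convention: the warped image at target voxel
#' \code{x} samples the source at \code{world(x) + u(x)}.
#'
#' @param vx,vy,vz numeric 3D arrays, displacement components in mm.
#' @param spacing,origin grid geometry (mm), identical to the reference
#'   volume.
#' @return An object of class \code{displacement_field}.
#' @export
displacement_field <- function(vx, vy, vz, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  d <- dim(vx)
  if (length(d) != 3L || !identical(d, dim(vy)) || !identical(d, dim(vz)))
    stop("components must be 3D arrays of identical dimension")
  if (any(!is.finite(vx)) || any(!is.finite(vy)) || any(!is.finite(vz)))
    stop("all displacement components must be finite")
  structure(list(vx = vx, vy = vy, vz = vz,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

#' @rdname displacement_field
#' @param x an object.
#' @export
is_displacement_field <- function(x) inherits(x, "displacement_field")

#' @rdname displacement_field
#' @param reference an \code{image_volume} whose grid the zero field adopts.
#' @export
zero_field <- function(reference) {
  z <- array(0, vol_dim(reference))
  displacement_field(z, z, z, reference$spacing, reference$origin)
}

#' Field magnitude in mm per voxel
#' @param dvf a \code{displacement_field}.
#' @return numeric 3D array of Euclidean magnitudes (mm).
#' @export
field_magnitude <- function(dvf) sqrt(dvf$vx^2 + dvf$vy^2 + dvf$vz^2)

#' Sample a volume with trilinear interpolation
#'
#' Exact at voxel centres, trilinear in between; points outside the grid
#' clamp to the nearest border voxel so no synthetic background gradient is
#' created at the edges.
#'
#' @param volume an \code{image_volume}.
#' @param points numeric vector (length 3) or n x 3 matrix of world-mm
#'   positions.
#' @return numeric vector of sampled intensities.
#' @export
trilinear_sample <- function(volume, points) {
  stopifnot(is_image_volume(volume))
  pts <- rbind2mat(points)
  if (any(!is.finite(pts))) stop("sample points must be finite")
  idx <- world_to_index(volume, pts)
  cpp_trilinear(as.numeric(volume$data), dim(volume$data), idx)
}

#' Warp an image through a displacement field
#'
#' Resamples \code{source} on the grid of \code{dvf}'s reference:
#' \code{out(x) = source(world(x) + u(x))} by trilinear interpolation.
#'
#' @param source an \code{image_volume} to be deformed.
#' @param dvf a \code{displacement_field} on the target grid.
#' @return an \code{image_volume} on the target grid.
#' @export
warp_image <- function(source, dvf) {
  stopifnot(is_image_volume(source), is_displacement_field(dvf))
  d <- vol_dim(dvf)
  g <- grid_index_arrays(d)
  # target world + displacement, then into source index coordinates
  px <- (dvf$origin[1] + g$i * dvf$spacing[1] + as.numeric(dvf$vx) -
           source$origin[1]) / source$spacing[1]
  py <- (dvf$origin[2] + g$j * dvf$spacing[2] + as.numeric(dvf$vy) -
           source$origin[2]) / source$spacing[2]
  pz <- (dvf$origin[3] + g$k * dvf$spacing[3] + as.numeric(dvf$vz) -
           source$origin[3]) / source$spacing[3]
  v <- cpp_trilinear(as.numeric(source$data), dim(source$data),
                     cbind(px, py, pz))
  image_volume(array(v, d), dvf$spacing, dvf$origin)
}

# flat 0-based index arrays for a grid, recycled in R's column-major order
grid_index_arrays <- function(d) {
  list(i = rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
       j = rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
       k = rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

#' Gaussian-smooth a displacement field or volume
#'
#' Each component is convolved with a truncated discrete Gaussian
#' (truncation radius 3 sigma), renormalized at the borders so constants are
#' preserved. \code{sigma} is in voxels; a scalar applies to all axes and
#' \code{sigma = 0} is the identity.
#'
#' @param dvf a \code{displacement_field}.
#' @param sigma non-negative smoothing SD in voxels (scalar or length 3).
#' @return the smoothed \code{displacement_field}.
#' @export
gaussian_smooth_field <- function(dvf, sigma) {
  stopifnot(is_displacement_field(dvf))
  sigma <- check_sigma(sigma)
  if (all(sigma == 0)) return(dvf)
  d <- vol_dim(dvf)
  sm <- function(a) array(cpp_gauss3(as.numeric(a), d, sigma), d)
  displacement_field(sm(dvf$vx), sm(dvf$vy), sm(dvf$vz),
                     dvf$spacing, dvf$origin)
}

#' @rdname gaussian_smooth_field
#' @param volume an \code{image_volume}.
#' @export
gaussian_smooth_volume <- function(volume, sigma) {
  stopifnot(is_image_volume(volume))
  sigma <- check_sigma(sigma)
  if (all(sigma == 0)) return(volume)
  d <- vol_dim(volume)
  image_volume(array(cpp_gauss3(as.numeric(volume$data), d, sigma), d),
               volume$spacing, volume$origin)
}

check_sigma <- function(sigma) {
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3)
  if (length(sigma) != 3L || any(!is.finite(sigma)) || any(sigma < 0))
    stop("'sigma' must be non-negative (voxels)")
  sigma
}

#' Downsample a volume by an integer factor
#'
#' Gaussian anti-alias prefilter (sigma = 0.5 * factor voxels) followed by
#' subsampling every \code{factor}-th voxel starting at the first, so the
#' origin is preserved. Output spacing is input spacing times the factor;
#' factor 1 returns the volume unchanged.
#'
#' @param volume an \code{image_volume}.
#' @param factor integer >= 1.
#' @return the downsampled \code{image_volume}.
#' @export
downsample <- function(volume, factor) {
  stopifnot(is_image_volume(volume))
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 1L)
    stop("'factor' must be a single integer >= 1")
  if (factor == 1L) return(volume)
  sm <- gaussian_smooth_volume(volume, 0.5 * factor)
  d <- vol_dim(volume)
  ix <- seq(1L, d[1], by = factor)
  iy <- seq(1L, d[2], by = factor)
  iz <- seq(1L, d[3], by = factor)
  image_volume(sm$data[ix, iy, iz, drop = FALSE],
               volume$spacing * factor, volume$origin)
}
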