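#' Multi-resolution schedule for demons registration
#'
#' The default schedule runs four pyramid levels at 4x, 3x, 2x and 1x the
#' CT grid resolution with at most 200, 100, 100 and 30 iterations and
#' Gaussian field smoothing of 3, 3, 0.9 and 0.7 voxels respectively. A
#' stopping criterion terminates a level early when the mean relative
#' change in the intensity mean-square difference over the last
#' \code{stop_window_iterations} iterations falls below
#' \code{stop_tolerance_percent} (default 1.5%).
#'
#' @param levels list of length-3 numeric vectors
#'   \code{c(resample_factor, max_iterations, smoothing_sigma_voxels)},
#'   ordered coarse to fine with strictly decreasing factors ending at 1.
#' @param stop_tolerance_percent early-stopping tolerance, percent.
#' @param stop_window_iterations number of successive iterations averaged
#'   by the stopping rule.
#' @return an object of class \code{demons_schedule}.
#' @export
demons_schedule <- function(levels = list(c(4, 200, 3), c(3, 100, 3),
                                          c(2, 100, 0.9), c(1, 30, 0.7)),
                            stop_tolerance_percent = 1.5,
                            stop_window_iterations = 5) {
  stopifnot(length(levels) >= 1)
  fac <- vapply(levels, `[`, numeric(1), 1)
  it <- vapply(levels, `[`, numeric(1), 2)
  if (any(diff(fac) >= 0) || fac[length(fac)] != 1)
    stop("level factors must be strictly decreasing and end at 1")
  if (any(it < 1)) stop("max_iterations must be >= 1")
  if (stop_tolerance_percent <= 0) stop("tolerance must be > 0")
  structure(list(levels = levels,
                 stop_tolerance_percent = stop_tolerance_percent,
                 stop_window_iterations = as.integer(stop_window_iterations)),
            class = "demons_schedule")
}

#' Mean square intensity difference between two volumes on one grid
#' @param fixed,warped \code{image_volume}s on identical grids.
#' @return scalar mean of squared per-voxel differences.
#' @export
mean_square_difference <- function(fixed, warped) {
  if (!same_grid(fixed, warped)) stop("grid mismatch")
  mean((fixed$data - warped$data)^2)
}

# central-difference gradient of a volume, mm^-1 (one-sided at borders)
volume_gradient <- function(vol) {
  a <- vol$data
  d <- dim(a)
  grad1 <- function(a, ax, h) {
    n <- d[ax]
    ip <- c(2:n, n); im <- c(1, 1:(n - 1)) # clamped neighbour indices
    den <- (ip - im) * h
    if (ax == 1) (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) /
        array(den, d)
    else if (ax == 2) (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) /
        array(rep(den, each = d[1]), d)
    else (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) /
        array(rep(den, each = d[1] * d[2]), d)
  }
  list(x = grad1(a, 1, vol$spacing[1]),
       y = grad1(a, 2, vol$spacing[2]),
       z = grad1(a, 3, vol$spacing[3]))
}

#' Symmetric demons force field for one iteration
#'
#' Per-voxel optical-flow force using the gradients of both the fixed and
#' the currently warped moving image:
#' \deqn{u = 2 (f - m)(\nabla f + \nabla m) / (||\nabla f + \nabla m||^2 +
#'   \alpha (f - m)^2)}
#' with gradients in 1/mm and the intensity normalization
#' \code{alpha = 1 / mean(spacing)^2}, which keeps the force bounded and in
#' mm. Voxels where the denominator falls below 1e-9 receive a zero update.
#'
#' @param fixed the target \code{image_volume}.
#' @param warped_moving the moving image warped by the current field, on
#'   the same grid.
#' @return a \code{displacement_field} of per-iteration forces (mm).
#' @export
demons_update <- function(fixed, warped_moving) {
  if (!same_grid(fixed, warped_moving)) stop("grid mismatch")
  gf <- volume_gradient(fixed)
  gm <- volume_gradient(warped_moving)
  gx <- gf$x + gm$x; gy <- gf$y + gm$y; gz <- gf$z + gm$z
  diffi <- fixed$data - warped_moving$data
  alpha <- 1 / mean(fixed$spacing)^2
  den <- gx^2 + gy^2 + gz^2 + alpha * diffi^2
  scale <- ifelse(den < 1e-9, 0, 2 * diffi / pmax(den, 1e-9))
  displacement_field(scale * gx, scale * gy, scale * gz,
                     fixed$spacing, fixed$origin)
}

#' Run demons iterations at a single pyramid level
#'
#' Iterates: warp the moving image with the current total field, record the
#' mean-square difference, compute the symmetric force, add it to the field
#' and Gaussian-smooth the total field. Terminates at
#' \code{max_iterations}, or early once the mean relative MSD change over
#' the last \code{window} iterations drops below
#' \code{tolerance_percent / 100}.
#'
#' @param fixed,moving \code{image_volume}s on the level grid.
#' @param init initial \code{displacement_field} on the same grid.
#' @param max_iterations iteration cap for the level.
#' @param sigma_voxels Gaussian smoothing SD of the total field, voxels.
#' @param tolerance_percent,window early-stopping rule parameters.
#' @return list with \code{field} (the final \code{displacement_field}) and
#'   \code{msd_trace} (MSD at the start of each iteration).
#' @export
register_level <- function(fixed, moving, init, max_iterations,
                           sigma_voxels, tolerance_percent = 1.5,
                           window = 5) {
  stopifnot(same_grid(fixed, moving), same_grid(fixed, init))
  field <- init
  trace <- numeric(0)
  for (it in seq_len(max_iterations)) {
    w <- warp_image(moving, field)
    trace[it] <- mean_square_difference(fixed, w)
    du <- demons_update(fixed, w)
    field <- gaussian_smooth_field(
      displacement_field(field$vx + du$vx, field$vy + du$vy,
                         field$vz + du$vz, field$spacing, field$origin),
      sigma_voxels)
    if (any(!is.finite(field$vx)) || any(!is.finite(field$vy)) ||
        any(!is.finite(field$vz)))
      stop("non-finite displacement field at iteration ", it)
    if (it > window) {
      prev <- trace[(it - window):(it - 1)]
      curr <- trace[(it - window + 1):it]
      rel <- ifelse(prev > 0, abs(curr - prev) / prev, 0)
      if (mean(rel) < tolerance_percent / 100) break
    }
  }
  list(field = field, msd_trace = trace)
}

# resample a coarse field onto a finer grid (component-wise trilinear;
# displacements are mm so no rescaling is needed)
upsample_field <- function(dvf, reference) {
  d <- vol_dim(reference)
  g <- grid_index_arrays(d)
  w <- cbind(reference$origin[1] + g$i * reference$spacing[1],
             reference$origin[2] + g$j * reference$spacing[2],
             reference$origin[3] + g$k * reference$spacing[3])
  comp <- function(a) {
    v <- trilinear_sample(image_volume(a, dvf$spacing, dvf$origin), w)
    array(v, d)
  }
  displacement_field(comp(dvf$vx), comp(dvf$vy), comp(dvf$vz),
                     reference$spacing, reference$origin)
}

#' Multi-resolution fast symmetric demons registration
#'
#' Registers \code{moving} onto \code{fixed}, coarse to fine along the
#' schedule, upsampling the displacement field between levels. The returned
#' field lives on the \code{fixed} (target) grid, pull-back convention:
#' warping \code{moving} with it reproduces \code{fixed}. Intensity
#' histogram matching is assumed to have been applied already (the
#' pipeline enforces this ordering).
#'
#' @param fixed the target \code{image_volume}.
#' @param moving the source \code{image_volume} (same grid).
#' @param schedule a \code{demons_schedule}.
#' @param verbose print per-level convergence lines.
#' @return an object of class \code{registration_result}: \code{dvf},
#'   \code{msd_trace} (list per level) and \code{iterations_used}.
#' @export
demons_register <- function(fixed, moving, schedule = demons_schedule(),
                            verbose = FALSE) {
  stopifnot(is_image_volume(fixed), is_image_volume(moving))
  stopifnot(inherits(schedule, "demons_schedule"))
  field <- NULL
  traces <- list()
  iters <- integer(0)
  for (lv in schedule$levels) {
    f <- as.integer(lv[1])
    fx <- downsample(fixed, f)
    mv <- downsample(moving, f)
    init <- if (is.null(field)) zero_field(fx) else upsample_field(field, fx)
    res <- register_level(fx, mv, init, max_iterations = lv[2],
                          sigma_voxels = lv[3],
                          tolerance_percent = schedule$stop_tolerance_percent,
                          window = schedule$stop_window_iterations)
    field <- res$field
    traces[[length(traces) + 1L]] <- res$msd_trace
    iters <- c(iters, length(res$msd_trace))
    if (verbose)
      message(sprintf("level %dx: %d iterations, MSD %.3f -> %.3f", f,
                      length(res$msd_trace), res$msd_trace[1],
                      res$msd_trace[length(res$msd_trace)]))
  }
  structure(list(dvf = field, msd_trace = traces, iterations_used = iters),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> levels:", length(x$msd_trace),
      "iterations:", paste(x$iterations_used, collapse = "/"),
      sprintf("final MSD %.4f\n",
              x$msd_trace[[length(x$msd_trace)]][x$iterations_used[length(x$iterations_used)]]))
  invisible(x)
}

#' Write per-level MSD traces to CSV
#' @param result a \code{registration_result}.
#' @param path output CSV path (columns level, iteration, msd).
#' @export
write_msd_trace <- function(result, path) {
  rows <- do.call(rbind, lapply(seq_along(result$msd_trace), function(l) {
    tr <- result$msd_trace[[l]]
    data.frame(level = l, iteration = seq_along(tr), msd = tr)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
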