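#' Specification of the synthetic head-and-neck phantom
#'
#' Describes a CT-like neck cross-section: an elliptical soft-tissue body
#' containing an air-filled pharyngeal tube, a spinal cord inside a bony
#' ring, a brainstem above the cord, two parotid ellipsoids, a lobed GTV
#' against the airway and a scatter of small high-intensity nodules
#' ("markers", lymph-node/vessel analogues that give feature-based
#' registration something to anchor on). All geometry is analytic, so
#' deformed copies of the phantom can be rendered exactly rather than by
#' resampling a stored grid.
#'
#' @param dims voxel counts, default 96 x 96 x 48.
#' @param spacing mm per voxel, default c(2, 2, 3) (2-3 mm slices are the
#'   usual planning-CT regime).
#' @param origin world position of voxel (0,0,0), mm.
#' @param seed integer seed controlling marker placement and image noise.
#' @param noise_sd additive Gaussian intensity noise SD (CT-number-like
#'   units), default 15.
#' @param n_markers number of scattered nodules, default 60.
#' @param levels named list of tissue intensity levels.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(dims = c(96, 96, 48), spacing = c(2, 2, 3),
                         origin = c(0, 0, 0), seed = 1, noise_sd = 15,
                         n_markers = 60,
                         levels = list(air = -1000, body = 40, bone = 300,
                                       spinal_cord = 80, brainstem = 100,
                                       parotid = 140, GTV = 200,
                                       airway = -800, marker = 280)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 8), length(spacing) == 3,
            all(spacing > 0))
  structure(list(dims = dims, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), seed = as.integer(seed),
                 noise_sd = noise_sd, n_markers = as.integer(n_markers),
                 levels = levels),
            class = "phantom_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# analytic scene: geometry derived from the phantom_spec; membership and
# the intensity function accept n x 3 world-mm point matrices
phantom_scene <- function(spec) {
  ex <- (spec$dims - 1) * spec$spacing + spec$origin  # upper world corner
  lo <- spec$origin
  cx <- (lo[1] + ex[1]) / 2; cy <- (lo[2] + ex[2]) / 2
  zr <- ex[3] - lo[3]
  geom <- list(
    body = list(c = c(cx, cy), semi = c(0.42 * (ex[1] - lo[1]),
                                        0.38 * (ex[2] - lo[2]))),
    airway = list(c = c(cx, cy - 38), r = 8),
    gtv = list(centers = rbind(c(cx - 17, cy - 29, lo[3] + 0.50 * zr),
                               c(cx - 23, cy - 21, lo[3] + 0.55 * zr),
                               c(cx - 11, cy - 35, lo[3] + 0.44 * zr)),
               radii = c(13, 9, 8)),
    cord = list(c = c(cx, cy + 36), r = 5,
                z = c(lo[3], lo[3] + 0.68 * zr)),
    bone = list(c = c(cx, cy + 36), r = c(8, 15),
                z = c(lo[3], lo[3] + 0.71 * zr)),
    brainstem = list(c = c(cx, cy + 32), r = 7.5,
                     z = c(lo[3] + 0.74 * zr, ex[3])),
    parotid_L = list(c = c(cx - 52, cy, lo[3] + 0.65 * zr),
                     semi = c(11, 15, 17)),
    parotid_R = list(c = c(cx + 52, cy, lo[3] + 0.65 * zr),
                     semi = c(11, 15, 17)))
  gtv_center <- geom$gtv$centers[1, ]
  # deterministic marker placement with clearance from all structures
  markers <- with_seed(spec$seed, {
    acc <- matrix(numeric(0), 0, 4) # x, y, z, radius
    tries <- 0
    while (nrow(acc) < spec$n_markers && tries < 80 * spec$n_markers) {
      tries <- tries + 1
      r <- stats::runif(1, 3, 5)
      p <- c(cx + stats::runif(1, -1, 1) * 0.8 * geom$body$semi[1],
             cy + stats::runif(1, -1, 1) * 0.8 * geom$body$semi[2],
             stats::runif(1, lo[3] + 8, ex[3] - 8))
      er <- sum(((p[1:2] - geom$body$c) / geom$body$semi)^2)
      clear <- er < 0.72 &&
        sqrt(sum((p[1:2] - geom$airway$c)^2)) > geom$airway$r + r + 4 &&
        sqrt(sum((p[1:2] - geom$bone$c)^2)) > geom$bone$r[2] + r + 4 &&
        min(sqrt(rowSums(sweep(geom$gtv$centers, 2, p)^2)) -
              geom$gtv$radii) > r + 6 &&
        sqrt(sum((p - geom$parotid_L$c)^2)) >
          max(geom$parotid_L$semi) + r + 4 &&
        sqrt(sum((p - geom$parotid_R$c)^2)) >
          max(geom$parotid_R$semi) + r + 4 &&
        sqrt(sum((p[1:2] - geom$brainstem$c)^2)) >
          geom$brainstem$r + r + 6 &&
        (nrow(acc) == 0 ||
           min(sqrt(rowSums(sweep(acc[, 1:3, drop = FALSE], 2, p)^2)) -
                 acc[, 4]) > r + 3)
      if (clear) acc <- rbind(acc, c(p, r))
    }
    acc
  })
  in_ellipse2 <- function(p, c2, semi)
    ((p[, 1] - c2[1]) / semi[1])^2 + ((p[, 2] - c2[2]) / semi[2])^2 <= 1
  membership <- list(
    body = function(p) in_ellipse2(p, geom$body$c, geom$body$semi),
    airway = function(p)
      (p[, 1] - geom$airway$c[1])^2 + (p[, 2] - geom$airway$c[2])^2 <=
        geom$airway$r^2,
    GTV = function(p) {
      hit <- rep(FALSE, nrow(p))
      for (i in seq_along(geom$gtv$radii))
        hit <- hit | rowSums(sweep(p, 2, geom$gtv$centers[i, ])^2) <=
          geom$gtv$radii[i]^2
      hit
    },
    spinal_cord = function(p)
      (p[, 1] - geom$cord$c[1])^2 + (p[, 2] - geom$cord$c[2])^2 <=
        geom$cord$r^2 & p[, 3] >= geom$cord$z[1] & p[, 3] <= geom$cord$z[2],
    bone = function(p) {
      r2 <- (p[, 1] - geom$bone$c[1])^2 + (p[, 2] - geom$bone$c[2])^2
      r2 >= geom$bone$r[1]^2 & r2 <= geom$bone$r[2]^2 &
        p[, 3] >= geom$bone$z[1] & p[, 3] <= geom$bone$z[2]
    },
    brainstem = function(p)
      (p[, 1] - geom$brainstem$c[1])^2 +
        (p[, 2] - geom$brainstem$c[2])^2 <= geom$brainstem$r^2 &
        p[, 3] >= geom$brainstem$z[1] & p[, 3] <= geom$brainstem$z[2],
    parotid_L = function(p)
      rowSums(sweep(sweep(p, 2, geom$parotid_L$c), 2,
                    geom$parotid_L$semi, "/")^2) <= 1,
    parotid_R = function(p)
      rowSums(sweep(sweep(p, 2, geom$parotid_R$c), 2,
                    geom$parotid_R$semi, "/")^2) <= 1,
    marker = function(p) {
      hit <- rep(FALSE, nrow(p))
      if (nrow(markers)) for (i in seq_len(nrow(markers)))
        hit <- hit | rowSums(sweep(p, 2, markers[i, 1:3])^2) <=
          markers[i, 4]^2
      hit
    })
  lv <- spec$levels
  intensity <- function(p) {
    v <- rep(lv$air, nrow(p))
    inb <- membership$body(p)
    v[inb] <- lv$body
    v[membership$bone(p) & inb] <- lv$bone
    v[membership$marker(p) & inb] <- lv$marker
    v[membership$spinal_cord(p)] <- lv$spinal_cord
    v[membership$brainstem(p)] <- lv$brainstem
    v[membership$parotid_L(p)] <- lv$parotid
    v[membership$parotid_R(p)] <- lv$parotid
    v[membership$GTV(p)] <- lv$GTV
    v[membership$airway(p) & inb] <- lv$airway
    v
  }
  list(geom = geom, markers = markers, membership = membership,
       intensity = intensity, gtv_center = gtv_center)
}

phantom_grid_points <- function(spec) {
  g <- grid_index_arrays(spec$dims)
  cbind(spec$origin[1] + g$i * spec$spacing[1],
        spec$origin[2] + g$j * spec$spacing[2],
        spec$origin[3] + g$k * spec$spacing[3])
}

roi_labels <- c("spinal_cord", "brainstem", "parotid_L", "parotid_R", "GTV")

#' Generate the planning phantom
#'
#' Renders the analytic scene at the voxel centres, adds seeded Gaussian
#' noise, and rasterizes the ground-truth ROI masks (spinal cord,
#' brainstem, both parotids, GTV, plus the body outline). Deterministic
#' given the phantom_spec seed; the declared organs are validated pairwise
#' disjoint on the grid.
#'
#' @param spec a \code{phantom_spec}.
#' @return an object of class \code{phantom_case}: \code{volume} (noisy),
#'   \code{clean} (noise-free), \code{masks} (named list of
#'   \code{binary_mask}, ROIs plus \code{body}), \code{scene}, \code{spec}.
#' @export
generate_planning_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  scene <- phantom_scene(spec)
  pts <- phantom_grid_points(spec)
  clean <- array(scene$intensity(pts), spec$dims)
  masks <- lapply(c(roi_labels, "body"), function(lb)
    binary_mask(array(scene$membership[[lb]](pts), spec$dims),
                spec$spacing, spec$origin, lb))
  names(masks) <- c(roi_labels, "body")
  for (lb in roi_labels)
    if (!any(masks[[lb]]$data)) stop("organ mask '", lb, "' is empty")
  for (i in seq_along(roi_labels)) for (j in seq_len(i - 1L))
    if (any(masks[[roi_labels[i]]]$data & masks[[roi_labels[j]]]$data))
      stop("organs overlap: ", roi_labels[i], " and ", roi_labels[j])
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed + 1L,
              array(stats::rnorm(prod(spec$dims), 0, spec$noise_sd),
                    spec$dims))
  else 0
  structure(list(volume = image_volume(clean + noise, spec$spacing,
                                       spec$origin),
                 clean = image_volume(clean, spec$spacing, spec$origin),
                 masks = masks, scene = scene, spec = spec),
            class = "phantom_case")
}

#' Specification of the analytic ground-truth deformation
#'
#' A smooth, invertible pull-back displacement field: a sum of Gaussian
#' bumps (each with a centre, isotropic sigma in mm and an amplitude
#' vector in mm), a radial GTV shrinkage term (full-strength scaling by
#' \code{gtv_shrink} within \code{shrink_radius} of the GTV centre, cosine-
#' tapered to zero at twice that radius, emulating tumour regression), and
#' a lateral "recession" bump pushing the right body surface medially (a
#' scaled-down analogue of the strong-responder case). Default peak
#' magnitude is kept at or below 8 mm so invertibility holds comfortably;
#' the Jacobian is verified numerically before use.
#'
#' @param bumps list of lists with elements \code{center} (mm),
#'   \code{sigma} (mm) and \code{amplitude} (mm 3-vector).
#' @param gtv_shrink radial scale factor applied to the GTV (default 0.7).
#' @param gtv_center GTV centre, mm; \code{NULL} takes the phantom's.
#' @param shrink_radius full-strength radius of the shrink term, mm.
#' @param min_jacobian lower bound demanded of the numerical Jacobian
#'   determinant.
#' @return an object of class \code{deformation_spec}.
#' @export
deformation_spec <- function(bumps = NULL, gtv_shrink = 0.7,
                             gtv_center = NULL, shrink_radius = 16,
                             min_jacobian = 0.1) {
  if (is.null(bumps))
    bumps <- list(
      list(center = c(62, 105, 50), sigma = 38, amplitude = c(3, -2, 1.5)),
      list(center = c(125, 115, 95), sigma = 35,
           amplitude = c(-2.5, 2, -1)),
      # lateral body recession, medial push on the patient's right
      list(center = c(170, 95, 70), sigma = 30, amplitude = c(-6, 0, 0)))
  if (!is.null(gtv_shrink) &&
      (gtv_shrink <= 0 || gtv_shrink > 1))
    stop("'gtv_shrink' must be in (0, 1]")
  structure(list(bumps = bumps, gtv_shrink = gtv_shrink,
                 gtv_center = gtv_center, shrink_radius = shrink_radius,
                 min_jacobian = min_jacobian),
            class = "deformation_spec")
}

#' Evaluate the analytic deformation at world points
#'
#' Returns the pull-back displacement u(x) in mm: the per-treatment image
#' at x shows the planning anatomy at x + u(x).
#'
#' @param dspec a \code{deformation_spec} with \code{gtv_center} resolved.
#' @param points n x 3 world-mm matrix.
#' @return n x 3 displacement matrix (mm).
#' @export
evaluate_deformation <- function(dspec, points) {
  p <- rbind2mat(points)
  u <- matrix(0, nrow(p), 3)
  for (b in dspec$bumps) {
    w <- exp(-rowSums(sweep(p, 2, b$center)^2) / (2 * b$sigma^2))
    u <- u + outer(w, b$amplitude)
  }
  if (!is.null(dspec$gtv_shrink) && dspec$gtv_shrink < 1) {
    if (is.null(dspec$gtv_center))
      stop("'gtv_center' must be set to apply GTV shrinkage")
    R <- dspec$shrink_radius
    dp <- sweep(p, 2, dspec$gtv_center)
    r <- sqrt(rowSums(dp^2))
    g <- ifelse(r <= R, 1,
                ifelse(r >= 2 * R, 0, 0.5 * (1 + cos(pi * (r - R) / R))))
    u <- u + dp * ((1 / dspec$gtv_shrink - 1) * g)
  }
  u
}

# numerical Jacobian determinant of x -> x + u(x) at the voxel centres
min_jacobian_det <- function(dspec, spec) {
  pts <- phantom_grid_points(spec)
  u <- evaluate_deformation(dspec, pts)
  d <- spec$dims
  J <- array(0, c(prod(d), 3, 3))
  for (comp in 1:3) {
    a <- array(u[, comp], d)
    g <- volume_gradient(image_volume(a, spec$spacing, spec$origin))
    J[, comp, 1] <- g$x; J[, comp, 2] <- g$y; J[, comp, 3] <- g$z
  }
  a11 <- 1 + J[, 1, 1]; a12 <- J[, 1, 2]; a13 <- J[, 1, 3]
  a21 <- J[, 2, 1]; a22 <- 1 + J[, 2, 2]; a23 <- J[, 2, 3]
  a31 <- J[, 3, 1]; a32 <- J[, 3, 2]; a33 <- 1 + J[, 3, 3]
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  min(det)
}

#' Generate the per-treatment phantom from a planning phantom
#'
#' The per-treatment volume is the analytic scene evaluated at the
#' pulled-back points x + u(x) — the deformation is applied exactly, never
#' interpolated from a stored grid — plus fresh seeded noise. Ground-truth
#' masks are the organ membership functions evaluated at the same
#' pulled-back points, and the true displacement field is u sampled at the
#' target voxel centres.
#'
#' @param planning a \code{phantom_case} from
#'   \code{generate_planning_phantom}.
#' @param deformation a \code{deformation_spec}; a \code{NULL}
#'   \code{gtv_center} is resolved to the phantom's GTV centre.
#' @return list with \code{volume}, \code{clean}, \code{masks}
#'   (ground-truth, target frame), \code{true_dvf}, \code{deformation}.
#' @export
generate_per_treatment <- function(planning,
                                   deformation = deformation_spec()) {
  stopifnot(inherits(planning, "phantom_case"),
            inherits(deformation, "deformation_spec"))
  spec <- planning$spec
  if (is.null(deformation$gtv_center))
    deformation$gtv_center <- planning$scene$gtv_center
  mj <- min_jacobian_det(deformation, spec)
  if (mj <= deformation$min_jacobian)
    stop(sprintf("deformation fails the invertibility check: min |J| = %.3f",
                 mj))
  pts <- phantom_grid_points(spec)
  u <- evaluate_deformation(deformation, pts)
  src <- pts + u
  clean <- array(planning$scene$intensity(src), spec$dims)
  masks <- lapply(c(roi_labels, "body"), function(lb)
    binary_mask(array(planning$scene$membership[[lb]](src), spec$dims),
                spec$spacing, spec$origin, lb))
  names(masks) <- c(roi_labels, "body")
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed + 2L,
              array(stats::rnorm(prod(spec$dims), 0, spec$noise_sd),
                    spec$dims))
  else 0
  dvf <- displacement_field(array(u[, 1], spec$dims),
                            array(u[, 2], spec$dims),
                            array(u[, 3], spec$dims),
                            spec$spacing, spec$origin)
  list(volume = image_volume(clean + noise, spec$spacing, spec$origin),
       clean = image_volume(clean, spec$spacing, spec$origin),
       masks = masks, true_dvf = dvf, deformation = deformation)
}

#' Displacement-recovery error report on the phantom
#'
#' Compares an estimated displacement field with the analytic truth: mean
#' and 95th-percentile error magnitude (mm) over the body and over each
#' organ region (regions taken in the target frame), plus the Dice score
#' of each planning organ mask propagated with the estimated field against
#' the ground-truth target mask.
#'
#' @param true_dvf,estimated_dvf \code{displacement_field}s on one grid.
#' @param planning_masks named list of planning-frame \code{binary_mask}s.
#' @param target_masks named list of ground-truth target-frame masks
#'   (must include \code{body}).
#' @return data.frame with one row per region: region, mean_error_mm,
#'   p95_error_mm, dice (NA for body).
#' @export
recovery_report <- function(true_dvf, estimated_dvf, planning_masks,
                            target_masks) {
  if (!same_grid(true_dvf, estimated_dvf)) stop("grid mismatch")
  err <- sqrt((true_dvf$vx - estimated_dvf$vx)^2 +
                (true_dvf$vy - estimated_dvf$vy)^2 +
                (true_dvf$vz - estimated_dvf$vz)^2)
  regions <- names(target_masks)
  rows <- lapply(regions, function(lb) {
    sel <- target_masks[[lb]]$data
    dc <- if (lb %in% names(planning_masks) && lb != "body") {
      prop <- propagate_mask(planning_masks[[lb]], estimated_dvf)
      dice(prop, target_masks[[lb]])
    } else NA_real_
    data.frame(region = lb, mean_error_mm = mean(err[sel]),
               p95_error_mm = as.numeric(stats::quantile(err[sel], 0.95)),
               dice = dc)
  })
  do.call(rbind, rows)
}
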