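#' Binary region-of-interest mask
#'
#' A labelled logical array on the grid of a reference image volume. The
#' conventional head-and-neck labels are spinal_cord, brainstem, parotid_L,
#' parotid_R and GTV, but any label is accepted.
#'
#' @param data logical (or 0/1) 3D array.
#' @param spacing,origin grid geometry in mm.
#' @param label ROI name.
#' @return an object of class \code{binary_mask}.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        label = "roi") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  storage.mode(data) <- "logical"
  if (any(is.na(data))) stop("mask values must be TRUE/FALSE")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), label = as.character(label)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> '", x$label, "' ", sum(x$data), " voxels of ",
      paste(dim(x$data), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' @rdname binary_mask
#' @param x an object.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Mask voxel count and enclosed volume
#' @param mask a \code{binary_mask}.
#' @return \code{mask_volume_mm3}: voxel count times voxel volume (mm^3).
#' @export
mask_volume_mm3 <- function(mask) sum(mask$data) * prod(mask$spacing)

#' Propagate a mask through a displacement field (pull-back lookup)
#'
#' For each voxel x of the target grid, the mask value at the nearest
#' source voxel to \code{world(x) + u(x)} is looked up (nearest-neighbour,
#' not interpolate-and-threshold). Work is restricted to a sub-volume: the
#' source ROI bounding box dilated by \code{ceil(max|u| / spacing) + 2}
#' voxels, a margin that guarantees equality with the full-grid lookup;
#' voxels outside the sub-volume are FALSE.
#'
#' @param mask_on_source a \code{binary_mask} on the source grid.
#' @param dvf a \code{displacement_field} on the target grid.
#' @return a \code{binary_mask} on the target grid with the same label.
#' @export
propagate_mask <- function(mask_on_source, dvf) {
  stopifnot(is_binary_mask(mask_on_source), is_displacement_field(dvf))
  d <- vol_dim(dvf)
  out <- array(FALSE, d)
  w <- which(mask_on_source$data)
  if (length(w)) {
    src_idx <- arrayInd(w, vol_dim(mask_on_source)) - 1L
    # ROI bounding box in world mm, then in target indices
    lo_w <- mask_on_source$origin +
      apply(src_idx, 2, min) * mask_on_source$spacing
    hi_w <- mask_on_source$origin +
      apply(src_idx, 2, max) * mask_on_source$spacing
    maxu <- sqrt(max(dvf$vx^2 + dvf$vy^2 + dvf$vz^2))
    marg <- ceiling(maxu / dvf$spacing) + 2
    lo <- pmax(0, floor((lo_w - dvf$origin) / dvf$spacing) - marg)
    hi <- pmin(d - 1, ceiling((hi_w - dvf$origin) / dvf$spacing) + marg)
    if (all(lo <= hi)) {
      ix <- (lo[1]:hi[1]) + 1L; iy <- (lo[2]:hi[2]) + 1L
      iz <- (lo[3]:hi[3]) + 1L
      nb <- c(length(ix), length(iy), length(iz))
      gi <- rep.int(ix - 1L, nb[2] * nb[3])
      gj <- rep.int(rep(iy - 1L, each = nb[1]), nb[3])
      gk <- rep(iz - 1L, each = nb[1] * nb[2])
      sub <- function(a) as.numeric(a[ix, iy, iz])
      px <- dvf$origin[1] + gi * dvf$spacing[1] + sub(dvf$vx)
      py <- dvf$origin[2] + gj * dvf$spacing[2] + sub(dvf$vy)
      pz <- dvf$origin[3] + gk * dvf$spacing[3] + sub(dvf$vz)
      si <- round((px - mask_on_source$origin[1]) / mask_on_source$spacing[1])
      sj <- round((py - mask_on_source$origin[2]) / mask_on_source$spacing[2])
      sk <- round((pz - mask_on_source$origin[3]) / mask_on_source$spacing[3])
      ds <- vol_dim(mask_on_source)
      inb <- si >= 0 & si < ds[1] & sj >= 0 & sj < ds[2] &
        sk >= 0 & sk < ds[3]
      val <- logical(length(si))
      val[inb] <- mask_on_source$data[1L + si[inb] + ds[1] *
                                        (sj[inb] + ds[2] * sk[inb])]
      out[ix, iy, iz] <- array(val, nb)
    }
  }
  binary_mask(out, dvf$spacing, dvf$origin, mask_on_source$label)
}

#' Triangulated ROI surface mesh
#' @param vertices n x 3 matrix of world-mm vertex positions.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param label ROI name.
#' @return an object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, triangles, label = "roi") {
  vertices <- rbind2mat(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 label = as.character(label)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> '", x$label, "' ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

mesh_edge_counts <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Is the mesh watertight?
#'
#' Every edge must be shared by an even number (almost always two) of
#' triangles. Voxel-face surfaces of masks with diagonal voxel contacts
#' contain edges shared by four triangles; these are still watertight for
#' ray-parity classification, so they count as closed.
#'
#' @param mesh a \code{surface_mesh}.
#' @export
is_closed_mesh <- function(mesh) {
  ec <- mesh_edge_counts(mesh)
  all(ec %% 2 == 0)
}

#' Extract the closed boundary surface of a binary mask
#'
#' Builds the exact voxel-face (cuberille) surface: every face between an
#' inside and an outside voxel (or the grid border) contributes two
#' triangles, with vertices on the voxel-corner lattice in world mm. The
#' surface is the 0.5 iso-surface of the nearest-neighbour mask field, is
#' closed by construction, and encloses exactly the masked volume
#' (voxel count x voxel volume).
#'
#' @param mask a non-empty \code{binary_mask}.
#' @param smooth_iterations number of Taubin (shrinkage-compensated
#'   Laplacian) smoothing passes applied to the vertices; 0 keeps the
#'   exact blocky voxel surface. A few passes remove the voxel staircase,
#'   which reduces re-discretization error when the mesh is warped and
#'   rasterized on another grid.
#' @return a \code{surface_mesh}.
#' @export
extract_mesh <- function(mask, smooth_iterations = 0) {
  stopifnot(is_binary_mask(mask))
  m <- mask$data
  if (!any(m)) stop("cannot extract a mesh from an empty mask")
  d <- dim(m)
  quads <- list()
  # boundary faces in each of the 6 directions; voxel (i,j,k) 0-based
  face_dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))
  ckey <- function(ci) ci[, 1] + (d[1] + 1) * (ci[, 2] + (d[2] + 1) * ci[, 3])
  for (dir in face_dirs) {
    # neighbour on the +dir side: shift_array moves content by +d, so the
    # voxel at i sees m[i + dir] after shifting by -dir
    nb <- shift_array(m, -dir[1], -dir[2], -dir[3], FALSE)
    bnd <- which(m & !nb)
    if (!length(bnd)) next
    v <- arrayInd(bnd, d) - 1L  # 0-based voxel index
    # the face sits on the +dir side of the voxel; corner lattice indices
    ax <- which(dir != 0)
    off <- if (dir[ax] > 0) 1L else 0L
    o1 <- (ax %% 3) + 1L; o2 <- (o1 %% 3) + 1L
    corner <- function(a1, a2) {
      ci <- v
      ci[, ax] <- ci[, ax] + off
      ci[, o1] <- ci[, o1] + a1
      ci[, o2] <- ci[, o2] + a2
      ci
    }
    c00 <- corner(0L, 0L); c10 <- corner(1L, 0L)
    c11 <- corner(1L, 1L); c01 <- corner(0L, 1L)
    # consistent outward winding (normals point away from the mask)
    quads[[length(quads) + 1L]] <- if (dir[ax] > 0)
      cbind(ckey(c00), ckey(c10), ckey(c11), ckey(c01))
    else
      cbind(ckey(c00), ckey(c01), ckey(c11), ckey(c10))
  }
  q <- do.call(rbind, quads)
  keys <- sort(unique(as.vector(q)))
  qi <- matrix(match(as.vector(q), keys), nrow = nrow(q))
  # corner lattice key -> world coordinates (corner i is at index i - 0.5)
  ci <- keys %% (d[1] + 1)
  rest <- keys %/% (d[1] + 1)
  cj <- rest %% (d[2] + 1)
  ck <- rest %/% (d[2] + 1)
  verts <- cbind(mask$origin[1] + (ci - 0.5) * mask$spacing[1],
                 mask$origin[2] + (cj - 0.5) * mask$spacing[2],
                 mask$origin[3] + (ck - 0.5) * mask$spacing[3])
  tris <- rbind(qi[, c(1, 2, 3)], qi[, c(1, 3, 4)])
  mesh <- surface_mesh(verts, tris, mask$label)
  if (smooth_iterations > 0)
    mesh <- taubin_smooth(mesh, smooth_iterations)
  mesh
}

#' Taubin mesh smoothing
#'
#' Alternating Laplacian steps with positive and negative weights
#' (lambda/mu), which smooths the surface without the systematic shrinkage
#' of plain Laplacian smoothing. Topology is unchanged.
#'
#' @param mesh a \code{surface_mesh}.
#' @param iterations number of lambda+mu passes.
#' @param lambda,mu Taubin weights (defaults 0.5 / -0.53).
#' @return the smoothed \code{surface_mesh}.
#' @export
taubin_smooth <- function(mesh, iterations = 5, lambda = 0.5,
                          mu = -0.53) {
  v <- mesh$vertices
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  n <- nrow(v)
  deg <- tabulate(e[, 1], n)
  lap_step <- function(v, w) {
    nbmean <- rowsum(v[e[, 2], , drop = FALSE], e[, 1])
    nbmean <- nbmean / deg
    v + w * (nbmean - v)
  }
  for (i in seq_len(iterations)) {
    v <- lap_step(v, lambda)
    v <- lap_step(v, mu)
  }
  surface_mesh(v, tr, mesh$label)
}

#' Warp a surface mesh through a thin-plate-spline transform
#'
#' Vertices are mapped by \code{apply_tps}; triangle topology is unchanged.
#'
#' @param mesh a \code{surface_mesh}.
#' @param t a \code{tps_transform}.
#' @return the warped \code{surface_mesh}.
#' @export
warp_mesh <- function(mesh, t) {
  surface_mesh(apply_tps(t, mesh$vertices), mesh$triangles, mesh$label)
}

#' Rasterize a closed surface mesh onto a voxel grid
#'
#' Voxel-centre classification by ray parity: a voxel belongs to the mask
#' iff its centre lies inside the surface, with boundary hits counting as
#' inside. The mesh must be closed (every edge shared by exactly two
#' triangles).
#'
#' @param mesh a closed \code{surface_mesh}.
#' @param grid an \code{image_volume}, \code{binary_mask} or
#'   \code{displacement_field} defining the output grid.
#' @return a \code{binary_mask} on the grid, labelled like the mesh.
#' @export
rasterize_mesh <- function(mesh, grid) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is_closed_mesh(mesh))
    stop("open mesh: some edges are not shared by exactly 2 triangles")
  d <- vol_dim(grid)
  inside <- cpp_rasterize(mesh$vertices, mesh$triangles - 1L, d,
                          grid$spacing, grid$origin)
  binary_mask(array(inside, d), grid$spacing, grid$origin, mesh$label)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a closed \code{surface_mesh}.
#' @return signed enclosed volume in mm^3 (absolute value reported).
#' @export
mesh_volume_mm3 <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det3)) / 6
}
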