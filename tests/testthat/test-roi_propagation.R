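test_that("propagate_mask: identity, integer shift, full-grid loop oracle", {
  sp <- small_phantom()
  mask <- sp$pl$masks$parotid_L
  d <- vol_dim(mask)
  # zero field on the same grid reproduces the mask exactly
  z <- displacement_field(array(0, d), array(0, d), array(0, d),
                          mask$spacing, mask$origin)
  expect_identical(propagate_mask(mask, z)$data, mask$data)
  # constant one-voxel x-translation preserves the voxel count (interior)
  tfield <- displacement_field(array(mask$spacing[1], d), array(0, d),
                               array(0, d), mask$spacing, mask$origin)
  pm <- propagate_mask(mask, tfield)
  expect_equal(sum(pm$data), sum(mask$data))
  expect_equal(pm$data[1:(d[1] - 1), , ], mask$data[2:d[1], , ])
  # random smooth field: voxel-exact equality with a full-grid loop oracle
  # (validates the sub-volume optimization)
  dims <- c(12, 11, 8); spc <- c(2, 2, 3)
  set.seed(20)
  small <- array(FALSE, dims); small[4:8, 3:7, 3:6] <- TRUE
  small[5, 5, 4] <- FALSE
  msk <- binary_mask(small, spc, c(0, 0, 0), "blob")
  dvf <- random_smooth_field(dims, spc, seed = 21, amp = 4)
  got <- propagate_mask(msk, dvf)
  oracle <- array(FALSE, dims)
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1))
    for (k in 0:(dims[3] - 1)) {
      p <- c(i * spc[1] + dvf$vx[i + 1, j + 1, k + 1],
             j * spc[2] + dvf$vy[i + 1, j + 1, k + 1],
             k * spc[3] + dvf$vz[i + 1, j + 1, k + 1])
      n <- round(p / spc)
      if (all(n >= 0) && all(n < dims))
        oracle[i + 1, j + 1, k + 1] <- small[n[1] + 1, n[2] + 1, n[3] + 1]
    }
  expect_identical(got$data, oracle)
})

test_that("extract_mesh: exact enclosed volume, centred sphere, errors", {
  # 10^3-voxel cube: the voxel-face surface encloses exactly 1000 voxels
  d <- c(16, 16, 16)
  cube <- array(FALSE, d); cube[4:13, 4:13, 4:13] <- TRUE
  mc <- binary_mask(cube, c(2, 2, 2), c(0, 0, 0), "cube")
  mesh <- extract_mesh(mc)
  expect_true(is_closed_mesh(mesh))
  expect_equal(mesh_volume_mm3(mesh), mask_volume_mm3(mc),
               tolerance = 1e-9)
  expect_lt(abs(mesh_volume_mm3(mesh) - 1000 * 8) / (1000 * 8), 0.1)
  # sphere mask: mesh centroid within half a voxel of the true centre
  ctr <- c(15, 15, 15)
  g <- expand.grid(x = (0:15) * 2, y = (0:15) * 2, z = (0:15) * 2)
  sph <- array((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <=
                 10^2, d)
  ms <- binary_mask(sph, c(2, 2, 2), c(0, 0, 0), "sphere")
  mesh_s <- extract_mesh(ms)
  expect_lt(max(abs(colMeans(mesh_s$vertices) - ctr)), 1)
  expect_error(extract_mesh(binary_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("warp_mesh preserves topology under any transform", {
  sp <- small_phantom()
  mesh <- extract_mesh(sp$pl$masks$GTV)
  src <- matrix(runif(45, 0, 150), 15, 3)
  co <- data.frame(x_source = src[, 1], y_source = src[, 2],
                   z_source = src[, 3], x_target = src[, 1] + 6,
                   y_target = src[, 2], z_target = src[, 3] - 3)
  tps <- fit_tps(co)
  wm <- warp_mesh(mesh, tps)
  expect_identical(wm$triangles, mesh$triangles)
  expect_equal(nrow(wm$vertices), nrow(mesh$vertices))
  expect_equal(wm$vertices, mesh$vertices +
                 matrix(rep(c(6, 0, -3), each = nrow(mesh$vertices)), ncol = 3),
               tolerance = 1e-6)
})

test_that("rasterize_mesh: round trips, translated cube, open-mesh error", {
  sp <- small_phantom()
  for (lb in c("spinal_cord", "parotid_R", "GTV")) {
    m <- sp$pl$masks[[lb]]
    rt <- rasterize_mesh(extract_mesh(m), m)
    expect_gte(dice(rt, m), 0.95)
  }
  # translated cube mesh rasterizes to the translated cube mask
  d <- c(12, 12, 12)
  cube <- array(FALSE, d); cube[3:6, 3:6, 3:6] <- TRUE
  mc <- binary_mask(cube, c(2, 2, 2), c(0, 0, 0), "cube")
  mesh <- extract_mesh(mc)
  mesh$vertices <- sweep(mesh$vertices, 2, c(4, 4, 4), "+") # 2 voxels
  shifted <- rasterize_mesh(mesh, mc)
  expected <- array(FALSE, d); expected[5:8, 5:8, 5:8] <- TRUE
  expect_identical(shifted$data, expected)
  # removing one triangle opens the surface
  open_mesh <- surface_mesh(mesh$vertices, mesh$triangles[-1, ], "open")
  expect_error(rasterize_mesh(open_mesh, mc), "open mesh")
})

test_that("taubin smoothing keeps meshes closed and nearly volume-true", {
  sp <- small_phantom()
  m <- sp$pl$masks$parotid_L
  mesh <- extract_mesh(m, smooth_iterations = 5)
  expect_true(is_closed_mesh(mesh))
  expect_lt(abs(mesh_volume_mm3(mesh) - mask_volume_mm3(m)) /
              mask_volume_mm3(m), 0.15)
  expect_gte(dice(rasterize_mesh(mesh, m), m), 0.95)
})

test_that("truth-field propagation reproduces analytic masks (thick blob)", {
  # the Dice >= 0.95 double-discretization bound holds for structures at
  # least ~10 voxels across; thin organs (the 5-voxel cord) sit lower
  dims <- c(36, 36, 24); spc <- c(2, 2, 3)
  ctr <- c(35, 35, 34)
  member <- function(p) rowSums(sweep(p, 2, ctr)^2) <= 24^2
  g <- as.matrix(expand.grid(x = (0:35) * 2, y = (0:35) * 2,
                             z = (0:23) * 3))
  mask_p <- binary_mask(array(member(g), dims), spc, c(0, 0, 0), "blob")
  bump <- function(p) 5 * exp(-rowSums(sweep(p, 2, c(40, 30, 30))^2) /
                                (2 * 30^2))
  u <- cbind(bump(g), -0.6 * bump(g), 0.4 * bump(g))
  dvf <- displacement_field(array(u[, 1], dims), array(u[, 2], dims),
                            array(u[, 3], dims), spc, c(0, 0, 0))
  truth <- binary_mask(array(member(g + u), dims), spc, c(0, 0, 0),
                       "blob")
  expect_gte(dice(propagate_mask(mask_p, dvf), truth), 0.95)
  # the coarse test phantom (4-6 mm voxels) sits lower but stays sane
  sp <- small_phantom()
  for (lb in c("parotid_L", "GTV"))
    expect_gte(dice(propagate_mask(sp$pl$masks[[lb]], sp$tx$true_dvf),
                    sp$tx$masks[[lb]]), 0.75)
})

test_that("PLY mesh IO round-trips", {
  sp <- small_phantom()
  mesh <- extract_mesh(sp$pl$masks$GTV)
  path <- tempfile(fileext = ".ply")
  write_ply(mesh, path)
  m2 <- read_ply(path, "GTV")
  expect_equal(m2$vertices, mesh$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(m2$triangles, mesh$triangles)
})
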