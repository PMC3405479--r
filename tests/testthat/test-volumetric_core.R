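test_that("trilinear sampling: centre identity, linear blend, clamping", {
  set.seed(1)
  v <- image_volume(array(rnorm(5 * 4 * 3, 100, 30), c(5, 4, 3)),
                    spacing = c(2, 2, 3), origin = c(-4, 1, 7))
  # every voxel centre returns the stored value exactly
  idx <- as.matrix(expand.grid(0:4, 0:3, 0:2))
  w <- index_to_world(v, idx)
  expect_equal(trilinear_sample(v, w), as.numeric(v$data[idx + 1]))
  # midpoint between two adjacent centres is the arithmetic mean
  v$data[2, 2, 2] <- 10; v$data[3, 2, 2] <- 20
  mid <- index_to_world(v, c(1.5, 1, 1))
  expect_equal(trilinear_sample(v, mid), 15)
  # far-outside points clamp to the border voxel
  expect_equal(trilinear_sample(v, c(-1e4, -1e4, -1e4)),
               v$data[1, 1, 1])
  expect_equal(trilinear_sample(v, c(1e4, 1e4, 1e4)),
               v$data[5, 4, 3])
  expect_error(trilinear_sample(v, c(NA, 0, 0)), "finite")
  # agreement with an independent scalar oracle at random points
  set.seed(2)
  for (i in 1:25) {
    p <- c(runif(1, -6, 8), runif(1, 0, 8), runif(1, 5, 15))
    expect_equal(trilinear_sample(v, p), oracle_trilinear(v, p),
                 tolerance = 1e-12)
  }
})

test_that("warp_image: identity field, integer translation, loop oracle", {
  set.seed(3)
  src <- image_volume(array(rnorm(8 * 7 * 6), c(8, 7, 6)),
                      spacing = c(2, 2, 3))
  expect_equal(warp_image(src, zero_field(src))$data, src$data)
  # constant field of one voxel (+2 mm in x): out(x) = src(x + 2mm)
  d <- vol_dim(src)
  f <- displacement_field(array(2, d), array(0, d), array(0, d),
                          src$spacing, src$origin)
  w <- warp_image(src, f)
  expect_equal(w$data[1:7, , ], src$data[2:8, , ])
  # random smooth field: per-voxel equality with the sampling oracle
  dvf <- random_smooth_field(d, src$spacing, seed = 4)
  w2 <- warp_image(src, dvf)
  for (q in seq(1, prod(d), by = 17)) {
    i <- arrayInd(q, d)
    p <- index_to_world(src, i - 1) +
      c(dvf$vx[q], dvf$vy[q], dvf$vz[q])
    expect_equal(w2$data[q], oracle_trilinear(src, as.numeric(p)),
                 tolerance = 1e-12)
  }
})

test_that("gaussian_smooth_field: constants, impulse oracle, sigma 0", {
  d <- c(9, 9, 9)
  const <- displacement_field(array(4, d), array(-2, d), array(0.5, d),
                              c(1, 1, 1))
  sm <- gaussian_smooth_field(const, 1.7)
  expect_equal(sm$vx, const$vx, tolerance = 1e-12)
  expect_equal(sm$vy, const$vy, tolerance = 1e-12)
  # impulse response matches a dense renormalized-truncated-kernel oracle
  imp <- array(0, d); imp[5, 5, 5] <- 1
  f <- displacement_field(imp, imp * 0, imp * 0, c(1, 1, 1))
  sigma <- 1.2
  got <- gaussian_smooth_field(f, sigma)$vx
  r <- ceiling(3 * sigma)
  k1 <- exp(-0.5 * (-r:r)^2 / sigma^2)
  oracle <- array(0, d)
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    acc <- 0; wtot <- 0
    # separable renormalized convolution written as an explicit triple sum
    wx <- rep(0, 9); wy <- rep(0, 9); wz <- rep(0, 9)
    for (t in -r:r) {
      if (i + t >= 1 && i + t <= 9) wx[i + t] <- k1[t + r + 1]
      if (j + t >= 1 && j + t <= 9) wy[j + t] <- k1[t + r + 1]
      if (k + t >= 1 && k + t <= 9) wz[k + t] <- k1[t + r + 1]
    }
    wx <- wx / sum(wx); wy <- wy / sum(wy); wz <- wz / sum(wz)
    oracle[i, j, k] <- wx[5] * wy[5] * wz[5]
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # sigma 0 is the identity; negative sigma errors
  expect_identical(gaussian_smooth_field(f, 0), f)
  expect_error(gaussian_smooth_field(f, -1), "non-negative")
  # mean preservation when the smoothed support stays clear of the
  # renormalized border zone (support +/- 3 sigma inside the grid)
  set.seed(5)
  g <- array(0, c(21, 21, 21))
  g[8:14, 8:14, 8:14] <- rnorm(343)
  fld <- displacement_field(g, g, g, c(1, 1, 1))
  smn <- gaussian_smooth_field(fld, 1)
  expect_equal(mean(smn$vx), mean(g), tolerance = 1e-6)
})

test_that("downsample: identity, constancy, grid arithmetic, composition", {
  set.seed(6)
  v <- image_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), c(1.5, 2, 3),
                    c(5, 5, 5))
  expect_identical(downsample(v, 1), v)
  cv <- image_volume(array(7, c(8, 8, 8)), c(1, 1, 1))
  expect_equal(downsample(cv, 3)$data,
               array(7, vol_dim(downsample(cv, 3))), tolerance = 1e-12)
  d2 <- downsample(v, 2)
  expect_identical(vol_dim(d2), c(4L, 4L, 4L))
  expect_equal(d2$spacing, v$spacing * 2)
  expect_equal(d2$origin, v$origin)
  # composed factors multiply the spacing like a single downsample
  expect_equal(downsample(downsample(v, 2), 2)$spacing,
               downsample(v, 4)$spacing)
  expect_error(downsample(v, 0), "factor")
})

test_that("index/world round trip is the identity on grid points", {
  v <- image_volume(array(0, c(6, 5, 4)), c(0.7, 2.3, 3.1),
                    c(-10, 4, 2.5))
  set.seed(7)
  idx <- cbind(sample(0:5, 30, TRUE), sample(0:4, 30, TRUE),
               sample(0:3, 30, TRUE))
  expect_equal(world_to_index(v, index_to_world(v, idx)), idx,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("volume and field constructors validate their invariants", {
  expect_error(image_volume(array(1, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(1, c(2, 2, 2)), c(1, -1, 1)),
               "spacing")
  expect_error(image_volume(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(displacement_field(array(0, c(2, 2, 2)),
                                  array(0, c(2, 2, 2)),
                                  array(0, c(3, 2, 2))), "identical")
  expect_error(displacement_field(array(Inf, c(2, 2, 2)),
                                  array(0, c(2, 2, 2)),
                                  array(0, c(2, 2, 2))), "finite")
})
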