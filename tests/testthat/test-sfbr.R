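# build a volume containing Gaussian blobs on a flat background
blob_volume <- function(centers, sigmas, dims = c(40, 40, 24),
                        spacing = c(2, 2, 3), amp = 200) {
  g <- expand.grid(x = (seq_len(dims[1]) - 1) * spacing[1],
                   y = (seq_len(dims[2]) - 1) * spacing[2],
                   z = (seq_len(dims[3]) - 1) * spacing[3])
  v <- rep(0, nrow(g))
  for (i in seq_len(nrow(centers)))
    v <- v + amp * exp(-((g$x - centers[i, 1])^2 + (g$y - centers[i, 2])^2 +
                           (g$z - centers[i, 3])^2) / (2 * sigmas[i]^2))
  image_volume(array(v, dims), spacing)
}

test_that("detect_salient_features finds isolated blobs, nothing in flat", {
  flat <- image_volume(array(3, c(12, 12, 8)))
  expect_equal(nrow(detect_salient_features(flat)), 0)
  p <- sfbr_params(min_contrast_mad = 0)  # noise-free volume, no floor
  one <- blob_volume(matrix(c(40, 38, 33), 1), 4)
  f1 <- detect_salient_features(one, p)
  expect_gte(nrow(f1), 1)
  top <- f1[1, ]
  expect_lt(sqrt((top$x - 40)^2 + (top$y - 38)^2 + (top$z - 33)^2),
            max(one$spacing))
  two <- blob_volume(rbind(c(24, 26, 21), c(56, 52, 45)), c(4, 4))
  f2 <- detect_salient_features(two, p)
  expect_gte(nrow(f2), 2)
  d1 <- sqrt((f2$x - 24)^2 + (f2$y - 26)^2 + (f2$z - 21)^2)
  d2 <- sqrt((f2$x - 56)^2 + (f2$y - 52)^2 + (f2$z - 45)^2)
  expect_lt(min(d1), 2 * max(two$spacing))
  expect_lt(min(d2), 2 * max(two$spacing))
  # determinism: identical volumes give identical ordered feature lists
  expect_identical(detect_salient_features(two, p), f2)
})

test_that("match_feature: self-match, known shift, noise discarding", {
  sp <- small_phantom()
  vol <- sp$pl$volume
  p <- sfbr_params()
  feats <- detect_salient_features(vol, p)
  expect_gt(nrow(feats), 10)
  m_self <- NULL
  for (i in seq_len(nrow(feats))) {
    m_self <- match_feature(feats[i, ], vol, vol, p)
    if (!is.null(m_self)) break
  }
  expect_false(is.null(m_self))
  expect_equal(as.numeric(m_self[1, 4:6]), as.numeric(m_self[1, 1:3]))
  expect_gte(m_self$correlation, 0.999)
  # 6 mm shift within the search radius, recovered within half a voxel
  sh <- image_volume(vol$data, vol$spacing, vol$origin)
  sh$data[1:(dim(sh$data)[1] - 1), , ] <- vol$data[2:dim(vol$data)[1], , ]
  # sh(x) = vol(x + 4 mm), so each feature window reappears 4 mm to the
  # negative x side: recovered displacement is -4 mm within half a voxel
  mm <- adaptreg:::match_features_batch(feats, vol, sh, p)
  ok <- mm$ok
  expect_gt(sum(ok), 5)
  dx <- mm$x_target[ok] - mm$x_source[ok]
  expect_lt(max(abs(dx + 4)), vol$spacing[1] / 2)
  # pure-noise targets are discarded with probability ~ 1 (100 trials)
  set.seed(42)
  discards <- 0
  trials <- 100
  dims <- c(13, 13, 9)
  src <- image_volume(array(rnorm(prod(dims)), dims), c(2, 2, 3))
  feat <- data.frame(x = 12, y = 12, z = 12, scale = 3.5, response = 1)
  for (i in seq_len(trials)) {
    tgt <- image_volume(array(rnorm(prod(dims)), dims), c(2, 2, 3))
    if (is.null(match_feature(feat, src, tgt,
                              sfbr_params(consistency_tol_mm = Inf))))
      discards <- discards + 1
  }
  expect_gte(discards, 97)
})

test_that("fit_tps reproduces translations and affine maps exactly", {
  set.seed(13)
  src <- matrix(runif(45, 0, 100), 15, 3)
  mk_corr <- function(tgt) {
    data.frame(x_source = src[, 1], y_source = src[, 2],
               z_source = src[, 3], x_target = tgt[, 1],
               y_target = tgt[, 2], z_target = tgt[, 3])
  }
  # pure translation
  tr <- mk_corr(sweep(src, 2, c(5, -3, 2), "+"))
  tps <- fit_tps(tr, lambda = 0)
  probe <- matrix(runif(300, -20, 120), 100, 3)
  expect_lt(max(abs(apply_tps(tps, probe) -
                      sweep(probe, 2, c(5, -3, 2), "+"))), 1e-6)
  # general affine map reproduced at 100 random probe points
  A <- matrix(c(1.1, 0.2, -0.1, 0.05, 0.9, 0.15, -0.2, 0.1, 1.05), 3, 3)
  b <- c(4, -7, 2)
  tgt <- sweep(src %*% t(A), 2, b, "+")
  tps2 <- fit_tps(mk_corr(tgt), lambda = 0)
  expect_lt(max(abs(apply_tps(tps2, probe) -
                      sweep(probe %*% t(A), 2, b, "+"))), 1e-6)
  # lambda = 0 interpolates anchors exactly; side conditions hold
  set.seed(14)
  tgt3 <- src + matrix(rnorm(45, 0, 4), 15, 3)
  tps3 <- fit_tps(mk_corr(tgt3), lambda = 0)
  expect_lt(max(abs(apply_tps(tps3, src) - tgt3)), 1e-6)
  expect_lt(tps3$side_condition_residual, 1e-8)
  # coplanar anchors are rejected with a rank message
  co_flat <- mk_corr(tgt3)
  co_flat$z_source <- 5
  expect_error(fit_tps(co_flat), "degenerate|rank|singular")
  expect_error(fit_tps(mk_corr(tgt3)[1:3, ]), "at least 4")
})

test_that("apply_tps agrees with a naive double-loop oracle", {
  set.seed(15)
  src <- matrix(runif(36, 0, 50), 12, 3)
  tgt <- src + matrix(rnorm(36, 0, 3), 12, 3)
  co <- data.frame(x_source = src[, 1], y_source = src[, 2],
                   z_source = src[, 3], x_target = tgt[, 1],
                   y_target = tgt[, 2], z_target = tgt[, 3])
  tps <- fit_tps(co)
  pts <- matrix(runif(60, -10, 60), 20, 3)
  got <- apply_tps(tps, pts)
  for (i in seq_len(nrow(pts))) {
    val <- as.numeric(c(1, pts[i, ]) %*% tps$affine)
    for (j in seq_len(nrow(src)))
      val <- val + sqrt(sum((pts[i, ] - src[j, ])^2)) * tps$weights[j, ]
    expect_equal(got[i, ], val, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("sfbr_register: self-registration is near identity; noise errors", {
  sp <- small_phantom()
  reg <- sfbr_register(sp$pl$volume, sp$pl$volume)
  expect_gte(reg$retained_count, 10)
  expect_true(all(reg$correspondences$correlation >= 0.80))
  set.seed(16)
  probe <- matrix(runif(60, 20, 160), 20, 3)
  expect_lt(max(sqrt(rowSums((apply_tps(reg$transform, probe) -
                                probe)^2))), 0.5)
  # independent noise volumes cannot produce enough reliable anchors
  n1 <- image_volume(array(rnorm(20^3), c(20, 20, 20)), c(2, 2, 2))
  n2 <- image_volume(array(rnorm(20^3), c(20, 20, 20)), c(2, 2, 2))
  expect_error(sfbr_register(n1, n2), "insufficient anchors")
})

test_that("TPS JSON and correspondence CSV round-trip", {
  set.seed(17)
  src <- matrix(runif(36, 0, 50), 12, 3)
  co <- data.frame(x_source = src[, 1], y_source = src[, 2],
                   z_source = src[, 3], x_target = src[, 1] + 2,
                   y_target = src[, 2] - 1, z_target = src[, 3] + 0.5,
                   correlation = runif(12, 0.85, 1))
  tps <- fit_tps(co)
  path <- tempfile(fileext = ".json")
  write_tps_json(tps, path)
  tps2 <- read_tps_json(path)
  pts <- matrix(runif(30, 0, 50), 10, 3)
  expect_equal(apply_tps(tps2, pts), apply_tps(tps, pts),
               tolerance = 1e-9, ignore_attr = TRUE)
  csv <- tempfile(fileext = ".csv")
  write_correspondences_csv(co, csv)
  expect_equal(read.csv(csv)$correlation, co$correlation)
})
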