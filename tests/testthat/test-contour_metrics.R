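mk_mask <- function(arr, spacing = c(2, 2, 3), label = "roi")
  binary_mask(arr, spacing, c(0, 0, 0), label)

test_that("dice follows the voxel-count formula", {
  d <- c(10, 10, 6)
  a <- array(FALSE, d); a[1:5, 1:5, 1:4] <- TRUE          # 100 voxels
  b <- array(FALSE, d); b[1:5, 1:5, 3:4] <- TRUE          # 50, all shared
  A <- mk_mask(a); B <- mk_mask(b)
  expect_equal(dice(A, A), 1)
  expect_equal(dice(A, B), 2 * 50 / 150)
  disj <- array(FALSE, d); disj[8:9, 8:9, 5:6] <- TRUE
  expect_equal(dice(A, mk_mask(disj)), 0)
  expect_error(dice(mk_mask(array(FALSE, d)), mk_mask(array(FALSE, d))),
               "empty")
  expect_error(dice(A, binary_mask(a, c(1, 1, 1))), "mismatch")
})

test_that("slice_hausdorff matches the brute-force max-min oracle", {
  expect_equal(slice_hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  pts <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(slice_hausdorff(pts, pts), 0)
  # two offset squares and random point sets vs the all-pairs oracle
  sq2 <- sweep(pts, 2, c(5, 1), "+")
  expect_equal(slice_hausdorff(pts, sq2), oracle_hausdorff(pts, sq2),
               tolerance = 1e-12)
  set.seed(30)
  for (i in 1:10) {
    a <- matrix(runif(20, 0, 30), ncol = 2)
    b <- matrix(runif(16, 0, 30), ncol = 2)
    expect_equal(slice_hausdorff(a, b), oracle_hausdorff(a, b),
                 tolerance = 1e-12)
  }
  expect_error(slice_hausdorff(matrix(numeric(0), 0, 2), pts), "empty")
})

test_that("mshd averages per-slice Hausdorff over expert slices", {
  d <- c(14, 14, 6)
  e <- array(FALSE, d); e[4:9, 4:9, 2] <- TRUE; e[4:9, 4:9, 4] <- TRUE
  p <- array(FALSE, d); p[4:9, 4:9, 2] <- TRUE; p[6:11, 4:9, 4] <- TRUE
  E <- mk_mask(e); P <- mk_mask(p)
  expect_equal(mshd(E, E)$mshd_mm, 0)
  h2 <- slice_hausdorff(oracle_slice_boundary(P, 2),
                        oracle_slice_boundary(E, 2))
  h4 <- slice_hausdorff(oracle_slice_boundary(P, 4),
                        oracle_slice_boundary(E, 4))
  got <- mshd(P, E)
  expect_equal(got$mshd_mm, (h2 + h4) / 2, tolerance = 1e-12)
  expect_equal(got$slice_count_used, 2)
  expect_error(mshd(P, mk_mask(array(FALSE, d))), "empty")
  expect_error(mshd(mk_mask(array(FALSE, d)), E), "empty")
})

test_that("mshd on random blobs equals a per-slice brute-force oracle", {
  for (s in 1:6) {
    pair <- random_mask_pair(400 + s)
    A <- pair$A; B <- pair$B
    ks <- which(apply(B$data, 3, any))
    vals <- sapply(ks, function(k) {
      be <- oracle_slice_boundary(B, k)
      bp <- oracle_slice_boundary(A, k)
      if (is.null(bp)) return(NA_real_)  # fallback handled separately
      oracle_hausdorff(be, bp)
    })
    got <- mshd(A, B)
    if (!any(is.na(vals)))
      expect_equal(got$mshd_mm, mean(vals), tolerance = 1e-9)
    expect_equal(got$slice_count_used, length(ks))
  }
})

test_that("mshd penalizes expert slices missing from the propagation", {
  d <- c(10, 10, 6)
  e <- array(FALSE, d); e[4:6, 4:6, 2] <- TRUE; e[4:6, 4:6, 5] <- TRUE
  p <- array(FALSE, d); p[4:6, 4:6, 2] <- TRUE   # slice 5 missing
  E <- mk_mask(e); P <- mk_mask(p)
  got <- mshd(P, E)
  # slice 2 contributes 0; slice 5 contributes the 3D distance from the
  # expert boundary on slice 5 to the propagated boundary (9 mm in z)
  expect_equal(got$mshd_mm, (0 + 9) / 2, tolerance = 1e-9)
})

test_that("com_displacement equals the mean-of-coordinates oracle", {
  d <- c(12, 12, 8)
  a <- array(FALSE, d); a[3:5, 4:6, 2:4] <- TRUE
  A <- mk_mask(a)
  expect_equal(com_displacement(A, A)$magnitude_mm, 0)
  b <- array(FALSE, d); b[6:8, 4:6, 2:4] <- TRUE  # +3 voxels in x (2 mm)
  B <- mk_mask(b)
  cd <- com_displacement(B, A)
  expect_equal(cd$vector_mm, c(6, 0, 0))
  expect_equal(cd$magnitude_mm, 6)
  set.seed(31)
  pair <- random_mask_pair(99)
  oc <- function(m) {
    w <- which(m$data, arr.ind = TRUE) - 1
    colMeans(sweep(w, 2, m$spacing, "*"))
  }
  got <- com_displacement(pair$A, pair$B)
  expect_equal(got$vector_mm, as.numeric(oc(pair$A) - oc(pair$B)),
               tolerance = 1e-12)
  expect_error(com_displacement(A, mk_mask(array(FALSE, d))), "empty")
})

test_that("metrics are invariant under a common integer-voxel shift", {
  pair <- random_mask_pair(55, dims = c(18, 18, 10))
  clear_border <- function(m, w = 3) {
    d <- dim(m$data); a <- m$data
    a[c(1:w, (d[1] - w + 1):d[1]), , ] <- FALSE
    a[, c(1:w, (d[2] - w + 1):d[2]), ] <- FALSE
    a[, , c(1, 2, d[3] - 1, d[3])] <- FALSE
    if (!any(a)) a[9, 9, 5] <- TRUE
    binary_mask(a, m$spacing, m$origin, m$label)
  }
  pair$A <- clear_border(pair$A); pair$B <- clear_border(pair$B)
  shift_mask <- function(m, v) {
    d <- dim(m$data)
    out <- array(FALSE, d)
    out[(1 + v[1]):d[1], (1 + v[2]):d[2], (1 + v[3]):d[3]] <-
      m$data[1:(d[1] - v[1]), 1:(d[2] - v[2]), 1:(d[3] - v[3])]
    binary_mask(out, m$spacing, m$origin, m$label)
  }
  v <- c(2, 1, 1)
  A2 <- shift_mask(pair$A, v); B2 <- shift_mask(pair$B, v)
  expect_equal(dice(A2, B2), dice(pair$A, pair$B), tolerance = 1e-12)
  expect_equal(mshd(A2, B2)$mshd_mm, mshd(pair$A, pair$B)$mshd_mm,
               tolerance = 1e-9)
  expect_equal(com_displacement(A2, B2)$magnitude_mm,
               com_displacement(pair$A, pair$B)$magnitude_mm,
               tolerance = 1e-9)
})

test_that("metric_report bundles the three measures", {
  pair <- random_mask_pair(77)
  r <- metric_report(pair$A, pair$B)
  expect_named(r, c("roi_label", "dice", "mshd_mm", "com_dx", "com_dy",
                    "com_dz", "com_mag_mm", "slice_count_used"))
  expect_equal(r$dice, dice(pair$A, pair$B))
  expect_equal(r$com_mag_mm, com_displacement(pair$A, pair$B)$magnitude_mm)
})
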