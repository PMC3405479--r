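test_that("mean_square_difference matches its definition and loop oracle", {
  set.seed(10)
  a <- image_volume(array(rnorm(4 * 4 * 4), c(4, 4, 4)), c(2, 2, 3))
  b <- image_volume(array(rnorm(4 * 4 * 4), c(4, 4, 4)), c(2, 2, 3))
  expect_equal(mean_square_difference(a, a), 0)
  off <- image_volume(a$data + 3, a$spacing, a$origin)
  expect_equal(mean_square_difference(a, off), 9, tolerance = 1e-12)
  acc <- 0
  for (q in seq_len(64)) acc <- acc + (a$data[q] - b$data[q])^2
  expect_equal(mean_square_difference(a, b), acc / 64, tolerance = 1e-12)
  bad <- image_volume(b$data, c(1, 1, 1))
  expect_error(mean_square_difference(a, bad), "mismatch")
})

test_that("demons_update: zero residual, degenerate guard, ramp solution", {
  set.seed(11)
  f <- image_volume(array(rnorm(5^3), c(5, 5, 5)), c(2, 2, 2))
  z <- demons_update(f, f)
  expect_equal(max(abs(field_magnitude(z))), 0)
  flat <- image_volume(array(1, c(5, 5, 5)), c(2, 2, 2))
  flat2 <- image_volume(array(2, c(5, 5, 5)), c(2, 2, 2))
  expect_equal(max(abs(field_magnitude(demons_update(flat, flat2)))), 0)
  # 1D linear ramp f = g*x, m = g*(x - d): closed form gives
  # u_x = d / (1 + alpha*d^2/4) ~ d for small d
  g <- 5; d_mm <- 0.4
  dims <- c(20, 5, 5); sp <- c(1, 1, 1)
  x <- array(rep((0:19) * sp[1], 5 * 5), dims)
  fr <- image_volume(g * x, sp)
  mr <- image_volume(g * (x - d_mm), sp)
  u <- demons_update(fr, mr)
  alpha <- 1 / mean(sp)^2
  expected <- d_mm / (1 + alpha * d_mm^2 / 4)
  interior <- u$vx[3:18, , ]
  expect_equal(mean(interior), expected, tolerance = 1e-6)
  expect_lt(max(abs(u$vy)), 1e-12)
})

test_that("register_level converges, respects caps and flags divergence", {
  sp <- small_phantom()
  fixed <- downsample(sp$pl$volume, 2)
  # identical inputs: stops within window + 1 iterations, tiny field
  res <- register_level(fixed, fixed, zero_field(fixed),
                        max_iterations = 50, sigma_voxels = 1,
                        tolerance_percent = 1.5, window = 5)
  expect_lte(length(res$msd_trace), 6)
  expect_lt(max(field_magnitude(res$field)) / min(fixed$spacing), 0.1)
  # trace length never exceeds the cap
  mv <- downsample(sp$tx$volume, 2)
  res2 <- register_level(fixed, mv, zero_field(fixed),
                         max_iterations = 7, sigma_voxels = 1,
                         tolerance_percent = 0.01, window = 5)
  expect_lte(length(res2$msd_trace), 7)
  # a genuine deformation strictly reduces the MSD
  expect_lt(res2$msd_trace[length(res2$msd_trace)], res2$msd_trace[1])
})

test_that("demons schedule validation", {
  expect_error(demons_schedule(levels = list(c(2, 10, 1), c(3, 10, 1))),
               "decreasing")
  expect_error(demons_schedule(levels = list(c(2, 10, 1))), "end at 1")
  expect_error(demons_schedule(stop_tolerance_percent = 0), "tolerance")
})

test_that("demons_register: identity case and offset invariance", {
  sp <- small_phantom()
  fixed <- downsample(sp$pl$volume, 2)  # 24x24x12, fast
  sched <- demons_schedule(levels = list(c(2, 20, 1.5), c(1, 10, 0.7)))
  res <- demons_register(fixed, fixed, sched)
  expect_lt(quantile(field_magnitude(res$dvf), 0.99) / min(fixed$spacing),
            0.1)
  expect_lte(length(res$msd_trace[[1]]), 20)
  # adding the same constant to both images leaves the result unchanged
  mv <- downsample(sp$tx$volume, 2)
  r1 <- demons_register(fixed, mv, sched)
  r2 <- demons_register(image_volume(fixed$data + 250, fixed$spacing,
                                     fixed$origin),
                        image_volume(mv$data + 250, mv$spacing, mv$origin),
                        sched)
  expect_equal(r1$dvf$vx, r2$dvf$vx, tolerance = 1e-9)
  expect_equal(r1$msd_trace, r2$msd_trace, tolerance = 1e-9)
})

test_that("demons recovers a small-deformation phantom at coarse scale", {
  sp <- small_phantom()
  moving <- histogram_match(sp$pl$volume, sp$tx$volume)
  sched <- demons_schedule(levels = list(c(2, 60, 1.5), c(1, 30, 0.7)))
  res <- demons_register(sp$tx$volume, moving, sched)
  err <- sqrt((sp$tx$true_dvf$vx - res$dvf$vx)^2 +
                (sp$tx$true_dvf$vy - res$dvf$vy)^2 +
                (sp$tx$true_dvf$vz - res$dvf$vz)^2)
  body <- sp$tx$masks$body$data
  # mean error over the body below one (mean) voxel spacing
  expect_lt(mean(err[body]), mean(sp$pl$spec$spacing))
  # MSD at termination is below MSD at the first iteration on every level
  for (tr in res$msd_trace) expect_lt(tr[length(tr)], tr[1] + 1e-9)
})

test_that("msd trace export writes one row per iteration", {
  sp <- small_phantom()
  fixed <- downsample(sp$pl$volume, 2)
  res <- demons_register(fixed, fixed,
                         demons_schedule(levels = list(c(1, 8, 0.7))))
  path <- tempfile(fileext = ".csv")
  write_msd_trace(res, path)
  df <- read.csv(path)
  expect_equal(nrow(df), sum(res$iterations_used))
  expect_named(df, c("level", "iteration", "msd"))
})
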