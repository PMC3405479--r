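# Shared fixtures. Expensive phantom/registration results are memoised in a
# session-local cache so several test files (and the acceptance suite) can
# reuse one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# coarse, fast phantom for unit tests (not the acceptance phantom)
small_phantom <- function() cached("small_phantom", {
  pl <- generate_planning_phantom(
    phantom_spec(dims = c(48, 48, 24), spacing = c(4, 4, 6), seed = 7,
                 n_markers = 25))
  tx <- generate_per_treatment(pl)
  list(pl = pl, tx = tx)
})

# the default phantom (default spec, seed 1) + both registrations, as
# named by acceptance criteria 4-6
acceptance_case <- function() cached("acceptance_case", {
  pl <- generate_planning_phantom(phantom_spec())
  tx <- generate_per_treatment(pl)
  moving <- histogram_match(pl$volume, tx$volume)
  demons <- demons_register(tx$volume, moving)
  sfbr <- sfbr_register(pl$volume, tx$volume)
  list(pl = pl, tx = tx, demons = demons, sfbr = sfbr)
})

# random smooth displacement field on a grid
random_smooth_field <- function(dims, spacing, seed, amp = 3) {
  set.seed(seed)
  sm <- function() {
    f <- image_volume(array(rnorm(prod(dims)), dims), spacing)
    gaussian_smooth_volume(f, 2)$data * amp
  }
  displacement_field(sm(), sm(), sm(), spacing, c(0, 0, 0))
}

# random blobby mask pair on a shared grid (for metric oracles)
random_mask_pair <- function(seed, dims = c(20, 18, 10),
                             spacing = c(2, 2, 3)) {
  set.seed(seed)
  mk <- function() {
    v <- image_volume(array(rnorm(prod(dims)), dims), spacing)
    s <- gaussian_smooth_volume(v, c(2, 2, 1.3))$data
    m <- s > quantile(s, 0.8)
    if (!any(m)) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                   ceiling(dims[3] / 2)] <- TRUE
    binary_mask(m, spacing, c(0, 0, 0), "blob")
  }
  list(A = mk(), B = mk())
}

# independent scalar trilinear oracle (explicit corner blend, clamping)
oracle_trilinear <- function(vol, p) {
  d <- dim(vol$data)
  idx <- (p - vol$origin) / vol$spacing
  idx <- pmin(pmax(idx, 0), d - 1)
  i0 <- pmin(floor(idx), pmax(d - 2, 0))
  f <- idx - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * vol$data[min(i0[1] + dx + 1, d[1]),
                              min(i0[2] + dy + 1, d[2]),
                              min(i0[3] + dz + 1, d[3])]
  }
  acc
}

# directed/symmetric Hausdorff oracle: explicit all-pairs max-min loops
oracle_hausdorff <- function(a, b) {
  dha <- 0
  for (i in seq_len(nrow(a))) {
    dmin <- Inf
    for (j in seq_len(nrow(b)))
      dmin <- min(dmin, sqrt(sum((a[i, ] - b[j, ])^2)))
    dha <- max(dha, dmin)
  }
  dhb <- 0
  for (j in seq_len(nrow(b))) {
    dmin <- Inf
    for (i in seq_len(nrow(a)))
      dmin <- min(dmin, sqrt(sum((a[i, ] - b[j, ])^2)))
    dhb <- max(dhb, dmin)
  }
  max(dha, dhb)
}

# slice boundary points the same way the metric defines them, but via an
# independent per-pixel neighbour loop
oracle_slice_boundary <- function(mask, k) {
  sl <- mask$data[, , k]
  d <- dim(sl)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!sl[i, j]) next
    nb <- c(if (i > 1) sl[i - 1, j] else FALSE,
            if (i < d[1]) sl[i + 1, j] else FALSE,
            if (j > 1) sl[i, j - 1] else FALSE,
            if (j < d[2]) sl[i, j + 1] else FALSE)
    if (!all(nb))
      pts <- rbind(pts, c(mask$origin[1] + (i - 1) * mask$spacing[1],
                          mask$origin[2] + (j - 1) * mask$spacing[2]))
  }
  pts
}
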