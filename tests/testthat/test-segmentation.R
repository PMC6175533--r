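test_that("scaling to 1 nm/px rounds dimensions half to even", {
  v <- array(runif(512 * 512, 0, 255), dim = c(512, 512, 1))
  st <- tomogram_stack(v, c(0.7, 0.7, 2))
  sc <- scale_to_1nm(st)          # 512 * 0.7 = 358.4 -> 358
  expect_equal(dim(sc$voxels)[1:2], c(358L, 358L))
  expect_equal(unname(sc$spacing), c(1, 1, 2))
})

test_that("preprocessing leaves a constant stack constant", {
  st <- tomogram_stack(array(37, c(24, 24, 3)), c(1, 1, 2))
  pre <- preprocess(st)
  # stretch is the identity and both filters preserve constants (up to
  # float round-off from the FFT-based convolution)
  expect_equal(pre$voxels, array(37, c(24, 24, 3)), tolerance = 1e-9)
})

test_that("contrast stretch maps the data range onto the working range", {
  v <- array(rep(0:100, length.out = 40 * 40 * 2), dim = c(40, 40, 2))
  # check the stretch in isolation via a stack whose filters cannot move the
  # extremes: constant-per-slice values 0 and 100
  v2 <- array(0, c(20, 20, 2)); v2[, , 2] <- 100
  pre <- preprocess(tomogram_stack(v2))
  expect_equal(min(pre$voxels), 0)
  expect_equal(max(pre$voxels), 255)
})

test_that("foreground is the dark side of the slice mean, holes filled", {
  v <- array(200, c(20, 20, 1))
  v[, 1:10, 1] <- 0
  st <- tomogram_stack(v)
  fg <- binarize_foreground(st)
  expect_true(all(fg[, 1:10, 1]))
  expect_false(any(fg[, 11:20, 1]))

  # hollow dark ring on bright background becomes a filled disk
  ring <- array(200, c(21, 21, 1))
  cc <- 11
  for (y in 1:21) for (x in 1:21) {
    d <- sqrt((y - cc)^2 + (x - cc)^2)
    if (d >= 5 && d <= 7) ring[y, x, 1] <- 0
  }
  fg2 <- binarize_foreground(tomogram_stack(ring))
  expect_true(fg2[cc, cc, 1])  # lumen filled

  # constant slice: nothing strictly darker than the mean
  fg3 <- binarize_foreground(tomogram_stack(array(5, c(8, 8, 2))))
  expect_false(any(fg3))
})

test_that("watershed separates touching balls and labels isolated ones", {
  d <- c(40, 64, 40)
  mask <- array(FALSE, d)
  mk <- function(cy, cx, cz, r) {
    for (y in 1:d[1]) for (x in 1:d[2]) for (z in 1:d[3])
      if ((y - cy)^2 + (x - cx)^2 + (z - cz)^2 <= r^2)
        mask[y, x, z] <<- TRUE
  }
  mk(20, 22, 20, 10)
  mk(20, 42, 20, 10)   # touches the first at x = 32
  lab <- split_watershed(mask, z_spacing_nm = 1)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  expect_equal(length(ids), 2L)
  for (ctr in list(c(20, 22, 20), c(20, 42, 20))) {
    errs <- vapply(ids, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      sqrt(sum((colMeans(w) - ctr)^2))
    }, numeric(1))
    expect_lt(min(errs), 2)
  }

  single <- array(FALSE, c(24, 24, 24))
  for (y in 1:24) for (x in 1:24) for (z in 1:24)
    if ((y - 12)^2 + (x - 12)^2 + (z - 12)^2 <= 64) single[y, x, z] <- TRUE
  expect_equal(max(split_watershed(single)), 1L)
  expect_equal(max(split_watershed(array(FALSE, c(8, 8, 8)))), 0L)
})

test_that("particle filter enforces volume, sphericity and ellipsoid fit", {
  crit <- particle_criteria(exclude_border = FALSE)

  ball <- digital_ball(10)
  lab <- array(0L, dim(ball)); lab[ball] <- 1L
  st <- particle_shape_stats(lab, 1L, c(1, 1, 1))
  # oracle: count voxels and boundary faces by brute force
  V <- sum(ball)
  faces <- 0
  d <- dim(ball)
  for (y in 1:d[1]) for (x in 1:d[2]) for (z in 1:d[3]) if (ball[y, x, z])
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      yy <- y + o[1]; xx <- x + o[2]; zz <- z + o[3]
      if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3] ||
          !ball[yy, xx, zz]) faces <- faces + 1
    }
  expect_equal(st$volume, V)
  sph_oracle <- pi^(1/3) * (6 * V)^(2/3) / (faces * 2 / 3)
  expect_equal(st$sphericity, sph_oracle, tolerance = 1e-12)
  expect_gte(st$sphericity, 0.8)
  out <- filter_particles(lab, crit)
  expect_equal(max(out$labels), 1L)  # retained

  # 1-voxel speck fails the volume gate
  speck <- array(0L, c(5, 5, 5)); speck[3, 3, 3] <- 1L
  out2 <- filter_particles(speck, crit, spacing = c(1, 1, 1))
  expect_equal(max(out2$labels), 0L)
  expect_equal(out2$report$reason, "volume")

  # elongated 3 x 3 x 40 rod fails sphericity
  rod <- array(0L, c(7, 7, 44)); rod[3:5, 3:5, 3:42] <- 1L
  strod <- particle_shape_stats(rod, 1L, c(1, 1, 1))
  expect_lt(strod$sphericity, st$sphericity)
  out3 <- filter_particles(rod, crit, spacing = c(1, 1, 1))
  expect_equal(max(out3$labels), 0L)
  expect_equal(out3$report$reason, "sphericity")
})

test_that("border-touching particles are excluded when requested", {
  lab <- array(0L, c(10, 10, 6))
  lab[1:3, 4:6, 2:4] <- 1L          # touches y border
  lab[6:8, 4:6, 2:4] <- 2L          # interior but tiny
  out <- filter_particles(lab, particle_criteria())
  expect_true("border" %in% out$report$reason)
})

test_that("segmentation is deterministic and shape-consistent", {
  spec <- small_phantom_spec()
  ph <- generate_phantom_stack(spec, seed = 2)
  a <- segment(ph$stack)
  b <- segment(ph$stack)
  expect_identical(a$labels, b$labels)
  expect_equal(dim(a$labels), dim(a$scaled$voxels))
  # every survivor satisfies the criteria post hoc
  crit <- particle_criteria()
  for (id in setdiff(unique(as.vector(a$labels)), 0L)) {
    st <- particle_shape_stats(a$labels, id, a$scaled$spacing)
    expect_gte(st$volume, crit$min_volume)
    expect_lte(st$volume, crit$max_volume)
    expect_gte(st$sphericity, crit$min_sphericity)
    expect_lte(st$ellipsoid_residual, crit$max_ellipsoid_residual)
  }
})

test_that("an empty phantom yields no vesicles", {
  spec <- small_phantom_spec(n_vesicles = 0)
  ph <- generate_phantom_stack(spec, seed = 1)
  res <- segment(ph$stack)
  expect_equal(max(res$labels), 0L)
})
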