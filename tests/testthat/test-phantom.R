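test_that("phantom generation is seed-deterministic", {
  spec <- small_phantom_spec()
  a <- generate_phantom_stack(spec, seed = 11)
  b <- generate_phantom_stack(spec, seed = 11)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom_stack(spec, seed = 12)
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("ground truth matches the requested composition", {
  spec <- phantom_spec(shape = c(x = 320, y = 320, z = 100),
                       n_vesicles = 60, dcv_fraction = 0.15)
  ph <- generate_phantom_stack(spec, seed = 5)
  expect_equal(nrow(ph$truth), 60L)
  expect_true(all(ph$truth$class %in% c("CCV", "DCV")))
  # class draw is the seeded binomial: reproducible
  ph2 <- generate_phantom_stack(spec, seed = 5)
  expect_identical(ph$truth$class, ph2$truth$class)
  expect_true(all(ph$truth$r_inner > 0))
  expect_true(all(ph$truth$distAZ >= 0))
})

test_that("dense cores are darker than clear-core lumina in stored polarity", {
  spec <- small_phantom_spec(dcv_fraction = 0.5)
  ph <- generate_phantom_stack(spec, seed = 3)
  tr <- ph$truth
  grab <- function(row) {
    # sample the central voxel of the vesicle
    ph$stack$voxels[round(row$y) + 1, round(row$x) + 1,
                    round(row$z / spec$spacing[["z"]]) + 1]
  }
  dcv_core <- vapply(which(tr$class == "DCV"), function(i) grab(tr[i, ]),
                     numeric(1))
  ccv_lumen <- vapply(which(tr$class == "CCV"), function(i) grab(tr[i, ]),
                      numeric(1))
  expect_true(mean(dcv_core) < mean(ccv_lumen))
})

test_that("DCV centres are biased away from the active zone", {
  spec <- phantom_spec(shape = c(x = 320, y = 320, z = 100),
                       n_vesicles = 50, dcv_fraction = 0.4)
  d_ccv <- c(); d_dcv <- c()
  for (seed in 1:3) {
    tr <- generate_phantom_stack(spec, seed = seed)$truth
    d_ccv <- c(d_ccv, tr$distAZ[tr$class == "CCV"])
    d_dcv <- c(d_dcv, tr$distAZ[tr$class == "DCV"])
  }
  expect_gt(median(d_dcv), median(d_ccv))
})

test_that("empirical DCV fraction converges to the nominal fraction", {
  spec <- phantom_spec(n_vesicles = 80, dcv_fraction = 0.2,
                       dcv_distance_bias = 0)
  fr <- vapply(1:5, function(seed) {
    tr <- generate_phantom_stack(spec, seed = seed,
                                 max_tries = 10000L)$truth
    mean(tr$class == "DCV")
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.2), 3 * sqrt(0.2 * 0.8 / (80 * 5)))
})

test_that("sampled feature tables reproduce their class parameters", {
  tab <- sample_feature_table(n = 10000, dcv_fraction = 0.3, seed = 9)
  expect_identical(tab, sample_feature_table(n = 10000, dcv_fraction = 0.3,
                                             seed = 9))
  p <- default_class_params()
  for (cl in c("CCV", "DCV")) {
    sel <- tab$label == (if (cl == "DCV") "D" else "C")
    n <- sum(sel)
    for (f in c("gv", "GVSD", "distAZ")) {
      se <- p[[cl]][[f]][2] / sqrt(n)
      expect_lt(abs(mean(tab[[f]][sel]) - p[[cl]][[f]][1]), 4 * se)
    }
    # r is truncated at 0 but far from it, so the mean is essentially exact
    expect_lt(abs(mean(tab$r[sel]) - p[[cl]]$r[1]), 4 * p[[cl]]$r[2] / sqrt(n))
  }
  all_c <- sample_feature_table(n = 50, dcv_fraction = 0, seed = 2)
  expect_true(all(all_c$label == "C"))
  bad <- default_class_params()
  bad$CCV$r[2] <- -1
  expect_error(sample_feature_table(bad, n = 10, seed = 1), "scale")
})

test_that("planted geometry is recovered by the feature measurements", {
  # noiseless phantom; compare planted centres/radii to measurements made
  # directly on the rasterized spheres (ideal masks, no segmentation)
  spec <- small_phantom_spec(n_vesicles = 6, min_gap_nm = 14)
  ph <- generate_phantom_stack(spec, seed = 8)
  st <- ph$stack
  # build the ideal label map from ground truth
  d <- dim(st$voxels)
  lab <- array(0L, d)
  for (i in seq_len(nrow(ph$truth))) {
    tr <- ph$truth[i, ]
    ro <- tr$r_inner + spec$membrane_nm
    ys <- which(abs((seq_len(d[1]) - 1) * 1 - tr$y) <= ro)
    xs <- which(abs((seq_len(d[2]) - 1) * 1 - tr$x) <= ro)
    zs <- which(abs((seq_len(d[3]) - 1) * 2 - tr$z) <= ro)
    for (z in zs) for (x in xs) for (y in ys) {
      dd <- sqrt(((y - 1) - tr$y)^2 + ((x - 1) - tr$x)^2 + (2 * (z - 1) - tr$z)^2)
      if (dd <= ro) lab[y, x, z] <- i
    }
  }
  feats <- extract_feature_table(st, lab, spec$az)
  m <- match_to_truth(feats, ph$truth)
  expect_true(all(m$dist <= 1))
  r_err <- feats$r - ph$truth$r_inner[m$planted]
  expect_true(all(abs(r_err[ph$truth$r_inner[m$planted] >= 5]) <= 1))
  expect_true(all(abs(feats$distAZ - ph$truth$distAZ[m$planted]) <= 1.5))
})
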