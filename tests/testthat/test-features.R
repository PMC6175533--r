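test_that("inner radius of a digital ball matches brute-force enumeration", {
  ball <- digital_ball(8)
  lab <- array(0L, dim(ball)); lab[ball] <- 1L
  r <- inner_radius(lab, 1L, spacing = c(1, 1, 1), membrane_nm = 0)

  # oracle: enumerate surface voxels (6-neighbour outside) and average the
  # Euclidean distance to the region centroid
  idx <- which(ball, arr.ind = TRUE)
  ctr <- colMeans(idx)
  d <- dim(ball)
  dists <- c()
  for (k in seq_len(nrow(idx))) {
    y <- idx[k, 1]; x <- idx[k, 2]; z <- idx[k, 3]
    on_surface <- FALSE
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      yy <- y + o[1]; xx <- x + o[2]; zz <- z + o[3]
      if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3] ||
          !ball[yy, xx, zz]) { on_surface <- TRUE; break }
    }
    if (on_surface) dists <- c(dists, sqrt(sum((c(y, x, z) - ctr)^2)))
  }
  expect_equal(as.numeric(r), mean(dists), tolerance = 1e-12)

  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_equal(as.numeric(inner_radius(single, 1L, membrane_nm = 0)), 0)
})

test_that("erosion that empties the region falls back to the full mask", {
  small <- array(0L, c(5, 5, 5)); small[2:3, 2:3, 2:3] <- 1L
  r <- inner_radius(small, 1L, spacing = c(1, 1, 1), membrane_nm = 10)
  expect_true(attr(r, "flagged"))
})

test_that("mean gray value averages the eroded region in either polarity", {
  ball <- digital_ball(6)
  lab <- array(0L, dim(ball)); lab[ball] <- 1L
  v <- array(0, dim(ball)); v[ball] <- 100
  st <- tomogram_stack(v)
  expect_equal(as.numeric(mean_gray(st, lab, 1L, membrane_nm = 0,
                                    gv_polarity = "as_stored")), 100)
  expect_equal(as.numeric(mean_gray(st, lab, 1L, membrane_nm = 0,
                                    gv_polarity = "invert")), 155)
  # symmetric split averages to the midpoint
  w <- which(ball)
  v2 <- array(0, dim(ball))
  v2[w[seq(1, length(w), 2)]] <- 90
  v2[w[seq(2, length(w), 2)]] <- 110
  half <- length(w) %/% 2
  got <- as.numeric(mean_gray(tomogram_stack(v2), lab, 1L, membrane_nm = 0,
                              gv_polarity = "as_stored"))
  expect_equal(got, mean(v2[ball]))
})

test_that("GVSD is the sample SD over the central-slice footprint", {
  lab <- array(0L, c(5, 5, 3)); lab[2, 2:3, 2] <- 1L
  v <- array(0, c(5, 5, 3)); v[2, 2, 2] <- 4; v[2, 3, 2] <- 6
  st <- tomogram_stack(v)
  # pass the volume as its own "blurred" copy to test the estimator itself
  expect_equal(as.numeric(gvsd_central_slice(st, lab, 1L, blurred = v)),
               sqrt(2), tolerance = 1e-12)
  # uniform footprint
  v[2, 2:3, 2] <- 7
  expect_equal(as.numeric(gvsd_central_slice(st, lab, 1L, blurred = v)), 0)
  # single-voxel footprint is flagged 0
  lab1 <- array(0L, c(5, 5, 3)); lab1[2, 2, 2] <- 1L
  g <- gvsd_central_slice(st, lab1, 1L, blurred = v)
  expect_equal(as.numeric(g), 0)
  expect_true(attr(g, "flagged"))
})

test_that("distance to the active zone honors anisotropic spacing", {
  expect_equal(distance_to_az(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(distance_to_az(c(1, 2, 3), c(1, 2, 3)), 0)
  # 3 slices away at 2 nm z spacing = 6 nm, already in physical units
  expect_equal(distance_to_az(c(0, 0, 0), c(0, 0, 6)), 6)
})

test_that("feature tables are invariant to label permutation and gray shifts", {
  spec <- small_phantom_spec(n_vesicles = 5, min_gap_nm = 14)
  ph <- generate_phantom_stack(spec, seed = 4)
  st <- ph$stack
  res <- segment(st)
  feats <- extract_feature_table(res$scaled, res$labels, spec$az)
  expect_gt(nrow(feats), 0)
  expect_false(any(duplicated(feats$id)))

  # permute ids: the multiset of records is unchanged
  ids <- sort(unique(res$labels[res$labels > 0]))
  perm <- rev(ids)
  relab <- res$labels
  relab[res$labels > 0] <- perm[match(res$labels[res$labels > 0], ids)]
  feats2 <- extract_feature_table(res$scaled, relab, spec$az)
  key <- function(d) d[order(d$x, d$y, d$z), c("x", "y", "z", "r", "gv",
                                               "GVSD", "distAZ")]
  a <- key(feats); b <- key(feats2)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 1e-12)

  # adding a constant shifts gv only (as-stored polarity)
  shifted <- res$scaled
  shifted$voxels <- shifted$voxels + 11
  p <- feature_params(gv_polarity = "as_stored")
  f0 <- extract_feature_table(res$scaled, res$labels, spec$az, params = p)
  f1 <- extract_feature_table(shifted, res$labels, spec$az, params = p)
  expect_equal(f1$gv, f0$gv + 11, tolerance = 1e-9)
  expect_equal(f1$r, f0$r, tolerance = 1e-12)
  expect_equal(f1$GVSD, f0$GVSD, tolerance = 1e-9)
  expect_equal(f1$distAZ, f0$distAZ, tolerance = 1e-12)
})

test_that("min-max normalization maps onto [0, 1] per tomogram", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(one <- minmax_normalize(5), "degenerate")
  expect_equal(one, 0)
  x <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(x), x)  # idempotent on [0, 1]-spanning data
  # joint vs separate normalization differ; separate is the contract
  t1 <- c(0, 10); t2 <- c(5, 20)
  expect_false(isTRUE(all.equal(minmax_normalize(c(t1, t2))[1:2],
                                minmax_normalize(t1))))
})

test_that("gv offset shifts all values only when the darkest is too light", {
  tab <- data.frame(r = 1:3, gv = c(120, 130, 135), GVSD = 1:3,
                    distAZ = 1:3)
  same <- apply_gv_offset(tab, threshold = 125)
  expect_equal(same$gv, tab$gv)      # darkest (120) already at or below
  down <- apply_gv_offset(tab, threshold = 113)
  expect_equal(down$gv, tab$gv - 7)  # darkest mapped onto the threshold
  expect_equal(attr(down, "gv_offset"), -7)
  expect_equal(diff(down$gv), diff(tab$gv))  # differences preserved
  expect_equal(apply_gv_offset(tab, NULL)$gv, tab$gv)
})

test_that("cell volume integrates polygon areas over slices", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  outlines <- rep(list(sq), 10)
  expect_equal(cell_volume(outlines, z_spacing_nm = 2), 20)
  expect_equal(cell_volume(list(NULL, NULL), z_spacing_nm = 2), 0)

  big <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  shoe <- cell_volume(list(big), z_spacing_nm = 1)
  # rasterization oracle: count unit-pixel centres inside the square
  centres <- expand.grid(x = seq(0.5, 99.5, 1), y = seq(0.5, 99.5, 1))
  raster <- nrow(centres)
  expect_lt(abs(shoe - raster) / raster, 0.05)

  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(cell_volume(list(bow), 1), "self-intersecting")
})
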