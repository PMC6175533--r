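# Vesicle segmentation: preprocessing, foreground separation, watershed
# splitting and particle filtering. Stained structures are dark (low stored
# intensity) throughout; the working gray range after preprocessing is
# [0, 255].

WORKING_MAX <- 255

#' Preprocess a tomogram for segmentation
#'
#' Rescales x/y to 1 nm/pixel by bilinear interpolation (z untouched),
#' stretches the contrast to the working range, then smooths each slice with
#' a circular mean filter (radius 3.45 px) followed by an edge-preserving
#' 2D bilateral filter.
#'
#' @param stack [tomogram_stack()]
#' @param nm_per_px x/y pixel size in nm; defaults to the stack spacing.
#' @param mean_radius mean-filter radius in px.
#' @param bilateral_sigma_s,bilateral_sigma_r spatial sigma (px) and range
#'   sigma (fraction of the working range) of the bilateral filter.
#' @return preprocessed [tomogram_stack()] at (1, 1, z) nm spacing.
#' @export
preprocess <- function(stack, nm_per_px = NULL, mean_radius = 3.45,
                       bilateral_sigma_s = 3, bilateral_sigma_r = 0.1) {
  scaled <- scale_to_1nm(stack, nm_per_px)
  v <- scaled$voxels
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1]) * WORKING_MAX
  v <- EBImage::filter2(v, disc_kernel(mean_radius), boundary = "replicate")
  v <- array(v, dim = dim(v))
  for (z in seq_len(dim(v)[3]))
    v[, , z] <- .cpp_bilateral2d(v[, , z], bilateral_sigma_s,
                                 bilateral_sigma_r * WORKING_MAX)
  tomogram_stack(v, c(1, 1, stack$spacing[["z"]]), id = stack$id)
}

#' Rescale a stack to 1 nm/pixel in x/y
#'
#' Bilinear interpolation in-plane, z untouched; new in-plane dimensions are
#' `round(old * nm_per_px)` (round half to even). Gray values are otherwise
#' left as stored: this is the "scaled duplicate" of the tomogram on which
#' features are measured.
#'
#' @inheritParams preprocess
#' @return [tomogram_stack()] at (1, 1, z) nm spacing.
#' @export
scale_to_1nm <- function(stack, nm_per_px = NULL) {
  stopifnot(inherits(stack, "tomogram_stack"))
  if (is.null(nm_per_px)) nm_per_px <- unname(stack$spacing[c("x", "y")])
  if (length(nm_per_px) == 1L) nm_per_px <- rep(nm_per_px, 2L)
  stopifnot(all(nm_per_px > 0))
  v <- stack$voxels
  d <- dim(v)
  new_ny <- as.integer(round(d[1] * nm_per_px[2]))
  new_nx <- as.integer(round(d[2] * nm_per_px[1]))
  if (new_ny != d[1] || new_nx != d[2]) {
    v <- EBImage::resize(v, w = new_ny, h = new_nx, filter = "bilinear")
    v <- array(v, dim = c(new_ny, new_nx, d[3]))
  }
  tomogram_stack(v, c(1, 1, stack$spacing[["z"]]), id = stack$id)
}

disc_kernel <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  inside <- g$dy^2 + g$dx^2 <= radius^2
  k <- matrix(as.numeric(inside), nrow = 2 * r + 1)
  k / sum(k)
}

#' Separate the (dark) foreground
#'
#' Thresholds every slice at its own mean gray value — voxels strictly
#' darker than the slice mean become foreground — then fills holes per slice
#' so vesicle lumina become solid.
#'
#' @param stack preprocessed [tomogram_stack()]
#' @return logical array of the same shape.
#' @export
binarize_foreground <- function(stack) {
  v <- stack$voxels
  d <- dim(v)
  fg <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    sl <- v[, , z]
    # degenerate (essentially constant) slices have nothing strictly darker
    # than their mean; guard against float ripple from the filters
    if (diff(range(sl)) <= 1e-6 * WORKING_MAX) next
    m <- sl < mean(sl)
    if (any(m)) m <- EBImage::fillHull(m) > 0
    fg[, , z] <- m
  }
  fg
}

#' Split touching vesicles by watershed
#'
#' A 2D watershed is run on each slice first (splitting touching
#' cross-sections); the 3D Euclidean distance transform of the split mask,
#' smoothed with a 3D Gaussian (sigma = 3.45 voxels), then seeds a 3D
#' watershed whose catchment basins become the particle labels.
#'
#' @param mask logical foreground array.
#' @param z_spacing_nm z step in nm on the 1 nm/px grid (anisotropic
#'   distances are honored by the distance transform).
#' @param sigma Gaussian smoothing sigma (voxels).
#' @return integer label array (`vesicle label map`), 0 = background.
#' @export
split_watershed <- function(mask, z_spacing_nm = 1, sigma = 3.45) {
  d <- dim(mask)
  if (!any(mask)) return(array(0L, d))
  split <- mask
  for (z in seq_len(d[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    lab2 <- slice_watershed(sl, sigma)
    split[, , z] <- sl & !boundary_2d(lab2)
  }
  edt <- .cpp_edt3d(split, dim(split), c(1, 1, z_spacing_nm))
  sm <- gaussian_blur3d(edt, sigma)
  seeds <- .cpp_regmax3d(sm, split, d, 26L)
  lab <- .cpp_watershed3d(sm, seeds, split, d, 26L)
  relabel_consecutive(lab)
}

# 2D watershed of one binary slice: distance transform, smoothing, regional
# maxima seeds, priority flood (8-connectivity).
slice_watershed <- function(sl, sigma) {
  d2 <- c(dim(sl), 1L)
  m <- array(sl, d2)
  edt <- .cpp_edt3d(m, d2, c(1, 1, 1e6))
  sm <- array(EBImage::gblur(array(edt, dim(sl)), sigma = sigma,
                             boundary = "replicate"), d2)
  seeds <- .cpp_regmax3d(sm, m, d2, 26L)
  array(.cpp_watershed3d(sm, seeds, m, d2, 26L), dim(sl))
}

# voxels whose 4-neighborhood contains a different positive label
boundary_2d <- function(lab) {
  b <- array(FALSE, dim(lab))
  shift <- function(m, dy, dx) {
    out <- m * 0L
    ny <- nrow(m); nx <- ncol(m)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift(lab, o[1], o[2])
    b <- b | (lab > 0 & nb > 0 & nb != lab)
  }
  b
}

gaussian_blur3d <- function(a, sigma) {
  k <- gauss_kernel(sigma)
  a <- convolve_axis(a, k, 1L)
  a <- convolve_axis(a, k, 2L)
  convolve_axis(a, k, 3L)
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0L) return(array(0L, dim(lab)))
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Default particle filter criteria
#'
#' Volume bounds in nm^3, a minimum sphericity and a maximum residual of the
#' moment-matched ellipsoid fit. These defaults are this package's own
#' working values (the published workflow does not restate its thresholds)
#' and are meant to retain sphere-like particles of vesicle size: a voxelized
#' ball scores a sphericity near 1 under the Cauchy-corrected surface
#' estimate used here, an elongated rod well below 0.8.
#'
#' @param min_volume,max_volume retained volume range (nm^3).
#' @param min_sphericity minimum `pi^(1/3) (6V)^(2/3) / A`.
#' @param max_ellipsoid_residual maximum symmetric-difference fraction
#'   between a particle and its moment-matched ellipsoid.
#' @param exclude_border remove particles touching the stack border
#'   (truncated vesicles and structures extending beyond the field, such as
#'   the plasma membrane, are not usable vesicle candidates).
#' @return list of criteria.
#' @export
particle_criteria <- function(min_volume = 300, max_volume = 300000,
                              min_sphericity = 0.8,
                              max_ellipsoid_residual = 0.15,
                              exclude_border = TRUE) {
  stopifnot(min_volume <= max_volume, min_sphericity > 0,
            min_sphericity <= 1, max_ellipsoid_residual >= 0)
  list(min_volume = min_volume, max_volume = max_volume,
       min_sphericity = min_sphericity,
       max_ellipsoid_residual = max_ellipsoid_residual,
       exclude_border = isTRUE(exclude_border))
}

#' Remove particles that do not look like vesicles
#'
#' Particles outside the volume range, below the sphericity threshold
#' (`pi^(1/3) (6V)^(2/3) / A`, with the surface area `A` estimated from
#' boundary faces with the Cauchy 2/3 correction so that spheres score ~1),
#' or with a large residual against their moment-matched ellipsoid are
#' removed; survivors are relabeled consecutively.
#'
#' @param labels integer label array.
#' @param criteria [particle_criteria()]
#' @param spacing voxel spacing (x, y, z) nm.
#' @return list: `labels` (filtered, consecutive) and `report` (data.frame
#'   of removed ids with the failing criterion and measured values).
#' @export
filter_particles <- function(labels, criteria = particle_criteria(),
                             spacing = c(1, 1, 1)) {
  ids <- sort(unique(labels[labels > 0]))
  voxel_vol <- prod(spacing)
  nvox <- tabulate(labels[labels > 0], nbins = max(labels, 1L))
  d <- dim(labels)
  border_ids <- if (isTRUE(criteria$exclude_border)) unique(c(
    labels[c(1, d[1]), , ], labels[, c(1, d[2]), ], labels[, , c(1, d[3])]))
    else integer(0)
  keep <- logical(length(ids))
  rep_rows <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    vol <- nvox[id] * voxel_vol
    if (id %in% border_ids) {
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(id = id, reason = "border", volume = vol,
                   sphericity = NA_real_, ellipsoid_residual = NA_real_)
      next
    }
    # cheap volume gate first; shape statistics only for plausible particles
    if (vol < criteria$min_volume || vol > criteria$max_volume) {
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(id = id, reason = "volume", volume = vol,
                   sphericity = NA_real_, ellipsoid_residual = NA_real_)
      next
    }
    st <- particle_shape_stats(labels, id, spacing)
    reason <- NULL
    if (st$sphericity < criteria$min_sphericity)
      reason <- "sphericity"
    else if (st$ellipsoid_residual > criteria$max_ellipsoid_residual)
      reason <- "ellipsoid_fit"
    if (is.null(reason)) keep[k] <- TRUE
    else rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(id = id, reason = reason, volume = st$volume,
                   sphericity = st$sphericity,
                   ellipsoid_residual = st$ellipsoid_residual)
  }
  out <- labels
  out[!(labels %in% ids[keep])] <- 0L
  report <- if (length(rep_rows)) do.call(rbind, rep_rows)
            else data.frame(id = integer(0), reason = character(0),
                            volume = numeric(0), sphericity = numeric(0),
                            ellipsoid_residual = numeric(0))
  list(labels = relabel_consecutive(out), report = report)
}

#' Shape statistics of one labeled particle
#'
#' Volume (nm^3), surface area (boundary faces, Cauchy-corrected by 2/3 so a
#' voxelized sphere scores its continuum area), sphericity and the residual
#' of the moment-matched ellipsoid fit (symmetric-difference fraction),
#' computed inside the particle's bounding box.
#'
#' @param labels integer label array.
#' @param id particle id.
#' @param spacing voxel spacing (x, y, z) nm.
#' @return list: `volume`, `area`, `sphericity`, `ellipsoid_residual`,
#'   `n_voxels`.
#' @export
particle_shape_stats <- function(labels, id, spacing = c(1, 1, 1)) {
  w <- which(labels == id, arr.ind = TRUE)
  sub <- crop_box(labels, w)
  m <- sub$arr == id
  sx <- spacing[1]; sy <- spacing[2]; sz <- spacing[3]
  nvox <- sum(m)
  volume <- nvox * sx * sy * sz
  faces <- boundary_faces(m)
  # exact face areas, corrected by 2/3 (Cauchy-Crofton) for voxelization bias
  area <- (2 / 3) * (faces$yz * sy * sz + faces$xz * sx * sz +
                     faces$xy * sx * sy)
  sphericity <- pi^(1 / 3) * (6 * volume)^(2 / 3) / area
  # moment-matched ellipsoid (solid ellipsoid has covariance diag(a^2/5))
  idx <- which(m, arr.ind = TRUE)
  pts <- cbind((idx[, 2] - 1) * sx, (idx[, 1] - 1) * sy, (idx[, 3] - 1) * sz)
  ctr <- colMeans(pts)
  resid <- 1
  if (nvox >= 4) {
    cv <- stats::cov(pts) * (nvox - 1) / nvox
    eg <- eigen(cv, symmetric = TRUE)
    ax <- sqrt(pmax(5 * eg$values, (min(sx, sy, sz) / 2)^2))
    rot <- eg$vectors
    rel <- sweep(pts, 2, ctr) %*% rot
    inside <- rowSums(sweep(rel, 2, ax, "/")^2) <= 1
    v_ell <- 4 / 3 * pi * prod(ax)
    inter <- sum(inside) * sx * sy * sz
    union <- volume + v_ell - inter
    resid <- if (union > 0) 1 - inter / union else 0
  } else resid <- 0
  list(volume = volume, area = area, sphericity = sphericity,
       ellipsoid_residual = resid, n_voxels = nvox)
}

crop_box <- function(arr, w, pad = 1L) {
  d <- dim(arr)
  lo <- pmax(apply(w, 2, min) - pad, 1L)
  hi <- pmin(apply(w, 2, max) + pad, d)
  list(arr = arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       lo = lo, hi = hi)
}

# boundary face counts of a binary array, per face orientation
boundary_faces <- function(m) {
  d <- dim(m)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  count_dir <- function(dy, dx, dz) {
    a <- padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    b <- padded[2:(d[1] + 1) + dy, 2:(d[2] + 1) + dx, 2:(d[3] + 1) + dz]
    sum(a & !b)
  }
  list(yz = count_dir(0, 1, 0) + count_dir(0, -1, 0),   # normal along x
       xz = count_dir(1, 0, 0) + count_dir(-1, 0, 0),   # normal along y
       xy = count_dir(0, 0, 1) + count_dir(0, 0, -1))   # normal along z
}

#' Segment vesicles in a tomogram
#'
#' Runs the full registration workflow — preprocessing, foreground
#' separation, watershed splitting, particle filtering — and returns the
#' vesicle label map together with the scaled stack, the two inputs the
#' classification stage expects.
#'
#' @param stack raw [tomogram_stack()]
#' @param nm_per_px x/y pixel size in nm (defaults to the stack spacing).
#' @param criteria [particle_criteria()]
#' @param ... passed to [preprocess()].
#' @return list: `labels` (integer array), `scaled` (the scaled but
#'   otherwise unfiltered duplicate [tomogram_stack()] at 1 nm/px, on which
#'   features are measured), `report` (particle removal report).
#' @export
segment <- function(stack, nm_per_px = NULL, criteria = particle_criteria(),
                    ...) {
  pre <- preprocess(stack, nm_per_px = nm_per_px, ...)
  fg <- binarize_foreground(pre)
  lab <- split_watershed(fg, z_spacing_nm = pre$spacing[["z"]])
  flt <- filter_particles(lab, criteria, spacing = pre$spacing)
  list(labels = flt$labels, scaled = scale_to_1nm(stack, nm_per_px),
       report = flt$report)
}
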