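# Per-vesicle image features: inner radius r, mean gray value gv,
# central-slice gray-value SD (GVSD), distance to the active zone (distAZ);
# plus the per-tomogram normalizations used downstream.
#
# gv is measured in display polarity (electron-dense = dark = numerically
# low), the orientation consistent with the signs of the shipped
# classifier's weights: clear-core vesicles have bright lumina and hence a
# higher gv than dense-core vesicles. An `invert` option (gv becomes
# working_max - stored value) covers stacks stored density-oriented.

#' Feature extraction parameters
#'
#' @param membrane_nm membrane thickness excluded (by morphological erosion)
#'   before measuring `r` and `gv`; 4.5 nm per side, consistent with the
#'   +9 nm outer-diameter correction.
#' @param blur_sigma Gaussian blur sigma (voxels) applied before GVSD to
#'   enhance the contribution of dark membrane voxels.
#' @param gv_polarity `"as_stored"` (default) measures gv directly on the
#'   stack, which is assumed to be in EM display polarity (dark = low), so
#'   clear-core vesicles score high; `"invert"` (gv becomes `255 - value`)
#'   covers stacks stored with electron density as high values.
#' @return list of parameters.
#' @export
feature_params <- function(membrane_nm = 4.5, blur_sigma = 3.45,
                           gv_polarity = c("as_stored", "invert")) {
  gv_polarity <- match.arg(gv_polarity)
  stopifnot(membrane_nm >= 0, blur_sigma >= 0)
  list(membrane_nm = membrane_nm, blur_sigma = blur_sigma,
       gv_polarity = gv_polarity)
}

# Inner region of one vesicle: its mask eroded by a ball of radius
# membrane_nm (physical units). Falls back to the full mask (flagged) if the
# erosion empties the region.
inner_region <- function(labels, id, spacing, membrane_nm) {
  w <- which(labels == id, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("no vesicle with id ", id, call. = FALSE)
  pad <- ceiling(membrane_nm / min(spacing)) + 1L
  box <- crop_box(labels, w, pad = pad)
  m <- box$arr == id
  flagged <- FALSE
  if (membrane_nm > 0) {
    edt <- .cpp_edt3d(m, dim(m), spacing[c(2, 1, 3)])  # (y, x, z) steps
    # the EDT measures to background voxel *centres*, which sit about half a
    # voxel beyond the true surface; erode to depth membrane_nm past it
    inner <- edt >= membrane_nm + 0.5 * min(spacing)
    if (!any(inner)) {
      inner <- m
      flagged <- TRUE
    }
  } else inner <- m
  list(mask = inner, full = m, lo = box$lo, flagged = flagged)
}

# physical (x, y, z) nm coordinates of TRUE voxels of a cropped mask
mask_coords <- function(mask, lo, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = (idx[, 2] + lo[2] - 2) * spacing[1],
        y = (idx[, 1] + lo[1] - 2) * spacing[2],
        z = (idx[, 3] + lo[3] - 2) * spacing[3])
}

# surface voxels: TRUE voxels with a 6-neighbour outside the region
surface_mask <- function(m) {
  d <- dim(m)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- padded[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        padded[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        padded[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        padded[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        padded[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        padded[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb
}

#' Inner radius of a vesicle
#'
#' Mean Euclidean distance (nm) from the centroid of the membrane-excluded
#' (eroded) region to its surface voxels. A single-voxel region has radius 0.
#'
#' @param labels integer label array.
#' @param id vesicle id.
#' @param spacing voxel spacing (x, y, z) nm.
#' @param membrane_nm erosion depth (nm).
#' @return radius in nm; attribute `flagged` is TRUE when the erosion
#'   emptied the region and the full mask was used instead.
#' @export
inner_radius <- function(labels, id, spacing = c(1, 1, 1),
                         membrane_nm = 4.5) {
  reg <- inner_region(labels, id, spacing, membrane_nm)
  pts <- mask_coords(reg$mask, reg$lo, spacing)
  ctr <- colMeans(pts)
  surf <- surface_mask(reg$mask)
  spts <- mask_coords(surf, reg$lo, spacing)
  r <- if (nrow(spts) == 0L) 0 else
    mean(sqrt(rowSums(sweep(spts, 2, ctr)^2)))
  if (nrow(pts) == 1L) r <- 0
  structure(r, flagged = reg$flagged)
}

#' Mean gray value of a vesicle
#'
#' Mean over the 3D membrane-excluded region, in display polarity by
#' default (dark = low, so clear-core lumina score high). With
#' `gv_polarity = "invert"` the returned value is `255 - mean(stored)`.
#'
#' @inheritParams inner_radius
#' @param stack [tomogram_stack()] aligned with `labels`.
#' @param gv_polarity see [feature_params()].
#' @return mean gray value (intensity units).
#' @export
mean_gray <- function(stack, labels, id, spacing = stack$spacing,
                      membrane_nm = 4.5, gv_polarity = "as_stored") {
  reg <- inner_region(labels, id, spacing, membrane_nm)
  sub <- stack$voxels[reg$lo[1]:(reg$lo[1] + dim(reg$mask)[1] - 1),
                      reg$lo[2]:(reg$lo[2] + dim(reg$mask)[2] - 1),
                      reg$lo[3]:(reg$lo[3] + dim(reg$mask)[3] - 1),
                      drop = FALSE]
  v <- mean(sub[reg$mask])
  if (gv_polarity == "invert") v <- WORKING_MAX - v
  structure(v, flagged = reg$flagged)
}

#' Gray-value SD on the central slice
#'
#' Sample standard deviation (n - 1) of gray values over the vesicle's full
#' (non-eroded) 2D footprint on the z-slice through its centroid, computed
#' on a Gaussian-blurred copy of the volume (blurred slice by slice, as a
#' stack blur enhances the contribution of dark membrane pixels without
#' mixing across the anisotropic z axis). Footprints smaller than 2 voxels
#' yield 0 (flagged). GVSD is polarity invariant.
#'
#' @inheritParams mean_gray
#' @param blurred optional pre-blurred volume (array) to avoid re-blurring
#'   per vesicle.
#' @param blur_sigma blur sigma in voxels, used when `blurred` is NULL.
#' @return GVSD (intensity units).
#' @export
gvsd_central_slice <- function(stack, labels, id, blurred = NULL,
                               blur_sigma = 3.45) {
  if (is.null(blurred))
    blurred <- blur_slices(stack$voxels, blur_sigma)
  w <- which(labels == id, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("no vesicle with id ", id, call. = FALSE)
  zc <- round(mean(w[, 3]))
  foot <- w[w[, 3] == zc, , drop = FALSE]
  if (nrow(foot) < 2L)
    return(structure(0, flagged = TRUE))
  vals <- blurred[cbind(foot[, 1], foot[, 2], zc)]
  structure(stats::sd(vals), flagged = FALSE)
}

#' 3D distance to the active zone
#'
#' Euclidean distance in nm between a vesicle centre and the annotated
#' active-zone point, honoring anisotropic spacing (both points in nm).
#'
#' @param center numeric (x, y, z) in nm.
#' @param az numeric (x, y, z) in nm.
#' @return distance in nm.
#' @export
distance_to_az <- function(center, az) {
  sqrt(sum((as.numeric(center) - as.numeric(az))^2))
}

#' Extract the full per-vesicle feature table
#'
#' One record per labeled vesicle: centre (nm, intensity-unweighted centroid
#' of the full mask, 0-based voxel indices times spacing), `r`, `gv`,
#' `GVSD`, `distAZ`.
#'
#' @param stack scaled [tomogram_stack()] aligned with `labels`.
#' @param labels integer vesicle label map.
#' @param az active-zone point, (x, y, z) nm.
#' @param params [feature_params()]
#' @return data.frame: `id`, `x`, `y`, `z`, `r`, `gv`, `GVSD`, `distAZ`,
#'   `flagged`; attribute `source_id` carries the stack id.
#' @export
extract_feature_table <- function(stack, labels, az,
                                  params = feature_params()) {
  stopifnot(all(dim(stack$voxels) == dim(labels)))
  ids <- sort(unique(labels[labels > 0]))
  sp <- stack$spacing
  blurred <- if (length(ids)) blur_slices(stack$voxels, params$blur_sigma)
             else NULL
  rows <- lapply(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    ctr <- c(x = (mean(w[, 2]) - 1) * sp[["x"]],
             y = (mean(w[, 1]) - 1) * sp[["y"]],
             z = (mean(w[, 3]) - 1) * sp[["z"]])
    r <- inner_radius(labels, id, sp, params$membrane_nm)
    gv <- mean_gray(stack, labels, id, sp, params$membrane_nm,
                    params$gv_polarity)
    gvsd <- gvsd_central_slice(stack, labels, id, blurred = blurred)
    data.frame(id = id, x = ctr[["x"]], y = ctr[["y"]], z = ctr[["z"]],
               r = as.numeric(r), gv = as.numeric(gv),
               GVSD = as.numeric(gvsd),
               distAZ = distance_to_az(ctr, az),
               flagged = isTRUE(attr(r, "flagged")) ||
                 isTRUE(attr(gv, "flagged")) || isTRUE(attr(gvsd, "flagged")))
  })
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                         z = numeric(0), r = numeric(0), gv = numeric(0),
                         GVSD = numeric(0), distAZ = numeric(0),
                         flagged = logical(0))
  rownames(tab) <- NULL
  attr(tab, "source_id") <- stack$id
  tab
}

#' Min-max normalization (per tomogram)
#'
#' Maps values to `[0, 1]` by subtracting the minimum and dividing by the
#' range. Applied independently per tomogram for gv and distAZ comparisons.
#' If all values are equal the output is all zeros, with a warning.
#'
#' @param x numeric vector (one tomogram's values).
#' @return normalized vector.
#' @export
minmax_normalize <- function(x) {
  stopifnot(length(x) >= 1)
  rng <- range(x)
  if (rng[2] == rng[1]) {
    warning("degenerate tomogram: max equals min, all values mapped to 0")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Shift gv so the darkest vesicle sits at a reference threshold
#'
#' Brightness adaptation between tomograms: in display polarity the darkest
#' vesicle has the lowest gv. If that vesicle is lighter than `threshold`
#' (its gv is above it), every gv is shifted by the constant that maps the
#' darkest vesicle onto the threshold; otherwise the table is returned
#' unchanged. With `threshold = NULL` or `NA` no offset is applied.
#'
#' @param table feature table with a `gv` column.
#' @param threshold reference gv level.
#' @return table with adjusted `gv`; attribute `gv_offset` records the shift.
#' @export
apply_gv_offset <- function(table, threshold = NULL) {
  if (is.null(threshold) || is.na(threshold) || nrow(table) == 0L) {
    attr(table, "gv_offset") <- 0
    return(table)
  }
  darkest <- min(table$gv)
  shift <- if (darkest > threshold) threshold - darkest else 0
  table$gv <- table$gv + shift
  attr(table, "gv_offset") <- shift
  table
}

#' Analyzed cell volume from per-slice outlines
#'
#' Sum over slices of polygon area (shoelace) times z spacing. Slices
#' without an outline contribute nothing.
#'
#' @param outlines list (one entry per slice, `NULL` allowed) of n x 2
#'   matrices of polygon vertices (x, y) in nm.
#' @param z_spacing_nm z step in nm.
#' @return volume in nm^3.
#' @export
cell_volume <- function(outlines, z_spacing_nm) {
  stopifnot(z_spacing_nm > 0)
  areas <- vapply(outlines, function(p) {
    if (is.null(p) || nrow(p) < 3L) return(0)
    if (polygon_self_intersects(p))
      stop("self-intersecting outline polygon", call. = FALSE)
    shoelace_area(p)
  }, numeric(1))
  sum(areas) * z_spacing_nm
}

shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # shares the closing vertex
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

# per-slice (2D) Gaussian blur of a volume
blur_slices <- function(a, sigma) {
  k <- gauss_kernel(sigma)
  a <- convolve_axis(a, k, 1L)
  convolve_axis(a, k, 2L)
}

segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) -
    (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}
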