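# Vesicle-pool summaries: class ratios, geometric conversions, group
# comparisons and distance distributions.

#' Dense-core vesicle percentage
#'
#' `100 * n_dcv / n_total`, rounded half away from zero to the requested
#' number of decimals (whole percents for count-table style reporting, one
#' decimal for small fractions).
#'
#' @param n_dcv,n_total counts, `0 <= n_dcv <= n_total`, `n_total > 0`.
#' @param digits decimals of the reported percentage.
#' @return percentage.
#' @export
dcv_ratio <- function(n_dcv, n_total, digits = 0) {
  stopifnot(n_total > 0, n_dcv >= 0, n_dcv <= n_total)
  round_half_away(100 * n_dcv / n_total, digits)
}

round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Inner and estimated outer diameter from the inner radius
#'
#' The measured inner radius is doubled to give the inner diameter and
#' increased by 9 nm (4.5 nm membrane per side) for the estimated outer
#' diameter.
#'
#' @param r_inner_nm inner radius (nm), non-negative.
#' @return named vector `c(inner, outer)` in nm.
#' @export
diameter_conversion <- function(r_inner_nm) {
  if (any(r_inner_nm < 0)) stop("radius must be non-negative", call. = FALSE)
  cbind(inner = 2 * r_inner_nm, outer = 2 * r_inner_nm + 9)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For groups of at most 8 without ties the exact
#' null distribution is used; otherwise the normal approximation with tie
#' correction. `U` is the number of pairs where a value of `a` exceeds one
#' of `b` (ties counting 1/2).
#'
#' @param a,b numeric samples (non-empty).
#' @return list: `U` (statistic of group `a`), `p` (two-sided p-value).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  has_ties <- any(duplicated(c(a, b)))
  exact <- max(length(a), length(b)) <= 8 && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = !exact))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Empirical CDF and kernel density of distances
#'
#' The kernel density uses a Gaussian kernel with bandwidth
#' `bandwidth_factor * max(values)` (default factor 0.07); the empirical
#' CDF reaches 1 at the maximum.
#'
#' @param values distances (>= 2 values).
#' @param bandwidth_factor multiplied by the data maximum to give the
#'   kernel SD.
#' @param n grid points of the density estimate.
#' @return list: `cdf` (function), `kde` (data.frame `x`, `y`),
#'   `bandwidth`.
#' @export
distance_distributions <- function(values, bandwidth_factor = 0.07,
                                   n = 512) {
  if (length(values) < 2)
    stop("need at least 2 values", call. = FALSE)
  bw <- bandwidth_factor * max(values)
  if (bw <= 0) stop("bandwidth must be positive", call. = FALSE)
  kde <- stats::density(values, bw = bw, kernel = "gaussian", n = n,
                        from = min(values) - 4 * bw,
                        to = max(values) + 4 * bw)
  list(cdf = stats::ecdf(values),
       kde = data.frame(x = kde$x, y = kde$y),
       bandwidth = bw)
}

#' Overall cell-size change across a stack
#'
#' Compares the x and y extents of the cell outline on the first and last
#' slice and adds the two absolute differences.
#'
#' @param first_extent,last_extent `c(x, y)` extents in nm.
#' @return change in nm.
#' @export
cell_size_change <- function(first_extent, last_extent) {
  stopifnot(all(first_extent > 0), all(last_extent > 0))
  sum(abs(first_extent - last_extent))
}

#' Per-group feature summaries with pairwise tests
#'
#' Summarizes `r`, normalized `gv`, normalized `distAZ` and `GVSD` per
#' state x class group and runs pairwise Mann-Whitney tests between classes
#' within each state (and between states within each class), with
#' significance stars at 0.05 / 0.01 / 0.001. gv and distAZ are min-max
#' normalized per tomogram before pooling.
#'
#' @param tables named list of classified tables (columns `r`, `gv`,
#'   `GVSD`, `distAZ`, `class`; one table per tomogram).
#' @param states character vector, one state label per table (recycled if
#'   length 1).
#' @param bonferroni apply Bonferroni correction across the emitted tests.
#' @return list: `summary` (data.frame of group n / median / mean / sd per
#'   feature), `tests` (data.frame of pairwise comparisons).
#' @export
summarize_groups <- function(tables, states = "all", bonferroni = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  states <- rep_len(states, length(tables))
  rows <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    stopifnot(all(c("r", "gv", "GVSD", "distAZ", "class") %in% names(tab)))
    if (nrow(tab) == 0) return(NULL)
    tab$gv_norm <- minmax_normalize(tab$gv)
    tab$distAZ_norm <- minmax_normalize(tab$distAZ)
    tab$state <- states[i]
    tab[, c("state", "class", "r", "gv_norm", "distAZ_norm", "GVSD")]
  })
  pooled <- do.call(rbind, rows)
  feats <- c("r", "gv_norm", "distAZ_norm", "GVSD")
  groups <- split(pooled, list(pooled$state, pooled$class), drop = TRUE)
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    gd <- groups[[g]]
    out <- data.frame(state = gd$state[1], class = gd$class[1], n = nrow(gd))
    for (f in feats) {
      out[[paste0(f, "_median")]] <- median(gd[[f]])
      out[[paste0(f, "_mean")]] <- mean(gd[[f]])
      out[[paste0(f, "_sd")]] <- if (nrow(gd) > 1) sd(gd[[f]]) else NA_real_
    }
    out
  }))
  rownames(summary) <- NULL
  tests <- list()
  pair_test <- function(d1, d2, what) {
    for (f in feats) {
      mw <- mann_whitney_u(d1[[f]], d2[[f]])
      tests[[length(tests) + 1L]] <<- data.frame(
        comparison = what, feature = f, U = mw$U, p = mw$p)
    }
  }
  for (st in unique(pooled$state)) {
    d <- pooled[pooled$state == st, ]
    if (all(c("CCV", "DCV") %in% d$class))
      pair_test(d[d$class == "CCV", ], d[d$class == "DCV", ],
                paste0(st, ": CCV vs DCV"))
  }
  sts <- unique(pooled$state)
  if (length(sts) == 2) {
    for (cl in intersect(unique(pooled$class), c("CCV", "DCV"))) {
      d1 <- pooled[pooled$state == sts[1] & pooled$class == cl, ]
      d2 <- pooled[pooled$state == sts[2] & pooled$class == cl, ]
      if (nrow(d1) && nrow(d2))
        pair_test(d1, d2, paste0(cl, ": ", sts[1], " vs ", sts[2]))
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests)
           else data.frame(comparison = character(0), feature = character(0),
                           U = numeric(0), p = numeric(0))
  if (bonferroni && nrow(tests)) tests$p <- pmin(tests$p * nrow(tests), 1)
  tests$stars <- ifelse(tests$p < 0.001, "***",
                   ifelse(tests$p < 0.01, "**",
                     ifelse(tests$p < 0.05, "*", "n.s.")))
  list(summary = summary, tests = tests)
}
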