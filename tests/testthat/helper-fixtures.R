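# Shared fixture builders. Everything is generated in code; no binary data.

# digital ball: TRUE where voxel centre within radius r of the centre voxel
digital_ball <- function(r, pad = 2L) {
  n <- 2L * (ceiling(r) + pad) + 1L
  c0 <- (n + 1) / 2
  idx <- expand.grid(y = 1:n, x = 1:n, z = 1:n)
  inside <- (idx$y - c0)^2 + (idx$x - c0)^2 + (idx$z - c0)^2 <= r^2
  array(inside, dim = c(n, n, n))
}

# small, fast phantom for pipeline-level tests
small_phantom_spec <- function(n_vesicles = 8, min_gap_nm = 8, ...) {
  phantom_spec(shape = c(x = 200, y = 200, z = 50),
               spacing = c(x = 1, y = 1, z = 2),
               n_vesicles = n_vesicles, min_gap_nm = min_gap_nm, ...)
}

# the well-separated 20-vesicle phantom used for recovery checks
recovery_phantom_spec <- function(...) {
  phantom_spec(shape = c(x = 280, y = 280, z = 70),
               spacing = c(x = 1, y = 1, z = 2),
               n_vesicles = 20, min_gap_nm = 12, ...)
}

# match detected feature records to planted ground truth by nearest centre;
# returns data.frame with planted index and centre distance per detection
match_to_truth <- function(feats, truth) {
  if (nrow(feats) == 0)
    return(data.frame(planted = integer(0), dist = numeric(0)))
  out <- t(vapply(seq_len(nrow(feats)), function(i) {
    d <- sqrt((truth$x - feats$x[i])^2 + (truth$y - feats$y[i])^2 +
              (truth$z - feats$z[i])^2)
    c(which.min(d), min(d))
  }, numeric(2)))
  data.frame(planted = out[, 1], dist = out[, 2])
}

# brute-force confusion counting (oracle for compute_metrics), DCV = -1
oracle_confusion <- function(truth, pred) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == -1 && pred[i] == -1) tp <- tp + 1
    if (truth[i] == 1 && pred[i] == -1) fp <- fp + 1
    if (truth[i] == -1 && pred[i] == 1) fn <- fn + 1
    if (truth[i] == 1 && pred[i] == 1) tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# exhaustive Mann-Whitney oracle: U by pairwise counting, exact two-sided p
# by enumerating all group assignments
oracle_mwu <- function(a, b) {
  U <- 0
  for (x in a) for (y in b) U <- U + (x > y) + 0.5 * (x == y)
  pooled <- c(a, b)
  n1 <- length(a)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) {
    aa <- pooled[ix]; bb <- pooled[-ix]
    u <- 0
    for (x in aa) for (y in bb) u <- u + (x > y) + 0.5 * (x == y)
    u
  })
  mu <- n1 * length(b) / 2
  p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  list(U = U, p = p)
}
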