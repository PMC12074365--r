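# Independent brute-force oracles used across test files. These deliberately
# re-derive every quantity with plain loops, not through the package's
# vectorized/compiled code paths.

oracle_transform <- function(x) exp(x^2) - 1

oracle_distance <- function(p, q, alpha, w) {
  s <- 0
  for (m in seq_along(p))
    s <- s + w[[m]] * oracle_transform(abs(p[[m]] - q[[m]]) * alpha[[m]])
  unname(s)
}

# exhaustive nearest-centroid search (ties to lowest index)
oracle_assign <- function(E, C, alpha, w, sizes = rep(1, nrow(E))) {
  labels <- integer(nrow(E))
  A_i <- e_i <- numeric(nrow(C))
  for (a in seq_len(nrow(E))) {
    ds <- vapply(seq_len(nrow(C)), function(cc)
      oracle_distance(E[a, ], C[cc, ], alpha, w), 0)
    labels[a] <- which.min(ds)  # which.min takes the first minimum
    A_i[labels[a]] <- A_i[labels[a]] + sizes[a]
    e_i[labels[a]] <- e_i[labels[a]] + sizes[a] * min(ds)
  }
  list(labels = labels, A_i = A_i, e_i = e_i)
}

oracle_fitness <- function(E, C, alpha, w, d) {
  as_ <- oracle_assign(E, C, alpha, w)
  s <- 0
  for (i in seq_len(nrow(C)))
    if (as_$A_i[i] > 0) s <- s + as_$e_i[i]^2 / as_$A_i[i]
  d / nrow(E) * s
}

# double-loop ASA over label grids
oracle_asa <- function(pred, gt) {
  ks <- setdiff(unique(as.vector(pred)), 0)
  gs <- setdiff(unique(as.vector(gt)), 0)
  num <- 0
  for (k in ks) {
    best <- 0
    for (g in gs) best <- max(best, sum(pred == k & gt == g))
    num <- num + best
  }
  num / sum(gt > 0)
}

oracle_majority <- function(pred, lesion) {
  ks <- as.integer(setdiff(sort(unique(as.vector(pred))), 0))
  out <- integer(0)
  for (k in ks) {
    n_in <- sum(pred == k & lesion)
    n_tot <- sum(pred == k)
    if (n_in > n_tot / 2) out <- c(out, k)
  }
  out
}

oracle_asa_dice <- function(pred, gt_lesion) {
  L <- oracle_majority(pred, gt_lesion > 0)
  gl <- sum(gt_lesion > 0)
  if (length(L) == 0 && gl == 0) return(1)
  if (length(L) == 0) return(0)
  gs <- setdiff(unique(as.vector(gt_lesion)), 0)
  num <- 0
  for (k in L) {
    best <- 0
    for (g in gs) best <- max(best, sum(pred == k & gt_lesion == g))
    num <- num + best
  }
  2 * num / (sum(pred %in% L) + gl)
}

oracle_confusion <- function(pred, gt) {
  p <- as.logical(pred); g <- as.logical(gt)
  list(TP = sum(p & g), TN = sum(!p & !g), FP = sum(p & !g), FN = sum(!p & g))
}

# all-pairs directed 95th-percentile Hausdorff on boundary point sets
oracle_hd95 <- function(pred, gt, spacing = 1) {
  bnd <- function(mask) {
    dm <- dim(mask)
    keep <- matrix(FALSE, 0, length(dm))
    idx <- which(mask)
    co <- arrayInd(idx, .dim = dm)
    is_b <- vapply(seq_along(idx), function(i) {
      for (a in seq_along(dm)) {
        for (s in c(-1L, 1L)) {
          nb <- co[i, ]; nb[a] <- nb[a] + s
          if (any(nb < 1) || any(nb > dm)) return(TRUE)
          if (!mask[matrix(nb, 1)]) return(TRUE)
        }
      }
      FALSE
    }, TRUE)
    co[is_b, , drop = FALSE]
  }
  a <- bnd(pred); b <- bnd(gt)
  sp <- rep(spacing, length.out = ncol(a))
  a <- sweep(a, 2, sp, "*"); b <- sweep(b, 2, sp, "*")
  dmat <- as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                              nrow(a) + seq_len(nrow(b)),
                                              drop = FALSE]
  d_ab <- apply(dmat, 1, min)
  d_ba <- apply(dmat, 2, min)
  max(stats::quantile(d_ab, 0.95, names = FALSE),
      stats::quantile(d_ba, 0.95, names = FALSE))
}

# small random labeled mask pair on a grid
random_mask_pair <- function(n = 8, p = 0.4) {
  pred <- matrix(stats::runif(n * n) < p, n, n)
  gt <- matrix(stats::runif(n * n) < p, n, n)
  if (!any(pred)) pred[sample(n * n, 2)] <- TRUE
  if (!any(gt)) gt[sample(n * n, 2)] <- TRUE
  list(pred = pred, gt = gt)
}

# small deterministic-seed phantom helpers
tiny_phantom <- function(seed, shape = c(32L, 32L), noise = 0.05, ...) {
  generate_phantom(phantom_spec(shape = shape, noise_sd = noise,
                                seed = seed, ...))
}

small_pso <- function(seed, S = 24, N = 8, dmin = 1, dmax = 4)
  pso_config(S, N, dmin, dmax, seed = seed)
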