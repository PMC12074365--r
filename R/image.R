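#' Percentile intensity normalization of one modality
#'
#' Normalizes a non-negative intensity grid so that the 25th percentile of
#' the non-zero values maps to 0.4 and the 75th percentile to 0.6, via the
#' linear map `v -> 0.4 + 0.2 * (v - p25) / (p75 - p25)`, then clips to
#' `[0, 1]`. Zero-intensity elements are flagged as background and excluded
#' from the percentile computation; their output value is 0. Percentiles use
#' the linear-interpolation convention (`stats::quantile` type 7).
#'
#' @param raw numeric array (2D or 3D) of non-negative intensities.
#' @return list with `values` (normalized array) and `background` (logical
#'   array, `TRUE` where `raw == 0`).
#' @export
normalize_channel <- function(raw) {
  if (any(raw < 0, na.rm = TRUE)) stop("raw intensities must be non-negative")
  background <- raw == 0
  nz <- raw[!background]
  if (length(unique(nz)) < 2L)
    stop("degenerate scale: channel has fewer than two distinct non-zero values")
  p <- stats::quantile(nz, c(0.25, 0.75), names = FALSE, type = 7)
  if (p[2] <= p[1])
    stop("degenerate scale: 25th and 75th percentiles coincide")
  out <- raw
  out[!background] <- 0.4 + 0.2 * (nz - p[1]) / (p[2] - p[1])
  out[] <- pmin(pmax(out, 0), 1)
  out[background] <- 0
  list(values = out, background = background)
}

#' Multi-modal image container
#'
#' Bundles four co-registered intensity grids (FLAIR, T1CE, T1, T2) of equal
#' shape with a shared background mask. With `normalize = TRUE` (default)
#' each channel is passed through [normalize_channel()]; the image-level
#' background mask is `TRUE` where all four raw channels are zero.
#'
#' @param flair,t1c,t1,t2 numeric arrays of equal dim (2D or 3D).
#' @param normalize apply percentile normalization per channel.
#' @return an object of class `multimodal_image`: list with `channels`
#'   (named list of arrays), `background` (logical array), `shape`, `s_dim`.
#' @export
multimodal_image <- function(flair, t1c, t1, t2, normalize = TRUE) {
  chans <- list(flair = flair, t1c = t1c, t1 = t1, t2 = t2)
  dims <- lapply(chans, function(x) dim(x) %||% length(x))
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same shape")
  shape <- dims[[1]]
  if (!length(shape) %in% 2:3) stop("channels must be 2D or 3D arrays")
  background <- Reduce(`&`, lapply(chans, function(x) x == 0))
  if (normalize) {
    chans <- lapply(chans, function(x) normalize_channel(x)$values)
  }
  structure(list(channels = chans, background = background,
                 shape = as.integer(shape), s_dim = length(shape)),
            class = "multimodal_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.multimodal_image <- function(x, ...) {
  cat(sprintf("Multi-modal image: %s, %d channels (%s)\n",
              paste(x$shape, collapse = " x "), length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  background: %d / %d elements\n",
              sum(x$background), prod(x$shape)))
  invisible(x)
}

# 0-based voxel coordinates normalized per axis to [0,1];
# rows follow arrayInd order over the linear indices `idx`.
.normalized_coords <- function(idx, shape) {
  co <- arrayInd(idx, .dim = shape)
  sweep(co - 1, 2, pmax(shape - 1L, 1L), "/")
}

#' Element matrix in joint spatial-intensity space
#'
#' Flattens the non-background elements of a multi-modal image into an
#' `A x (S+M)` feature matrix: `S` spatial coordinates normalized per axis to
#' `[0,1]` (0-based indices; for 3D the axis order is slice, row, column as
#' stored), followed by the four modality intensities (flair, t1c, t1, t2).
#' In superpixel mode each superpixel contributes one row (its mean feature)
#' with a size weight, so cluster counts and error sums are voxel-weighted.
#'
#' @param image a [multimodal_image()].
#' @param mode `"voxel"` or `"superpixel"`.
#' @param superpixels a [slic_superpixels()] decomposition (required in
#'   superpixel mode).
#' @return list with `features` (A x (S+M) matrix), `sizes` (per-row voxel
#'   multiplicity), `index` (linear grid indices; in superpixel mode a list
#'   of member indices per row), `shape`, `s_dim`, `mode`.
#' @export
element_matrix <- function(image, mode = c("voxel", "superpixel"),
                           superpixels = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "multimodal_image"))
  if (mode == "voxel") {
    idx <- which(!image$background)
    if (length(idx) == 0L) stop("image is entirely background")
    sp <- .normalized_coords(idx, image$shape)
    ints <- vapply(image$channels, function(ch) ch[idx],
                   numeric(length(idx)))
    feat <- cbind(sp, ints)
    colnames(feat) <- c(paste0("s", seq_len(image$s_dim)),
                        names(image$channels))
    list(features = feat, sizes = rep(1, length(idx)), index = idx,
         shape = image$shape, s_dim = image$s_dim, mode = mode)
  } else {
    if (is.null(superpixels)) stop("superpixel mode requires a decomposition")
    feat <- superpixels$features
    list(features = feat, sizes = superpixels$sizes,
         index = superpixels$members, shape = image$shape,
         s_dim = image$s_dim, mode = mode, labels_grid = superpixels$labels)
  }
}

#' SLIC superpixel decomposition
#'
#' Partitions the non-background domain of a multi-modal image into
#' approximately `k` compact, intensity-homogeneous superpixels using the
#' SLIC algorithm (localized k-means in a joint color-spatial space with the
#' standard distance `sqrt(dc^2 + (ds/g)^2 * m^2)`, where `g` is the grid
#' interval and `m` the compactness). Cluster centers are seeded on a regular
#' grid and each is updated from the elements within its `2g` neighborhood.
#'
#' @param image a [multimodal_image()].
#' @param k target number of superpixels.
#' @param compactness trade-off `m` between spatial and intensity proximity.
#' @param max_iter number of update sweeps.
#' @return list with `labels` (integer grid, 0 = background), `sizes`,
#'   `features` (per-superpixel mean joint feature), `members` (list of
#'   member linear indices), `n`.
#' @export
slic_superpixels <- function(image, k, compactness = 5.0, max_iter = 10L) {
  stopifnot(inherits(image, "multimodal_image"), k >= 1)
  idx <- which(!image$background)
  A <- length(idx)
  if (k > A) stop("k exceeds the number of non-background elements")
  shape <- image$shape
  co <- arrayInd(idx, .dim = shape)           # 1-based integer coords
  ints <- vapply(image$channels, function(ch) ch[idx], numeric(A))
  g <- max((A / k)^(1 / image$s_dim), 1)      # grid interval

  # seed centers on a regular grid over the bounding box, snapped to the
  # nearest non-background element
  rngs <- lapply(seq_len(image$s_dim), function(a) range(co[, a]))
  n_per <- pmax(1L, round((vapply(rngs, diff, 0) + 1) / g))
  while (prod(n_per) < k) n_per[which.min(n_per)] <- n_per[which.min(n_per)] + 1L
  seq_axis <- lapply(seq_len(image$s_dim), function(a)
    rngs[[a]][1] + (seq_len(n_per[a]) - 0.5) / n_per[a] * (diff(rngs[[a]]) + 1))
  grid <- as.matrix(expand.grid(seq_axis))
  # keep the k grid points closest to actual tissue
  nearest <- apply(grid, 1, function(pt) {
    d2 <- rowSums(sweep(co, 2, pt)^2)
    j <- which.min(d2)
    c(j, d2[j])
  })
  ord <- order(nearest[2, ])[seq_len(min(k, ncol(nearest)))]
  centers_sp <- co[nearest[1, ord], , drop = FALSE] + 0.0
  centers_int <- ints[nearest[1, ord], , drop = FALSE]
  n_c <- nrow(centers_sp)

  lab <- rep(1L, A)
  for (it in seq_len(max_iter)) {
    best <- rep(Inf, A)
    lab_new <- lab
    for (cc in seq_len(n_c)) {
      sel <- rep(TRUE, A)
      for (a in seq_len(image$s_dim))
        sel <- sel & abs(co[, a] - centers_sp[cc, a]) <= 2 * g
      if (!any(sel)) next
      ds2 <- rowSums(sweep(co[sel, , drop = FALSE], 2, centers_sp[cc, ])^2)
      dc2 <- rowSums(sweep(ints[sel, , drop = FALSE], 2, centers_int[cc, ])^2)
      D <- dc2 + ds2 / g^2 * compactness^2
      better <- D < best[sel]
      w <- which(sel)[better]
      best[w] <- D[better]
      lab_new[w] <- cc
    }
    # orphans (outside all windows) go to the nearest center spatially
    orphan <- which(!is.finite(best))
    for (o in orphan)
      lab_new[o] <- which.min(rowSums(sweep(centers_sp, 2, co[o, ])^2))
    lab <- lab_new
    for (cc in seq_len(n_c)) {
      mem <- lab == cc
      if (any(mem)) {
        centers_sp[cc, ] <- colMeans(co[mem, , drop = FALSE])
        centers_int[cc, ] <- colMeans(ints[mem, , drop = FALSE])
      }
    }
  }
  # drop empty superpixels, relabel compactly
  keep <- sort(unique(lab))
  lab <- match(lab, keep)
  n_c <- length(keep)

  labels <- array(0L, dim = shape)
  labels[idx] <- lab
  sp_norm <- .normalized_coords(idx, shape)
  feat <- matrix(0, n_c, image$s_dim + length(image$channels))
  sizes <- tabulate(lab, n_c)
  members <- split(idx, lab)
  for (cc in seq_len(n_c)) {
    mem <- lab == cc
    feat[cc, ] <- c(colMeans(sp_norm[mem, , drop = FALSE]),
                    colMeans(ints[mem, , drop = FALSE]))
  }
  colnames(feat) <- c(paste0("s", seq_len(image$s_dim)),
                      names(image$channels))
  list(labels = labels, sizes = sizes, features = feat,
       members = members, n = n_c)
}
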