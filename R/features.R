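#' Construct a Gabor kernel
#'
#' An oriented band-pass kernel: a Gaussian envelope modulating a cosine
#' carrier along the orientation direction. Kernels are made zero-mean
#' (mean subtracted) so responses measure local structure, not brightness.
#'
#' @param sigma Gaussian envelope scale (elements).
#' @param frequency carrier frequency (cycles per element).
#' @param orientation orientation angle(s) in radians: one angle in 2D,
#'   `c(azimuth, elevation)` in 3D.
#' @param s_dim 2 or 3.
#' @param size odd kernel side length; default covers about three sigma.
#' @return object of class `gabor_filter` with the kernel array and its
#'   parameters.
#' @export
gabor_kernel <- function(sigma, frequency, orientation, s_dim = 2L,
                         size = NULL) {
  stopifnot(sigma > 0, frequency > 0, s_dim %in% 2:3)
  if (is.null(size)) size <- 2L * ceiling(1.5 * sigma) + 1L
  if (size %% 2 == 0) size <- size + 1L
  h <- (size - 1L) / 2
  ax <- seq(-h, h)
  if (s_dim == 2L) {
    u <- c(cos(orientation[1]), sin(orientation[1]))
    X <- outer(ax, rep(1, size)); Y <- outer(rep(1, size), ax)
    proj <- u[1] * X + u[2] * Y
    env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  } else {
    stopifnot(length(orientation) >= 2)
    th <- orientation[1]; ph <- orientation[2]
    u <- c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
    g <- expand.grid(x = ax, y = ax, z = ax)
    proj <- array(u[1] * g$x + u[2] * g$y + u[3] * g$z, dim = rep(size, 3))
    env <- array(exp(-(g$x^2 + g$y^2 + g$z^2) / (2 * sigma^2)),
                 dim = rep(size, 3))
  }
  ker <- env * cos(2 * pi * frequency * proj)
  ker <- ker - mean(ker)
  structure(list(kernel = ker, sigma = sigma, frequency = frequency,
                 orientation = orientation, s_dim = as.integer(s_dim),
                 assigned_modality = NA_character_,
                 selection_basis = NA_character_),
            class = "gabor_filter")
}

#' Randomized overcomplete Gabor bank
#'
#' Draws `n_candidates` kernels with parameters sampled continuously and
#' uniformly across scales, frequencies and orientations.
#'
#' @param n_candidates number of candidate filters.
#' @param s_dim 2 or 3.
#' @param sigma_range,frequency_range uniform sampling ranges.
#' @param seed optional integer seed.
#' @return list of `gabor_filter` objects (class `gabor_bank`).
#' @export
build_gabor_bank <- function(n_candidates, s_dim = 2L,
                             sigma_range = c(1, 3),
                             frequency_range = c(0.05, 0.35),
                             seed = NULL) {
  stopifnot(n_candidates >= 1,
            diff(sigma_range) > 0, diff(frequency_range) > 0)
  if (!is.null(seed)) set.seed(seed)
  bank <- lapply(seq_len(n_candidates), function(i) {
    ori <- if (s_dim == 2L) stats::runif(1, 0, pi)
           else c(stats::runif(1, 0, pi), stats::runif(1, -pi / 2, pi / 2))
    gabor_kernel(stats::runif(1, sigma_range[1], sigma_range[2]),
                 stats::runif(1, frequency_range[1], frequency_range[2]),
                 ori, s_dim)
  })
  class(bank) <- "gabor_bank"
  bank
}

# convolve one channel with one kernel (replicate padding)
.convolve <- function(channel, kernel) {
  dm <- dim(channel)
  if (length(dm) == 2L) {
    cpp_convolve2d(channel, kernel)
  } else {
    cpp_convolve3d(as.numeric(channel), as.integer(dm),
                   as.numeric(kernel), as.integer(dim(kernel)))
  }
}

#' Apply a Gabor filter to one image channel
#'
#' @param channel numeric grid.
#' @param filter a `gabor_filter`.
#' @return response grid of the same shape.
#' @export
apply_gabor <- function(channel, filter) .convolve(channel, filter$kernel)

# vectorize kernels onto a common (max-size, center-padded) support
.vectorize_bank <- function(bank) {
  sizes <- vapply(bank, function(f) dim(f$kernel)[1], 0L)
  smax <- max(sizes)
  nd <- bank[[1]]$s_dim
  t(vapply(bank, function(f) {
    k <- f$kernel
    pad <- array(0, dim = rep(smax, nd))
    off <- (smax - dim(k)[1]) / 2
    idx <- lapply(dim(k), function(n) seq_len(n) + off)
    pad <- do.call(`[<-`, c(list(pad), idx, list(value = k)))
    as.numeric(pad)
  }, numeric(smax^nd)))
}

#' Select modality-specific filters from a candidate bank
#'
#' Vectorized kernels are clustered by k-means; from every cluster two
#' representatives are kept: the filter with maximal discriminative power
#' (largest absolute mean-response difference between tumor and non-tumor
#' elements, over its best modality) and the filter with maximal response
#' variance. Each selected filter is assigned exclusively to the modality on
#' which its discriminative score is maximal.
#'
#' @param bank a [build_gabor_bank()] result (needs at least `2 * k`
#'   candidates).
#' @param images list of [multimodal_image()] training images.
#' @param masks list of logical tumor masks aligned with `images`.
#' @param k number of k-means clusters (paper setting 75, giving up to 150
#'   selected filters).
#' @param sample_per_image number of elements scored per image.
#' @param seed optional integer seed.
#' @return a `gabor_bank` of at most `2 * k` filters with
#'   `assigned_modality` and `selection_basis` filled in.
#' @export
select_filters <- function(bank, images, masks, k = 75L,
                           sample_per_image = 2000L, seed = NULL) {
  stopifnot(length(bank) >= 2L * k, length(images) == length(masks),
            length(images) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  mods <- names(images[[1]]$channels)

  # score every candidate on a subsample of labeled elements
  n <- length(bank)
  disc <- var_resp <- matrix(0, n, length(mods),
                             dimnames = list(NULL, mods))
  samples <- lapply(seq_along(images), function(i) {
    idx <- which(!images[[i]]$background)
    idx[sample.int(length(idx), min(sample_per_image, length(idx)))]
  })
  for (fi in seq_len(n)) {
    for (m in mods) {
      resp <- tum <- list()
      for (i in seq_along(images)) {
        r <- apply_gabor(images[[i]]$channels[[m]], bank[[fi]])
        resp[[i]] <- r[samples[[i]]]
        tum[[i]] <- masks[[i]][samples[[i]]]
      }
      resp <- unlist(resp); tum <- unlist(tum)
      mt <- mean(resp[tum]); mn <- mean(resp[!tum])
      disc[fi, m] <- abs((if (is.nan(mt)) 0 else mt) -
                         (if (is.nan(mn)) 0 else mn))
      var_resp[fi, m] <- stats::var(resp)
    }
  }

  km <- stats::kmeans(.vectorize_bank(bank), centers = k, iter.max = 50,
                      nstart = 3)
  selected <- list()
  for (cl in seq_len(k)) {
    mem <- which(km$cluster == cl)
    if (length(mem) == 0L) next
    if (length(mem) < 2L)
      message("k-means cluster ", cl,
              " has a single member; representatives coincide")
    best_disc <- mem[which.max(apply(disc[mem, , drop = FALSE], 1, max))]
    best_var <- mem[which.max(apply(var_resp[mem, , drop = FALSE], 1, max))]
    for (pick in list(c(best_disc, "discriminative"),
                      c(best_var, "variance"))) {
      f <- bank[[as.integer(pick[1])]]
      f$assigned_modality <- mods[which.max(disc[as.integer(pick[1]), ])]
      f$selection_basis <- pick[2]
      selected[[length(selected) + 1L]] <- f
    }
  }
  class(selected) <- "gabor_bank"
  selected
}

#' Gabor response matrix
#'
#' Applies every selected filter to its assigned modality and returns the
#' responses at the requested elements.
#'
#' @param image a [multimodal_image()].
#' @param filters a selected `gabor_bank` (with assigned modalities).
#' @param index linear element indices (default: all non-background).
#' @return numeric matrix, one column per filter.
#' @export
gabor_responses <- function(image, filters, index = NULL) {
  if (is.null(index)) index <- which(!image$background)
  out <- matrix(0, length(index), length(filters))
  colnames(out) <- sprintf("gf%03d", seq_along(filters))
  for (fi in seq_along(filters)) {
    m <- filters[[fi]]$assigned_modality
    if (is.na(m)) stop("filters must carry an assigned modality; ",
                       "run select_filters() first")
    out[, fi] <- apply_gabor(image$channels[[m]], filters[[fi]])[index]
  }
  out
}

#' Voxel-level descriptors
#'
#' Per modality: the raw (normalized) intensity, the local standard
#' deviation under a Gaussian window, and the median-filtered intensity.
#'
#' @param image a [multimodal_image()].
#' @param gaussian_window,median_window odd window sizes in elements.
#' @return named list of descriptor grids
#'   (`raw_*`, `gsd_*`, `med_*` per modality).
#' @export
voxel_descriptors <- function(image, gaussian_window = 5L,
                              median_window = 5L) {
  stopifnot(inherits(image, "multimodal_image"))
  if (gaussian_window > min(image$shape) || median_window > min(image$shape))
    stop("descriptor window exceeds the image extent")
  nd <- image$s_dim
  w <- as.integer(gaussian_window)
  h <- (w - 1L) / 2
  sig <- w / 4
  ax <- seq(-h, h)
  if (nd == 2L) {
    g1 <- exp(-ax^2 / (2 * sig^2))
    gk <- outer(g1, g1)
  } else {
    g <- expand.grid(x = ax, y = ax, z = ax)
    gk <- array(exp(-(g$x^2 + g$y^2 + g$z^2) / (2 * sig^2)), dim = rep(w, 3))
  }
  gk <- gk / sum(gk)
  out <- list()
  for (m in names(image$channels)) {
    ch <- image$channels[[m]]
    out[[paste0("raw_", m)]] <- ch
    mu <- .convolve(ch, gk)
    mu2 <- .convolve(ch^2, gk)
    out[[paste0("gsd_", m)]] <- sqrt(pmax(mu2 - mu^2, 0))
    out[[paste0("med_", m)]] <- if (nd == 2L)
      cpp_median2d(ch, as.integer(median_window))
    else cpp_median3d(as.numeric(ch), as.integer(image$shape),
                      as.integer(median_window))
  }
  out
}

#' Box-counting fractal dimension of a binary mask
#'
#' Counts occupied boxes over a dyadic ladder of box sizes and returns the
#' least-squares slope of `log(count)` against `log(1/size)`. The sizes used
#' and the per-size counts are attached as attributes.
#'
#' @param mask logical/0-1 grid.
#' @return the estimated dimension (0, with a warning, for a single-element
#'   mask).
#' @export
fractal_dimension <- function(mask) {
  dm <- dim(mask) %||% length(mask)
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) stop("mask is empty")
  if (length(idx) == 1L) {
    warning("single-element mask; fractal dimension reported as 0")
    return(structure(0, sizes = 1L, counts = 1L))
  }
  co <- arrayInd(idx, .dim = dm)
  smax <- 2^floor(log2(max(dm) / 2))
  sizes <- 2^(0:log2(smax))
  counts <- vapply(sizes, function(s) {
    boxes <- floor((co - 1L) / s)
    nrow(unique(boxes))
  }, 0)
  keep <- counts > 0
  fit <- stats::lm(log(counts[keep]) ~ log(1 / sizes[keep]))
  structure(unname(stats::coef(fit)[2]), sizes = sizes, counts = counts)
}

# gray-level co-occurrence contrast and homogeneity over a cluster support:
# intensities quantized into n_levels bins over [0,1], axis-aligned offsets
# at distance 1 (both elements inside the cluster), symmetric, averaged
.glcm_stats <- function(channel, member_idx, shape, n_levels = 16L) {
  q <- array(NA_integer_, dim = shape)
  q[member_idx] <- pmin(pmax(floor(channel[member_idx] * n_levels) + 1L, 1L),
                        n_levels)
  nd <- length(shape)
  pairs_i <- integer(0); pairs_j <- integer(0)
  co <- arrayInd(member_idx, .dim = shape)
  for (axis in seq_len(nd)) {
    nb <- co
    nb[, axis] <- nb[, axis] + 1L
    ok <- nb[, axis] <= shape[axis]
    if (!any(ok)) next
    nb_lin <- as.vector((nb[ok, , drop = FALSE] - 1L) %*%
                        cumprod(c(1L, shape[-nd]))) + 1L
    v1 <- q[member_idx[ok]]
    v2 <- q[nb_lin]
    good <- !is.na(v2)
    pairs_i <- c(pairs_i, v1[good]); pairs_j <- c(pairs_j, v2[good])
  }
  if (length(pairs_i) == 0L) return(c(contrast = 0, homogeneity = 1))
  # symmetrize
  ii <- c(pairs_i, pairs_j); jj <- c(pairs_j, pairs_i)
  p <- 1 / length(ii)
  c(contrast = sum(p * (ii - jj)^2),
    homogeneity = sum(p / (1 + abs(ii - jj))))
}

# polygon area of the convex hull of 2D points (shoelace)
.hull_area <- function(pts) {
  if (nrow(unique(pts)) < 3L) return(0)
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Cluster-level descriptors
#'
#' For every cluster of a labeling: a modality-independent geometric block
#' (size, bounding-box extents, aspect ratio, bounding-box density,
#' boundary-to-size ratio, eccentricity, convexity, normalized centroid,
#' second-order central spatial moments, box-counting fractal dimension) and
#' a modality-dependent block (mean, standard deviation, and co-occurrence
#' contrast and homogeneity of the intensities over the cluster support, per
#' modality). Convexity in 2D is the cluster area over its convex-hull area;
#' in 3D it is averaged over axial slices.
#'
#' @param labels integer cluster grid (0 = background) or an `mdpso_seg`.
#' @param image the [multimodal_image()] the labeling belongs to.
#' @param n_levels gray levels for the co-occurrence summary.
#' @return numeric matrix, one row per cluster label, with named columns;
#'   rownames are the cluster labels.
#' @export
cluster_descriptors <- function(labels, image, n_levels = 16L) {
  if (inherits(labels, "mdpso_seg")) labels <- labels$labels
  shape <- image$shape
  nd <- image$s_dim
  ks <- sort(unique(labels[labels > 0]))
  mom_names <- if (nd == 2L) c("m_11", "m_22", "m_12")
               else c("m_11", "m_22", "m_33", "m_12", "m_13", "m_23")
  geo_names <- c("size", paste0("bbox_", seq_len(nd)), "aspect", "density",
                 "boundary_ratio", "eccentricity", "convexity",
                 paste0("centroid_", seq_len(nd)), mom_names, "fractal_dim")
  int_names <- as.vector(outer(c("mean", "sd", "contrast", "homogeneity"),
                               names(image$channels), paste, sep = "_"))
  out <- matrix(0, length(ks), length(geo_names) + length(int_names),
                dimnames = list(ks, c(geo_names, int_names)))
  for (r in seq_along(ks)) {
    k <- ks[r]
    idx <- which(labels == k)
    co <- arrayInd(idx, .dim = shape)
    size <- length(idx)
    ext <- apply(co, 2, function(v) diff(range(v)) + 1)
    aspect <- max(ext) / min(ext)
    density <- size / prod(ext)
    mask <- array(FALSE, shape); mask[idx] <- TRUE
    brat <- length(.mask_boundary(mask)) / size
    cen <- colMeans(co)
    cc <- sweep(co, 2, cen)
    covm <- crossprod(cc) / size
    ev <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[nd] / ev[1]))
    conv <- if (nd == 2L) {
      ha <- .hull_area(co)
      if (ha > 0) min(size / ha, 1) else 1
    } else {
      vals <- vapply(unique(co[, 3]), function(z) {
        pts <- co[co[, 3] == z, 1:2, drop = FALSE]
        ha <- .hull_area(pts)
        if (ha > 0) min(nrow(pts) / ha, 1) else 1
      }, 0)
      mean(vals)
    }
    fd <- suppressWarnings(as.numeric(fractal_dimension(mask)))
    moms <- if (nd == 2L) c(covm[1, 1], covm[2, 2], covm[1, 2])
            else c(covm[1, 1], covm[2, 2], covm[3, 3],
                   covm[1, 2], covm[1, 3], covm[2, 3])
    out[r, geo_names] <- c(size, ext, aspect, density, brat, ecc, conv,
                           (cen - 1) / pmax(shape - 1L, 1L), moms, fd)
    for (m in names(image$channels)) {
      v <- image$channels[[m]][idx]
      gl <- .glcm_stats(image$channels[[m]], idx, shape, n_levels)
      out[r, paste(c("mean", "sd", "contrast", "homogeneity"), m,
                   sep = "_")] <-
        c(mean(v), if (size > 1) stats::sd(v) else 0, gl["contrast"],
          gl["homogeneity"])
    }
  }
  out
}

#' Assemble the per-element feature table
#'
#' Concatenates, for every requested element: the voxel-level block (raw
#' intensities, Gaussian local standard deviations, median-filtered
#' intensities per modality), the responses of the selected Gabor filters,
#' and the element's cluster descriptor block, through which contextual
#' region-level information reaches the classifier. `include_voxel` and
#' `include_cluster` toggle the blocks: the GF-only ablation (classification
#' solely from Gabor responses) drops both. The recorded column schema is
#' attached as the `"schema"` attribute.
#'
#' @param image a [multimodal_image()].
#' @param labels cluster labeling grid (or `mdpso_seg`); may be `NULL` when
#'   `include_cluster = FALSE`.
#' @param filters a selected `gabor_bank`.
#' @param index linear element indices (default all non-background).
#' @param include_cluster attach the cluster-descriptor block.
#' @param include_voxel attach the voxel-level descriptor block.
#' @param gaussian_window,median_window see [voxel_descriptors()].
#' @return a data.frame of features with attribute `schema`.
#' @export
assemble_features <- function(image, labels = NULL, filters,
                              index = NULL, include_cluster = TRUE,
                              include_voxel = TRUE,
                              gaussian_window = 5L, median_window = 5L) {
  if (is.null(index)) index <- which(!image$background)
  gf <- gabor_responses(image, filters, index)
  if (include_voxel) {
    vd <- voxel_descriptors(image, gaussian_window, median_window)
    tab <- as.data.frame(lapply(vd, function(g) g[index]))
    tab <- cbind(tab, as.data.frame(gf))
  } else {
    vd <- list()
    tab <- as.data.frame(gf)
  }
  if (include_cluster) {
    if (is.null(labels)) stop("cluster block requested but no labeling given")
    if (inherits(labels, "mdpso_seg")) labels <- labels$labels
    cd <- cluster_descriptors(labels, image)
    lab_el <- labels[index]
    if (any(lab_el == 0))
      stop("requested elements include unlabeled (background) positions")
    block <- cd[match(as.character(lab_el), rownames(cd)), , drop = FALSE]
    colnames(block) <- paste0("cl_", colnames(block))
    tab <- cbind(tab, as.data.frame(block, row.names = NULL))
  }
  attr(tab, "schema") <- list(
    columns = names(tab),
    n_voxel = length(vd), n_gabor = ncol(gf),
    n_cluster = if (include_cluster) ncol(tab) - length(vd) - ncol(gf) else 0L,
    gaussian_window = gaussian_window, median_window = median_window,
    include_cluster = include_cluster, include_voxel = include_voxel)
  tab
}
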