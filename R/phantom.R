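#' Phantom specification
#'
#' Settings for the synthetic multi-modal phantom generator: grid shape,
#' lesion count and geometry, per-modality lesion contrast offsets, smooth
#' background anatomy, and additive noise. Defaults emulate the modality
#' behavior of glioma MRI at a desk-test scale: a FLAIR-bright /
#' T2-bright / T1-dark lesion with a contrast-enhancing core on T1CE, on a
#' slowly varying tissue field inside an elliptical "brain" with a
#' zero-intensity exterior.
#'
#' @param shape grid shape, length 2 (slice) or 3 (volume).
#' @param n_lesions number of lesions.
#' @param contrast named per-modality additive lesion-core contrast (on the
#'   normalized `[0,1]` intensity scale).
#' @param rim_factor fraction of the core contrast applied in the lesion rim
#'   (edema-like ring), per modality; FLAIR/T2 keep most of it.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param radius_frac range of lesion equivalent radius as a fraction of the
#'   smallest grid extent.
#' @param irregularity amplitude of the low-order radial boundary
#'   perturbation (0 = exact ellipse).
#' @param core_frac relative linear scale of the core inside the lesion.
#' @param seed integer seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L), n_lesions = 1L,
                         contrast = c(flair = 0.35, t1c = 0.15,
                                      t1 = -0.15, t2 = 0.25),
                         rim_factor = c(flair = 0.9, t1c = 0.2,
                                        t1 = 0.6, t2 = 0.9),
                         noise_sd = 0.05, radius_frac = c(0.10, 0.18),
                         irregularity = 0.15, core_frac = 0.55,
                         seed = NULL) {
  stopifnot(length(shape) %in% 2:3, all(shape >= 8), n_lesions >= 1,
            noise_sd >= 0, core_frac > 0, core_frac < 1,
            all(radius_frac > 0), all(radius_frac < 0.5))
  mods <- c("flair", "t1c", "t1", "t2")
  stopifnot(all(mods %in% names(contrast)), all(mods %in% names(rim_factor)))
  structure(list(shape = as.integer(shape), n_lesions = as.integer(n_lesions),
                 contrast = contrast[mods], rim_factor = rim_factor[mods],
                 noise_sd = noise_sd, radius_frac = radius_frac,
                 irregularity = irregularity, core_frac = core_frac,
                 seed = seed),
            class = "phantom_spec")
}

# smooth random field in [-1,1]: sum of a few low-frequency cosine waves
.smooth_field <- function(shape) {
  nd <- length(shape)
  co <- lapply(shape, function(n) (seq_len(n) - 0.5) / n)
  f <- array(0, dim = shape)
  for (j in 1:3) {
    freq <- stats::runif(nd, 0.5, 2.5)
    phase <- stats::runif(nd, 0, 2 * pi)
    wave <- Reduce(function(acc, a) {
      v <- cos(2 * pi * freq[a] * co[[a]] + phase[a])
      outer_shape <- rep(1L, nd); outer_shape[a] <- shape[a]
      acc * array(rep(v, each = prod(shape[seq_len(a - 1L)])), dim = shape)
    }, seq_len(nd), accumulate = FALSE,
    init = array(1, dim = shape))
    f <- f + wave / j
  }
  f / max(abs(f))
}

#' Generate a synthetic multi-modal phantom
#'
#' Builds four co-registered channels on a common anatomy: an elliptical
#' brain (zero-intensity exterior, exercising the zero-background rule), a
#' smooth low-frequency tissue field per modality, `n_lesions`
#' ellipse/ellipsoid lesions with irregular (radially perturbed) boundaries,
#' each with a core and an edema-like rim carrying per-modality contrast
#' offsets, plus additive Gaussian noise. Channels are produced directly on
#' the normalized `[0,1]` scale (pass `raw_scale = TRUE` to obtain
#' arbitrary-unit raw intensities for exercising percentile normalization).
#'
#' @param spec a [phantom_spec()].
#' @param raw_scale return raw-unit channels (x1000) instead of `[0,1]`.
#' @return list of class `phantom`: `image` (a [multimodal_image()]),
#'   `lesion_mask` (logical grid, core + rim), `lesion_labels` (integer grid,
#'   one label per lesion), `regions` (integer partition: 1 = tissue, per
#'   lesion rim/core get their own labels, 0 = exterior), `spec`.
#' @export
generate_phantom <- function(spec, raw_scale = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  shape <- spec$shape
  nd <- length(shape)
  mods <- names(spec$contrast)

  co <- arrayInd(seq_len(prod(shape)), .dim = shape)
  cen <- (shape + 1) / 2
  semi <- shape * 0.46
  brain_q <- rowSums(sweep(sweep(co, 2, cen), 2, semi, "/")^2)
  brain <- array(brain_q <= 1, dim = shape)

  # lesion placement: centers inside the brain with margin for the radius
  rmin <- min(shape) * spec$radius_frac[1]
  rmax <- min(shape) * spec$radius_frac[2]
  lesion_labels <- array(0L, dim = shape)
  core_mask <- array(FALSE, dim = shape)
  geometry <- vector("list", spec$n_lesions)
  for (li in seq_len(spec$n_lesions)) {
    placed <- FALSE
    for (try in 1:200) {
      r <- stats::runif(nd, rmin, rmax)       # per-axis semi-axes
      ctr <- cen + (stats::runif(nd, -0.6, 0.6)) * (semi - max(r) - 1)
      if (any(ctr - max(r) < 1) || any(ctr + max(r) > shape)) next
      dx <- sweep(co, 2, ctr)
      q <- sqrt(rowSums(sweep(dx, 2, r, "/")^2))   # normalized radius
      ang <- atan2(dx[, 2], dx[, 1])
      pert <- 1 + spec$irregularity *
        (0.6 * sin(2 * ang + stats::runif(1, 0, 2 * pi)) +
         0.4 * sin(3 * ang + stats::runif(1, 0, 2 * pi)))
      if (nd == 3L) {
        ang2 <- atan2(dx[, 3], sqrt(dx[, 1]^2 + dx[, 2]^2))
        pert <- pert + spec$irregularity * 0.4 *
          sin(2 * ang2 + stats::runif(1, 0, 2 * pi))
      }
      inside <- q <= pert
      if (any(lesion_labels[inside] > 0)) next   # avoid lesion overlap
      lesion_labels[inside] <- li
      core_mask[q <= spec$core_frac * pert] <- TRUE
      geometry[[li]] <- list(center = ctr, radii = r)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place lesion ", li, " within the phantom")
  }
  lesion_mask <- lesion_labels > 0 & brain
  lesion_labels[!brain] <- 0L
  core_mask <- core_mask & brain

  regions <- array(0L, dim = shape)
  regions[brain] <- 1L
  for (li in seq_len(spec$n_lesions)) {
    regions[lesion_labels == li & !core_mask] <- 2L * li        # rim
    regions[lesion_labels == li & core_mask] <- 2L * li + 1L    # core
  }

  chans <- lapply(mods, function(m) {
    base <- 0.45 + 0.08 * .smooth_field(shape)
    v <- base
    v[lesion_mask & !core_mask] <- v[lesion_mask & !core_mask] +
      spec$contrast[[m]] * spec$rim_factor[[m]]
    v[core_mask] <- v[core_mask] + spec$contrast[[m]]
    if (spec$noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, spec$noise_sd)
    v <- pmin(pmax(v, 0.02), 1)   # keep tissue strictly positive
    v[!brain] <- 0
    array(v, dim = shape)
  })
  names(chans) <- mods
  if (raw_scale) chans <- lapply(chans, function(x) x * 1000)

  img <- multimodal_image(chans$flair, chans$t1c, chans$t1, chans$t2,
                          normalize = raw_scale)
  structure(list(image = img, lesion_mask = lesion_mask,
                 lesion_labels = lesion_labels, regions = regions,
                 geometry = geometry, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Synthetic phantom: %s, %d lesion(s), %d lesion elements\n",
              paste(x$spec$shape, collapse = " x "), x$spec$n_lesions,
              sum(x$lesion_mask)))
  invisible(x)
}
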