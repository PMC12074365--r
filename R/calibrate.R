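#' Calibration specification for the distance weights
#'
#' Defines the search for the per-attribute scales and weights of the
#' transformed distance. Six tunables are searched in a `[0, 5]` box each:
#' a shared spatial scale (`alpha_spatial`), a shared intensity scale
#' (`alpha_intensity`), the isotropic spatial weight (`w_spatial`) and the
#' FLAIR, T1CE and T2 intensity weights. The T1 intensity weight is pinned
#' to 1 (the unit reference), spatial weights are tied isotropic, and the
#' FLAIR weight is required to be the strictly largest intensity weight;
#' proposals violating the constraints are rejected and resampled.
#'
#' @param slices calibration cases: list of lists with `image`
#'   (a [multimodal_image()]) and `lesion` (ground-truth lesion grid or
#'   mask); [generate_phantom()] outputs work directly.
#' @param budget number of optimization trials.
#' @param box lower/upper bound of every tunable (default `c(0, 5)`).
#' @param pso a [pso_config()] used for each trial segmentation; defaults to
#'   a reduced search suitable for small calibration slices.
#' @param pinned_modality the intensity weight fixed at unity (default
#'   `"t1"`, the lowest-information channel here).
#' @param seed integer seed for the whole trial sequence.
#' @return object of class `calibration_spec`.
#' @export
calibration_spec <- function(slices, budget = 40L, box = c(0, 5),
                             pso = NULL, pinned_modality = "t1",
                             seed = NULL) {
  stopifnot(length(slices) >= 1, budget >= 1, length(box) == 2,
            box[2] > box[1],
            pinned_modality %in% c("t1c", "t1", "t2"))
  slices <- lapply(slices, function(s) {
    if (inherits(s, "phantom"))
      list(image = s$image, lesion = s$lesion_labels)
    else s
  })
  if (is.null(pso))
    pso <- pso_config(swarm_size = 24, iterations = 8, dmin = 2, dmax = 5)
  structure(list(slices = slices, budget = as.integer(budget), box = box,
                 pso = pso, pinned_modality = pinned_modality, seed = seed),
            class = "calibration_spec")
}

# map the six tunables to a distance_config;
# order: alpha_spatial, alpha_intensity, w_spatial, w_flair, w_t1c, w_t2
.calibration_to_config <- function(x, s_dim, pinned = "t1") {
  eps <- 1e-6
  free <- setdiff(c("t1c", "t1", "t2"), pinned)
  w_mod <- c(flair = x[4])
  w_mod[free] <- x[5:6]
  w_mod[pinned] <- 1
  w_mod <- w_mod[c("flair", "t1c", "t1", "t2")]
  distance_config(alpha = c(rep(max(x[1], eps), s_dim),
                            rep(max(x[2], eps), 4)),
                  weight = c(rep(x[3], s_dim), w_mod),
                  s_dim = s_dim)
}

#' Calibrate the distance scales and weights
#'
#' Runs a sequential model-based search (TPE-style, [tpe_optimize()]) over
#' the six tunables of [calibration_spec()], scoring every proposal by the
#' mean lesion ASA-Dice of an MDPSO segmentation of each calibration slice,
#' and returns the best constraint-satisfying configuration.
#'
#' @param spec a [calibration_spec()].
#' @return list with `config` (the calibrated [distance_config()]),
#'   `objective` (its mean lesion ASA-Dice), `trials` (full trial log) and
#'   `n_infeasible` (rejected constraint-violating proposals).
#' @export
calibrate_distance <- function(spec) {
  stopifnot(inherits(spec, "calibration_spec"))
  s_dim <- spec$slices[[1]]$image$s_dim
  pinned <- spec$pinned_modality
  constraint <- function(x) {
    # FLAIR must strictly exceed the two free weights and the pinned unit
    x[4] > max(x[5], x[6], 1) && x[1] > 0 && x[2] > 0
  }
  trial_seed <- (spec$seed %||% 1L) %% 1000000L
  objective <- function(x) {
    cfg <- .calibration_to_config(x, s_dim, pinned)
    scores <- vapply(seq_along(spec$slices), function(i) {
      s <- spec$slices[[i]]
      pso <- spec$pso
      pso$seed <- trial_seed + i
      seg <- mdpso_segment(s$image, pso = pso, dist = cfg)
      asa_dice(seg$labels, s$lesion)
    }, 0)
    mean(scores)
  }
  res <- tpe_optimize(objective,
                      lower = stats::setNames(rep(spec$box[1], 6),
                        c("alpha_spatial", "alpha_intensity", "w_spatial",
                          "w_flair", "w_t1c", "w_t2")),
                      upper = rep(spec$box[2], 6),
                      n_trials = spec$budget, constraint = constraint,
                      seed = spec$seed)
  list(config = .calibration_to_config(res$par, s_dim, pinned),
       objective = res$value, trials = res$trials,
       n_infeasible = res$n_infeasible)
}
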