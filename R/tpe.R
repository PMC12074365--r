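#' Sequential model-based optimization (TPE-style)
#'
#' Maximizes a black-box objective over a box by the tree-structured
#' Parzen-estimator recipe: after a uniform start-up phase the observed
#' trials are split into a "good" quantile and the rest, one-dimensional
#' kernel densities are built over each group, and the next candidate is the
#' sample (from the good density) that maximizes the good-to-bad density
#' ratio. An optional constraint predicate causes infeasible proposals to be
#' rejected and resampled.
#'
#' @param objective function `x -> real` (finite) to maximize.
#' @param lower,upper numeric box bounds.
#' @param n_trials total number of evaluated trials.
#' @param n_startup uniform exploratory trials before the model kicks in.
#' @param gamma fraction of trials regarded as "good".
#' @param n_candidates candidates scored per model-based trial.
#' @param constraint optional predicate `x -> logical`; infeasible proposals
#'   are resampled (up to 100 attempts, then the best feasible uniform draw).
#' @param seed optional integer seed.
#' @return list with `par`, `value`, `trials` (data.frame of all evaluated
#'   configurations with objectives), `n_infeasible`.
#' @export
tpe_optimize <- function(objective, lower, upper, n_trials,
                         n_startup = max(5L, ceiling(n_trials / 4)),
                         gamma = 0.25, n_candidates = 24L,
                         constraint = NULL, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- length(lower)
  n_infeasible <- 0L
  draw_uniform <- function() stats::runif(p, lower, upper)
  feasible <- function(x) is.null(constraint) || isTRUE(constraint(x))
  propose_uniform <- function() {
    for (i in 1:100) {
      x <- draw_uniform()
      if (feasible(x)) return(x)
      n_infeasible <<- n_infeasible + 1L
    }
    stop("could not draw a feasible configuration in 100 attempts")
  }
  X <- matrix(NA_real_, n_trials, p)
  y <- rep(NA_real_, n_trials)
  kde <- function(xs, at, lo, hi) {
    bw <- tryCatch(stats::bw.nrd0(xs), error = function(e) 0)
    bw <- max(bw, (hi - lo) / 50)
    mean(stats::dnorm(at, xs, bw)) + 1e-12
  }
  for (t in seq_len(n_trials)) {
    if (t <= max(n_startup, 2L)) {
      x <- propose_uniform()
    } else {
      done <- seq_len(t - 1L)
      n_good <- max(2L, ceiling(gamma * length(done)))
      ord <- order(y[done], decreasing = TRUE)
      good <- done[ord[seq_len(n_good)]]
      bad <- setdiff(done, good)
      if (length(bad) < 2L) bad <- done
      best_score <- -Inf; x <- NULL
      tries <- 0L
      while (is.null(x) || tries < n_candidates) {
        # sample from the good density: jitter a random good point
        g <- good[sample.int(length(good), 1L)]
        cand <- vapply(seq_len(p), function(j) {
          bw <- tryCatch(stats::bw.nrd0(X[good, j]), error = function(e) 0)
          bw <- max(bw, (upper[j] - lower[j]) / 50)
          min(max(stats::rnorm(1, X[g, j], bw), lower[j]), upper[j])
        }, 0)
        tries <- tries + 1L
        if (!feasible(cand)) { n_infeasible <- n_infeasible + 1L; next }
        score <- sum(vapply(seq_len(p), function(j)
          log(kde(X[good, j], cand[j], lower[j], upper[j])) -
          log(kde(X[bad, j], cand[j], lower[j], upper[j])), 0))
        if (score > best_score) { best_score <- score; x <- cand }
        if (tries >= 4L * n_candidates) break
      }
      if (is.null(x)) x <- propose_uniform()
    }
    X[t, ] <- x
    val <- objective(x)
    if (!is.finite(val)) val <- -Inf
    y[t] <- val
  }
  best <- which.max(y)
  trials <- as.data.frame(X)
  names(trials) <- names(lower) %||% paste0("x", seq_len(p))
  trials$objective <- y
  list(par = X[best, ], value = y[best], trials = trials,
       n_infeasible = n_infeasible)
}
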