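#' PSO configuration
#'
#' Bundles the settings of the multidimensional particle swarm optimizer:
#' swarm size, iteration count, the searched range of dimension indices, the
#' cognitive/social coefficients, the linearly annealed inertia weight, and
#' velocity clamping.
#'
#' @param swarm_size number of particles (S).
#' @param iterations number of optimization iterations (N) after the
#'   initialization sweep.
#' @param dmin,dmax inclusive bounds of the discrete dimension index searched
#'   by the swarm.
#' @param c1,c2 cognitive and social acceleration coefficients. The default
#'   1.49445 is the widely used constricted-PSO value.
#' @param w_start,w_end inertia weight at the first and last iteration; the
#'   weight decreases linearly between them.
#' @param velocity_clamp_fraction each velocity coordinate is clamped to this
#'   fraction of the corresponding search-bound range.
#' @param seed optional integer seed; when given, [mdpso_optimize()] is fully
#'   reproducible.
#' @return an object of class `pso_config`.
#' @export
pso_config <- function(swarm_size, iterations, dmin, dmax,
                       c1 = 1.49445, c2 = 1.49445,
                       w_start = 0.9, w_end = 0.4,
                       velocity_clamp_fraction = 0.2, seed = NULL) {
  stopifnot(swarm_size >= 1, iterations >= 1, dmin <= dmax,
            c1 > 0, c2 > 0, w_start >= w_end,
            velocity_clamp_fraction > 0, velocity_clamp_fraction <= 1)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 dmin = as.integer(dmin), dmax = as.integer(dmax),
                 c1 = c1, c2 = c2, w_start = w_start, w_end = w_end,
                 velocity_clamp_fraction = velocity_clamp_fraction,
                 seed = seed),
            class = "pso_config")
}

#' Linearly annealed inertia weight
#'
#' The inertia weight decreases linearly from `w_start` to `w_end` over the
#' iterations, attaining both endpoints exactly: `w(0) = w_start` and
#' `w(N-1) = w_end`.
#'
#' @param iter 0-based iteration index in `[0, N]`.
#' @param config a [pso_config()].
#' @return the inertia weight at `iter`.
#' @export
inertia_weight <- function(iter, config) {
  N <- config$iterations
  if (any(iter < 0) || any(iter > N)) stop("iter must lie in [0, N]")
  if (N == 1) return(rep(config$w_start, length(iter)))
  config$w_start + (config$w_end - config$w_start) * iter / (N - 1)
}

#' One positional velocity update
#'
#' Computes the new velocity
#' `v <- c1*r1*(pbest - x) + c2*r2*(gbest - x) + w*v` component-wise and
#' clamps each coordinate into `[-vmax, vmax]`. `r1` and `r2` default to
#' fresh uniform draws per coordinate; passing them explicitly makes the
#' update deterministic.
#'
#' @param x,v current position and velocity.
#' @param pbest,gbest personal and global best positions in this dimension.
#' @param w inertia weight.
#' @param c1,c2 acceleration coefficients.
#' @param vmax per-coordinate clamp bound (recycled).
#' @param r1,r2 uniform multipliers in `[0,1]`, drawn per coordinate if `NULL`.
#' @return the clamped new velocity.
#' @export
pso_velocity_step <- function(x, v, pbest, gbest, w, c1, c2, vmax,
                              r1 = NULL, r2 = NULL) {
  n <- length(x)
  if (is.null(r1)) r1 <- stats::runif(n)
  if (is.null(r2)) r2 <- stats::runif(n)
  vnew <- c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x) + w * v
  pmin(pmax(vnew, -vmax), vmax)
}

#' One positional update
#'
#' Adds the velocity to the position and clamps the result into the search
#' bounds.
#'
#' @param x,v position and (already updated) velocity.
#' @param lower,upper search bounds (recycled).
#' @return the new, in-bounds position.
#' @export
pso_position_step <- function(x, v, lower, upper) {
  pmin(pmax(x + v, lower), upper)
}

#' One dimensional (cluster-count) update
#'
#' Updates the dimensional velocity
#' `vd <- c1*r1*(dbest - d) + c2*r2*(dhat - d) + w*vd`, then moves the
#' dimension index to `round(d + vd)` clamped into `[dmin, dmax]`. The
#' dimensional velocity is retained (not zeroed) after clamping.
#'
#' @param d current dimension index; `vd` its dimensional velocity.
#' @param dbest particle's personal best dimension; `dhat` the swarm's best.
#' @param w inertia weight; `c1,c2` acceleration coefficients.
#' @param dmin,dmax dimension bounds.
#' @param r1,r2 uniform multipliers, drawn if `NULL`.
#' @return list with the new integer `d` and real `vd`.
#' @export
pso_dimension_step <- function(d, vd, dbest, dhat, w, c1, c2, dmin, dmax,
                               r1 = NULL, r2 = NULL) {
  if (is.null(r1)) r1 <- stats::runif(1)
  if (is.null(r2)) r2 <- stats::runif(1)
  vd <- c1 * r1 * (dbest - d) + c2 * r2 * (dhat - d) + w * vd
  dnew <- as.integer(min(max(round(d + vd), dmin), dmax))
  list(d = dnew, vd = vd)
}

# Default state transfer when a particle enters a dimension it has never
# visited: copy the nearest stored dimension's position, truncate or pad with
# fresh uniform draws to the new length.
.default_resize <- function(x, lower, upper) {
  n_new <- length(lower)
  n_old <- length(x)
  if (n_old >= n_new) return(x[seq_len(n_new)])
  c(x, stats::runif(n_new - n_old, lower[(n_old + 1):n_new],
                    upper[(n_old + 1):n_new]))
}

#' Multidimensional particle swarm optimization
#'
#' Minimizes a fitness function `rho(x, d)` jointly over a discrete dimension
#' index `d` in `[dmin, dmax]` and a continuous position `x` whose length
#' depends on `d`. Each particle carries an independent positional PSO state
#' per visited dimension index plus a dimensional velocity that lets it
#' migrate between dimensions; the swarm tracks a global best per dimension
#' and the overall best dimension.
#'
#' During initialization every particle is evaluated at all
#' `K = dmax - dmin + 1` dimension indices; afterwards each particle
#' evaluates only its current dimension once per iteration, so the total
#' budget is exactly `S*K + N*S` fitness evaluations. A particle entering a
#' never-visited dimension re-initializes its state there from its nearest
#' stored dimension (truncated or padded with fresh uniform draws).
#' Candidates with non-finite fitness are rejected (counted, never promoted
#' to a best).
#'
#' @param fitness function `(x, d) -> real` to minimize; must be callable for
#'   every `d` in range.
#' @param config a [pso_config()].
#' @param bounds function `d -> list(lower, upper)` giving finite per-coordinate
#'   search bounds for dimension index `d`.
#' @param resize optional function `(x, lower, upper) -> x'` adapting a stored
#'   position to a new dimension's length; the default truncates/pads with
#'   uniform draws.
#' @param init optional function `(d, lower, upper) -> x0` drawing an initial
#'   position for dimension index `d`; the default draws uniformly within the
#'   bounds.
#' @return an object of class `mdpso_fit`: a list with `par` (best position),
#'   `d` (best dimension index), `value` (best fitness), `trace` (data frame
#'   with iteration, particle, d, fitness per evaluation; initialization
#'   rows carry iteration -1), `gbest_history`
#'   (iterations x K matrix of per-dimension global bests), `n_evals`,
#'   `n_rejected`, and `config`.
#' @export
mdpso_optimize <- function(fitness, config, bounds, resize = NULL,
                           init = NULL) {
  stopifnot(inherits(config, "pso_config"), is.function(fitness),
            is.function(bounds))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(resize)) resize <- .default_resize
  if (is.null(init))
    init <- function(d, lower, upper) stats::runif(length(lower), lower, upper)
  S <- config$swarm_size; N <- config$iterations
  dmin <- config$dmin; dmax <- config$dmax
  K <- dmax - dmin + 1L
  dims <- dmin:dmax
  c1 <- config$c1; c2 <- config$c2

  bnd <- lapply(dims, bounds)
  names(bnd) <- as.character(dims)
  for (b in bnd) {
    stopifnot(length(b$lower) == length(b$upper),
              all(is.finite(b$lower)), all(is.finite(b$upper)),
              all(b$upper >= b$lower))
  }
  vmax <- lapply(bnd, function(b)
    config$velocity_clamp_fraction * (b$upper - b$lower))

  n_evals <- 0L; n_rejected <- 0L
  eval_fit <- function(x, d) {
    n_evals <<- n_evals + 1L
    val <- fitness(x, d)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      n_rejected <<- n_rejected + 1L
      return(NA_real_)
    }
    val
  }

  # per-particle state, keyed by dimension index as character
  particles <- vector("list", S)
  gbest_pos <- stats::setNames(vector("list", K), as.character(dims))
  gbest_fit <- stats::setNames(rep(Inf, K), as.character(dims))
  gbest_particle <- NA_integer_

  # initialization sweep: every particle evaluated at every dimension index;
  # recorded in the trace with iteration = -1
  init_trace <- data.frame(iteration = rep(-1L, S * K),
                           particle = rep(seq_len(S), each = K),
                           d = rep(dims, S), fitness = NA_real_)
  for (k in seq_len(S)) {
    pos <- vel <- pb_pos <- stats::setNames(vector("list", K),
                                            as.character(dims))
    pb_fit <- stats::setNames(rep(Inf, K), as.character(dims))
    for (d in dims) {
      key <- as.character(d)
      b <- bnd[[key]]
      x0 <- pmin(pmax(init(d, b$lower, b$upper), b$lower), b$upper)
      pos[[key]] <- x0
      vel[[key]] <- numeric(length(x0))
      f0 <- eval_fit(x0, d)
      init_trace$fitness[(k - 1L) * K + (d - dmin + 1L)] <- f0
      pb_pos[[key]] <- x0
      pb_fit[key] <- if (is.na(f0)) Inf else f0
      if (!is.na(f0) && f0 < gbest_fit[key]) {
        gbest_fit[key] <- f0
        gbest_pos[[key]] <- x0
        if (f0 <= min(gbest_fit)) gbest_particle <- k
      }
    }
    particles[[k]] <- list(
      pos = pos, vel = vel, pb_pos = pb_pos, pb_fit = pb_fit,
      d = sample(dims, 1L), vd = 0,
      dbest = dims[which.min(pb_fit)])
  }

  trace <- data.frame(iteration = rep(seq_len(N) - 1L, each = S),
                      particle = rep(seq_len(S), N),
                      d = NA_integer_, fitness = NA_real_)
  gbest_history <- matrix(NA_real_, N, K, dimnames = list(NULL, dims))

  for (t in seq_len(N) - 1L) {
    w <- inertia_weight(t, config)
    dhat <- dims[which.min(gbest_fit)]
    for (k in seq_len(S)) {
      p <- particles[[k]]
      # dimensional PSO step
      upd <- pso_dimension_step(p$d, p$vd, p$dbest, dhat, w, c1, c2,
                                dmin, dmax)
      p$d <- upd$d; p$vd <- upd$vd
      key <- as.character(p$d)
      b <- bnd[[key]]
      if (is.null(p$pos[[key]])) {
        # entering a never-visited dimension: transfer nearest stored state
        stored <- as.integer(names(Filter(Negate(is.null), p$pos)))
        src <- stored[which.min(abs(stored - p$d))]
        x0 <- resize(p$pos[[as.character(src)]], b$lower, b$upper)
        p$pos[[key]] <- pmin(pmax(x0, b$lower), b$upper)
        p$vel[[key]] <- numeric(length(b$lower))
        p$pb_pos[[key]] <- p$pos[[key]]
        p$pb_fit[key] <- Inf
      }
      # positional PSO step against the per-dimension global best
      gb <- gbest_pos[[key]]
      if (is.null(gb)) gb <- p$pb_pos[[key]]
      p$vel[[key]] <- pso_velocity_step(p$pos[[key]], p$vel[[key]],
                                        p$pb_pos[[key]], gb, w, c1, c2,
                                        vmax[[key]])
      p$pos[[key]] <- pso_position_step(p$pos[[key]], p$vel[[key]],
                                        b$lower, b$upper)
      f <- eval_fit(p$pos[[key]], p$d)
      row <- t * S + k
      trace$d[row] <- p$d
      trace$fitness[row] <- if (is.na(f)) NA_real_ else f
      if (!is.na(f)) {
        if (f < p$pb_fit[key]) {
          p$pb_fit[key] <- f
          p$pb_pos[[key]] <- p$pos[[key]]
          p$dbest <- dims[which.min(p$pb_fit[as.character(dims)])]
        }
        if (f < gbest_fit[key]) {
          gbest_fit[key] <- f
          gbest_pos[[key]] <- p$pos[[key]]
          if (f <= min(gbest_fit)) gbest_particle <- k
        }
      }
      particles[[k]] <- p
    }
    gbest_history[t + 1L, ] <- gbest_fit
  }

  trace <- rbind(init_trace, trace)
  dhat <- dims[which.min(gbest_fit)]
  structure(list(par = gbest_pos[[as.character(dhat)]], d = dhat,
                 value = unname(min(gbest_fit)),
                 gbest_per_dim = gbest_fit,
                 gbest_particle = gbest_particle,
                 trace = trace, gbest_history = gbest_history,
                 n_evals = n_evals, n_rejected = n_rejected,
                 config = config),
            class = "mdpso_fit")
}

#' @export
print.mdpso_fit <- function(x, ...) {
  cat("Multidimensional PSO fit\n")
  cat(sprintf("  best dimension index d^: %d (searched %d..%d)\n",
              x$d, x$config$dmin, x$config$dmax))
  cat(sprintf("  best fitness: %.6g\n", x$value))
  cat(sprintf("  position length: %d\n", length(x$par)))
  cat(sprintf("  fitness evaluations: %d (%d rejected)\n",
              x$n_evals, x$n_rejected))
  invisible(x)
}
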