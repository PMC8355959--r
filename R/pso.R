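#' Particle swarm configuration
#'
#' Defaults are the constriction-equivalent coefficients in wide use
#' (inertia 0.729, cognitive and social accelerations 1.49445) with a swarm
#' of 30 particles and a fixed budget of 200 iterations.
#'
#' @param n_particles swarm size N (>= 2).
#' @param dimension search-space dimension D (>= 1).
#' @param inertia inertia weight w (>= 0).
#' @param c1,c2 cognitive and social acceleration coefficients (>= 0).
#' @param max_iterations iteration budget (>= 0).
#' @param position_bounds 2 x D matrix (rows: lower, upper) or length-2
#'   vector recycled across dimensions.
#' @param velocity_clamp optional fraction of each dimension's range used as
#'   a symmetric velocity limit; NULL disables clamping.
#' @param patience early-stop window: stop when the incumbent improves by
#'   less than `tol` over this many iterations; NULL disables early stopping.
#' @param tol improvement tolerance for early stopping.
#' @param seed integer seed.
#' @return a `pso_config`.
#' @export
pso_config <- function(n_particles = 30L, dimension,
                       inertia = 0.729, c1 = 1.49445, c2 = 1.49445,
                       max_iterations = 200L,
                       position_bounds = c(-1, 1),
                       velocity_clamp = NULL,
                       patience = NULL, tol = 1e-10,
                       seed = 42L) {
  stop_if_not_count(n_particles, "n_particles", min = 2L)
  stop_if_not_count(dimension, "dimension", min = 1L)
  stop_if_not_count(max_iterations, "max_iterations", min = 0L)
  stopifnot(inertia >= 0, c1 >= 0, c2 >= 0)
  if (is.vector(position_bounds) && length(position_bounds) == 2L) {
    position_bounds <- matrix(rep(position_bounds, dimension), nrow = 2L)
  }
  stopifnot(is.matrix(position_bounds), nrow(position_bounds) == 2L,
            ncol(position_bounds) == dimension,
            all(position_bounds[1L, ] < position_bounds[2L, ]))
  structure(
    list(n_particles = as.integer(n_particles),
         dimension = as.integer(dimension),
         inertia = inertia, c1 = c1, c2 = c2,
         max_iterations = as.integer(max_iterations),
         position_bounds = position_bounds,
         velocity_clamp = velocity_clamp,
         patience = patience, tol = tol,
         seed = as.integer(seed)),
    class = "pso_config"
  )
}

#' One velocity update
#'
#' `v' = w v + c1 r1 (p - x) + c2 r2 (g - x)` componentwise, with independent
#' uniform(0, 1) draws `r1`, `r2` per dimension, then clamped if a velocity
#' limit is configured.
#'
#' @param v,x current velocity and position (length D).
#' @param p,g personal-best and global-best positions (length D).
#' @param config a `pso_config`.
#' @param r1,r2 the uniform draws (length D); supplied by the optimizer loop,
#'   exposed here so the update is a pure function.
#' @export
update_velocity <- function(v, x, p, g, config, r1, r2) {
  D <- config$dimension
  stopifnot(length(v) == D, length(x) == D, length(p) == D, length(g) == D,
            length(r1) == D, length(r2) == D)
  v_next <- config$inertia * v + config$c1 * r1 * (p - x) + config$c2 * r2 * (g - x)
  if (!is.null(config$velocity_clamp)) {
    vmax <- config$velocity_clamp *
      (config$position_bounds[2L, ] - config$position_bounds[1L, ])
    v_next <- pmin(pmax(v_next, -vmax), vmax)
  }
  v_next
}

#' One position update
#'
#' `x' = x + v'`, then clipped to the position bounds; the velocity component
#' of any clipped dimension is zeroed so particles do not press against the
#' box.
#' @inheritParams update_velocity
#' @param v_next the updated velocity.
#' @return list with `x` and (possibly modified) `v`.
#' @export
update_position <- function(x, v_next, config) {
  lo <- config$position_bounds[1L, ]
  hi <- config$position_bounds[2L, ]
  x_next <- x + v_next
  below <- x_next < lo
  above <- x_next > hi
  x_next[below] <- lo[below]
  x_next[above] <- hi[above]
  v_next[below | above] <- 0
  list(x = x_next, v = v_next)
}

#' Minimize a function by particle swarm
#'
#' Initial positions are uniform within the bounds and initial velocities are
#' zero. Each iteration updates every particle's velocity and position,
#' evaluates the fitness, and keeps personal and global incumbents under the
#' replace-if-better rule, so the global-best fitness trace is non-increasing.
#' Non-finite fitness values are treated as `+Inf` with a warning.
#'
#' @param fitness_fn function mapping a length-D numeric vector to a scalar;
#'   lower is better.
#' @param config a `pso_config`.
#' @return list with `best_position`, `best_fitness`, `fitness_history`
#'   (global best after initialization and after each iteration), and
#'   `iterations` actually run.
#' @export
pso_optimize <- function(fitness_fn, config) {
  stopifnot(inherits(config, "pso_config"), is.function(fitness_fn))
  N <- config$n_particles
  D <- config$dimension
  lo <- config$position_bounds[1L, ]
  hi <- config$position_bounds[2L, ]

  eval_fitness <- function(pos) {
    val <- fitness_fn(pos)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      warning("non-finite fitness treated as +Inf", call. = FALSE)
      return(Inf)
    }
    val
  }

  with_seed(config$seed, {
    x <- matrix(stats::runif(N * D, rep(lo, each = N), rep(hi, each = N)), N, D)
    v <- matrix(0, N, D)
    p_fit <- apply(x, 1L, eval_fitness)
    p <- x
    gi <- which.min(p_fit)
    g <- p[gi, ]
    g_fit <- p_fit[gi]
    history <- numeric(config$max_iterations + 1L)
    history[1L] <- g_fit

    iter <- 0L
    while (iter < config$max_iterations) {
      iter <- iter + 1L
      for (i in seq_len(N)) {
        r1 <- stats::runif(D)
        r2 <- stats::runif(D)
        v_next <- update_velocity(v[i, ], x[i, ], p[i, ], g, config, r1, r2)
        upd <- update_position(x[i, ], v_next, config)
        x[i, ] <- upd$x
        v[i, ] <- upd$v
        fit <- eval_fitness(upd$x)
        if (fit < p_fit[i]) {
          p_fit[i] <- fit
          p[i, ] <- upd$x
          if (fit < g_fit) {
            g_fit <- fit
            g <- upd$x
          }
        }
      }
      history[iter + 1L] <- g_fit
      if (!is.null(config$patience) && iter > config$patience) {
        if (history[iter + 1L - config$patience] - g_fit < config$tol) break
      }
    }

    list(best_position = g, best_fitness = g_fit,
         fitness_history = history[seq_len(iter + 1L)],
         iterations = iter)
  })
}
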