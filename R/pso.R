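#' Particle swarm optimizer settings
#'
#' Hyperparameters of the swarm: size, inertia weight, cognitive and
#' social learning factors, iteration budget and velocity clamp. Defaults
#' are the constriction-equivalent setting (inertia 0.729, learning
#' factors 1.494), swarm of 30 and 200 iterations; all configurable.
#'
#' @param swarm_size number of particles m (>= 1).
#' @param max_iters iteration budget (>= 1); the swarm always runs the
#'   full budget (no early stopping).
#' @param inertia inertia weight applied to the previous velocity.
#' @param c1,c2 cognitive (personal-best) and social (global-best)
#'   learning factors.
#' @param velocity_clamp maximum |velocity| per dimension, as a fraction
#'   of that dimension's bound span.
#' @param seed optional integer seed for reproducible runs.
#' @return An object of class `"pso_control"` (list).
#' @export
pso_control <- function(swarm_size = 30L, max_iters = 200L,
                        inertia = 0.729, c1 = 1.494, c2 = 1.494,
                        velocity_clamp = 0.5, seed = NULL) {
  stopifnot(swarm_size >= 1L, max_iters >= 1L, velocity_clamp > 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iters = as.integer(max_iters),
                 inertia = inertia, c1 = c1, c2 = c2,
                 velocity_clamp = velocity_clamp, seed = seed),
            class = "pso_control")
}

# run fn with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Minimize a function over a box with particle swarm optimization
#'
#' Standard global-best PSO. Each particle i updates, per dimension k,
#' \deqn{v_{ik} \leftarrow \omega v_{ik} + C_1\,r_1\,(l_{ik} - x_{ik})
#'   + C_2\,r_2\,(l_{gk} - x_{ik}), \qquad
#'   x_{ik} \leftarrow x_{ik} + v_{ik}}
#' with \eqn{r_1, r_2 \sim U(0,1)}, personal best \eqn{l_i} and global
#' best \eqn{l_g}. Velocities are clamped to a fraction of the bound
#' span; positions are clipped to the box and the violating velocity
#' component zeroed. The swarm runs a fixed iteration budget and returns
#' the best position found.
#'
#' @param objective function of a length-K numeric vector returning a
#'   finite scalar; `NaN` aborts with an error naming the position.
#' @param lower,upper numeric vectors of box bounds (lower < upper).
#' @param control a [pso_control()] object.
#' @param init_position optional matrix (swarm_size x K) of starting
#'   positions; default uniform in the box.
#' @param init_velocity optional matrix of starting velocities; default
#'   uniform in +/- clamp.
#'
#' @return A list of class `"pso_fit"`: `par` (best position), `value`
#'   (best objective), `history` (global-best value after initialization
#'   and after each iteration, length `max_iters + 1`, non-increasing),
#'   `iterations`, `evaluations`.
#' @examples
#' fit <- pso_minimize(function(x) (x - 3)^2, lower = 0, upper = 10,
#'                     control = pso_control(seed = 1))
#' fit$par
#' @export
pso_minimize <- function(objective, lower, upper, control = pso_control(),
                         init_position = NULL, init_velocity = NULL) {
  stopifnot(is.function(objective), length(lower) == length(upper),
            all(lower < upper), inherits(control, "pso_control"))
  K <- length(lower)
  m <- control$swarm_size
  span <- upper - lower
  vmax <- control$velocity_clamp * span

  evalf <- function(x) {
    v <- objective(x)
    if (!is.numeric(v) || length(v) != 1L || is.nan(v))
      stop("objective returned NaN/non-scalar at position (",
           paste(format(x), collapse = ", "), ")", call. = FALSE)
    v
  }

  with_seed(control$seed, function() {
    X <- if (is.null(init_position)) {
      matrix(stats::runif(m * K), m, K) %*% diag(span, K) +
        matrix(lower, m, K, byrow = TRUE)
    } else {
      stopifnot(nrow(init_position) == m, ncol(init_position) == K)
      init_position
    }
    V <- if (is.null(init_velocity)) {
      matrix(stats::runif(m * K, -1, 1), m, K) %*% diag(vmax, K)
    } else init_velocity

    pbest <- X
    pval <- apply(X, 1L, evalf)
    g <- which.min(pval)
    gbest <- X[g, ]; gval <- pval[g]
    history <- numeric(control$max_iters + 1L)
    history[1L] <- gval
    nev <- m

    for (it in seq_len(control$max_iters)) {
      r1 <- matrix(stats::runif(m * K), m, K)
      r2 <- matrix(stats::runif(m * K), m, K)
      V <- control$inertia * V +
        control$c1 * r1 * (pbest - X) +
        control$c2 * r2 * (matrix(gbest, m, K, byrow = TRUE) - X)
      V <- pmin(pmax(V, matrix(-vmax, m, K, byrow = TRUE)),
                matrix(vmax, m, K, byrow = TRUE))
      X <- X + V
      lo <- X < matrix(lower, m, K, byrow = TRUE)
      hi <- X > matrix(upper, m, K, byrow = TRUE)
      V[lo | hi] <- 0
      X <- pmin(pmax(X, matrix(lower, m, K, byrow = TRUE)),
                matrix(upper, m, K, byrow = TRUE))
      val <- apply(X, 1L, evalf)
      nev <- nev + m
      better <- val < pval
      pbest[better, ] <- X[better, , drop = FALSE]
      pval[better] <- val[better]
      g <- which.min(pval)
      if (pval[g] < gval) { gval <- pval[g]; gbest <- pbest[g, ] }
      history[it + 1L] <- gval
    }
    structure(list(par = gbest, value = gval, history = history,
                   iterations = control$max_iters, evaluations = nev),
              class = "pso_fit")
  })
}

#' @export
print.pso_fit <- function(x, ...) {
  cat(sprintf("PSO: best value %.6g after %d iterations (%d evaluations)\n",
              x$value, x$iterations, x$evaluations))
  cat("  par:", paste(format(x$par, digits = 6), collapse = ", "), "\n")
  invisible(x)
}
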