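#' Identify Hill pharmacodynamic parameters from an observed BIS trace
#'
#' Fits the sigmoid Emax model \eqn{BIS(t) = E_0 - E_{max}\,
#' C_e(t)^{\gamma} / (EC_{50}^{\gamma} + C_e(t)^{\gamma})} to an observed
#' BIS trace by minimizing the root-mean-square error with particle swarm
#' optimization over \eqn{\theta = (E_0, E_{max}, EC_{50}, \gamma)}.
#' Optionally the effect-site equilibration constant ke0 is appended to
#' the search vector, in which case `ce` must carry the plasma
#' concentration (`C1`) so the effect-site trace can be re-derived for
#' each candidate ke0.
#'
#' Because PSO is stochastic, `restarts` independent swarms (seeds
#' `seed, seed+1, ...`) are run and the best solution kept.
#'
#' @param observed numeric vector of observed BIS values, or a
#'   `bis_trace` data.frame with a `bis` column.
#' @param ce effect-site concentrations on the same grid, or a
#'   `conc_trace` data.frame (its `Ce` column is used; `C1` and `time`
#'   are used when `fit_ke0 = TRUE`).
#' @param bounds 2-row matrix (`rbind(lower, upper)`) of search bounds in
#'   the order E0, Emax, EC50, gamma (and ke0 when fitted). Default:
#'   E0 in \[80, 100\], Emax in \[40, 100\], EC50 in \[0.5, 10\] ug/mL,
#'   gamma in \[0.5, 6\] (ke0 in \[0.1, 1.5\] 1/min).
#' @param control a [pso_control()]; its `seed` field seeds the first
#'   restart.
#' @param restarts number of independent swarm runs (best kept).
#' @param fit_ke0 logical; include ke0 in the search vector.
#'
#' @return An object of class `"pd_fit"`: list with elements `pd`
#'   (a [pd_params()]), `ke0` (fitted or `NA`), `objective` (RMSE at the
#'   optimum), `metrics` (an [eval_report()]), `history` (global-best RMSE
#'   per iteration of the winning restart), `observed`, `ce`, `fitted`,
#'   `time`, `bounds`. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `simulate`, `plot`.
#' @examples
#' pd <- pd_params(92, 70, 2.5, 2.2)
#' ce <- seq(0, 6, length.out = 200)
#' obs <- bis_from_ce(ce, pd)
#' fit <- fit_pd(obs, ce, control = pso_control(seed = 7), restarts = 2)
#' coef(fit)
#' @export
fit_pd <- function(observed, ce, bounds = NULL,
                   control = pso_control(), restarts = 1L,
                   fit_ke0 = FALSE) {
  time <- NULL
  c1 <- NULL
  if (is.data.frame(observed)) {
    if (!"bis" %in% names(observed))
      stop("'observed' data.frame must have a 'bis' column", call. = FALSE)
    time <- observed$time
    observed <- observed$bis
  }
  if (is.data.frame(ce)) {
    if (!is.null(ce$time)) {
      if (!is.null(time) && (length(time) != length(ce$time) ||
                             any(abs(time - ce$time) > 1e-9)))
        stop("observed and concentration traces are on different time grids",
             call. = FALSE)
      time <- ce$time
    }
    c1 <- ce$C1
    ce <- ce$Ce
  }
  if (length(observed) == 0L) stop("empty trace", call. = FALSE)
  if (length(observed) != length(ce))
    stop("'observed' and 'ce' must share a grid (equal lengths)",
         call. = FALSE)
  if (fit_ke0 && (is.null(c1) || is.null(time)))
    stop("fit_ke0 = TRUE requires a conc_trace with 'time' and 'C1'",
         call. = FALSE)

  if (is.null(bounds)) {
    bounds <- rbind(lower = c(e0 = 80, emax = 40, ec50 = 0.5, gamma = 0.5),
                    upper = c(e0 = 100, emax = 100, ec50 = 10, gamma = 6))
    if (fit_ke0)
      bounds <- cbind(bounds, ke0 = c(0.1, 1.5))
  }
  K <- ncol(bounds)
  par_names <- colnames(bounds)

  obj <- function(theta) {
    ce_th <- if (fit_ke0) effect_site(time, c1, theta[5L]) else ce
    pd <- list(e0 = theta[1L], emax = theta[2L], ec50 = theta[3L],
               gamma = theta[4L])
    sqrt(mean((observed - bis_from_ce(pmax(ce_th, 0), pd))^2))
  }

  seed0 <- control$seed
  best <- NULL
  for (r in seq_len(restarts)) {
    ctl <- control
    ctl$seed <- if (is.null(seed0)) NULL else seed0 + (r - 1L)
    run <- pso_minimize(obj, bounds[1L, ], bounds[2L, ], control = ctl)
    if (is.null(best) || run$value < best$value) best <- run
  }

  theta <- best$par
  names(theta) <- par_names
  pd <- pd_params(theta[["e0"]], min(theta[["emax"]], theta[["e0"]]),
                  theta[["ec50"]], theta[["gamma"]])
  ke0_hat <- if (fit_ke0) theta[["ke0"]] else NA_real_
  ce_fit <- if (fit_ke0) effect_site(time, c1, ke0_hat) else ce
  fitted_bis <- bis_from_ce(pmax(ce_fit, 0), pd)

  # constant observed traces leave R2 undefined (degenerate but legal input)
  metrics <- tryCatch(eval_report(observed, fitted_bis),
                      error = function(e) structure(
                        list(r2 = NA_real_,
                             rmse = rmse(observed, fitted_bis),
                             mape = if (all(observed != 0))
                               mape(observed, fitted_bis) else NA_real_,
                             n = length(observed)),
                        class = "eval_report"))

  structure(list(pd = pd, ke0 = ke0_hat, objective = best$value,
                 metrics = metrics,
                 history = best$history,
                 observed = observed, ce = ce_fit, fitted = fitted_bis,
                 time = time, bounds = bounds, restarts = restarts),
            class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, digits = 4, ...) {
  cat("Hill PD model identified by particle swarm optimization\n")
  print(x$pd, digits = digits)
  if (!is.na(x$ke0)) cat(sprintf("  ke0 = %.*g 1/min\n", digits, x$ke0))
  cat(sprintf("  RMSE %.*g over %d points (R2 = %.*g)\n", digits,
              x$objective, length(x$observed), digits, x$metrics$r2))
  invisible(x)
}

#' @export
coef.pd_fit <- function(object, ...) {
  cf <- c(e0 = object$pd$e0, emax = object$pd$emax,
          ec50 = object$pd$ec50, gamma = object$pd$gamma)
  if (!is.na(object$ke0)) cf <- c(cf, ke0 = object$ke0)
  cf
}

#' @export
fitted.pd_fit <- function(object, ...) object$fitted

#' @export
residuals.pd_fit <- function(object, ...) object$observed - object$fitted

#' Predict BIS for new effect-site concentrations
#'
#' @param object a `pd_fit`.
#' @param newdata numeric vector of effect-site concentrations; default
#'   the training trace.
#' @param ... unused.
#' @return Predicted BIS values.
#' @export
predict.pd_fit <- function(object, newdata = NULL, ...) {
  ce <- if (is.null(newdata)) object$ce else newdata
  bis_from_ce(pmax(ce, 0), object$pd)
}

#' @export
summary.pd_fit <- function(object, ...) {
  out <- list(coef = coef(object), metrics = object$metrics,
              n = length(object$observed),
              iterations = length(object$history) - 1L,
              restarts = object$restarts,
              converged_value = object$objective)
  class(out) <- "summary.pd_fit"
  out
}

#' @export
print.summary.pd_fit <- function(x, digits = 4, ...) {
  cat("Identified Hill PD parameters:\n")
  print(round(x$coef, digits))
  cat(sprintf("Swarm: %d iterations x %d restart(s); final RMSE %.*g\n",
              x$iterations, x$restarts, digits, x$converged_value))
  print(x$metrics, digits = digits)
  invisible(x)
}

#' Simulate noisy BIS observations from a fitted PD model
#'
#' Draws `nsim` replicate traces: fitted BIS plus i.i.d. Gaussian noise
#' with the residual standard deviation, clipped to \[0, 100\].
#'
#' @param object a `pd_fit`.
#' @param nsim number of replicate traces.
#' @param seed optional seed.
#' @param ... unused.
#' @return A matrix with one column per replicate.
#' @export
simulate.pd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sd_hat <- stats::sd(residuals(object))
  n <- length(object$fitted)
  with_seed(seed, function() {
    sims <- matrix(stats::rnorm(n * nsim, mean = object$fitted, sd = sd_hat),
                   n, nsim)
    pmin(pmax(sims, 0), 100)
  })
}

#' Plot an identified PD fit
#'
#' Observed vs fitted BIS over time (or index when no grid is attached),
#' with the swarm's convergence history in a second panel.
#'
#' @param x a `pd_fit`.
#' @param ... passed to `plot`.
#' @export
plot.pd_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tt <- if (is.null(x$time)) seq_along(x$observed) else x$time
  plot(tt, x$observed, type = "l", col = "grey40",
       xlab = if (is.null(x$time)) "index" else "time (min)",
       ylab = "BIS", main = "Observed vs fitted BIS", ...)
  graphics::lines(tt, x$fitted, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("observed", "fitted"),
                   col = c("grey40", "firebrick"), lwd = c(1, 2), bty = "n")
  plot(seq_along(x$history) - 1L, x$history, type = "s",
       xlab = "iteration", ylab = "best RMSE",
       main = "Swarm convergence")
  invisible(x)
}
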