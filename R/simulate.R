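#' Sigmoid Emax (Hill) pharmacodynamic parameters
#'
#' Parameters of the BIS model
#' \deqn{BIS = E_0 - E_{max}\,\frac{C_e^{\gamma}}{EC_{50}^{\gamma} +
#'   C_e^{\gamma}}}
#' where \eqn{E_0} is the awake (zero-drug) BIS, \eqn{E_{max}} the maximal
#' BIS depression, \eqn{EC_{50}} the effect-site concentration producing
#' half-maximal depression, and \eqn{\gamma} the Hill steepness.
#'
#' @param e0 awake BIS, in (0, 100].
#' @param emax maximal BIS depression, in (0, e0].
#' @param ec50 half-maximal effect-site concentration (ug/mL), > 0.
#' @param gamma Hill coefficient (dimensionless), > 0.
#'
#' @return An object of class `"pd_params"` (named list).
#' @examples
#' pd_params(e0 = 95, emax = 75, ec50 = 2.5, gamma = 2)
#' @export
pd_params <- function(e0, emax, ec50, gamma) {
  for (nm in c("e0", "emax", "ec50", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (e0 <= 0 || e0 > 100) stop("'e0' must be in (0, 100]", call. = FALSE)
  if (emax <= 0 || emax > e0)
    stop("'emax' must be in (0, e0]", call. = FALSE)
  if (ec50 <= 0) stop("'ec50' must be > 0", call. = FALSE)
  if (gamma <= 0) stop("'gamma' must be > 0", call. = FALSE)
  structure(list(e0 = e0, emax = emax, ec50 = ec50, gamma = gamma),
            class = "pd_params")
}

#' @export
print.pd_params <- function(x, digits = 4, ...) {
  cat(sprintf("Hill PD parameters: E0 = %.*g, Emax = %.*g, EC50 = %.*g ug/mL, gamma = %.*g\n",
              digits, x$e0, digits, x$emax, digits, x$ec50, digits, x$gamma))
  invisible(x)
}

#' BIS from effect-site concentration (Hill model)
#'
#' @param ce effect-site concentration(s), ug/mL, >= 0 (vectorized).
#' @param pd a [pd_params()] object.
#' @return BIS value(s), strictly decreasing in `ce`, bounded in
#'   `[e0 - emax, e0]`.
#' @examples
#' bis_from_ce(0, pd_params(95, 75, 2.5, 2))   # 95
#' bis_from_ce(2.5, pd_params(95, 75, 2.5, 2)) # 95 - 75/2
#' @export
bis_from_ce <- function(ce, pd) {
  stopifnot(is.numeric(ce))
  if (any(ce < 0)) stop("'ce' must be >= 0", call. = FALSE)
  cg <- ce^pd$gamma
  pd$e0 - pd$emax * cg / (pd$ec50^pd$gamma + cg)
}

#' Simulate compartment and effect-site concentrations
#'
#' Integrates the mammillary three-compartment disposition system
#' \deqn{\dot C_1 = -(k_{10}+k_{12}+k_{13})C_1 + k_{21}\frac{V_2}{V_1}C_2 +
#'   k_{31}\frac{V_3}{V_1}C_3 + \frac{u(t)}{V_1}}
#' \deqn{\dot C_2 = k_{12}\frac{V_1}{V_2}C_1 - k_{21}C_2, \qquad
#'       \dot C_3 = k_{13}\frac{V_1}{V_3}C_1 - k_{31}C_3}
#' with piecewise-constant infusion rate u(t) (mg/min) from the protocol
#' and boluses applied as instantaneous jumps `dose/V1` in `C1`.
#' The effect-site concentration follows the first-order link
#' \eqn{\dot C_e = k_{e0}(C_1 - C_e)}.
#'
#' Integration uses an adaptive stiff-capable solver (`deSolve::lsoda`,
#' rtol 1e-8 / atol 1e-10), restarted at every bolus and segment boundary
#' so input discontinuities are handled exactly; the solution is reported
#' on the requested grid.
#'
#' @param params a [pk_params()] object.
#' @param protocol an [infusion_protocol()].
#' @param times strictly increasing time grid (min), starting at >= 0.
#' @param ke0 effect-site equilibration rate constant (1/min, >= 0).
#'   Default 0.456, the standard literature value for this covariate model.
#' @param initial_state named numeric vector `c(C1, C2, C3, Ce)` at
#'   `times[1]`; default all zero.
#'
#' @return An object of class `"conc_trace"`: a data.frame with columns
#'   `time` (min) and `C1`, `C2`, `C3`, `Ce` (ug/mL).
#' @examples
#' p <- patient("ref", 53, 77, 177, "male")
#' prot <- infusion_protocol(boluses = data.frame(time = 0, dose = 90))
#' simulate_concentrations(pk_params(p), prot, times = seq(0, 10, 0.5))
#' @export
simulate_concentrations <- function(params, protocol, times, ke0 = 0.456,
                                    initial_state = c(C1 = 0, C2 = 0,
                                                      C3 = 0, Ce = 0)) {
  stopifnot(inherits(params, "pk_params"),
            inherits(protocol, "infusion_protocol"))
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be a strictly increasing grid of length >= 2",
         call. = FALSE)
  if (!is.numeric(ke0) || length(ke0) != 1L || ke0 < 0)
    stop("'ke0' must be a single number >= 0", call. = FALSE)
  state <- c(C1 = 0, C2 = 0, C3 = 0, Ce = 0)
  state[names(initial_state)] <- initial_state

  t0 <- times[1L]; t1 <- times[length(times)]
  seg <- protocol$segments; bol <- protocol$boluses
  # integrate piecewise between input discontinuities
  brk <- sort(unique(c(t0, t1,
                       bol$time, seg$t_start, seg$t_end)))
  brk <- brk[brk >= t0 & brk <= t1]

  deriv <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      dC1 <- -(k10 + k12 + k13) * C1 + k21 * V2 / V1 * C2 +
        k31 * V3 / V1 * C3 + u / V1
      dC2 <- k12 * V1 / V2 * C1 - k21 * C2
      dC3 <- k13 * V1 / V3 * C1 - k31 * C3
      dCe <- ke0 * (C1 - Ce)
      list(c(dC1, dC2, dC3, dCe))
    })
  }

  base_parms <- c(unlist(params[c("V1", "V2", "V3",
                                  "k10", "k12", "k13", "k21", "k31")]),
                  ke0 = ke0)
  out <- matrix(NA_real_, nrow = length(times), ncol = 4L,
                dimnames = list(NULL, c("C1", "C2", "C3", "Ce")))
  apply_boluses <- function(state, at) {
    hit <- which(bol$time == at)
    if (length(hit))
      state["C1"] <- state["C1"] + sum(bol$dose[hit]) / params$V1
    state
  }
  state <- apply_boluses(state, t0)
  if (times[1L] == t0) out[1L, ] <- state

  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    if (i > 1L) state <- apply_boluses(state, a)
    u <- infusion_rate(protocol, a)
    idx <- which(times > a & times <= b)
    tt <- unique(c(a, times[idx], b))
    sol <- deSolve::lsoda(y = state, times = tt, func = deriv,
                          parms = c(base_parms, u = u),
                          rtol = 1e-8, atol = 1e-10)
    if (length(idx))
      out[idx, ] <- sol[match(times[idx], sol[, "time"]), -1L, drop = FALSE]
    state <- sol[nrow(sol), -1L]
  }
  res <- data.frame(time = times, out)
  class(res) <- c("conc_trace", "data.frame")
  res
}

#' @export
print.conc_trace <- function(x, ...) {
  cat(sprintf("Concentration trace: %d points over [%.2f, %.2f] min; peak C1 = %.3f, peak Ce = %.3f ug/mL\n",
              nrow(x), x$time[1L], x$time[nrow(x)], max(x$C1), max(x$Ce)))
  invisible(x)
}

#' Simulate a BIS trace for a patient under a dosing protocol
#'
#' Composes [simulate_concentrations()] with [bis_from_ce()]: the PK
#' parameters are derived from the patient's covariates, the effect-site
#' concentration is propagated with rate `ke0`, and the Hill model maps it
#' to BIS pointwise.
#'
#' @inheritParams simulate_concentrations
#' @param patient a [patient()] object.
#' @param pd a [pd_params()] object.
#' @return A data.frame of class `"bis_trace"` with columns `time`, `bis`
#'   and (as attribute `"conc"`) the underlying concentration trace.
#' @export
simulate_bis <- function(patient, protocol, pd, times, ke0 = 0.456) {
  conc <- simulate_concentrations(pk_params(patient), protocol, times,
                                  ke0 = ke0)
  bis <- bis_from_ce(pmax(conc$Ce, 0), pd)
  res <- data.frame(time = times, bis = bis)
  attr(res, "conc") <- conc
  class(res) <- c("bis_trace", "data.frame")
  res
}

#' @export
print.bis_trace <- function(x, ...) {
  cat(sprintf("BIS trace: %d points over [%.2f, %.2f] min; range [%.1f, %.1f]\n",
              nrow(x), x$time[1L], x$time[nrow(x)], min(x$bis), max(x$bis)))
  invisible(x)
}

#' First-order effect-site filter applied to a plasma concentration trace
#'
#' Solves \eqn{\dot C_e = k_{e0}(C_1 - C_e)} on the trace's grid assuming
#' C1 varies linearly between grid points (exact exponential update per
#' step). Used when re-deriving Ce for a candidate ke0 during
#' identification without re-running the full ODE solver.
#'
#' @param time strictly increasing time grid (min).
#' @param c1 plasma concentrations on that grid.
#' @param ke0 equilibration rate constant (1/min, > 0).
#' @param ce0 initial effect-site concentration.
#' @return Numeric vector of effect-site concentrations.
#' @export
effect_site <- function(time, c1, ke0, ce0 = 0) {
  stopifnot(length(time) == length(c1), ke0 > 0)
  n <- length(time)
  ce <- numeric(n)
  ce[1L] <- ce0
  for (i in seq_len(n - 1L)) {
    h <- time[i + 1L] - time[i]
    e <- exp(-ke0 * h)
    slope <- (c1[i + 1L] - c1[i]) / h
    # exact response to linear input: Ce' = ke0 (a + s(t-t_i) - Ce)
    ce[i + 1L] <- c1[i] + slope * h - slope / ke0 +
      (ce[i] - c1[i] + slope / ke0) * e
  }
  ce
}
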