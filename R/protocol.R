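#' Infusion protocol: timed boluses plus constant-rate segments
#'
#' Describes the drug input \eqn{u(t)} driving the central compartment:
#' instantaneous boluses (mg) at given times and non-overlapping
#' constant-rate infusion segments (mg/min).
#'
#' @param boluses data.frame with columns `time` (min, >= 0) and `dose`
#'   (mg, >= 0); may be empty or `NULL`.
#' @param segments data.frame with columns `t_start`, `t_end` (min) and
#'   `rate` (mg/min, >= 0); segments must satisfy `t_start < t_end` and may
#'   not overlap. May be empty or `NULL`.
#'
#' @return An object of class `"infusion_protocol"`.
#' @examples
#' infusion_protocol(boluses = data.frame(time = 0, dose = 90),
#'                   segments = data.frame(t_start = 0.5, t_end = 60,
#'                                         rate = 6))
#' @export
infusion_protocol <- function(boluses = NULL, segments = NULL) {
  if (is.null(boluses)) boluses <- data.frame(time = numeric(), dose = numeric())
  if (is.null(segments))
    segments <- data.frame(t_start = numeric(), t_end = numeric(),
                           rate = numeric())
  stopifnot(is.data.frame(boluses), all(c("time", "dose") %in% names(boluses)),
            is.data.frame(segments),
            all(c("t_start", "t_end", "rate") %in% names(segments)))
  if (nrow(boluses) && (any(boluses$time < 0) || any(boluses$dose < 0)))
    stop("bolus times and doses must be >= 0", call. = FALSE)
  if (nrow(segments)) {
    if (any(segments$t_start < 0) || any(segments$rate < 0))
      stop("segment times and rates must be >= 0", call. = FALSE)
    if (any(segments$t_start >= segments$t_end))
      stop("each segment must have t_start < t_end", call. = FALSE)
    o <- order(segments$t_start)
    segments <- segments[o, , drop = FALSE]
    if (nrow(segments) > 1L &&
        any(segments$t_start[-1L] < segments$t_end[-nrow(segments)]))
      stop("infusion segments may not overlap", call. = FALSE)
  }
  boluses <- boluses[order(boluses$time), , drop = FALSE]
  rownames(boluses) <- rownames(segments) <- NULL
  structure(list(boluses = boluses, segments = segments),
            class = "infusion_protocol")
}

#' @export
print.infusion_protocol <- function(x, ...) {
  cat(sprintf("Infusion protocol: %d bolus(es), %d segment(s)\n",
              nrow(x$boluses), nrow(x$segments)))
  if (nrow(x$boluses))
    for (i in seq_len(nrow(x$boluses)))
      cat(sprintf("  bolus  %6.2f mg at t = %.2f min\n",
                  x$boluses$dose[i], x$boluses$time[i]))
  if (nrow(x$segments))
    for (i in seq_len(nrow(x$segments)))
      cat(sprintf("  infuse %6.3f mg/min over [%.2f, %.2f] min\n",
                  x$segments$rate[i], x$segments$t_start[i],
                  x$segments$t_end[i]))
  invisible(x)
}

#' Infusion rate at given times
#'
#' Evaluates the piecewise-constant infusion rate u(t) of a protocol
#' (boluses excluded; they are instantaneous state jumps).
#'
#' @param protocol an [infusion_protocol()].
#' @param t numeric vector of times (min).
#' @return Numeric vector of rates (mg/min). Segment start is inclusive,
#'   segment end exclusive.
#' @export
infusion_rate <- function(protocol, t) {
  stopifnot(inherits(protocol, "infusion_protocol"))
  u <- numeric(length(t))
  s <- protocol$segments
  for (i in seq_len(nrow(s))) {
    on <- t >= s$t_start[i] & t < s$t_end[i]
    u[on] <- s$rate[i]
  }
  u
}
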