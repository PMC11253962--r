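# shared fixtures: the reference-covariate patient zeroes every
# correction term of the covariate equations
ref_patient <- function() patient("ref", age = 53, weight = 77,
                                  height = 177, sex = "male")

ref_pk <- function() pk_params(ref_patient(), lbm = 59)

# protocol with one induction bolus and one maintenance segment
demo_protocol <- function(dose = 90, rate = 6, t_end = 60)
  infusion_protocol(boluses = data.frame(time = 0, dose = dose),
                    segments = data.frame(t_start = 0.5, t_end = t_end,
                                          rate = rate))

# brute-force depth-1 stump: exhaustive search over every feature and
# every midpoint threshold; independent oracle for the greedy splitter
brute_force_stump_sse <- function(x, y) {
  x <- as.matrix(x)
  best <- sum((y - mean(y))^2)
  for (j in seq_len(ncol(x))) {
    ux <- sort(unique(x[, j]))
    if (length(ux) < 2L) next
    for (th in (ux[-1] + ux[-length(ux)]) / 2) {
      l <- y[x[, j] <= th]; r <- y[x[, j] > th]
      sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
      if (sse < best) best <- sse
    }
  }
  best
}
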