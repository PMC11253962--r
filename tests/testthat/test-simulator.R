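test_that("protocol validation rejects malformed inputs", {
  expect_error(infusion_protocol(boluses = data.frame(time = -1, dose = 5)),
               ">= 0")
  expect_error(infusion_protocol(
    segments = data.frame(t_start = 5, t_end = 5, rate = 1)),
    "t_start < t_end")
  expect_error(infusion_protocol(
    segments = data.frame(t_start = c(0, 5), t_end = c(10, 15),
                          rate = c(1, 2))),
    "overlap")
})

test_that("infusion rate is piecewise constant, start-inclusive", {
  prot <- infusion_protocol(
    segments = data.frame(t_start = c(0, 10), t_end = c(5, 20),
                          rate = c(2, 1)))
  expect_equal(infusion_rate(prot, c(0, 4.9, 5, 7, 10, 19.9, 20)),
               c(2, 2, 0, 0, 1, 1, 0))
})

test_that("zero input from zero state stays identically zero", {
  tr <- simulate_concentrations(ref_pk(), infusion_protocol(),
                                times = seq(0, 30, by = 1))
  expect_true(all(as.matrix(tr[, c("C1", "C2", "C3", "Ce")]) == 0))
})

test_that("constant infusion converges to the analytic steady state", {
  # at steady state all derivatives vanish: C2 = C3 = Ce = C1 = u / Cl1
  u <- 1
  tr <- simulate_concentrations(
    ref_pk(),
    infusion_protocol(segments = data.frame(t_start = 0, t_end = 5000,
                                            rate = u)),
    times = seq(0, 5000, by = 5))
  final <- unlist(tr[nrow(tr), c("C1", "C2", "C3", "Ce")])
  expect_equal(unname(final), rep(u / 1.89, 4), tolerance = 1e-3)
})

test_that("a bolus with no elimination or transfer holds C1 = dose/V1", {
  pk <- ref_pk()
  pk[c("k10", "k12", "k13", "k21", "k31")] <- 0
  class(pk) <- "pk_params"
  tr <- simulate_concentrations(
    pk, infusion_protocol(boluses = data.frame(time = 0, dose = 10)),
    times = seq(0, 20, by = 1), ke0 = 0)
  expect_equal(tr$C1, rep(10 / 4.27, nrow(tr)), tolerance = 1e-10)
  expect_equal(tr$C2, rep(0, nrow(tr)))
})

test_that("drug amount balances the dosed and eliminated mass", {
  # d/dt (V1 C1 + V2 C2 + V3 C3) = u(t) - Cl1 C1, checked by quadrature
  pk <- ref_pk()
  times <- seq(0, 40, by = 0.01)
  prot <- demo_protocol(dose = 0, rate = 6, t_end = 40)
  tr <- simulate_concentrations(pk, prot, times)
  amount <- pk$V1 * tr$C1 + pk$V2 * tr$C2 + pk$V3 * tr$C3
  # u is piecewise constant with jumps on grid points: integrate it at
  # interval midpoints (exact); the continuous elimination term by trapezoid
  mid_u <- infusion_rate(prot, (times[-1] + times[-length(times)]) / 2)
  elim <- pk$Cl1 * tr$C1
  integral <- cumsum(c(0, mid_u * diff(times) -
                         (elim[-1] + elim[-length(elim)]) / 2 *
                         diff(times)))
  expect_equal(amount, integral, tolerance = 1e-6)
})

test_that("concentrations stay non-negative and the grid must increase", {
  tr <- simulate_concentrations(ref_pk(), demo_protocol(),
                                times = seq(0, 60, by = 0.25))
  expect_true(all(as.matrix(tr[, -1]) > -1e-9))
  expect_error(simulate_concentrations(ref_pk(), demo_protocol(),
                                       times = c(0, 1, 1)),
               "strictly increasing")
})

test_that("refining the grid leaves the final state unchanged", {
  prot <- demo_protocol()
  t1 <- seq(0, 30, by = 0.2)
  t2 <- seq(0, 30, by = 0.1)
  a <- simulate_concentrations(ref_pk(), prot, t1)
  b <- simulate_concentrations(ref_pk(), prot, t2)
  expect_equal(unlist(a[nrow(a), -1]), unlist(b[nrow(b), -1]),
               tolerance = 1e-6)
})

test_that("the Hill model hits its anchor points and bounds", {
  pd <- pd_params(e0 = 100, emax = 60, ec50 = 4, gamma = 2)
  expect_equal(bis_from_ce(0, pd), 100)
  expect_equal(bis_from_ce(4, pd), 100 - 60 / 2) # 70 at EC50
  ce <- seq(0, 50, by = 0.1)
  bis <- bis_from_ce(ce, pd)
  expect_true(all(diff(bis) < 0))
  expect_true(all(bis <= 100 & bis >= 40))
  expect_error(bis_from_ce(-1, pd), ">= 0")
  expect_error(pd_params(90, 95, 2, 2), "emax")
})

test_that("simulate_bis composes the PK solution with the Hill map", {
  pd <- pd_params(92, 70, 2.5, 2)
  times <- seq(0, 30, by = 0.5)
  b <- simulate_bis(ref_patient(), demo_protocol(), pd, times)
  conc <- attr(b, "conc")
  expect_equal(b$bis, bis_from_ce(pmax(conc$Ce, 0), pd))
  expect_true(min(b$bis) >= 92 - 70)
  # zero protocol: BIS stays at E0
  b0 <- simulate_bis(ref_patient(), infusion_protocol(), pd, times)
  expect_equal(b0$bis, rep(92, length(times)))
})

test_that("pointwise larger Ce gives pointwise smaller BIS", {
  pd <- pd_params(90, 65, 2, 1.8)
  ce1 <- seq(0, 5, by = 0.1)
  ce2 <- ce1 + 0.3
  expect_true(all(bis_from_ce(ce2, pd) < bis_from_ce(ce1, pd)))
})

test_that("the closed-form effect-site filter agrees with the ODE link", {
  # independent route: exact linear-interpolant update vs lsoda integration
  times <- seq(0, 30, by = 0.1)
  tr <- simulate_concentrations(ref_pk(), demo_protocol(), times,
                                ke0 = 0.456)
  ce2 <- effect_site(times, tr$C1, ke0 = 0.456)
  expect_equal(tr$Ce, ce2, tolerance = 1e-3)
})
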