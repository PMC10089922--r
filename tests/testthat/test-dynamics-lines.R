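test_that("the BVA semicircle has the shot-noise form", {
  expect_equal(bva_expected_sigma(0, 5), 0)
  expect_equal(bva_expected_sigma(1, 5), 0)
  expect_equal(bva_expected_sigma(0.5, 5), sqrt(0.05), tolerance = 1e-12)
  expect_lt(bva_expected_sigma(0.5, 50), bva_expected_sigma(0.5, 5))
})

test_that("static populations show no dynamic shift in BVA", {
  run <- static_run()
  bv <- bva(run$stream, run$sel$fret)
  expect_lt(abs(bv$ds), 0.01)
  # bin-averaged sigma tracks the semicircle where populated
  pop <- bv$bins[!is.na(bv$bins$sigma) & bv$bins$n > 50, ]
  expect_lt(max(abs(pop$sigma - bva_expected_sigma(pop$E_mid, 5))), 0.05)
})

test_that("two-state exchange produces a positive BVA shift", {
  run <- dyn_run()
  fr <- run$sel$fret[run$sel$fret$DD + run$sel$fret$AD >= 60, ]
  bv <- bva(run$stream, fr)
  expect_gt(bv$ds, 0.008)
  # and exceeds the static null by far
  st <- static_run()
  expect_gt(bv$ds, 3 * abs(bva(st$stream, st$sel$fret)$ds))
})

test_that("burst lifetimes are maximum-likelihood accurate", {
  set.seed(2)
  mt <- 2 + rexp(1e4, 1 / 2) + rnorm(1e4, 0, 0.25)
  expect_lt(abs(burst_lifetime(mt) - 2), 0.06)
  # 50% flat background: bias < 5% with the background term
  mtb <- c(2 + rexp(5e3, 1 / 2) + rnorm(5e3, 0, 0.25), runif(5e3, 0, 25))
  expect_lt(abs(burst_lifetime(mtb) - 2) / 2, 0.05)
  expect_true(is.na(burst_lifetime(mt[1:10])))
})

test_that("static FRET lines: straight, curved, and quadrature-consistent", {
  sl0 <- static_fret_line(4, 0)
  expect_equal(sl0$E_of_tau(4), 0)
  expect_equal(sl0$E_of_tau(0), 1)
  expect_equal(sl0$E_of_tau(1), 0.75)
  sl <- static_fret_line(4, 6, 65)
  # curved line lies above the straight line at mid-range lifetimes
  mid <- c(1.5, 2, 2.5)
  expect_true(all(sl$E_of_tau(mid) > sl0$E_of_tau(mid)))
  # independent quadrature oracle at one mean distance
  rbar <- 65
  wfun <- function(r) dnorm(r, rbar, 6)
  e_r <- function(r) 1 / (1 + (r / 65)^6)
  num_tau <- integrate(function(r) wfun(r) * (4 * (1 - e_r(r)))^2,
                       35, 95)$value
  den_tau <- integrate(function(r) wfun(r) * 4 * (1 - e_r(r)), 35, 95)$value
  tauF <- num_tau / den_tau
  E_sp <- 1 - den_tau / integrate(wfun, 35, 95)$value / 4
  expect_lt(abs(sl$E_of_tau(tauF) - E_sp), 1e-4)
})

test_that("the dynamic FRET line passes through its endpoints and mixture", {
  dl <- dynamic_fret_line(0.2, 0.8, 4)
  expect_equal(dl$E_of_tau(4 * 0.8), 0.2, tolerance = 1e-12)
  expect_equal(dl$E_of_tau(4 * 0.2), 0.8, tolerance = 1e-12)
  # equal-occupancy mixing point: (2.72 ns, 0.5)
  expect_equal(dl$E_of_tau(2.72), 0.5, tolerance = 1e-12)
  expect_error(dl$E_of_tau(3.9), "domain")
  # degenerate states collapse to the static point
  dl2 <- dynamic_fret_line(0.5, 0.5, 4)
  expect_equal(dl2$E_of_tau(2), 0.5)
})

test_that("E-tau dynamic shift is null for static and 0.18 for the mixture", {
  sl0 <- static_fret_line(4, 0)
  # closed-form mixing example: ds = 0.5 - E_static(2.72) = 0.18
  ds <- dynamic_shift_etau(static_line = sl0, center = c(2.72, 0.5))
  expect_equal(ds$ds, 0.18, tolerance = 1e-10)
  # static simulation: |ds| < 0.01
  run <- static_run()
  fr <- run$sel$fret[run$sel$fret$DD + run$sel$fret$AD >= 100, ]
  fr <- fr[seq_len(min(nrow(fr), 900)), ]
  tau <- burst_lifetimes(run$stream, fr, bg = run$bg)
  es <- accurate_E_S(fr$DDc, fr$ADc, fr$AAc, run$sim$corrections)
  d0 <- dynamic_shift_etau(es$E, tau, sl0)
  expect_lt(abs(d0$ds), 0.01)
})

test_that("two-state simulations match the occupancy-mixing oracle", {
  run <- dyn_run()
  fr <- run$sel$fret[run$sel$fret$DD + run$sel$fret$AD >= 60, ]
  fr <- fr[seq_len(min(nrow(fr), 900)), ]
  tau <- burst_lifetimes(run$stream, fr, bg = run$bg)
  es <- accurate_E_S(fr$DDc, fr$ADc, fr$AAc, run$sim$corrections)
  sl0 <- static_fret_line(4, 0)
  obs <- dynamic_shift_etau(es$E, tau, sl0)
  # forward oracle: burst-wise occupancy fractions from the analytic
  # two-state occupancy distribution at the mean burst duration
  Tbar <- median(fr$duration_ms) * 1e-3
  oc <- two_state_occupancy(Tbar, 1000, 1000)
  E1 <- 0.3; E2 <- 0.7
  Em <- oc$f * E1 + (1 - oc$f) * E2
  t1 <- 4 * (1 - E1); t2 <- 4 * (1 - E2)
  tm <- (oc$f * t1^2 + (1 - oc$f) * t2^2) / (oc$f * t1 + (1 - oc$f) * t2)
  pred_center <- c(sum(oc$p * tm), sum(oc$p * Em))
  pred <- dynamic_shift_etau(static_line = sl0, center = pred_center)
  expect_gt(obs$ds, 0.5 * pred$ds)
  expect_lt(obs$ds, 1.5 * pred$ds)
})

test_that("distance-fluctuation inversion round-trips and is monotone", {
  expect_equal(estimate_delta_R(0, R_mean = 65)$delta_R_A, 0)
  fw <- estimate_delta_R(0, R_mean = 65)$forward
  est <- estimate_delta_R(fw(5), R_mean = 65)
  expect_lt(abs(est$delta_R_A - 5), 1e-3)
  ds_grid <- vapply(c(2, 4, 6, 8, 10), fw, numeric(1))
  expect_true(all(diff(ds_grid) > 0))
  dr <- vapply(ds_grid, function(d)
    estimate_delta_R(d, R_mean = 65)$delta_R_A, numeric(1))
  expect_true(all(diff(dr) > 0))
})
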