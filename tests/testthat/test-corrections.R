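test_that("apparent E and S follow the count-ratio definitions", {
  expect_equal(apparent_E(20, 80), 0.8)
  expect_equal(apparent_E(50, 0), 0)
  expect_equal(apparent_E(67, 33), 0.33)
  expect_true(is.na(apparent_E(0, 0)))
  expect_equal(apparent_S(40, 20, 60), 0.5)
})

test_that("background correction subtracts rate x duration per channel", {
  bg <- background_model(c(DD = 2000, AD = 2000, AA = 0))
  cc <- background_correct(data.frame(DD = 100, AD = 1, AA = 7), bg, 1e-3)
  expect_equal(unname(cc[1, ]), c(98, -1, 7))
  expect_identical(attr(cc, "negative"), 1L)
  # zero rates: identity
  cc0 <- background_correct(data.frame(DD = 5, AD = 6, AA = 7),
                            background_model(c(DD = 0, AD = 0, AA = 0)), 1)
  expect_equal(unname(cc0[1, ]), c(5, 6, 7))
})

test_that("alpha and delta invert the donor-/acceptor-only centers", {
  set.seed(1)
  e_do <- rnorm(5000, 0.0476, 0.03)
  a <- alpha_from_donor_only(e_do)
  expect_lt(abs(a$alpha - 0.05), 0.005)
  s_ao <- rnorm(5000, 0.107, 0.04)
  d <- delta_from_acceptor_only(s_ao)
  expect_lt(abs(d$delta - 0.12), 0.01)
  expect_error(alpha_from_donor_only(e_do[1:50]), "too few")
  expect_error(delta_from_acceptor_only(s_ao[1:50]), "too few")
})

test_that("null crosstalk and direct excitation estimate near zero", {
  run <- fixture("null_ctdex_run", function() {
    cfg <- sim_config(n_bursts = 4000,
                      model = kinetic_model(data.frame(E = 0.5)),
                      dyes = dye_physics(crosstalk = 0, direct_exc = 0),
                      seed = 13)
    sim <- simulate_bursts(cfg)
    s <- assign_excitation(sim$stream, sim$stream$meta$excitation_scheme)
    bg <- estimate_background(s)
    select_bursts(search_bursts(s, bg), bg)
  })
  don <- run$donor_only[run$donor_only$DD + run$donor_only$AD >= 100, ]
  a <- suppressWarnings(alpha_from_donor_only(don$E_app))
  expect_lt(abs(a$alpha), 0.004)
  aon <- run$acceptor_only[run$acceptor_only$AA >= 100, ]
  d <- suppressWarnings(delta_from_acceptor_only(aon$S_app))
  expect_lt(abs(d$delta), 0.012)
})

test_that("the corrected FRET signal removes crosstalk and direct excitation", {
  expect_equal(fret_signal(100, 100, 50, 0.05, 0.12), 89)
  expect_equal(fret_signal(10, 7, 3, 0, 0), 7)
  # all-crosstalk burst: AD = alpha * DD -> F = -delta * AA
  expect_equal(fret_signal(200, 0.05 * 200, 40, 0.05, 0.12), -0.12 * 40)
})

test_that("beta/gamma regression inverts the Lee relation exactly", {
  beta <- 1.6; gamma <- 0.4
  E <- c(0.2, 0.5, 0.8)
  S <- 1 / (1 + beta * gamma + beta * (1 - gamma) * E)
  fit <- beta_gamma_global(E, S)
  expect_equal(fit$beta, beta, tolerance = 1e-10)
  expect_equal(fit$gamma, gamma, tolerance = 1e-10)
  # ideal dyes: 1/S constant at 2 -> returns (1, 1)
  fit1 <- beta_gamma_global(c(0.3, 0.7), c(0.5, 0.5))
  expect_equal(fit1$beta, 1, tolerance = 1e-10)
  expect_equal(fit1$gamma, 1, tolerance = 1e-10)
  expect_error(beta_gamma_global(0.5, 0.5), "at least two")
  expect_warning(beta_gamma_global(c(0.50, 0.55), c(0.45, 0.44)),
                 "ill-conditioned")
})

test_that("accurate E and S apply the full correction formulas", {
  cs <- correction_set(0.05, 1.6, 0.4, 0.12)
  es <- accurate_E_S(100, 100, 50, cs)
  f <- 89
  expect_equal(es$E, f / (0.4 * 100 + f), tolerance = 1e-12)  # 0.6899
  expect_equal(es$S, (0.4 * 100 + f) / (0.4 * 100 + f + 50 / 1.6),
               tolerance = 1e-12)                              # 0.805
  # identity case: gamma = beta = 1, alpha = delta = 0 -> E = E_app
  cs1 <- correction_set(0, 1, 1, 0)
  dd <- c(30, 80); ad <- c(70, 20); aa <- c(50, 50)
  expect_equal(accurate_E_S(dd, ad, aa, cs1)$E, apparent_E(dd, ad))
})

test_that("E is invariant under joint rescaling of Aex counts and beta", {
  cs <- correction_set(0.05, 1.6, 0.4, 0.12)
  cs2 <- correction_set(0.05, 1.6 * 3, 0.4, 0.12 / 3)
  # delta rescales with beta because delta multiplies the Aex counts
  e1 <- accurate_E_S(100, 100, 50, cs)$E
  e2 <- accurate_E_S(100, 100, 50 * 3, cs2)$E
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("gamma error propagation has the textbook shape", {
  expect_equal(efficiency_uncertainty(0), 0)
  expect_equal(efficiency_uncertainty(1), 0)
  expect_equal(efficiency_uncertainty(0.49), 0.49 * 0.51 * 0.23)
  expect_equal(efficiency_uncertainty(0.92), 0.92 * 0.08 * 0.23)
  e <- seq(0.01, 0.99, by = 0.01)
  de <- efficiency_uncertainty(e)
  expect_equal(e[which.max(de)], 0.5)
  expect_equal(de, rev(de))  # symmetric under E <-> 1-E
})

test_that("lifetime-route gamma recovers the truth on static samples", {
  run <- static_run()
  fr <- run$sel$fret[run$sel$fret$DD + run$sel$fret$AD >= 60, ]
  fr <- fr[seq_len(min(nrow(fr), 700)), ]
  tau <- burst_lifetimes(run$stream, fr, bg = run$bg)
  g <- gamma_from_static_line(fr$DDc, fr$ADc, fr$AAc, tau, tau_d0_ns = 4,
                              alpha = 0.05, delta = 0.12)
  expect_equal(g$gamma, 0.4, tolerance = 0.05)
  expect_false(g$dynamic_warning)
})
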