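test_that("implied corrections follow the detection-physics decomposition", {
  m <- kinetic_model(data.frame(E = 0.5))
  # gamma = g_A phi_A / (g_D phi_D) for crosstalk-free detection
  cfg <- sim_config(1, m, dye_physics(phi_d = 0.72, phi_a = 0.32,
                                      g_d = 1, g_a = 1, crosstalk = 0,
                                      direct_exc = 0),
                    seed = 1, exc_ratio = 1)
  cs <- implied_corrections(cfg)
  expect_equal(cs$gamma, 0.32 / 0.72, tolerance = 1e-12)
  expect_equal(cs$alpha, 0)
  expect_equal(cs$delta, 0)
  expect_equal(cs$beta, 1)
  # symmetric ideal dyes: gamma 1, beta set by the excitation-rate ratio
  cfg2 <- sim_config(1, m, dye_physics(phi_d = 0.5, phi_a = 0.5,
                                       g_d = 1, g_a = 1, crosstalk = 0,
                                       direct_exc = 0),
                     seed = 1, exc_ratio = 1.6)
  expect_equal(implied_corrections(cfg2)$gamma, 1)
  expect_equal(implied_corrections(cfg2)$beta, 1.6)
  # package defaults reproduce the consensus factors
  cs3 <- implied_corrections(sim_config(1, m, seed = 1))
  expect_equal(cs3$alpha, 0.05, tolerance = 1e-12)
  expect_equal(cs3$beta, 1.6, tolerance = 1e-12)
  expect_equal(cs3$gamma, 0.4, tolerance = 1e-12)
  expect_equal(cs3$delta, 0.12, tolerance = 1e-12)
})

test_that("the same seed reproduces a bit-identical stream", {
  m <- two_state_model(E1 = 0.3, E2 = 0.7, k12 = 800, k21 = 500)
  cfg <- sim_config(n_bursts = 200, model = m, seed = 7)
  a <- simulate_bursts(cfg)
  b <- simulate_bursts(cfg)
  expect_identical(a$stream$ticks, b$stream$ticks)
  expect_identical(a$stream$detector, b$stream$detector)
  expect_identical(a$stream$microtime_ns, b$stream$microtime_ns)
  expect_identical(a$bursts, b$bursts)
})

test_that("zero-state models are rejected and fractions must normalise", {
  expect_error(kinetic_model(data.frame(E = numeric(0))), "at least one")
  m <- kinetic_model(data.frame(E = 0.5))
  expect_error(sim_config(10, m, seed = 1,
                          species = c(da = 0.5, donly = 0.2, aonly = 0.1)),
               "sum to 1")
})

test_that("static bursts are shot-noise limited (binomial photon counts)", {
  # ideal dyes, no background: per-burst acceptor counts among Dex photons
  # must be Binomial(N, E); chi-square goodness of fit at the 1% level
  m <- kinetic_model(data.frame(E = 0.5))
  cfg <- sim_config(n_bursts = 10000, model = m,
                    dyes = dye_physics(phi_d = 1, phi_a = 1, g_d = 1,
                                       g_a = 1, crosstalk = 0,
                                       direct_exc = 0),
                    species = c(da = 1, donly = 0, aonly = 0),
                    bg_khz = c(dd = 0, ad = 0, aa = 0), seed = 11)
  sim <- simulate_bursts(cfg)
  s <- assign_excitation(sim$stream, sim$stream$meta$excitation_scheme)
  tt <- photon_times(s)
  band <- s$map$band[match(s$detector, s$map$detector)]
  dex <- s$excitation == "Dex"
  gt <- sim$bursts
  idx0 <- findInterval(gt$t0 - 1e-9, tt)
  idx1 <- findInterval(gt$t1 + 1e-9, tt)
  N <- k <- integer(nrow(gt))
  for (b in seq_len(nrow(gt))) {
    i <- seq(idx0[b] + 1, idx1[b])
    i <- i[dex[i]]
    N[b] <- length(i)
    k[b] <- sum(band[i] == "acceptor")
  }
  # unbiasedness: mean E_app within 3 binomial standard errors
  e_app <- k[N > 0] / N[N > 0]
  se <- sqrt(0.25 / sum(N))
  expect_lt(abs(sum(k) / sum(N) - 0.5), 3 * se)
  # GOF: aggregate over bursts with a common N
  Ntab <- sort(table(N), decreasing = TRUE)
  Nuse <- as.integer(names(Ntab))[1:5]
  for (nn in Nuse) {
    kk <- k[N == nn]
    br <- quantile(rbinom(5000, nn, 0.5), c(0.2, 0.4, 0.6, 0.8))
    cuts <- cut(kk, breaks = c(-1, unique(br), nn + 1))
    pexp <- diff(pbinom(c(-1, unique(br), nn + 1), nn, 0.5))
    gof <- suppressWarnings(chisq.test(table(cuts), p = pexp))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("symmetric two-state exchange gives half-half occupancy", {
  m <- two_state_model(E1 = 0.3, E2 = 0.7, k12 = 2000, k21 = 2000)
  expect_equal(m$stationary, c(0.5, 0.5))
  cfg <- sim_config(n_bursts = 2000, model = m, seed = 3,
                    species = c(da = 1, donly = 0, aonly = 0))
  sim <- simulate_bursts(cfg)
  dw <- sim$dwells
  occ1 <- sum((dw$t1 - dw$t0)[dw$state == 1]) / sum(dw$t1 - dw$t0)
  expect_lt(abs(occ1 - 0.5), 0.02)
})

test_that("donor microtimes follow the state-quenched lifetime", {
  # E = 0.75, tau_D(0) = 4 ns -> donor lifetime 1 ns (+ pulse offset)
  m <- kinetic_model(data.frame(E = 0.75))
  cfg <- sim_config(n_bursts = 800, model = m,
                    species = c(da = 1, donly = 0, aonly = 0),
                    bg_khz = c(dd = 0, ad = 0, aa = 0), seed = 5)
  sim <- simulate_bursts(cfg)
  s <- assign_excitation(sim$stream, sim$stream$meta$excitation_scheme)
  band <- s$map$band[match(s$detector, s$map$detector)]
  mt <- s$microtime_ns[band == "donor" & s$excitation == "Dex"]
  # mean = offset (2 ns) + tau (IRF is zero-mean)
  expect_equal(mean(mt), 2 + 1, tolerance = 0.02)
})

test_that("polarized decays reproduce the anisotropy model", {
  # frozen dye: r(t) constant at r0
  pd <- simulate_polarized_decays(rho_ns = numeric(0), b = numeric(0),
                                  r_inf = 0.38, r0 = 0.38,
                                  n_photons = 2e5, seed = 1)
  rt <- anisotropy_decay(pd)
  expect_equal(median(rt$r, na.rm = TRUE), 0.38, tolerance = 0.02)
  # two-component model: r(0) = r0
  pd2 <- simulate_polarized_decays(rho_ns = c(0.5, 5), b = c(0.14, 0.14),
                                   r_inf = 0.10, n_photons = 5e5, seed = 2)
  rt2 <- anisotropy_decay(pd2)
  # model value at the first bin center t = 0.05 ns
  r0_bin <- 0.14 * exp(-0.1) + 0.14 * exp(-0.01) + 0.10
  expect_lt(abs(rt2$r[1] - r0_bin), 0.02)
  # invalid inputs
  expect_error(simulate_polarized_decays(1, b = -0.1, r_inf = 0.48),
               "nonnegative")
  expect_error(simulate_polarized_decays(1, b = 0.1, r_inf = 0.1, r0 = 0.3),
               "sum to r0")
})
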