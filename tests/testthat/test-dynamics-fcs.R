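test_that("species filters are unbiased and handle degenerate patterns", {
  # orthogonal patterns -> indicator filters
  P <- cbind(a = c(1, 1, 0, 0) / 2, b = c(0, 0, 1, 1) / 2)
  W <- species_filters(P)
  expect_equal(unname(W %*% P), diag(2), tolerance = 1e-12)
  expect_equal(unname(W[1, ]), c(1, 1, 0, 0), tolerance = 1e-12)
  # exponential-decay patterns recover a 40/60 mixture to 1%
  t <- seq(0.25, 20, by = 0.5)
  p1 <- dexp(t, 1); p1 <- p1 / sum(p1)
  p2 <- dexp(t, 1 / 3); p2 <- p2 / sum(p2)
  W2 <- species_filters(cbind(p1, p2), mix = c(0.4, 0.6))
  mixed <- 1e6 * (0.4 * p1 + 0.6 * p2)
  amp <- as.numeric(W2 %*% mixed) / 1e6
  expect_equal(amp, c(0.4, 0.6), tolerance = 0.01)
  # filters sum to one across species when the mix spans the total
  expect_equal(unname(colSums(W2)), rep(1, length(t)), tolerance = 1e-8)
  expect_error(species_filters(cbind(p1, p1)), "collinear")
})

test_that("a Poisson stream carries no correlation", {
  set.seed(5)
  n <- 40000
  tt <- sort(runif(n, 0, 2))  # uniform rate over one long segment
  map <- channel_map(c(0L, 1L), c("donor", "acceptor"))
  st <- photon_stream(round(tt * 8e7), rep(0L, n), map)
  st$excitation <- rep("Dex", n)
  bt <- data.frame(burst = 1L, i0 = 1L, i1 = n, t0 = 0, t1 = 2,
                   duration_ms = 2000, n = n)
  cur <- correlate_bursts(st, bt, 1, 1, lag_edges = lag_grid(1e-5, 1e-2, 6))
  expect_lt(max(abs(cur$sacf1), na.rm = TRUE), 0.05)
})

test_that("a modulated rate produces the expected oscillating correlation", {
  set.seed(6)
  # thinning a 40 kHz stream with 1 + cos(2 pi t / P), P = 2 ms
  n <- 160000; P <- 2e-3
  tt <- sort(runif(n, 0, 2))
  keep <- runif(n) < (1 + cos(2 * pi * tt / P)) / 2
  tt <- tt[keep]
  map <- channel_map(c(0L, 1L), c("donor", "acceptor"))
  st <- photon_stream(round(tt * 8e7), rep(0L, length(tt)), map)
  st$excitation <- rep("Dex", length(tt))
  bt <- data.frame(burst = 1L, i0 = 1L, i1 = length(tt), t0 = 0, t1 = 2,
                   duration_ms = 2000, n = length(tt))
  edges <- seq(1e-4, 3e-3, by = 2e-4)
  cur <- correlate_bursts(st, bt, 1, 1, lag_edges = edges)
  # theory: G(tau) = 0.5 cos(2 pi tau / P)
  theory <- 0.5 * cos(2 * pi * cur$lag_s / P)
  expect_gt(cor(cur$sacf1, theory), 0.95)
})

test_that("the global FCS fit recovers relaxation times from model curves", {
  set.seed(7)
  lag <- lag_grid(1e-6, 5e-3, 10)
  mid <- sqrt(lag[-1] * lag[-length(lag)])
  t1 <- 2e-5; t2 <- 4e-4
  mk <- function(a1, a2) a1 * exp(-mid / t1) + a2 * exp(-mid / t2) +
    rnorm(length(mid), 0, 0.004)
  cur <- data.frame(lag_s = mid, sacf1 = mk(0.5, 0.7),
                    sacf2 = mk(0.4, 0.9), sccf = mk(-0.45, -0.8))
  fit <- fit_fcs(cur, envelope = "flat")
  expect_lt(abs(fit$t_relax_s[1] - t1) / t1, 0.15)
  expect_lt(abs(fit$t_relax_s[2] - t2) / t2, 0.15)
  # anti-correlated species show negative kinetic amplitudes in the SCCF
  expect_lt(fit$amplitudes["sccf", "a1"], 0)
  expect_lt(fit$amplitudes["sccf", "a2"], 0)
  # single-process data with two requested terms: minor second amplitude
  cur1 <- data.frame(lag_s = mid, sacf1 = 0.8 * exp(-mid / t2) +
                       rnorm(length(mid), 0, 0.003))
  fit1 <- fit_fcs(cur1, curve_cols = "sacf1", envelope = "flat")
  a <- fit1$amplitudes[1, c("a1", "a2")]
  expect_lt(min(abs(a)) / max(abs(a)), 0.15)
})

test_that("filtered FCS resolves two-process exchange on simulated bursts", {
  # reduced-scale version of the full study simulation: relaxation times
  # 20 us and 400 us with strong additive efficiency contrasts
  kf <- 1 / 2e-5; ks <- 1 / 4e-4
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- Q[2, 1] <- Q[3, 4] <- Q[4, 3] <- kf / 2
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- ks / 2
  mod <- kinetic_model(data.frame(E = c(0.3, 0.62, 0.63, 0.95)), rates = Q)
  sim <- simulate_bursts(sim_config(n_bursts = 9000, model = mod,
                                    seed = 31))
  s <- assign_excitation(sim$stream, sim$stream$meta$excitation_scheme)
  bg <- estimate_background(s)
  sel <- select_bursts(search_bursts(s, bg), bg)
  rp <- reference_patterns(s, sel$fret, e_low = c(0, 0.4),
                           e_high = c(0.62, 1))
  flt <- species_filters(rp$patterns)
  bins <- rp$assign_bins(s)
  w1 <- ifelse(is.na(bins), 0, flt[1, pmax(bins, 1)])
  w2 <- ifelse(is.na(bins), 0, flt[2, pmax(bins, 1)])
  cur <- correlate_bursts(s, sel$fret, w1, w2,
                          lag_edges = lag_grid(1e-6, 5e-3, 8))
  fit <- fit_fcs(cur, curve_cols = c("sacf1_norm", "sacf2_norm",
                                     "sccf_norm"), envelope = "flat")
  # reduced statistics: the fast term carries few photon pairs, so only a
  # coarse recovery is checked here (the full-scale check is elsewhere)
  expect_lt(abs(fit$t_relax_s[1] - 2e-5) / 2e-5, 0.5)
  expect_lt(abs(fit$t_relax_s[2] - 4e-4) / 4e-4, 0.35)
  expect_lt(fit$amplitudes["sccf_norm", "a2"], 0)
})
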