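poisson_stream <- function(rate_hz, duration_s, seed, det = 0L) {
  set.seed(seed)
  n <- rpois(1, rate_hz * duration_s)
  map <- channel_map(c(0L, 1L), c("donor", "acceptor"))
  st <- photon_stream(sort(round(runif(n, 0, duration_s) * 8e7)),
                      rep(det, n), map)
  st$excitation <- rep("Dex", n)
  st
}

test_that("background recovery: pure Poisson stream at 2 kHz within 5%", {
  st <- poisson_stream(2000, 120, seed = 1)
  bg <- suppressWarnings(estimate_background(st))
  expect_equal(unname(bg$rates[["DD"]]), 2000, tolerance = 0.05)
  expect_identical(unname(bg$rates[["AA"]]), 0)  # empty channel -> 0
  expect_warning(estimate_background(st), "fewer than 100")
})

test_that("background with injected bursts stays within 10%", {
  run <- static_run()  # default 1.0 / 0.6 / 0.8 kHz channel backgrounds
  expect_equal(unname(run$bg$rates[["DD"]]), 1000, tolerance = 0.10)
  expect_equal(unname(run$bg$rates[["AD"]]), 600, tolerance = 0.10)
  expect_equal(unname(run$bg$rates[["AA"]]), 800, tolerance = 0.10)
})

test_that("burst search finds an isolated photon cluster exactly", {
  map <- channel_map(c(0L, 1L), c("donor", "acceptor"))
  ticks <- round(seq(0, 1e-3, length.out = 50) * 8e7)  # 50 kHz cluster
  st <- photon_stream(ticks, rep(0L, 50), map)
  st$excitation <- rep("Dex", 50)
  bb <- search_bursts(st, background_model(c(DD = 0, AD = 0, AA = 0)))
  expect_identical(nrow(bb), 1L)
  expect_identical(bb$n, 50L)
  expect_error(search_bursts(st, background_model(c(DD = 0, AD = 0, AA = 0)),
                             m = 1), "at least 2")
})

test_that("pure background produces essentially no bursts", {
  st <- poisson_stream(2000, 300, seed = 2)   # 6e5 photons
  bg <- suppressWarnings(estimate_background(st))
  bb <- search_bursts(st, bg)
  expect_lte(nrow(bb), 1)  # < 1 false positive per 1e6 photons at defaults
})

test_that("burst search recovers simulated bursts with small boundary error", {
  run <- static_run()
  gt <- run$sim$bursts
  found <- run$bursts
  # ground-truth bursts expected to be found: >= 50 photons
  rate_eff <- gt$rate_khz * 1e3
  big <- gt[rate_eff * gt$duration_ms * 1e-3 >= 50 &
              gt$species == "da", ]
  hit <- outer(big$t0, found$t1, "<") & outer(big$t1, found$t0, ">")
  frac <- mean(rowSums(hit) > 0)
  expect_gte(frac, 0.95)
  # boundary error <= m photons in time units: compare matched edges
  m <- attr(found, "search")$m
  match_idx <- apply(hit, 1, function(z) which(z)[1])
  ok <- !is.na(match_idx)
  dt_edge <- abs(big$t0[ok] - found$t0[match_idx[ok]])
  # edges can extend into the background by up to the search's rate
  # threshold scale m / (F * bg)
  expect_lt(median(dt_edge),
            m / (attr(found, "search")$F * sum(run$bg$rates)))
})

test_that("burst search is translation invariant", {
  run <- static_run()
  st <- run$stream
  shift <- 1e4
  st2 <- st
  st2$ticks <- st$ticks + shift
  bb1 <- search_bursts(st, run$bg)
  bb2 <- search_bursts(st2, run$bg)
  expect_identical(bb1$i0, bb2$i0)
  expect_identical(bb1$i1, bb2$i1)
  expect_equal(bb2$t0 - bb1$t0, rep(shift / st$clock_rate, nrow(bb1)))
})

test_that("selection partitions by stoichiometry with disjoint subsets", {
  # hand-built burst rows through the real selector
  bt <- data.frame(burst = 1:3, i0 = 1, i1 = 2, t0 = c(0, 1, 2),
                   t1 = c(0.001, 1.001, 2.001), duration_ms = 1,
                   n = c(60L, 60L, 60L),
                   DD = c(40L, 0L, 25L), AD = c(20L, 0L, 15L),
                   AA = c(0L, 60L, 20L), DA = 0L, flagged = 0L)
  bg0 <- background_model(c(DD = 0, AD = 0, AA = 0))
  sel <- select_bursts(bt, bg0)
  expect_identical(sel$donor_only$burst, 1L)      # no Aex counts -> S = 1
  expect_identical(sel$acceptor_only$burst, 2L)   # no Dex counts -> S = 0
  expect_identical(sel$fret$burst, 3L)
  expect_error(select_bursts(bt, bg0, a_only_max = 0.5,
                             fret_range = c(0.3, 0.75)), "overlap")
})

test_that("a 70/20/10 species mixture is recovered within 3% absolute", {
  run <- static_run()
  sel <- run$sel
  n <- nrow(sel$fret) + nrow(sel$donor_only) + nrow(sel$acceptor_only)
  # acceptor-only molecules are dimmer in the Dex channels; compare against
  # the simulated species of matched bursts
  gt <- run$sim$bursts
  frac <- c(fret = nrow(sel$fret), donly = nrow(sel$donor_only),
            aonly = nrow(sel$acceptor_only)) / n
  expect_lt(abs(frac[["fret"]] - 0.7), 0.03)
  expect_lt(abs(frac[["donly"]] - 0.2), 0.03)
  expect_lt(abs(frac[["aonly"]] - 0.1), 0.03)
})

test_that("burst summaries report the expected moments and correlations", {
  # two identical bursts -> zero SDs
  bt <- data.frame(duration_ms = c(1, 1), n = c(50L, 50L))
  sm <- burst_summary(bt)
  expect_equal(unname(sm$sd), c(0, 0, 0))
  expect_error(burst_summary(bt[1, ]), "at least two")
  # constant brightness: photons ~ duration
  set.seed(8)
  dur <- rlnorm(500, log(1.5), 0.4)
  bt2 <- data.frame(duration_ms = dur, n = rpois(500, 55 * dur))
  expect_gt(burst_summary(bt2)$correlations["photons", "duration_ms"], 0.9)
  # fixed photon budget: rate anti-correlates with duration
  bt3 <- data.frame(duration_ms = dur, n = 80L)
  expect_lt(burst_summary(bt3)$correlations["rate_khz", "duration_ms"], 0)
})
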