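# Shared simulation fixtures, built lazily and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# static single-state measurement at E = 0.5, analysed up to burst selection
static_run <- function() fixture("static_run", function() {
  cfg <- sim_config(n_bursts = 4000,
                    model = kinetic_model(data.frame(E = 0.5)), seed = 42)
  sim <- simulate_bursts(cfg)
  s <- assign_excitation(sim$stream, sim$stream$meta$excitation_scheme)
  bg <- estimate_background(s)
  bursts <- search_bursts(s, bg)
  sel <- select_bursts(bursts, bg)
  list(cfg = cfg, sim = sim, stream = s, bg = bg, bursts = bursts,
       sel = sel)
})

# tiny hand-checkable ALEX stream: known channel labels
hand_stream <- function() {
  map <- channel_map(c(0L, 1L), c("donor", "acceptor"))
  # period 100 us at 1 MHz clock -> 100 ticks; Dex [0,45), Aex [50,95)
  ticks <- c(10, 20, 47, 60, 110, 130, 155, 197, 210, 260, 296, 330)
  det <- c(0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L)
  stream <- photon_stream(ticks, det, map, clock_rate = 1e6)
  scheme <- alex_scheme(100, c(0, 45), c(50, 95))
  list(stream = stream, scheme = scheme)
}

# symmetric two-state exchange (E 0.3/0.7, relaxation 500 us)
dyn_run <- function() fixture("dyn_run", function() {
  m <- two_state_model(E1 = 0.3, E2 = 0.7, k12 = 1000, k21 = 1000)
  sim <- simulate_bursts(sim_config(n_bursts = 3000, model = m, seed = 21))
  s <- assign_excitation(sim$stream, sim$stream$meta$excitation_scheme)
  bg <- estimate_background(s)
  sel <- select_bursts(search_bursts(s, bg), bg)
  list(sim = sim, stream = s, bg = bg, sel = sel)
})
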