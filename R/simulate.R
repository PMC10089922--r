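# Photon-level simulator of freely diffusing FRET-labelled molecules.
# Bursts are drawn with lognormal durations and brightnesses, state
# trajectories follow a continuous-time Markov chain, photon colours follow
# the per-state detection model (crosstalk, direct excitation, detection/QY
# asymmetry), donor microtimes are exponential with the state-dependent
# lifetime convolved with a Gaussian IRF, and background is Poisson per
# channel. Every run is reproducible from its seed.

#' Dye and detection physics for the simulator
#'
#' Photophysical and detection parameters of the donor/acceptor pair.
#' `crosstalk` is the probability that a detected donor-emission photon is
#' registered in the acceptor channel; `direct_exc` is the number of direct
#' acceptor excitations per donor excitation during the donor-excitation
#' period. The defaults reproduce the consensus correction factors
#' alpha = 0.05, gamma = 0.4 and (with the default excitation-flux ratio 1.6)
#' delta = 0.12 for the Alexa546/Alexa647-like pair with quantum yields
#' 0.72/0.32.
#'
#' @param phi_d,phi_a donor/acceptor fluorescence quantum yields.
#' @param g_d,g_a donor/acceptor detection efficiencies.
#' @param crosstalk donor-to-acceptor-channel crosstalk probability.
#' @param direct_exc direct acceptor-excitation probability per donor
#'   excitation.
#' @param tau_d0_ns intrinsic (FRET-free) donor lifetime, ns.
#' @param tau_a_ns acceptor lifetime, ns.
#' @param irf_sigma_ns Gaussian IRF width (sigma), ns.
#' @return a `dye_physics` list.
#' @export
dye_physics <- function(phi_d = 0.72, phi_a = 0.32, g_d = 1, g_a = 6 / 7,
                        crosstalk = 1 / 21, direct_exc = 0.192,
                        tau_d0_ns = 4, tau_a_ns = 1.2, irf_sigma_ns = 0.25) {
  stopifnot(phi_d > 0, phi_d <= 1, phi_a > 0, phi_a <= 1,
            g_d > 0, g_a > 0, crosstalk >= 0, crosstalk < 1,
            direct_exc >= 0, tau_d0_ns > 0, tau_a_ns > 0, irf_sigma_ns >= 0)
  structure(as.list(environment()), class = "dye_physics")
}

#' Kinetic model of interconverting FRET states
#'
#' States are defined either by FRET efficiency `E` or by interdye distance
#' `R` (Angstrom, converted through the Forster equation at simulation time);
#' `sigma_r` gives a per-state Gaussian distance broadening (flexible-linker
#' width, or the width of a structurally heterogeneous ensemble). `rates` is
#' the generator matrix of exchange rates k_ij (per second, off-diagonals);
#' omit it for a static model.
#'
#' @param states data frame with columns `label`, `E` and/or `R`, optional
#'   `sigma_r` (Angstrom, default 0): a quasi-static per-dwell Gaussian
#'   distance broadening (conformational heterogeneity; one draw per dwell).
#' @param rates n x n matrix of exchange rates (s^-1), or `NULL` if static.
#' @param sigma_linker fast Gaussian distance broadening by the flexible dye
#'   linkers (Angstrom): redrawn photon by photon, i.e. averaged within
#'   bursts, as appropriate for ns-to-us linker motion.
#' @return a `kinetic_model` with the stationary distribution attached.
#' @export
kinetic_model <- function(states, rates = NULL, sigma_linker = 0) {
  states <- as.data.frame(states)
  n <- nrow(states)
  if (n < 1) stop("kinetic model needs at least one state")
  if (is.null(states$sigma_r)) states$sigma_r <- 0
  if (is.null(states$label)) states$label <- paste0("S", seq_len(n))
  if (is.null(states$E) && is.null(states$R))
    stop("states need either E or R")
  if (!is.null(states$E) && any(!is.na(states$E) &
                                (states$E <= 0 | states$E >= 1)))
    stop("state efficiencies must lie in (0, 1)")
  if (is.null(rates)) rates <- matrix(0, n, n)
  rates <- as.matrix(rates)
  stopifnot(nrow(rates) == n, ncol(rates) == n)
  diag(rates) <- 0
  if (any(rates < 0)) stop("exchange rates must be nonnegative")
  if (sigma_linker < 0) stop("sigma_linker must be nonnegative")
  structure(list(states = states, rates = rates,
                 sigma_linker = sigma_linker,
                 stationary = stationary_dist(rates)),
            class = "kinetic_model")
}

#' Stationary distribution of a rate matrix
#'
#' @param rates off-diagonal rate matrix (s^-1).
#' @return stationary probability vector.
#' @export
stationary_dist <- function(rates) {
  n <- nrow(rates)
  if (n == 1) return(1)
  if (all(rates == 0)) return(rep(1 / n, n))  # static mixture: uniform
  Q <- rates
  diag(Q) <- -rowSums(Q)
  # solve p Q = 0, sum(p) = 1
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- qr.solve(A, b)
  if (any(p < -1e-9)) stop("rate matrix has no proper stationary distribution")
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Convenience two-state exchange model
#'
#' @param E1,E2 state efficiencies (alternatively give `R1`, `R2`).
#' @param k12,k21 forward/backward exchange rates (s^-1).
#' @param R1,R2 state distances (Angstrom), used when efficiencies omitted.
#' @param sigma_r per-state distance broadening, recycled to length 2.
#' @export
two_state_model <- function(E1 = NULL, E2 = NULL, k12, k21,
                            R1 = NULL, R2 = NULL, sigma_r = 0) {
  st <- if (!is.null(E1)) data.frame(E = c(E1, E2)) else
    data.frame(R = c(R1, R2))
  st$sigma_r <- rep_len(sigma_r, 2)
  kinetic_model(st, rates = matrix(c(0, k12, k21, 0), 2, 2, byrow = TRUE))
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the simulator: burst statistics
#' (lognormal durations 1.7 +/- 0.9 ms and total detected count rates
#' 55 +/- 18 kHz, giving roughly 90 photons per burst), species fractions of
#' double-, donor-only- and acceptor-only-labelled molecules, per-channel
#' background rates, the excitation-flux ratio (the implied beta factor),
#' the Forster radius and the dye/kinetic models.
#'
#' @param n_bursts number of bursts to simulate.
#' @param model a [kinetic_model()].
#' @param dyes a [dye_physics()].
#' @param seed mandatory RNG seed.
#' @param duration_mean_ms,duration_sd_ms burst-duration moments (lognormal).
#' @param rate_mean_khz,rate_sd_khz per-burst total count-rate moments.
#' @param species fractions `c(da=, donly=, aonly=)`, must sum to 1.
#' @param bg_khz background rates `c(dd=, ad=, aa=)` in kHz.
#' @param exc_ratio acceptor/donor excitation-flux ratio (implied beta).
#' @param r0_A Forster radius, Angstrom.
#' @param mode `"pie"` (ns-interleaved pulses, microtimes present) or
#'   `"alex"` (microsecond alternation, no microtimes).
#' @param gap_mean_ms mean exponential gap between consecutive bursts; the
#'   default keeps molecule coincidences below one percent, as in dilute
#'   (tens of pM) measurements.
#' @param alex_period_us usALEX alternation period (alex mode).
#' @param clock_rate macrotime clock, Hz.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_bursts, model, dyes = dye_physics(), seed,
                       duration_mean_ms = 1.7, duration_sd_ms = 0.9,
                       rate_mean_khz = 55, rate_sd_khz = 18,
                       species = c(da = 0.7, donly = 0.2, aonly = 0.1),
                       bg_khz = c(dd = 1.0, ad = 0.6, aa = 0.8),
                       exc_ratio = 1.6, r0_A = 65,
                       mode = c("pie", "alex"), gap_mean_ms = 200,
                       alex_period_us = 50, clock_rate = 8e7) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("sim_config requires an explicit seed")
  if (!inherits(model, "kinetic_model")) stop("model must be a kinetic_model")
  if (nrow(model$states) < 1) stop("kinetic model has zero states")
  species <- species[c("da", "donly", "aonly")]
  species[is.na(species)] <- 0
  if (abs(sum(species) - 1) > 1e-8) stop("species fractions must sum to 1")
  bg_khz <- bg_khz[c("dd", "ad", "aa")]
  if (any(bg_khz < 0) || exc_ratio <= 0) stop("rates must be nonnegative")
  structure(as.list(environment()), class = "sim_config")
}

#' Correction factors implied by a simulation configuration
#'
#' The analytically exact alpha, beta, gamma and delta implied by the dye
#' physics and excitation settings of a [sim_config()]; this is the oracle
#' against which correction-factor recovery is tested. Gamma follows the
#' detection-efficiency/quantum-yield decomposition
#' gamma = g_A phi_A / (g_D phi_D), with the crosstalk rerouting loss of the
#' donor channel folded in.
#'
#' @param config a [sim_config()].
#' @return a [correction_set()].
#' @export
implied_corrections <- function(config) {
  d <- config$dyes
  correction_set(
    alpha = d$crosstalk / (1 - d$crosstalk),
    beta = config$exc_ratio,
    gamma = d$g_a * d$phi_a / (d$g_d * d$phi_d * (1 - d$crosstalk)),
    delta = d$direct_exc / config$exc_ratio,
    provenance = "implied by simulator configuration")
}

# Per-state relative detected-count weights (per donor excitation) for the
# three channels, given segment efficiencies E (NA for acceptor-only).
.channel_weights <- function(E, species, dyes, exc_ratio) {
  ct <- dyes$crosstalk
  dd <- ad <- aa <- numeric(length(E))
  da <- species == "da"
  dn <- species == "donly"
  an <- species == "aonly"
  dd[da] <- (1 - E[da]) * dyes$g_d * dyes$phi_d * (1 - ct)
  ad[da] <- (1 - E[da]) * dyes$g_d * dyes$phi_d * ct +
    E[da] * dyes$g_a * dyes$phi_a + dyes$direct_exc * dyes$g_a * dyes$phi_a
  aa[da] <- exc_ratio * dyes$g_a * dyes$phi_a
  dd[dn] <- dyes$g_d * dyes$phi_d * (1 - ct)
  ad[dn] <- dyes$g_d * dyes$phi_d * ct
  aa[dn] <- 0
  dd[an] <- 0
  ad[an] <- dyes$direct_exc * dyes$g_a * dyes$phi_a
  aa[an] <- exc_ratio * dyes$g_a * dyes$phi_a
  cbind(dd = dd, ad = ad, aa = aa)
}

# resample values falling outside [lo, hi) by redrawing with `draw(n)`
.resample_into <- function(x, lo, hi, draw) {
  bad <- which(x < lo | x >= hi)
  it <- 0
  while (length(bad) && it < 50) {
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] < lo | x[bad] >= hi]
    it <- it + 1
  }
  if (length(bad)) x[bad] <- lo + (hi - lo) * runif(length(bad))
  x
}

#' Simulate a photon stream of diffusing single molecules
#'
#' Generates bursts with the configured duration/brightness statistics,
#' simulates each double-labelled molecule's state trajectory as a
#' continuous-time Markov chain, draws one interdye distance per dwell from
#' the state's Gaussian distance distribution (quasi-static linker/ensemble
#' broadening), emits photons with the per-state channel probabilities and,
#' in PIE mode, TCSPC microtimes with state-dependent donor lifetimes
#' tau = tau_D(0) (1 - E) convolved with the IRF. Background photons are
#' Poisson per channel. The same seed yields a bit-identical stream.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with elements `stream` (unlabelled [photon_stream()] whose
#'   `meta$excitation_scheme` holds the scheme to pass to
#'   [assign_excitation()]), `bursts` (ground-truth burst table), `dwells`
#'   (state dwell segments with per-dwell E) and `corrections`
#'   (the [implied_corrections()]).
#' @export
simulate_bursts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_bursts
  m <- config$model
  dyes <- config$dyes

  lnorm_pars <- function(mean, sd) {
    s2 <- log(1 + (sd / mean)^2)
    c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  }
  dp <- lnorm_pars(config$duration_mean_ms * 1e-3,
                   config$duration_sd_ms * 1e-3)
  rp <- lnorm_pars(config$rate_mean_khz * 1e3, config$rate_sd_khz * 1e3)
  durations <- rlnorm(n, dp[1], dp[2])
  rates <- rlnorm(n, rp[1], rp[2])
  species <- sample(c("da", "donly", "aonly"), n, replace = TRUE,
                    prob = config$species)
  gaps <- rexp(n, 1 / (config$gap_mean_ms * 1e-3))
  t0 <- cumsum(gaps) + cumsum(c(0, head(durations, -1)))
  total_T <- t0[n] + durations[n] + config$gap_mean_ms * 1e-3

  # --- state segments -------------------------------------------------------
  da_idx <- which(species == "da")
  if (length(da_idx) && nrow(m$states) > 1) {
    seg <- sim_ctmc_segments(durations[da_idx], m$rates, m$stationary)
    seg <- data.frame(burst = da_idx[seg$burst], state = seg$state,
                      t0 = seg$t0, t1 = seg$t1)
  } else if (length(da_idx)) {
    seg <- data.frame(burst = da_idx, state = 1L, t0 = 0,
                      t1 = durations[da_idx])
  } else {
    seg <- data.frame(burst = integer(), state = integer(),
                      t0 = numeric(), t1 = numeric())
  }
  other <- which(species != "da")
  if (length(other))
    seg <- rbind(seg, data.frame(burst = other, state = NA_integer_,
                                 t0 = 0, t1 = durations[other]))
  seg <- seg[order(seg$burst, seg$t0), , drop = FALSE]
  seg$species <- species[seg$burst]

  # per-dwell efficiency: quasi-static Gaussian distance draw per dwell
  stR <- if (!is.null(m$states$R)) m$states$R else
    config$r0_A * (1 / m$states$E - 1)^(1 / 6)
  stE <- if (!is.null(m$states$E)) m$states$E else
    1 / (1 + (m$states$R / config$r0_A)^6)
  E_seg <- R_seg <- rep(NA_real_, nrow(seg))
  is_da <- seg$species == "da"
  sidx <- seg$state[is_da]
  sig <- m$states$sigma_r[sidx]
  needs_broad <- sig > 0
  Eda <- stE[sidx]
  Rda <- stR[sidx]
  if (any(needs_broad)) {
    Rdraw <- pmax(rnorm(sum(needs_broad), Rda[needs_broad],
                        sig[needs_broad]), 5)
    Rda[needs_broad] <- Rdraw
    Eda[needs_broad] <- 1 / (1 + (Rdraw / config$r0_A)^6)
  }
  E_seg[is_da] <- Eda
  R_seg[is_da] <- Rda
  E_seg[seg$species == "donly"] <- 0
  seg$E <- E_seg
  seg$R <- R_seg

  # --- photons per segment --------------------------------------------------
  w <- .channel_weights(seg$E, seg$species, dyes, config$exc_ratio)
  wtot <- rowSums(w)
  # normalise so the species-stationary mean total weight maps to the drawn
  # burst rate
  wbar_da <- sum(rowSums(.channel_weights(stE, rep("da", length(stE)),
                                          dyes, config$exc_ratio)) *
                   m$stationary)
  wbar <- ifelse(seg$species == "da", wbar_da, wtot)
  seg_rate <- rates[seg$burst] * wtot / pmax(wbar, 1e-300)
  n_ph <- rpois(nrow(seg), seg_rate * (seg$t1 - seg$t0))
  ph_seg <- rep(seq_len(nrow(seg)), n_ph)
  npho <- length(ph_seg)
  t_ph <- t0[seg$burst[ph_seg]] + seg$t0[ph_seg] +
    runif(npho) * (seg$t1 - seg$t0)[ph_seg]

  # per-photon efficiency: fast linker broadening is redrawn photon by
  # photon (detected photons sample the distance distribution weighted by
  # the total detection brightness, hence the accept-reject step)
  E_ph <- seg$E[ph_seg]
  if (m$sigma_linker > 0 && npho) {
    daph <- which(seg$species[ph_seg] == "da")
    if (length(daph)) {
      wmax <- max(rowSums(.channel_weights(c(0, 1), c("da", "da"), dyes,
                                           config$exc_ratio)))
      draw_E <- function(k, mu) {
        out <- numeric(k)
        todo <- seq_len(k)
        for (it in 1:50) {
          r <- pmax(rnorm(length(todo), mu[todo], m$sigma_linker), 5)
          e <- 1 / (1 + (r / config$r0_A)^6)
          wt <- rowSums(.channel_weights(e, rep("da", length(e)), dyes,
                                         config$exc_ratio))
          acc <- runif(length(todo)) < wt / wmax
          out[todo[acc]] <- e[acc]
          todo <- todo[!acc]
          if (!length(todo)) break
        }
        if (length(todo)) out[todo] <- 1 /
          (1 + (pmax(rnorm(length(todo), mu[todo], m$sigma_linker), 5) /
                  config$r0_A)^6)
        out
      }
      E_ph[daph] <- draw_E(length(daph), seg$R[ph_seg[daph]])
    }
  }
  # channel per photon from the per-photon weights
  wph <- .channel_weights(E_ph, seg$species[ph_seg], dyes, config$exc_ratio)
  wtph <- pmax(rowSums(wph), 1e-300)
  p1 <- wph[, "dd"] / wtph
  p2 <- (wph[, "dd"] + wph[, "ad"]) / wtph
  u <- runif(npho)
  chan <- ifelse(u < p1, "DD", ifelse(u < p2, "AD", "AA"))
  # AD subcomponents (crosstalk / fret / direct)
  comp <- rep(NA_character_, npho)
  ad <- which(chan == "AD")
  if (length(ad)) {
    Ead <- E_ph[ad]
    spc <- seg$species[ph_seg[ad]]
    w_xt <- ifelse(spc == "aonly", 0,
                   (1 - ifelse(is.na(Ead), 0, Ead)) * dyes$g_d * dyes$phi_d *
                     dyes$crosstalk)
    w_fr <- ifelse(spc == "da", ifelse(is.na(Ead), 0, Ead), 0) *
      dyes$g_a * dyes$phi_a
    w_di <- ifelse(spc == "donly", 0, dyes$direct_exc * dyes$g_a * dyes$phi_a)
    wtd <- w_xt + w_fr + w_di
    u2 <- runif(length(ad)) * wtd
    comp[ad] <- ifelse(u2 < w_xt, "xt", ifelse(u2 < w_xt + w_fr, "fret",
                                               "direct"))
  }

  # --- microtimes / excitation bookkeeping ----------------------------------
  period_ns <- 50
  dex_off <- 2; aex_off <- 27
  microtime <- NULL
  if (config$mode == "pie" && npho) {
    tau_don <- dyes$tau_d0_ns * (1 - ifelse(is.na(E_ph), 0, E_ph))
    mt <- numeric(npho)
    irf <- function(k) rnorm(k, 0, dyes$irf_sigma_ns)
    dd <- which(chan == "DD" | comp == "xt")
    mt[dd] <- dex_off + rexp(length(dd), 1 / tau_don[dd]) + irf(length(dd))
    fr <- which(!is.na(comp) & comp == "fret")
    mt[fr] <- dex_off + rexp(length(fr), 1 / tau_don[fr]) +
      rexp(length(fr), 1 / dyes$tau_a_ns) + irf(length(fr))
    di <- which(!is.na(comp) & comp == "direct")
    mt[di] <- dex_off + rexp(length(di), 1 / dyes$tau_a_ns) + irf(length(di))
    aa <- which(chan == "AA")
    mt[aa] <- aex_off + rexp(length(aa), 1 / dyes$tau_a_ns) + irf(length(aa))
    dexw <- c(0, period_ns / 2); aexw <- c(period_ns / 2, period_ns)
    isdex <- chan != "AA"
    mt[isdex] <- .resample_into(mt[isdex], dexw[1], dexw[2], function(k)
      dex_off + rexp(k, 1 / 2) + irf(k))
    mt[!isdex] <- .resample_into(mt[!isdex], aexw[1], aexw[2], function(k)
      aex_off + rexp(k, 1 / 2) + irf(k))
    microtime <- mt
  }
  if (config$mode == "alex" && npho) {
    # fold photon times into the proper alternation window
    P <- config$alex_period_us * 1e-6
    dexw <- c(0, 0.45) * P; aexw <- c(0.5, 0.95) * P
    isdex <- chan != "AA"
    base <- floor(t_ph / P) * P
    t_ph[isdex] <- base[isdex] + dexw[1] +
      runif(sum(isdex)) * diff(dexw)
    t_ph[!isdex] <- base[!isdex] + aexw[1] +
      runif(sum(!isdex)) * diff(aexw)
  }

  detector <- ifelse(chan == "DD", 0L, 1L)

  # --- background -----------------------------------------------------------
  bg_n <- rpois(3, config$bg_khz * 1e3 * total_T)
  bg_t <- runif(sum(bg_n)) * total_T
  bg_det <- rep(c(0L, 1L, 1L), bg_n)
  bg_chan <- rep(c("DD", "AD", "AA"), bg_n)
  bg_mt <- NULL
  if (config$mode == "pie") {
    half <- period_ns / 2
    bg_mt <- ifelse(bg_chan == "AA", half, 0) + runif(sum(bg_n)) * half
  } else {
    P <- config$alex_period_us * 1e-6
    dexw <- c(0, 0.45) * P; aexw <- c(0.5, 0.95) * P
    base <- floor(bg_t / P) * P
    isdex <- bg_chan != "AA"
    bg_t[isdex] <- base[isdex] + dexw[1] + runif(sum(isdex)) * diff(dexw)
    bg_t[!isdex] <- base[!isdex] + aexw[1] + runif(sum(!isdex)) * diff(aexw)
  }

  all_t <- c(t_ph, bg_t)
  all_det <- c(detector, bg_det)
  all_mt <- if (config$mode == "pie") c(microtime, bg_mt) else NULL
  ord <- order(all_t)
  ticks <- round(all_t[ord] * config$clock_rate)
  # enforce nondecreasing after rounding ties
  ticks <- cummax(ticks)

  map <- channel_map(c(0L, 1L), c("donor", "acceptor"))
  scheme <- if (config$mode == "pie")
    pie_scheme(c(0, period_ns / 2), c(period_ns / 2, period_ns), period_ns)
  else
    alex_scheme(round(config$alex_period_us * 1e-6 * config$clock_rate),
                c(0, 0.45) * config$alex_period_us * 1e-6 * config$clock_rate,
                c(0.5, 0.95) * config$alex_period_us * 1e-6 *
                  config$clock_rate)
  stream <- photon_stream(ticks, all_det[ord], map,
                          clock_rate = config$clock_rate,
                          microtime_ns = if (is.null(all_mt)) NULL else
                            all_mt[ord],
                          tcspc_period_ns = if (is.null(all_mt)) NULL else
                            period_ns,
                          meta = list(duration_s = total_T,
                                      excitation_scheme = scheme,
                                      seed = seed))

  dtseg <- seg$t1 - seg$t0
  valid <- !is.na(seg$E)
  occ <- rep(NA_real_, n)
  if (any(valid)) {
    num <- rowsum(seg$E[valid] * dtseg[valid], seg$burst[valid])
    den <- rowsum(dtseg[valid], seg$burst[valid])
    occ[as.integer(rownames(num))] <- num / den
  }
  bursts <- data.frame(burst = seq_len(n), species = species, t0 = t0,
                       t1 = t0 + durations, duration_ms = durations * 1e3,
                       rate_khz = rates / 1e3, E_true = occ)
  list(stream = stream, bursts = bursts, dwells = seg,
       corrections = implied_corrections(config), config = config)
}

#' Simulate polarized fluorescence decays
#'
#' Draws photons from a single-exponential fluorescence decay whose
#' time-dependent anisotropy follows
#' r(t) = sum_i b_i exp(-t/rho_i) + r_inf, and sorts each photon into the
#' parallel or perpendicular channel in the ratio (1 + 2 r) : (1 - r)
#' (G = 1). The reconstructed r(t) matches the input model within counting
#' noise.
#'
#' @param rho_ns rotational correlation times, ns.
#' @param b amplitudes per component (nonnegative).
#' @param r_inf residual anisotropy; `b` and `r_inf` must sum to `r0`.
#' @param r0 fundamental anisotropy, in [0, 0.4].
#' @param tau_ns fluorescence lifetime, ns.
#' @param n_photons photons to draw.
#' @param window_ns,bin_ns histogram range and bin width.
#' @param seed RNG seed.
#' @return a `polarized_decay`: bin centers (ns), parallel/perpendicular
#'   counts, G factor.
#' @export
simulate_polarized_decays <- function(rho_ns, b, r_inf, r0 = 0.38,
                                      tau_ns = 4, n_photons = 1e5,
                                      window_ns = 40, bin_ns = 0.1,
                                      seed = 1) {
  if (any(b < 0)) stop("anisotropy amplitudes must be nonnegative")
  if (r_inf < 0) stop("residual anisotropy must be nonnegative")
  if (r0 < 0 || r0 > 0.4) stop("r0 must lie in [0, 0.4]")
  if (abs(sum(b) + r_inf - r0) > 1e-8)
    stop("amplitudes plus r_inf must sum to r0")
  set.seed(seed)
  t <- rexp(n_photons, 1 / tau_ns)
  t <- .resample_into(t, 0, window_ns, function(k) rexp(k, 1 / tau_ns))
  r_t <- r_inf + if (length(b)) colSums(b * exp(-outer(1 / rho_ns, t))) else 0
  # detected fractions: I_par : I_perp = (1 + 2r) : (1 - r)
  par <- runif(n_photons) < (1 + 2 * r_t) / (2 + r_t)
  edges <- seq(0, window_ns, by = bin_ns)
  hp <- graphics::hist(t[par], breaks = edges, plot = FALSE)$counts
  hs <- graphics::hist(t[!par], breaks = edges, plot = FALSE)$counts
  structure(list(time_ns = edges[-1] - bin_ns / 2, parallel = hp,
                 perpendicular = hs, G = 1, bin_ns = bin_ns,
                 model = list(rho_ns = rho_ns, b = b, r_inf = r_inf,
                              r0 = r0, tau_ns = tau_ns)),
            class = "polarized_decay")
}
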