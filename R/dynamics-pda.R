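# Dynamic photon distribution analysis: shot-noise-exact modelling of
# apparent-FRET-efficiency histograms in fixed time windows for a two-state
# kinetic system, and a global chi-square fit across window lengths.

#' Occupancy-time distribution of a two-state chain
#'
#' Distribution of the fraction of a window of length `T` spent in state 1
#' for a stationary two-state Markov chain with rates k12 (1 -> 2) and k21.
#' Computed from the renewal-series expansion over transition counts,
#' truncated when terms fall below `tol`; the atoms at fractions 0 and 1
#' are the no-transition probabilities.
#'
#' @param T_s window length (s).
#' @param k12,k21 exchange rates (s^-1).
#' @param n_grid interior grid points for the continuous part.
#' @param tol series truncation tolerance.
#' @return list with `f` (fraction grid including 0 and 1), `p`
#'   (probability mass per grid point; interior masses integrate the
#'   density over grid cells).
#' @export
two_state_occupancy <- function(T_s, k12, k21, n_grid = 101, tol = 1e-10) {
  stopifnot(T_s > 0, k12 >= 0, k21 >= 0)
  p1 <- k21 / (k12 + k21)
  p2 <- 1 - p1
  if (k12 == 0 && k21 == 0)
    return(list(f = c(0, 1), p = c(p2, p1)))
  # interior density over x = time in state 1
  f_int <- seq(0, 1, length.out = n_grid + 2)[2:(n_grid + 1)]
  kT <- (k12 + k21) * T_s
  if (kT > 150) {
    # fast-exchange limit: the occupancy fraction is Gaussian around the
    # stationary value with variance 2 p1 p2 / (kT) (1 - (1 - e^-kT)/kT)
    v <- 2 * p1 * p2 / kT * (1 - (1 - exp(-kT)) / kT)
    w <- dnorm(f_int, p1, sqrt(max(v, 1e-12)))
    if (sum(w) == 0) w[which.min(abs(f_int - p1))] <- 1
    return(list(f = c(0, f_int, 1), p = c(0, w / sum(w), 0)))
  }
  x <- f_int * T_s
  y <- T_s - x
  a <- k12; b <- k21
  dens <- numeric(length(x))
  # start in 1: end in 1 (n complete 1->2 and 2->1 cycles) or end in 2
  # start in 2: symmetric with roles swapped
  for (nn in 1:200) {
    lfac <- function(k) lgamma(k + 1)
    # start 1 end 1: e^{-ax} a^n x^n/n! * b^n y^{n-1} e^{-by}/(n-1)!
    t11 <- exp(-a * x - b * y + nn * log(a * x) - lfac(nn) +
                 nn * log(b) + (nn - 1) * log(y) - lfac(nn - 1))
    # start 1 end 2: a^n x^{n-1} e^{-ax}/(n-1)! * b^{n-1} y^{n-1} e^{-by}/(n-1)!
    t12 <- exp(-a * x - b * y + nn * log(a) + (nn - 1) * log(x) -
                 lfac(nn - 1) + (nn - 1) * log(b * y) - lfac(nn - 1))
    t22 <- exp(-a * x - b * y + nn * log(b * y) - lfac(nn) +
                 nn * log(a) + (nn - 1) * log(x) - lfac(nn - 1))
    t21 <- exp(-a * x - b * y + nn * log(b) + (nn - 1) * log(y) -
                 lfac(nn - 1) + (nn - 1) * log(a * x) - lfac(nn - 1))
    term <- p1 * (t11 + t12) + p2 * (t22 + t21)
    dens <- dens + term
    if (max(term) < tol * max(max(dens), 1e-300)) break
  }
  dx <- T_s / (n_grid + 1)
  p_int <- dens * dx
  p0 <- p2 * exp(-b * T_s)   # never in state 1
  p1T <- p1 * exp(-a * T_s)  # always in state 1
  tot <- p0 + p1T + sum(p_int)
  list(f = c(0, f_int, 1), p = c(p0, p_int, p1T) / tot)
}

#' PDA model
#'
#' Two-state kinetic model for dynamic PDA: state efficiencies (or
#' distances with per-state Gaussian broadening, e.g. a broad detached
#' ensemble versus a compact state), exchange rates, and optionally an
#' extra static component (weight, R, sigma) for a residual static
#' population.
#'
#' @param model a [kinetic_model()] with one or two states.
#' @param r0_A Forster radius used for distance-to-efficiency conversion.
#' @param corrections optional [correction_set()]: the forward model then
#'   predicts raw proximity-ratio histograms, mapping each state's true
#'   efficiency to its apparent Dex acceptor probability via alpha, gamma,
#'   delta and beta (crosstalk, detection ratio, direct excitation).
#' @param extra optional list(weight=, R=, sigma_r=) static component.
#' @export
pda_model <- function(model, r0_A = 65, corrections = NULL, extra = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  if (nrow(model$states) > 2)
    stop("dynamic PDA supports at most two dynamic states")
  structure(list(model = model, r0_A = r0_A, corrections = corrections,
                 extra = extra),
            class = "pda_model")
}

# apparent-signal weights of an efficiency under a correction set:
# a = acceptor-channel weight, b = total Dex weight (per donor excitation,
# in units of the donor-channel signal scale)
.apparent_weights <- function(E, cs) {
  if (is.null(cs)) return(list(a = E, b = rep(1, length(E))))
  a <- cs$alpha * (1 - E) + cs$gamma * E + cs$delta * cs$beta * cs$gamma
  list(a = a, b = (1 - E) + a)
}

# distribution of a state's efficiency on an E grid (distance broadening)
.state_E_dist <- function(R, sigma, r0, n_nodes = 41) {
  if (is.na(sigma) || sigma <= 0) {
    return(list(E = distance_to_efficiency(R, r0), w = 1))
  }
  z <- seq(-4, 4, length.out = n_nodes)
  r <- pmax(R + z * sigma, 2)
  w <- dnorm(z); w <- w / sum(w)
  list(E = distance_to_efficiency(r, r0), w = w)
}

# state E/R bookkeeping for a pda_model
.pda_states <- function(pm) {
  st <- pm$model$states
  R <- if (!is.null(st$R)) st$R else
    pm$r0_A * (1 / st$E - 1)^(1 / 6)
  sig <- st$sigma_r
  lapply(seq_len(nrow(st)), function(i) .state_E_dist(R[i], sig[i], pm$r0_A))
}

#' Predict the windowed E_app histogram of a PDA model
#'
#' For each time window: the occupancy-fraction distribution of the
#' two-state chain is combined with the per-state (possibly broadened)
#' efficiency distributions into a distribution of the window-averaged
#' efficiency, and acceptor counts are Binomial given the total photon
#' number drawn from the empirical photon-count distribution. Expected
#' background counts can be folded in as a first-moment shift of the
#' window-averaged efficiency.
#'
#' @param pm a [pda_model()].
#' @param window_s window length (s).
#' @param N_counts integer vector: observed total (Dex) photon counts of
#'   the analysed windows (the empirical count distribution).
#' @param breaks E_app histogram breaks (default 0..1 by 0.05).
#' @param k12,k21 override the model's rates (used by the fitter).
#' @param bg_counts expected background counts `c(donor=, acceptor=)` per
#'   window.
#' @param cache precomputed kernel from a previous call with identical
#'   N_counts/breaks (see the `cache` element of the return value).
#' @return list with `breaks`, `density` (expected probability per bin),
#'   and `cache` for refitting.
#' @export
pda_predict <- function(pm, window_s, N_counts, breaks = seq(0, 1, 0.05),
                       k12 = NULL, k21 = NULL,
                       bg_counts = c(donor = 0, acceptor = 0),
                       cache = NULL) {
  st <- .pda_states(pm)
  two_state <- length(st) == 2
  if (is.null(k12)) k12 <- if (two_state) pm$model$rates[1, 2] else 0
  if (is.null(k21)) k21 <- if (two_state) pm$model$rates[2, 1] else 0
  nfgrid <- 31
  occ <- if (two_state) two_state_occupancy(window_s, k12, k21,
                                            n_grid = nfgrid) else
    list(f = 1, p = 1)
  if (is.null(cache))
    cache <- .pda_kernel(st, N_counts, breaks, occ$f, bg_counts,
                         pm$extra, pm$r0_A, pm$corrections, occ$p)
  # acceptance-weighted mixture over occupancy fractions: dim compositions
  # pass the window photon-count cut less often, so the per-f acceptance
  # (cache$acc) must weight the occupancy probabilities
  dens <- as.numeric(cache$A %*% occ$p) /
    sum(cache$acc * occ$p)
  if (!is.null(pm$extra) && pm$extra$weight > 0)
    dens <- (1 - pm$extra$weight) * dens + pm$extra$weight * cache$extra_dens
  list(breaks = breaks, density = dens / sum(dens), cache = cache,
       occupancy = occ)
}

# accumulate weights w into integer bins 1..nbins
.acc_bins <- function(bi, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(as.numeric(w), as.integer(bi))
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# accumulate values x with weights w onto grid centers by linear
# interpolation between the two neighbouring centers (first-order exact,
# so point masses do not get snapped to a center)
.acc_interp <- function(x, w, centers) {
  de <- centers[2] - centers[1]
  pos <- (x - centers[1]) / de
  lo <- pmin(pmax(floor(pos), 0), length(centers) - 1)
  frac <- pmin(pmax(pos - lo, 0), 1)
  out <- numeric(length(centers))
  s1 <- rowsum(as.numeric(w * (1 - frac)), as.integer(lo + 1))
  out[as.integer(rownames(s1))] <- s1[, 1]
  s2 <- rowsum(as.numeric(w * frac),
               as.integer(pmin(lo + 2, length(centers))))
  out[as.integer(rownames(s2))] <-
    out[as.integer(rownames(s2))] + s2[, 1]
  out
}

# Precompute the mapping from occupancy-fraction probabilities to expected
# E_app histogram densities: A[bin, f], summed over the empirical photon
# count distribution; also the histogram of an optional extra static
# component.
.pda_kernel <- function(st, N_counts, breaks, fgrid, bg_counts, extra, r0,
                        cs = NULL, p_f = NULL) {
  de <- 0.005
  egrid <- seq(de / 2, 1 - de / 2, by = de)
  eedges <- seq(0, 1, by = de)
  ne <- length(egrid)
  nb <- length(breaks) - 1
  two_state <- length(st) == 2
  d1 <- st[[1]]
  d2 <- if (two_state) st[[2]] else st[[1]]
  aw1 <- .apparent_weights(d1$E, cs)
  aw2 <- .apparent_weights(d2$E, cs)
  # distribution of the window-average apparent acceptor probability per
  # occupancy fraction, on egrid; state brightness differences (gamma < 1)
  # weight the occupancy mixing
  Q <- matrix(0, ne, length(fgrid))
  for (j in seq_along(fgrid)) {
    f <- fgrid[j]
    qb <- outer(f * aw1$a, (1 - f) * aw2$a, "+") /
      outer(f * aw1$b, (1 - f) * aw2$b, "+")
    wb <- outer(d1$w, d2$w)
    Q[, j] <- .acc_interp(as.numeric(qb), as.numeric(wb), egrid)
  }
  q_extra <- if (!is.null(extra)) {
    extra_e <- .state_E_dist(extra$R, extra$sigma_r, r0)
    awe <- .apparent_weights(extra_e$E, cs)
    .acc_interp(awe$a / awe$b, extra_e$w, egrid)
  } else numeric(ne)
  nbg <- sum(bg_counts)
  tabN <- table(N_counts[N_counts >= 5 & N_counts <= 500])
  Nvals <- as.integer(names(tabN))
  wN <- as.numeric(tabN) / sum(tabN)
  # Window brightness is correlated with the apparent acceptor probability:
  # both channel weights are affine in E, so the relative Dex brightness is
  # a deterministic monotone function of q. Windows with a dim (high-E)
  # composition contribute fewer photons, so the empirical photon-count
  # distribution must be conditioned on q:
  # P(N | q) ~ P_emp(N / s(q)) / s(q).
  s_q <- rep(1, ne)
  if (!is.null(cs)) {
    cc <- cs$delta * cs$beta * cs$gamma
    u <- egrid * (1 + cs$alpha) - cs$alpha
    E_of_q <- (u - (1 - egrid) * cc) / (u + (1 - egrid) * cs$gamma)
    E_of_q <- pmin(pmax(E_of_q, 0), 1)
    s_q <- (1 + cs$alpha) * (1 - E_of_q) + cs$gamma * E_of_q + cc
    # anchor the scale at the stationary-mixture mean brightness
    m_q <- as.numeric(Q %*% (if (is.null(p_f)) rep(1 / ncol(Q), ncol(Q))
                             else p_f))
    s_q <- s_q / weighted.mean(s_q, pmax(m_q, 1e-12))
  }
  if (length(Nvals) >= 2 && any(abs(s_q - 1) > 1e-9)) {
    p_emp <- function(x) {
      y <- approx(Nvals, wN, xout = x, rule = 2)$y
      y[x < min(Nvals) - 2 | x > max(Nvals) + 2] <- 0
      y
    }
    Wnq <- vapply(seq_len(ne), function(g)
      p_emp(Nvals / s_q[g]) / s_q[g], numeric(length(Nvals)))  # nN x ne
  } else {
    Wnq <- matrix(wN, length(Nvals), ne)
  }
  A <- matrix(0, nb, length(fgrid))
  colnorm <- rep(1e-300, length(fgrid))
  extra_dens <- numeric(nb)
  for (i in seq_along(Nvals)) {
    N <- Nvals[i]
    # background folded in as a first-moment shift of the mean efficiency
    esig <- egrid
    if (nbg > 0 && N > nbg)
      esig <- pmin(pmax((egrid * (N - nbg) + bg_counts[["acceptor"]]) / N,
                        0), 1)
    B <- vapply(seq_along(egrid), function(g) dbinom(0:N, N, esig[g]),
                numeric(N + 1))
    hb <- pmin(pmax(findInterval((0:N) / N, breaks,
                                 rightmost.closed = TRUE), 1), nb)
    Hmap <- matrix(0, nb, N + 1)
    Hmap[cbind(hb, seq_len(N + 1))] <- 1
    Bw <- B * rep(Wnq[i, ], each = N + 1)
    A <- A + Hmap %*% (Bw %*% Q)
    colnorm <- colnorm + as.numeric(Wnq[i, ] %*% Q)
    if (!is.null(extra))
      extra_dens <- extra_dens + wN[i] * as.numeric(Hmap %*% (B %*% q_extra))
  }
  list(A = A, acc = colnorm, egrid = egrid,
       extra_dens = extra_dens / max(sum(extra_dens), 1e-300))
}

#' Extract PDA time windows from bursts
#'
#' Chops each burst into consecutive windows of fixed length and counts the
#' donor-excitation photons (total N and acceptor k) per window.
#'
#' @param stream labelled [photon_stream()].
#' @param bursts `burst_table`.
#' @param window_ms window length (ms).
#' @param min_n windows with fewer Dex photons are dropped.
#' @param s_range per-window apparent-stoichiometry guard: windows whose
#'   Dex/(Dex+Aex) count ratio falls outside this range are chance overlaps
#'   with donor-only or acceptor-only molecules and are dropped.
#' @return data frame with columns `N`, `k` (and `E_app = k/N`).
#' @export
pda_windows <- function(stream, bursts, window_ms, min_n = 10,
                        s_range = c(0.2, 0.8)) {
  band <- stream$map$band[match(stream$detector, stream$map$detector)]
  exc <- stream$excitation
  if (is.null(exc)) stop("assign excitation first")
  is_dex <- !is.na(exc) & exc == "Dex"
  is_aex <- !is.na(exc) & exc == "Aex"
  is_acc <- band == "acceptor"
  tt <- photon_times(stream)
  Tw <- window_ms * 1e-3
  nb <- nrow(bursts)
  len <- bursts$i1 - bursts$i0 + 1
  idx0 <- sequence(len) + rep(bursts$i0, len) - 1L
  bid0 <- rep(seq_len(nb), len)
  lab <- is_dex[idx0]
  keep0 <- lab | is_aex[idx0]
  idx0 <- idx0[keep0]; bid0 <- bid0[keep0]; lab <- lab[keep0]
  nwb <- floor((bursts$t1 - bursts$t0) / Tw)   # complete windows per burst
  wi <- floor((tt[idx0] - bursts$t0[bid0]) / Tw)
  keep <- wi < nwb[bid0]
  idx0 <- idx0[keep]; bid0 <- bid0[keep]; wi <- wi[keep]; lab <- lab[keep]
  if (!length(idx0))
    return(data.frame(N = integer(), k = integer(), E_app = numeric()))
  maxw <- max(wi) + 1
  key <- (bid0 - 1) * maxw + wi + 1
  Ns <- tabulate(key[lab], nbins = nb * maxw)
  ks <- tabulate(key[lab & is_acc[idx0]], nbins = nb * maxw)
  As <- tabulate(key[!lab], nbins = nb * maxw)
  Sw <- ifelse(Ns + As > 0, Ns / (Ns + As), NA)
  keep <- Ns >= min_n & !is.na(Sw) & Sw >= s_range[1] & Sw <= s_range[2]
  data.frame(N = Ns[keep], k = ks[keep], E_app = ks[keep] / Ns[keep])
}

#' Global dynamic-PDA fit across window lengths
#'
#' Joint chi-square minimisation of the two-state dynamic PDA model over
#' several time-window lengths (and optionally several datasets sharing the
#' kinetic parameters). The free parameters are the exchange rates; the
#' state distances/efficiencies come from the model. Returns the fitted
#' rates, the relaxation time 1/(k12 + k21) and the reduced chi-square.
#'
#' @param window_data named list: for each window length (names in ms), a
#'   data frame from [pda_windows()].
#' @param pm a [pda_model()].
#' @param breaks histogram breaks.
#' @param bg_counts_per_ms expected background counts `c(donor=, acceptor=)`
#'   per ms of window.
#' @param init optional `c(k12, k21)` start (s^-1).
#' @param chi2_flag reduced-chi-square threshold above which the fit is
#'   flagged.
#' @param fit_states when `TRUE`, a first stage refines the two state
#'   distances and the occupancy on the shortest window (in the
#'   slow-exchange limit) before the rates are fitted -- the global
#'   procedure used for real measurements, which keeps static shape
#'   mismatches out of the kinetic parameters.
#' @return a `pda_fit` list.
#' @export
fit_dynamic_pda <- function(window_data, pm, breaks = seq(0, 1, 0.05),
                            bg_counts_per_ms = c(donor = 0, acceptor = 0),
                            init = NULL, chi2_flag = 3,
                            fit_states = FALSE) {
  stopifnot(length(window_data) >= 1)
  w_ms <- as.numeric(names(window_data))
  if (any(is.na(w_ms))) stop("window_data must be named by length in ms")
  nb <- length(breaks) - 1
  obs <- lapply(window_data, function(d)
    tabulate(pmin(pmax(findInterval(d$E_app, breaks,
                                    rightmost.closed = TRUE), 1), nb),
             nbins = nb))
  caches <- vector("list", length(window_data))
  if (fit_states && nrow(pm$model$states) == 2) {
    iw <- which.min(w_ms)
    obs1 <- obs[[iw]]
    st <- pm$model$states
    R0s <- if (!is.null(st$R)) st$R else pm$r0_A * (1 / st$E - 1)^(1 / 6)
    stage1 <- function(p) {
      st2 <- st
      st2$R <- c(p[1], p[2])
      st2$E <- NULL
      p1 <- stats::plogis(p[3])
      pm2 <- pm
      pm2$model$states <- st2
      ks <- 1 / 50e-3   # slow-exchange limit
      pr <- pda_predict(pm2, w_ms[iw] * 1e-3, window_data[[iw]]$N,
                        breaks = breaks, k12 = ks * (1 - p1),
                        k21 = ks * p1,
                        bg_counts = bg_counts_per_ms * w_ms[iw])
      e <- pr$density * sum(obs1)
      sum((obs1 - e)^2 / pmax(e, 0.5))
    }
    p10 <- pm$model$stationary[1]
    s1 <- optim(c(R0s, stats::qlogis(min(max(p10, 0.05), 0.95))), stage1,
                method = "Nelder-Mead",
                control = list(maxit = 120, reltol = 1e-5))
    stR <- c(s1$par[1], s1$par[2])
    p1_hat <- stats::plogis(s1$par[3])
    pm$model$states$R <- stR
    pm$model$states$E <- NULL
    # keep the fitted occupancy by constraining the rate ratio
    ratio_fix <- (1 - p1_hat) / p1_hat   # k12/k21
  } else {
    ratio_fix <- NULL
  }
  chi2 <- function(p) {
    k12 <- exp(p[1]); k21 <- exp(p[2])
    tot <- 0
    for (i in seq_along(window_data)) {
      pr <- pda_predict(pm, w_ms[i] * 1e-3, window_data[[i]]$N,
                        breaks = breaks, k12 = k12, k21 = k21,
                        bg_counts = bg_counts_per_ms * w_ms[i],
                        cache = caches[[i]])
      caches[[i]] <<- pr$cache
      e <- pr$density * sum(obs[[i]])
      tot <- tot + sum((obs[[i]] - e)^2 / pmax(e, 0.5))
    }
    tot
  }
  # multi-start: the chi-square surface along the total rate is shallow in
  # the slow-exchange regime, so several relaxation-time starts are tried
  if (!is.null(ratio_fix)) {
    # occupancy fixed from stage 1: optimise the total rate only
    chi1 <- function(lks) {
      ks <- exp(lks)
      chi2(log(c(ks * ratio_fix / (1 + ratio_fix),
                 ks / (1 + ratio_fix))))
    }
    ops <- lapply(log(c(0.5, 0.5) / c(1.5e-3, 5e-3, 15e-3, 50e-3)),
                  function(s0) optim(s0, chi1, method = "Brent",
                                     lower = s0 - 2.5, upper = s0 + 2.5))
    op <- ops[[which.min(vapply(ops, `[[`, numeric(1), "value"))]]
    ks <- exp(op$par[1])
    k12 <- ks * ratio_fix / (1 + ratio_fix)
    k21 <- ks / (1 + ratio_fix)
    op$value <- op$value
  } else {
    starts <- if (!is.null(init)) list(log(init)) else {
      relax_ms <- c(1.5, 5, 15, 50)
      lapply(relax_ms, function(r) log(c(0.5, 0.5) / (r * 1e-3)))
    }
    ops <- lapply(starts, function(s0)
      optim(s0, chi2, method = "Nelder-Mead",
            control = list(maxit = 300, reltol = 1e-6)))
    op <- ops[[which.min(vapply(ops, `[[`, numeric(1), "value"))]]
    k12 <- exp(op$par[1]); k21 <- exp(op$par[2])
  }
  dof <- nb * length(window_data) - 2
  out <- list(k12 = k12, k21 = k21,
              relaxation_s = 1 / (k12 + k21),
              chi2 = op$value, chi2_red = op$value / dof,
              states = pm$model$states,
              flagged = op$value / dof > chi2_flag ||
                op$convergence != 0,
              convergence = op$convergence)
  class(out) <- "pda_fit"
  out
}
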