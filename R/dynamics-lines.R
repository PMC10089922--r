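# Dynamics detection via burst variance analysis (BVA) and FRET-efficiency
# versus donor-lifetime analysis: static and dynamic FRET lines, dynamic
# shifts and the inversion of a dynamic shift into a distance-fluctuation
# amplitude.

#' Shot-noise-limited BVA standard deviation
#'
#' Expected standard deviation of the apparent FRET efficiency over
#' `n`-photon windows for a static molecule: sigma = sqrt(E (1 - E) / n)
#' (the BVA semicircle).
#'
#' @param E_app apparent FRET efficiency.
#' @param n photons per window.
#' @export
bva_expected_sigma <- function(E_app, n = 5) {
  stopifnot(n >= 2, all(E_app >= 0 & E_app <= 1))
  sqrt(E_app * (1 - E_app) / n)
}

#' Burst variance analysis
#'
#' For each burst, the apparent FRET efficiency is computed over consecutive
#' non-overlapping windows of `n` donor-excitation photons and the
#' empirical standard deviation across windows (Bessel plus c4 finite-sample
#' correction, so that static bursts center on the semicircle even with few
#' windows) is compared to the shot-noise semicircle. Dynamics show up as excess standard deviation.
#' The population center (E0, sigma0) is the mean of a two-dimensional
#' Gaussian fit (sample moments), and the dynamic shift is
#' ds_BVA = sigma0 - sqrt(E0 (1 - E0)/n).
#'
#' @param stream a labelled [photon_stream()].
#' @param bursts a `burst_table` (typically the FRET-pair subset).
#' @param n photons per window (default 5).
#' @param bin_width width of the E bins for the bin-averaged sigma.
#' @param min_windows bursts with fewer windows are excluded.
#' @return a `bva_result`: per-burst table, per-bin average sigma, the
#'   population center and `ds`.
#' @export
bva <- function(stream, bursts, n = 5, bin_width = 0.05, min_windows = 2) {
  band <- stream$map$band[match(stream$detector, stream$map$detector)]
  exc <- stream$excitation
  if (is.null(exc)) stop("assign excitation before BVA")
  is_dex <- !is.na(exc) & exc == "Dex"
  is_acc <- band == "acceptor"
  nb <- nrow(bursts)
  e_burst <- sig_burst <- rep(NA_real_, nb)
  excluded <- 0L
  for (b in seq_len(nb)) {
    idx <- bursts$i0[b]:bursts$i1[b]
    dexi <- idx[is_dex[idx]]
    k <- floor(length(dexi) / n)
    if (k < min_windows) { excluded <- excluded + 1L; next }
    acc <- is_acc[dexi[seq_len(k * n)]]
    ew <- colMeans(matrix(acc, nrow = n))
    e_burst[b] <- mean(is_acc[dexi])
    # c4 correction: E[s] = c4(k) sigma for Gaussian-like window noise
    c4 <- sqrt(2 / (k - 1)) * exp(lgamma(k / 2) - lgamma((k - 1) / 2))
    sig_burst[b] <- sd(ew) / c4
  }
  ok <- is.finite(sig_burst)
  per_burst <- data.frame(burst = bursts$burst[ok], E_app = e_burst[ok],
                          sigma = sig_burst[ok])
  edges <- seq(0, 1, by = bin_width)
  binidx <- findInterval(pmin(pmax(per_burst$E_app, 0), 1 - 1e-9), edges)
  bin_sigma <- tapply(per_burst$sigma, factor(binidx, levels =
                                                seq_len(length(edges) - 1)),
                      mean)
  bins <- data.frame(E_mid = edges[-1] - bin_width / 2,
                     sigma = as.numeric(bin_sigma),
                     n = as.numeric(table(factor(binidx, levels =
                                                   seq_len(length(edges) - 1)))))
  center <- c(E = mean(per_burst$E_app), sigma = mean(per_burst$sigma))
  ds <- unname(center["sigma"] - bva_expected_sigma(center["E"], n))
  structure(list(per_burst = per_burst, bins = bins, center = center,
                 ds = ds, n = n, excluded = excluded),
            class = "bva_result")
}

#' Maximum-likelihood donor lifetime of a burst
#'
#' Fits a single-exponential decay convolved with a Gaussian IRF
#' (exponentially modified Gaussian) plus a flat background term to the
#' donor-channel TCSPC microtimes of one burst, by maximum likelihood.
#'
#' @param mt_ns microtimes (ns) of donor-channel donor-excitation photons.
#' @param window_ns `c(lo, hi)` fit window within the TCSPC period.
#' @param irf_mu_ns,irf_sigma_ns IRF position and width.
#' @param bg_fraction flat-background fraction; `NA` (default) fits it.
#' @param tau_range_ns allowed lifetime range.
#' @param min_photons below this, `NA` is returned.
#' @return fitted lifetime (ns) or `NA`.
#' @export
burst_lifetime <- function(mt_ns, window_ns = c(0, 25), irf_mu_ns = 2,
                           irf_sigma_ns = 0.25, bg_fraction = NA,
                           tau_range_ns = c(0.05, 10), min_photons = 20) {
  mt <- mt_ns[mt_ns >= window_ns[1] & mt_ns < window_ns[2]]
  if (length(mt) < min_photons) return(NA_real_)
  W <- diff(window_ns)
  logdens <- function(tau, b) {
    le <- .lemg(mt, irf_mu_ns, irf_sigma_ns, tau)
    sum(log(pmax((1 - b) * exp(le) + b / W, 1e-300)))
  }
  if (is.na(bg_fraction)) {
    obj <- function(p) -logdens(exp(p[1]), stats::plogis(p[2]))
    op <- optim(c(log(max(mean(mt) - irf_mu_ns, 0.2)), stats::qlogis(0.05)),
                obj, method = "Nelder-Mead",
                control = list(maxit = 500))
    tau <- exp(op$par[1])
  } else {
    op <- optimize(function(lt) -logdens(exp(lt), bg_fraction),
                   log(tau_range_ns))
    tau <- exp(op$minimum)
  }
  if (tau < tau_range_ns[1] || tau > tau_range_ns[2]) return(NA_real_)
  tau
}

# log density of Exp(tau) convolved with N(mu, sigma^2)
.lemg <- function(t, mu, sigma, tau) {
  if (sigma <= 0) {
    out <- ifelse(t >= mu, -(t - mu) / tau - log(tau), -Inf)
    return(out)
  }
  -log(tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    pnorm((t - mu) / sigma - sigma / tau, log.p = TRUE)
}

#' Per-burst donor lifetimes for a burst table
#'
#' Applies [burst_lifetime()] to the donor-channel Dex microtimes of each
#' burst.
#'
#' @param stream a labelled PIE [photon_stream()].
#' @param bursts a `burst_table`.
#' @param bg optional [background_model()]: the flat-background fraction of
#'   each burst is then fixed at rate x duration / donor counts instead of
#'   being fitted per burst (removes the small-sample bias of the
#'   two-parameter fit).
#' @param ... passed to [burst_lifetime()].
#' @return numeric vector of lifetimes (ns), `NA` where undeterminable.
#' @export
burst_lifetimes <- function(stream, bursts, bg = NULL, ...) {
  if (is.null(stream$microtime_ns))
    stop("lifetime analysis requires microtimes (PIE mode)")
  band <- stream$map$band[match(stream$detector, stream$map$detector)]
  exc <- stream$excitation
  is_don <- band == "donor" & !is.na(exc) & exc == "Dex"
  vapply(seq_len(nrow(bursts)), function(b) {
    idx <- bursts$i0[b]:bursts$i1[b]
    mt <- stream$microtime_ns[idx[is_don[idx]]]
    bfrac <- NA
    if (!is.null(bg) && length(mt))
      bfrac <- min(bg$rates[["DD"]] * (bursts$t1[b] - bursts$t0[b]) /
                     length(mt), 0.8)
    burst_lifetime(mt, bg_fraction = bfrac, ...)
  }, numeric(1))
}

#' Static FRET line
#'
#' Relation between intensity-based FRET efficiency and the
#' fluorescence-weighted average donor lifetime for static molecules. With
#' zero linker width this is the ideal straight line E = 1 - tau/tau_D(0);
#' with Gaussian distance fluctuations of width `sigma_linker` around each
#' mean distance, the species-averaged E and photon-weighted lifetime
#' <tau>_F = <tau^2>/<tau> trace a slightly curved line. The curve is
#' computed by Gaussian quadrature over the distance distribution and
#' returned both as dense samples and as a fast cubic-polynomial
#' approximation.
#'
#' @param tau_d0_ns intrinsic donor lifetime (ns).
#' @param sigma_linker_A linker-induced distance SD (Angstrom; 0 for the
#'   ideal line).
#' @param r0_A Forster radius.
#' @param n_nodes quadrature nodes; `n_grid` mean-distance samples.
#' @param n_grid grid size along the curve.
#' @return a `fret_line`: function `E_of_tau`, sample table, cubic
#'   coefficients.
#' @export
static_fret_line <- function(tau_d0_ns, sigma_linker_A = 6, r0_A = 65,
                             n_nodes = 64, n_grid = 200) {
  stopifnot(tau_d0_ns > 0)
  if (sigma_linker_A <= 0) {
    f <- function(tau) 1 - tau / tau_d0_ns
    samples <- data.frame(tau = seq(0, tau_d0_ns, length.out = n_grid))
    samples$E <- f(samples$tau)
    return(structure(list(E_of_tau = f, samples = samples,
                          cubic = c(1, -1 / tau_d0_ns, 0, 0),
                          tau_d0_ns = tau_d0_ns, sigma_linker_A = 0,
                          r0_A = r0_A),
                     class = "fret_line"))
  }
  rbar <- seq(0.3 * r0_A, 2.5 * r0_A, length.out = n_grid)
  gh_z <- seq(-5, 5, length.out = n_nodes)
  tau_x <- E_y <- numeric(n_grid)
  for (i in seq_len(n_grid)) {
    r <- rbar[i] + gh_z * sigma_linker_A
    wq <- dnorm(gh_z)
    keep <- r > 1
    r <- r[keep]; wq <- wq[keep] / sum(wq[keep])
    e <- distance_to_efficiency(r, r0_A)
    tau <- tau_d0_ns * (1 - e)
    E_y[i] <- 1 - sum(wq * tau) / tau_d0_ns      # species-averaged E
    tau_x[i] <- sum(wq * tau^2) / sum(wq * tau)  # photon-weighted lifetime
  }
  ord <- order(tau_x)
  samples <- data.frame(tau = tau_x[ord], E = E_y[ord])
  f <- approxfun(samples$tau, samples$E, rule = 2)
  cf <- coef(lm(E ~ poly(tau, 3, raw = TRUE), data = samples))
  structure(list(E_of_tau = f, samples = samples, cubic = unname(cf),
                 tau_d0_ns = tau_d0_ns, sigma_linker_A = sigma_linker_A,
                 r0_A = r0_A),
            class = "fret_line")
}

#' Dynamic FRET line for two-state exchange
#'
#' Molecules interconverting between two states (E1, tau1) and (E2, tau2)
#' with tau_i = tau_D(0)(1 - E_i) fall on the mixing curve
#' E(<tau>_F) = 1 - (tau1 tau2 / (tau1 + tau2 - <tau>_F)) / tau_D(0),
#' whose endpoints coincide with the states.
#'
#' @param E1,E2 state efficiencies.
#' @param tau_d0_ns intrinsic donor lifetime.
#' @return a `fret_line` whose `E_of_tau` errors outside [min, max] of the
#'   state lifetimes.
#' @export
dynamic_fret_line <- function(E1, E2, tau_d0_ns) {
  tau1 <- tau_d0_ns * (1 - E1)
  tau2 <- tau_d0_ns * (1 - E2)
  lo <- min(tau1, tau2); hi <- max(tau1, tau2)
  f <- function(tau) {
    if (any(tau < lo - 1e-9 | tau > hi + 1e-9))
      stop("lifetime outside the dynamic-line domain [",
           signif(lo, 4), ", ", signif(hi, 4), "] ns")
    1 - (tau1 * tau2 / (tau1 + tau2 - tau)) / tau_d0_ns
  }
  samples <- data.frame(tau = seq(lo, hi, length.out = 100))
  samples$E <- f(samples$tau)
  structure(list(E_of_tau = f, samples = samples,
                 states = data.frame(E = c(E1, E2), tau = c(tau1, tau2)),
                 tau_d0_ns = tau_d0_ns),
            class = "fret_line")
}

#' Dynamic shift in the E-tau plane
#'
#' The vertical offset of the population center (tau0, E0) from the static
#' FRET line: ds = E0 - E_static(tau0); the sign is retained. The center is
#' the mean of a two-dimensional Gaussian fit to the per-burst (tau, E)
#' scatter.
#'
#' @param E,tau_ns per-burst efficiencies and donor lifetimes (NA dropped),
#'   or give `center = c(tau, E)` directly.
#' @param static_line a `fret_line` from [static_fret_line()].
#' @param center optional `c(tau0, E0)` overriding the fit.
#' @return list with `ds`, `center`.
#' @export
dynamic_shift_etau <- function(E = NULL, tau_ns = NULL, static_line,
                               center = NULL) {
  if (is.null(center)) {
    ok <- is.finite(E) & is.finite(tau_ns)
    if (sum(ok) < 10) stop("too few bursts with E and lifetime")
    center <- c(tau = mean(tau_ns[ok]), E = mean(E[ok]))
  }
  rng <- range(static_line$samples$tau)
  if (center[1] < rng[1] - 1e-6 || center[1] > rng[2] + 1e-6)
    stop("population lifetime outside the static-line domain")
  ds <- unname(center[2] - static_line$E_of_tau(center[1]))
  list(ds = ds, center = center)
}

#' Distance-fluctuation amplitude from a dynamic shift
#'
#' Assumes dynamics between two nearby states at distances R<E> +/- dR with
#' equal occupancy, and numerically inverts the two-state mixing model to
#' find the dR that reproduces the observed dynamic shift (after baseline
#' subtraction). Returns 0 when ds is at or below the baseline.
#'
#' @param ds observed dynamic shift (E units).
#' @param R_mean central distance R<E> (Angstrom); alternatively give `E0`.
#' @param r0_A Forster radius; `tau_d0_ns` donor lifetime.
#' @param E0 central efficiency (used if `R_mean` missing).
#' @param static_line optional `fret_line` (default: ideal straight line).
#' @param baseline static-reference ds subtracted before inversion.
#' @return list with `delta_R_A`, the bracketing diagnostics and the
#'   forward-model function.
#' @export
estimate_delta_R <- function(ds, R_mean = NULL, r0_A = 65, tau_d0_ns = 4,
                             E0 = NULL, static_line = NULL, baseline = 0) {
  if (is.null(static_line))
    static_line <- static_fret_line(tau_d0_ns, 0, r0_A)
  if (is.null(R_mean)) {
    if (is.null(E0)) stop("give R_mean or E0")
    R_mean <- efficiency_to_distance(E0, r0_A)$R
  }
  forward <- function(dR) {
    e <- distance_to_efficiency(c(R_mean - dR, R_mean + dR), r0_A)
    tau <- tau_d0_ns * (1 - e)
    tauF <- sum(tau^2) / sum(tau)
    mean(e) - static_line$E_of_tau(tauF)
  }
  ds_eff <- ds - baseline
  if (ds_eff <= 0) return(list(delta_R_A = 0, forward = forward))
  hi <- min(R_mean - 1, 60)
  if (forward(hi) < ds_eff)
    stop("dynamic shift not reachable by the two-state model ",
         "(bracket [0, ", hi, "] max ", signif(forward(hi), 3), ")")
  root <- uniroot(function(d) forward(d) - ds_eff, c(0, hi), tol = 1e-6)
  list(delta_R_A = root$root, iter = root$iter, forward = forward)
}
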