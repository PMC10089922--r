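# Species-filtered fluorescence correlation spectroscopy: statistical
# filters built from reference microtime/channel patterns, burst-restricted
# photon-pair correlation on a quasi-logarithmic lag grid, and a global fit
# of species auto- and cross-correlations with shared relaxation times.

#' Statistical species filters from reference patterns
#'
#' Given the normalised (channel x microtime-bin) photon patterns of two
#' species, computes per-bin weight vectors w_s such that filtering is
#' unbiased: sum_b w_s(b) p_s'(b) = delta_ss'. The weights are the
#' generalised-least-squares solution with the mixed (total) pattern as the
#' covariance proxy: W = (M^T C^-1 M)^-1 M^T C^-1.
#'
#' @param patterns matrix (bins x species), columns sum to 1.
#' @param mix mixing fractions used for the covariance proxy (default equal).
#' @return matrix (species x bins) of filter weights.
#' @export
species_filters <- function(patterns, mix = NULL) {
  M <- as.matrix(patterns)
  if (ncol(M) < 2) stop("need at least two species patterns")
  M <- sweep(M, 2, colSums(M), "/")
  if (is.null(mix)) mix <- rep(1 / ncol(M), ncol(M))
  tot <- as.numeric(M %*% mix)
  keep <- tot > 0
  Mk <- M[keep, , drop = FALSE]
  Cinv <- 1 / tot[keep]
  G <- t(Mk) %*% (Cinv * Mk)
  if (rcond(G) < 1e-12)
    stop("reference patterns are collinear; filters are not identifiable")
  W <- solve(G, t(Mk) * rep(Cinv, each = ncol(Mk)))
  out <- matrix(0, ncol(M), nrow(M))
  out[, keep] <- W
  rownames(out) <- colnames(M)
  out
}

#' Reference patterns from E-selected subensembles
#'
#' Builds the (channel x microtime-bin) reference patterns of the low- and
#' high-FRET species from bursts at the lower and upper edge of the
#' apparent-efficiency histogram, using the Dex photons of both detection
#' channels.
#'
#' @param stream labelled PIE [photon_stream()].
#' @param bursts `burst_table` with `E_app` (e.g. the `fret` subset of
#'   [select_bursts()], else computed from raw counts).
#' @param e_low,e_high E_app ranges defining the two subensembles.
#' @param mt_breaks microtime bin edges (ns) within the Dex window.
#' @return list with `patterns` (bins x 2), `assign_bins(stream)` helper
#'   mapping photons to pattern bins (`NA` for non-Dex photons).
#' @export
reference_patterns <- function(stream, bursts, e_low = c(0, 0.4),
                               e_high = c(0.75, 1),
                               mt_breaks = seq(0, 25, by = 1)) {
  if (is.null(stream$microtime_ns))
    stop("filtered FCS requires microtimes")
  e_app <- if (!is.null(bursts$E_app)) bursts$E_app else
    apparent_E(bursts$DD, bursts$AD)
  sel_lo <- which(e_app >= e_low[1] & e_app <= e_low[2])
  sel_hi <- which(e_app >= e_high[1] & e_app <= e_high[2])
  if (length(sel_lo) < 10 || length(sel_hi) < 10)
    stop("too few bursts in a reference subensemble (",
         length(sel_lo), " low, ", length(sel_hi), " high)")
  nmt <- length(mt_breaks) - 1
  assign_bins <- function(str) {
    band <- str$map$band[match(str$detector, str$map$detector)]
    exc <- str$excitation
    ok <- !is.na(exc) & exc == "Dex"
    mtb <- findInterval(str$microtime_ns, mt_breaks,
                        rightmost.closed = TRUE)
    out <- rep(NA_integer_, length(band))
    good <- ok & mtb >= 1 & mtb <= nmt
    out[good] <- mtb[good] + ifelse(band[good] == "acceptor", nmt, 0)
    out
  }
  bins <- assign_bins(stream)
  patt <- function(sel) {
    idx <- unlist(lapply(sel, function(b) bursts$i0[b]:bursts$i1[b]))
    tabulate(bins[idx], nbins = 2 * nmt)
  }
  P <- cbind(low = patt(sel_lo), high = patt(sel_hi))
  P <- sweep(P, 2, colSums(P), "/")
  list(patterns = P, assign_bins = assign_bins, mt_breaks = mt_breaks)
}

#' Quasi-logarithmic lag grid
#'
#' @param lag_min_s,lag_max_s lag range (s).
#' @param pts_per_decade grid density.
#' @export
lag_grid <- function(lag_min_s = 2e-6, lag_max_s = 1e-2,
                     pts_per_decade = 8) {
  n <- ceiling(log10(lag_max_s / lag_min_s) * pts_per_decade)
  exp(seq(log(lag_min_s), log(lag_max_s), length.out = n + 1))
}

#' Burst-restricted weighted photon correlation
#'
#' Correlates (species-weighted) photon streams by direct pair counting
#' within bursts on a quasi-logarithmic lag grid. The normalisation uses
#' the global mean weight rates over the in-burst time together with the
#' per-burst geometric lag overlap, so slow kinetic components are not
#' detrended by per-burst averaging; burst-to-burst brightness variation
#' contributes a lag-independent offset absorbed by the fit. Returns both
#' species autocorrelations (SACF) and the symmetrised species
#' cross-correlation (SCCF).
#'
#' @param stream labelled [photon_stream()].
#' @param bursts `burst_table` defining the correlated segments.
#' @param w1,w2 per-photon species weights (recycled to all photons; use 1
#'   for a plain autocorrelation).
#' @param lag_edges lag-bin edges (s), see [lag_grid()].
#' @return data frame with lag midpoints and columns `sacf1`, `sacf2`,
#'   `sccf`, plus the raw pair counts.
#' @export
correlate_bursts <- function(stream, bursts, w1 = 1, w2 = 1,
                             lag_edges = lag_grid()) {
  if (!nrow(bursts)) stop("empty burst table")
  tt <- photon_times(stream)
  nph <- length(tt)
  w1 <- rep_len(w1, nph); w2 <- rep_len(w2, nph)
  idx <- unlist(lapply(seq_len(nrow(bursts)), function(b)
    bursts$i0[b]:bursts$i1[b]))
  bid <- rep(seq_len(nrow(bursts)),
             bursts$i1 - bursts$i0 + 1)
  res <- pair_correlate(tt[idx], as.integer(bid), w1[idx], w2[idx],
                        lag_edges, bursts$t0, bursts$t1)
  mid <- sqrt(lag_edges[-1] * lag_edges[-length(lag_edges)])
  rho1 <- res$wsum1 / res$tsum
  rho2 <- res$wsum2 / res$tsum
  rhot <- res$nphot / res$tsum
  div <- function(g, rr, n) ifelse(n > 0, g / (rr * n) - 1, NA_real_)
  out <- data.frame(lag_s = mid,
                    sacf1 = div(res$g11, rho1 * rho1, res$ngeo),
                    sacf2 = div(res$g22, rho2 * rho2, res$ngeo),
                    sccf = div((res$g12 + res$g21) / 2, rho1 * rho2,
                               res$ngeo),
                    total = div(res$gtt, rhot * rhot, res$ngeo),
                    pairs1 = res$n11, pairs2 = res$n22, pairs12 = res$n12,
                    pairs_total = res$gtt)
  # species curves normalised by the total correlation: burst-brightness
  # and transit structure are common to all curves and cancel in the
  # ratio, leaving the kinetic terms (total brightness is nearly
  # state-independent)
  for (cc in c("sacf1", "sacf2", "sccf"))
    out[[paste0(cc, "_norm")]] <- (1 + out[[cc]]) / (1 + out$total) - 1
  out
}

#' Global FCS fit with shared relaxation times
#'
#' Fits all supplied correlation curves jointly with the model
#' G_c(tau) = (1 + tau/tau_d)^-1 (g0_c + sum_i a_ci exp(-tau/t_Ri)),
#' sharing the diffusion time and the kinetic relaxation times across
#' curves; per-curve amplitudes (negative allowed, e.g. anti-correlated
#' cross-correlations) are profiled out analytically at each step, so only
#' the time constants are optimised numerically.
#'
#' @param curves data frame from [correlate_bursts()] (or any data frame
#'   with `lag_s` and one column per curve).
#' @param curve_cols column names to fit jointly.
#' @param n_relax number of kinetic relaxation terms (1 or 2).
#' @param t_init initial relaxation times (s).
#' @param tau_d_init initial diffusion time (s).
#' @param weights optional per-row weights (default sqrt of the pair-count
#'   normalisation if present).
#' @param envelope `"diffusion"` fits a shared 1/(1 + tau/tau_d) transit
#'   term; `"flat"` fits none (appropriate for total-normalised curves,
#'   where transit and brightness structure already cancel).
#' @return an `fcs_fit`: sorted relaxation times `t_relax_s`, per-curve
#'   amplitude matrix, diffusion time and diagnostics.
#' @export
fit_fcs <- function(curves, curve_cols = c("sacf1", "sacf2", "sccf"),
                    n_relax = 2, t_init = NULL, tau_d_init = 2e-3,
                    weights = NULL, envelope = c("diffusion", "flat")) {
  stopifnot(n_relax %in% 1:2, length(curve_cols) >= 1)
  envelope <- match.arg(envelope)
  lag <- curves$lag_s
  Y <- as.matrix(curves[, curve_cols, drop = FALSE])
  ok <- rowSums(!is.finite(Y)) == 0
  lag <- lag[ok]; Y <- Y[ok, , drop = FALSE]
  if (length(lag) < 8) stop("too few finite lag points to fit")
  if (is.null(t_init))
    t_init <- exp(seq(log(min(lag) * 3), log(max(lag) / 3),
                      length.out = n_relax + 2))[2:(n_relax + 1)]
  w <- if (is.null(weights)) {
    if ("pairs1" %in% names(curves)) sqrt(pmax(curves$pairs1[ok], 1)) else
      rep(1, length(lag))
  } else weights[ok]
  nc <- ncol(Y)
  # profile the per-curve linear amplitudes for given time constants;
  # with two terms the second time is parameterised as t2 = t1 (2 + e^p2)
  # so the components cannot collapse onto each other
  times_of <- function(p) {
    if (n_relax == 1) exp(p[1]) else exp(p[1]) * c(1, 2 + exp(p[2]))
  }
  profiled <- function(p) {
    tr <- times_of(p)
    env <- if (envelope == "flat") rep(1, length(lag)) else
      1 / (1 + lag / exp(p[n_relax + 1]))
    X <- cbind(env, env * exp(-outer(lag, 1 / tr)))
    rss <- 0
    amps <- matrix(NA_real_, nc, 1 + n_relax)
    for (i in seq_len(nc)) {
      fit <- lm.fit(X * w, Y[, i] * w)
      rss <- rss + sum(fit$residuals^2)
      amps[i, ] <- fit$coefficients
    }
    list(rss = rss, amps = amps)
  }
  obj <- function(p) profiled(p)$rss
  # multi-start: relaxation-time pairs spanning the lag range
  to_par <- function(tt) {
    tt <- sort(tt)
    if (n_relax == 1) log(tt) else
      c(log(tt[1]), log(max(tt[2] / tt[1] - 2, 0.2)))
  }
  tdpar <- if (envelope == "flat") NULL else log(tau_d_init)
  starts <- list(c(to_par(t_init), tdpar))
  if (n_relax == 2) {
    cand <- exp(seq(log(min(lag) * 2), log(max(lag) / 2), length.out = 5))
    for (i in 1:4) for (j in (i + 1):5)
      starts <- c(starts, list(c(to_par(c(cand[i], cand[j])), tdpar)))
  }
  ops <- lapply(starts, function(s0)
    optim(s0, obj, method = "Nelder-Mead",
          control = list(maxit = 800, reltol = 1e-10)))
  op <- ops[[which.min(vapply(ops, `[[`, numeric(1), "value"))]]
  p <- op$par
  tr <- times_of(p)
  ord <- order(tr)
  pro <- profiled(p)
  amps <- pro$amps[, c(1, 1 + ord), drop = FALSE]
  colnames(amps) <- c("g0", paste0("a", seq_len(n_relax)))
  rownames(amps) <- curve_cols
  bound_warn <- any(tr < min(lag) * 1.2 | tr > max(lag) / 1.2)
  if (bound_warn)
    warning("a relaxation time sits near the lag-grid bounds")
  structure(list(t_relax_s = tr[ord],
                 tau_d_s = if (envelope == "flat") Inf else
                   exp(p[n_relax + 1]),
                 amplitudes = amps, deviance = pro$rss,
                 convergence = op$convergence,
                 boundary_warning = bound_warn),
            class = "fcs_fit")
}
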