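# Determination and application of the four correction factors (alpha,
# beta, gamma, delta) that turn apparent photon counts into accurate FRET
# efficiencies and stoichiometries, plus the gamma-driven uncertainty
# propagation.

#' Correction-factor set
#'
#' Holds the four corrections for spectral crosstalk (alpha), excitation-flux
#' normalisation (beta), detection-efficiency/quantum-yield ratio (gamma) and
#' direct acceptor excitation (delta), with optional uncertainties and the
#' provenance of each determination.
#'
#' @param alpha,beta,gamma,delta correction factors; alpha, delta >= 0 and
#'   beta, gamma > 0.
#' @param d_alpha,d_beta,d_gamma,d_delta uncertainties. `d_gamma` defaults to
#'   the study-level 23 percent relative uncertainty of gamma.
#' @param provenance free-form description of how the factors were obtained.
#' @export
correction_set <- function(alpha, beta, gamma, delta,
                           d_alpha = NA, d_beta = NA,
                           d_gamma = 0.23 * gamma, d_delta = NA,
                           provenance = "") {
  if (alpha < 0 || delta < 0) stop("alpha and delta must be nonnegative")
  if (beta <= 0 || gamma <= 0) stop("beta and gamma must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 d_alpha = d_alpha, d_beta = d_beta, d_gamma = d_gamma,
                 d_delta = d_delta, provenance = provenance),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  cat(sprintf("corrections: alpha=%.4g beta=%.4g gamma=%.4g delta=%.4g\n",
              x$alpha, x$beta, x$gamma, x$delta))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n")
  invisible(x)
}

#' Apparent (raw) FRET efficiency
#'
#' E_app = I_Aem|Dex / (I_Dem|Dex + I_Aem|Dex). Bursts with a zero
#' denominator are undefined and returned as `NA` (flagged).
#'
#' @param dd,ad donor-excitation donor/acceptor counts (vectors).
#' @export
apparent_E <- function(dd, ad) {
  den <- dd + ad
  out <- ad / den
  out[den <= 0] <- NA_real_
  out
}

#' Apparent stoichiometry
#'
#' S_app = (I_Dem|Dex + I_Aem|Dex) / (I_Dem|Dex + I_Aem|Dex + I_Aem|Aex),
#' computed from (optionally background-corrected) counts.
#'
#' @param dd,ad,aa channel counts.
#' @export
apparent_S <- function(dd, ad, aa) {
  den <- dd + ad + aa
  out <- (dd + ad) / den
  out[den <= 0] <- NA_real_
  out
}

#' Background-correct channel counts
#'
#' Subtracts `rate x duration` from each channel:
#' iiI_X = iI_X - rate_X * duration. Negative results are allowed (they can
#' arise from background subtraction) and flagged via the `negative`
#' attribute.
#'
#' @param counts matrix or data frame with columns `DD`, `AD`, `AA`.
#' @param bg a [background_model()] (rates in Hz per channel).
#' @param duration_s per-burst duration in seconds.
#' @return numeric matrix of corrected counts with columns `DD`, `AD`, `AA`.
#' @export
background_correct <- function(counts, bg, duration_s) {
  stopifnot(all(duration_s > 0))
  cc <- as.matrix(as.data.frame(counts)[, c("DD", "AD", "AA")])
  out <- cbind(DD = cc[, "DD"] - bg$rates[["DD"]] * duration_s,
               AD = cc[, "AD"] - bg$rates[["AD"]] * duration_s,
               AA = cc[, "AA"] - bg$rates[["AA"]] * duration_s)
  attr(out, "negative") <- unname(which(rowSums(out < 0) > 0))
  out
}

#' Crosstalk factor from the donor-only population
#'
#' alpha = <E_app>_DO / (1 - <E_app>_DO), with the donor-only E_app center
#' taken from a single-component Gaussian fit (robust against outliers).
#'
#' @param e_app apparent FRET efficiencies of donor-only bursts.
#' @param min_bursts minimum population size.
#' @return list with `alpha`, the fitted center and the burst count.
#' @export
alpha_from_donor_only <- function(e_app, min_bursts = 100) {
  e_app <- e_app[is.finite(e_app)]
  if (length(e_app) < min_bursts)
    stop("too few donor-only bursts for alpha estimation: ", length(e_app))
  ctr <- fit_gaussians(e_app, 1)$components$mean[1]
  list(alpha = ctr / (1 - ctr), center = ctr, n = length(e_app))
}

#' Direct-excitation factor from the acceptor-only population
#'
#' delta = <S_app>_AO / (1 - <S_app>_AO), with the acceptor-only apparent
#' stoichiometry center from a single-component Gaussian fit.
#'
#' @param s_app apparent stoichiometries of acceptor-only bursts.
#' @param min_bursts minimum population size.
#' @export
delta_from_acceptor_only <- function(s_app, min_bursts = 100) {
  s_app <- s_app[is.finite(s_app)]
  if (length(s_app) < min_bursts)
    stop("too few acceptor-only bursts for delta estimation: ",
         length(s_app))
  ctr <- fit_gaussians(s_app, 1)$components$mean[1]
  list(delta = ctr / (1 - ctr), center = ctr, n = length(s_app))
}

#' Corrected acceptor fluorescence after donor excitation
#'
#' F_A|D = iiI_Aem|Dex - alpha iiI_Dem|Dex - delta iiI_Aem|Aex.
#'
#' @param dd,ad,aa background-corrected channel counts.
#' @param alpha,delta crosstalk and direct-excitation factors.
#' @export
fret_signal <- function(dd, ad, aa, alpha, delta) {
  ad - alpha * dd - delta * aa
}

#' Global beta/gamma determination from multiple FRET populations
#'
#' Linear regression of 1/S against E across two or more population centers
#' (E computed with alpha/delta corrections but gamma = beta = 1). With
#' intercept Omega and slope Sigma, beta = Omega + Sigma - 1 and
#' gamma = (Omega - 1) / (Omega + Sigma - 1). This exploits the flat-S
#' property: after correction, the stoichiometry of double-labelled
#' molecules is independent of E.
#'
#' @param E_centers,S_centers centers of at least two FRET populations.
#' @return list with `beta`, `gamma` and the regression fit.
#' @export
beta_gamma_global <- function(E_centers, S_centers) {
  stopifnot(length(E_centers) == length(S_centers))
  if (length(E_centers) < 2)
    stop("need at least two FRET populations with distinct E; ",
         "consider the lifetime-based gamma route for a single population")
  if (max(E_centers) - min(E_centers) < 0.1)
    warning("populations closer than 0.1 in E: beta/gamma regression ",
            "is ill-conditioned")
  fit <- lm(I(1 / S_centers) ~ E_centers)
  omega <- unname(coef(fit)[1])
  sigma <- unname(coef(fit)[2])
  beta <- omega + sigma - 1
  gamma <- (omega - 1) / beta
  if (!is.finite(beta) || beta <= 0 || !is.finite(gamma) || gamma <= 0)
    stop("beta/gamma regression produced non-physical factors (omega=",
         signif(omega, 4), ", sigma=", signif(sigma, 4), ")")
  list(beta = beta, gamma = gamma, intercept = omega, slope = sigma,
       fit = fit)
}

#' Gamma from the static FRET line (lifetime route)
#'
#' For a static sample measured with pulsed excitation, gamma is chosen so
#' that the corrected population center falls on the static FRET line
#' E = 1 - tau/tau_D(0) (optionally the linker-corrected curve). A warning
#' is recorded when the population sits significantly off any static line
#' (dynamic sample).
#'
#' @param dd,ad,aa background-corrected per-burst counts (alpha/delta applied
#'   inside via `alpha`, `delta`).
#' @param tau_ns per-burst donor lifetimes.
#' @param tau_d0_ns intrinsic donor lifetime.
#' @param alpha,delta crosstalk/direct-excitation factors.
#' @param static_line optional function E(tau) (e.g. from
#'   [static_fret_line()]); defaults to the ideal straight line.
#' @param ds_warn dynamic-shift magnitude above which a warning is emitted.
#' @return list with `gamma`, the population center and a `dynamic_warning`
#'   flag.
#' @export
gamma_from_static_line <- function(dd, ad, aa, tau_ns, tau_d0_ns,
                                   alpha = 0, delta = 0,
                                   static_line = NULL, ds_warn = 0.05) {
  keep <- is.finite(tau_ns) & is.finite(dd) & is.finite(ad)
  dd <- dd[keep]; ad <- ad[keep]; aa <- aa[keep]; tau <- tau_ns[keep]
  if (length(dd) < 50) stop("too few bursts with lifetimes for gamma fit")
  f <- fret_signal(dd, ad, aa, alpha, delta)
  if (is.null(static_line))
    static_line <- function(tau) pmin(pmax(1 - tau / tau_d0_ns, 0), 1)
  tau0 <- fit_gaussians(tau, 1,
                        range = c(0, 1.2 * tau_d0_ns))$components$mean[1]
  target <- static_line(tau0)
  center_E <- function(g) {
    e <- f / (g * dd + f)
    fit_gaussians(e, 1, range = c(-0.2, 1.2))$components$mean[1]
  }
  gamma <- uniroot(function(g) center_E(g) - target, c(0.02, 50),
                   tol = 1e-4)$root
  dynamic_warning <- FALSE
  # crude dynamics check: residual spread of E around the static line
  e_fin <- f / (gamma * dd + f)
  resid <- stats::median(e_fin[is.finite(e_fin)]) - target
  if (abs(resid) > ds_warn) {
    dynamic_warning <- TRUE
    warning("population center off the static line by ", signif(resid, 3),
            "; sample may be dynamic - lifetime-route gamma is unreliable")
  }
  list(gamma = gamma, tau_center = tau0, E_center = target,
       dynamic_warning = dynamic_warning)
}

#' Accurate FRET efficiency and stoichiometry
#'
#' E = F_A|D / (gamma iiI_Dem|Dex + F_A|D) and
#' S = (gamma iiI_Dem|Dex + F_A|D) /
#'     (gamma iiI_Dem|Dex + F_A|D + iiI_Aem|Aex / beta).
#' Bursts with zero denominators are returned as `NA`.
#'
#' @param dd,ad,aa background-corrected channel counts.
#' @param cs a [correction_set()].
#' @return data frame with columns `E` and `S`.
#' @export
accurate_E_S <- function(dd, ad, aa, cs) {
  f <- fret_signal(dd, ad, aa, cs$alpha, cs$delta)
  denE <- cs$gamma * dd + f
  E <- f / denE
  E[denE == 0] <- NA_real_
  denS <- denE + aa / cs$beta
  S <- denE / denS
  S[denS == 0] <- NA_real_
  data.frame(E = E, S = S)
}

#' Gamma-driven FRET-efficiency uncertainty
#'
#' Error propagation of the gamma uncertainty into the reported efficiency:
#' Delta E = E (1 - E) Delta gamma / gamma. Maximal at E = 0.5 and symmetric
#' under E <-> 1 - E.
#'
#' @param E FRET efficiency (vectorised).
#' @param rel_dgamma relative gamma uncertainty Delta gamma / gamma
#'   (default: the study-level 23 percent).
#' @export
efficiency_uncertainty <- function(E, rel_dgamma = 0.23) {
  stopifnot(rel_dgamma >= 0)
  E * (1 - E) * rel_dgamma
}
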