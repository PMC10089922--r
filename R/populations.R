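# FRET-efficiency histograms, Gaussian population fits, cross-laboratory
# consensus statistics and Forster distance conversion.

#' Fit Gaussian components to a FRET-efficiency sample
#'
#' Unbinned maximum-likelihood fit (default, via finite Gaussian mixtures)
#' or least-squares fit to a binned histogram. Components are ordered by
#' mean. The reported "mean FRET efficiency" of a population is always a
#' Gaussian component mean.
#'
#' @param x sample of per-burst efficiencies (or stoichiometries).
#' @param n_components 1, 2 or 3.
#' @param method `"mle"` (unbinned) or `"ls"` (binned least squares).
#' @param range fit range; values outside are dropped (used e.g. to exclude
#'   a donor-only peak). Default `c(-0.1, 1.1)`.
#' @param bin_width histogram bin width for `"ls"` and the sigma floor.
#' @param init optional list with `mean`, `sigma`, `weight` start values.
#' @return a `gaussian_fit`: `components` data frame (mean, sigma, weight),
#'   the method, n used and a log-likelihood or residual norm.
#' @export
fit_gaussians <- function(x, n_components = 1,
                          method = c("mle", "ls"),
                          range = c(-0.1, 1.1), bin_width = 0.025,
                          init = NULL) {
  method <- match.arg(method)
  stopifnot(n_components %in% 1:3)
  x <- x[is.finite(x) & x >= range[1] & x <= range[2]]
  if (length(x) < 2 * n_components)
    stop("too few values (", length(x), ") for a ", n_components,
         "-component fit")
  floor_sigma <- bin_width / 2
  if (n_components == 1) {
    s <- sd(x)
    if (!is.finite(s) || s < floor_sigma) {
      warning("degenerate sample: sigma floored at half a bin width")
      s <- floor_sigma
    }
    comps <- data.frame(mean = mean(x), sigma = s, weight = 1)
    ll <- sum(dnorm(x, comps$mean, comps$sigma, log = TRUE))
    return(structure(list(components = comps, n = length(x),
                          method = "mle", loglik = ll),
                     class = "gaussian_fit"))
  }
  if (method == "mle") {
    sub <- if (length(x) > 2000) sample(seq_along(x), 2000) else
      seq_along(x)
    fit <- tryCatch(
      mclust::Mclust(x, G = n_components, modelNames = "V",
                     initialization = list(subset = sub), verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit))
      stop("Gaussian mixture fit did not converge (n=", length(x),
           ", G=", n_components, ")")
    ord <- order(fit$parameters$mean)
    comps <- data.frame(mean = fit$parameters$mean[ord],
                        sigma = sqrt(fit$parameters$variance$sigmasq)[ord],
                        weight = fit$parameters$pro[ord])
    ll <- fit$loglik
  } else {
    h <- hist(x, breaks = seq(range[1], range[2] + bin_width,
                              by = bin_width), plot = FALSE)
    xc <- h$mids; yc <- h$counts
    if (is.null(init)) {
      qs <- quantile(x, probs = (seq_len(n_components) - 0.5) /
                       n_components)
      init <- list(mean = as.numeric(qs),
                   sigma = rep(max(sd(x) / n_components, floor_sigma),
                               n_components),
                   weight = rep(1 / n_components, n_components))
    }
    par0 <- c(init$mean, log(init$sigma), log(init$weight * length(x) *
                                                bin_width))
    k <- n_components
    obj <- function(p) {
      mu <- p[1:k]; sg <- exp(p[(k + 1):(2 * k)])
      am <- exp(p[(2 * k + 1):(3 * k)])
      pred <- rowSums(vapply(1:k, function(i) am[i] * dnorm(xc, mu[i],
                                                            sg[i]),
                             numeric(length(xc))))
      sum((yc - pred)^2)
    }
    op <- optim(par0, obj, method = "BFGS",
                control = list(maxit = 2000))
    mu <- op$par[1:k]; sg <- exp(op$par[(k + 1):(2 * k)])
    am <- exp(op$par[(2 * k + 1):(3 * k)])
    ord <- order(mu)
    comps <- data.frame(mean = mu[ord], sigma = sg[ord],
                        weight = (am / sum(am))[ord])
    ll <- -op$value
  }
  comps$sigma <- pmax(comps$sigma, floor_sigma)
  if (any(diff(comps$mean) < comps$sigma[-nrow(comps)] / 2))
    warning("Gaussian components overlap (|delta mean| < sigma/2)")
  structure(list(components = comps, n = length(x), method = method,
                 loglik = ll),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("Gaussian fit (", x$method, ", n=", x$n, "):\n", sep = "")
  print(round(x$components, 4))
  invisible(x)
}

#' Cross-replicate consensus statistics
#'
#' Grand mean and standard deviation over replicate (e.g. per-laboratory)
#' mean efficiencies; when paired apo/holo means are supplied, the paired
#' differences and their standard deviation. The difference SD is the SD of
#' the per-replicate differences, so replicate-level systematic offsets
#' cancel exactly.
#'
#' @param means replicate means (ignored when `apo`/`holo` given).
#' @param apo,holo paired per-replicate condition means.
#' @return list of consensus statistics.
#' @export
consensus <- function(means = NULL, apo = NULL, holo = NULL) {
  out <- list()
  if (!is.null(apo) || !is.null(holo)) {
    if (is.null(apo) || is.null(holo) || length(apo) != length(holo))
      stop("paired difference statistics need apo and holo means of equal ",
           "length (unpaired input)")
    if (length(apo) < 2) stop("need at least two replicates")
    d <- holo - apo
    out$apo <- list(mean = mean(apo), sd = sd(apo))
    out$holo <- list(mean = mean(holo), sd = sd(holo))
    out$difference <- list(values = d, mean = mean(d), sd = sd(d))
    means <- c(apo, holo)
  }
  if (!is.null(means)) {
    if (length(means) < 2) stop("need at least two replicates")
    out$grand_mean <- mean(means)
    out$sd <- sd(means)
    out$n <- length(means)
  }
  out
}

#' Forster conversion: efficiency to distance
#'
#' R<E> = R0 (1/E - 1)^(1/6), with first-order propagation of the
#' efficiency and Forster-radius uncertainties into distance contributions.
#'
#' @param E FRET efficiency in (0, 1).
#' @param R0 Forster radius (Angstrom).
#' @param dE,dR0 uncertainties to propagate (optional).
#' @return data frame with `R`, `dR_E`, `dR_R0`, `dR` (quadrature sum).
#' @export
efficiency_to_distance <- function(E, R0, dE = 0, dR0 = 0) {
  if (any(E <= 0 | E >= 1)) stop("E must lie strictly in (0, 1)")
  if (any(R0 <= 0)) stop("R0 must be positive")
  R <- R0 * (1 / E - 1)^(1 / 6)
  dR_E <- R0 / 6 * (1 / E - 1)^(-5 / 6) / E^2 * dE
  dR_R0 <- (R / R0) * dR0
  data.frame(R = R, dR_E = dR_E, dR_R0 = dR_R0,
             dR = sqrt(dR_E^2 + dR_R0^2), R0 = R0)
}

#' Forster conversion: distance to efficiency
#'
#' E = 1 / (1 + (R/R0)^6); exact inverse of [efficiency_to_distance()].
#'
#' @param R interdye distance (Angstrom).
#' @param R0 Forster radius (Angstrom).
#' @export
distance_to_efficiency <- function(R, R0) 1 / (1 + (R / R0)^6)
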