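# End-to-end orchestration: photon stream -> background -> bursts ->
# corrections -> populations (-> dynamics), plus cross-replicate consensus
# reports. The R functions are the interface; scripts wrap them where a
# shell entry point is wanted.

#' Pipeline configuration
#'
#' @param burst list of burst-search/selection parameters (`m`, `F`,
#'   `L_min`, `d_only_min`, `a_only_max`, `fret_range`, `min_aa`, and
#'   `min_dex`, the minimum number of donor-excitation photons a burst must
#'   carry to enter population fits -- small bursts carry a shot-noise
#'   ratio bias of order 1/N in corrected E).
#' @param n_components Gaussian components for the E histogram per dataset.
#' @param corrections optional fixed [correction_set()]; when `NULL`,
#'   alpha/delta come from the donor-/acceptor-only populations and
#'   beta/gamma from the global multi-population regression.
#' @param fit_range E fit range (donor-only exclusion is done by range).
#' @param dynamics character vector of analyses to run: any of `"bva"`,
#'   `"etau"`.
#' @param tau_d0_ns donor lifetime for E-tau analyses.
#' @param r0_A Forster radius for distance conversion.
#' @param sigma_linker_A linker width of the static FRET line (0 for the
#'   ideal straight line).
#' @param seed seed for any stochastic steps.
#' @export
pipeline_config <- function(burst = list(), n_components = 1,
                            corrections = NULL, fit_range = c(-0.1, 1.1),
                            dynamics = character(),
                            tau_d0_ns = 4, r0_A = 65, sigma_linker_A = 6,
                            seed = 1) {
  bdef <- list(m = 10, F = 6, L_min = 30, d_only_min = 0.8,
               a_only_max = 0.2, fret_range = c(0.25, 0.75), min_aa = 10,
               min_dex = 60)
  bdef[names(burst)] <- burst
  structure(list(burst = bdef, n_components = n_components,
                 corrections = corrections, fit_range = fit_range,
                 dynamics = dynamics, tau_d0_ns = tau_d0_ns, r0_A = r0_A,
                 sigma_linker_A = sigma_linker_A, seed = seed),
            class = "pipeline_config")
}

# single-dataset stage: bursts, selection, population centers
.pipeline_stage <- function(stream, cfg) {
  if (is.null(stream$excitation)) {
    sch <- stream$meta$excitation_scheme
    if (is.null(sch)) stop("stream carries no excitation scheme")
    stream <- assign_excitation(stream, sch)
  }
  bg <- estimate_background(stream)
  b <- cfg$burst
  bursts <- search_bursts(stream, bg, m = b$m, F = b$F, L_min = b$L_min)
  sel <- select_bursts(bursts, bg, d_only_min = b$d_only_min,
                       a_only_max = b$a_only_max,
                       fret_range = b$fret_range, min_aa = b$min_aa)
  list(stream = stream, bg = bg, bursts = bursts, sel = sel)
}

#' Run the analysis pipeline
#'
#' Executes the ordered stages on one or more photon streams (replicate
#' measurements or different samples sharing the same setup): excitation
#' assignment, background estimation, burst search and ALEX selection,
#' alpha/delta from the donor-/acceptor-only populations, beta/gamma from
#' the global regression across all FRET populations (or a supplied
#' [correction_set()]), accurate E/S, Gaussian population fits and distance
#' conversion, plus optional dynamics analyses. Reruns with the same
#' config and seed give identical numbers.
#'
#' @param streams a [photon_stream()], a [simulate_bursts()] result, or a
#'   (optionally named) list of either.
#' @param config a [pipeline_config()].
#' @return a `pipeline_report`: per-dataset results, the correction set
#'   used with provenance, and the effective config.
#' @export
run_pipeline <- function(streams, config = pipeline_config()) {
  if (inherits(streams, "photon_stream") ||
      (is.list(streams) && !is.null(streams$stream)))
    streams <- list(dataset1 = streams)
  if (is.null(names(streams)))
    names(streams) <- paste0("dataset", seq_along(streams))
  streams <- lapply(streams, function(s)
    if (inherits(s, "photon_stream")) s else s$stream)
  set.seed(config$seed)
  stages <- lapply(streams, .pipeline_stage, cfg = config)
  failures <- list()

  # correction factors
  cs <- config$corrections
  provenance <- if (!is.null(cs)) "supplied" else NULL
  if (is.null(cs)) {
    alphas <- deltas <- numeric(0)
    centers_E <- centers_S <- numeric(0)
    for (nm in names(stages)) {
      st <- stages[[nm]]
      don <- st$sel$donor_only
      don <- don[don$DD + don$AD >= config$burst$min_dex, , drop = FALSE]
      aon <- st$sel$acceptor_only
      aon <- aon[aon$AA >= config$burst$min_dex, , drop = FALSE]
      a_try <- tryCatch(alpha_from_donor_only(don$E_app)$alpha,
                        error = function(e) NA_real_)
      d_try <- tryCatch(delta_from_acceptor_only(aon$S_app)$delta,
                        error = function(e) NA_real_)
      alphas <- c(alphas, a_try); deltas <- c(deltas, d_try)
    }
    alpha <- mean(alphas, na.rm = TRUE)
    delta <- mean(deltas, na.rm = TRUE)
    if (!is.finite(alpha) || !is.finite(delta))
      stop("alpha/delta could not be determined from any dataset")
    for (nm in names(stages)) {
      st <- stages[[nm]]
      fr <- st$sel$fret
      fr <- fr[fr$DD + fr$AD >= config$burst$min_dex, , drop = FALSE]
      if (nrow(fr) < 50) next
      f <- fret_signal(fr$DDc, fr$ADc, fr$AAc, alpha, delta)
      e_pr <- f / (fr$DDc + f)
      s_pr <- (fr$DDc + f) / (fr$DDc + f + fr$AAc)
      ne <- config$n_components
      fe <- fit_gaussians(e_pr, ne, range = config$fit_range)
      for (ci in seq_len(ne)) {
        ctr <- fe$components$mean[ci]
        # stoichiometry center of bursts near this E component
        wsel <- abs(e_pr - ctr) < 2 * fe$components$sigma[ci]
        if (sum(wsel, na.rm = TRUE) < 20) next
        centers_E <- c(centers_E, ctr)
        centers_S <- c(centers_S,
                       fit_gaussians(s_pr[which(wsel)], 1,
                                     range = c(0.05, 1.1))$components$mean[1])
      }
    }
    bg_fit <- beta_gamma_global(centers_E, centers_S)
    cs <- correction_set(alpha, bg_fit$beta, bg_fit$gamma, delta,
                         provenance = paste0(
                           "alpha/delta from donor-/acceptor-only ",
                           "populations; beta/gamma from global 1/S vs E ",
                           "regression over ", length(centers_E),
                           " population centers"))
  }

  datasets <- list()
  for (nm in names(stages)) {
    st <- stages[[nm]]
    fr <- st$sel$fret
    fr <- fr[fr$DD + fr$AD >= config$burst$min_dex, , drop = FALSE]
    res <- list(bg = st$bg, n_bursts = nrow(st$bursts),
                n_fret = nrow(fr),
                summary = if (nrow(st$bursts) >= 2)
                  burst_summary(st$bursts) else NULL)
    if (nrow(fr) >= 20) {
      es <- accurate_E_S(fr$DDc, fr$ADc, fr$AAc, cs)
      res$E <- es$E; res$S <- es$S
      fe <- tryCatch(fit_gaussians(es$E, config$n_components,
                                   range = config$fit_range),
                     error = function(e) { failures[[nm]] <<- conditionMessage(e); NULL })
      res$fit <- fe
      if (!is.null(fe)) {
        mn <- fe$components$mean
        ok <- mn > 0 & mn < 1
        res$distances <- if (any(ok))
          efficiency_to_distance(mn[ok], config$r0_A,
                                 dE = efficiency_uncertainty(mn[ok])) else NULL
      }
      if ("bva" %in% config$dynamics)
        res$bva <- bva(st$stream, fr)
      if ("etau" %in% config$dynamics &&
          !is.null(st$stream$microtime_ns)) {
        tau <- burst_lifetimes(st$stream, fr, bg = st$bg)
        sl <- static_fret_line(config$tau_d0_ns, config$sigma_linker_A,
                               config$r0_A)
        res$etau <- tryCatch(
          dynamic_shift_etau(res$E, tau, sl),
          error = function(e) { failures[[nm]] <<- conditionMessage(e); NULL })
        res$tau <- tau
      }
    }
    datasets[[nm]] <- res
  }
  structure(list(datasets = datasets, corrections = cs,
                 config = config, failures = failures,
                 provenance = list(
                   package_version = as.character(
                     utils::packageVersion("fretburst")),
                   seed = config$seed, timestamp = format(Sys.time()))),
            class = "pipeline_report")
}

#' Cross-replicate consensus report
#'
#' Collects the Gaussian mean efficiencies and correction factors of
#' several pipeline runs (replicate laboratories/measurements) into
#' consensus tables: per-dataset mean and SD across runs, paired
#' differences when two conditions are named, and the distribution of each
#' correction factor.
#'
#' @param runs list of `pipeline_report`s with matching dataset names.
#' @param pair optional `c(apo_name, holo_name)` for paired differences.
#' @return list of data frames: `means`, `consensus`, `corrections`, and
#'   optionally `difference`.
#' @export
consensus_report <- function(runs, pair = NULL) {
  if (length(runs) < 2) stop("need at least two runs for a consensus")
  nms <- names(runs[[1]]$datasets)
  for (r in runs)
    if (!identical(names(r$datasets), nms))
      stop("mismatched dataset labels across runs")
  means <- sapply(nms, function(nm)
    vapply(runs, function(r) {
      f <- r$datasets[[nm]]$fit
      if (is.null(f)) NA_real_ else f$components$mean[
        which.max(f$components$weight)]
    }, numeric(1)))
  means <- matrix(means, nrow = length(runs),
                  dimnames = list(NULL, nms))
  cons <- data.frame(dataset = nms,
                     mean = colMeans(means, na.rm = TRUE),
                     sd = apply(means, 2, sd, na.rm = TRUE))
  corr <- t(vapply(runs, function(r)
    unlist(r$corrections[c("alpha", "beta", "gamma", "delta")]),
    numeric(4)))
  out <- list(means = means, consensus = cons,
              corrections = as.data.frame(corr))
  if (!is.null(pair)) {
    if (!all(pair %in% nms)) stop("pair names not in datasets")
    out$difference <- consensus(apo = means[, pair[1]],
                                holo = means[, pair[2]])
  }
  out
}
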