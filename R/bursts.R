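# Background estimation, all-photon sliding-window burst search,
# ALEX-based burst selection and per-burst summary statistics.

#' Background model
#'
#' Per-channel background rates (Hz) for the three intensity channels.
#'
#' @param rates named vector `c(DD=, AD=, AA=)` in Hz.
#' @param method description of how the rates were obtained.
#' @export
background_model <- function(rates, method = "manual") {
  rates <- rates[c("DD", "AD", "AA")]
  if (any(is.na(rates)) || any(rates < 0))
    stop("background rates must be nonnegative and named DD, AD, AA")
  structure(list(rates = rates, method = method),
            class = "background_model")
}

#' Estimate per-channel background rates
#'
#' Fits the tail of the inter-photon delay distribution of each channel to
#' an exponential: delays above the `tail_quantile` quantile are dominated by
#' background (bursts produce short delays), and by memorylessness the
#' maximum-likelihood rate is 1 / mean(d - d0) over the exceedances.
#' Channels with fewer than 100 photons get rate 0 with a warning.
#'
#' @param stream a labelled [photon_stream()].
#' @param tail_quantile quantile defining the tail threshold d0.
#' @return a [background_model()].
#' @export
estimate_background <- function(stream, tail_quantile = 0.9) {
  if (is.null(stream$excitation))
    stop("assign excitation before estimating background")
  tt <- photon_times(stream)
  band <- stream$map$band[match(stream$detector, stream$map$detector)]
  sel <- list(
    DD = band == "donor" & stream$excitation == "Dex",
    AD = band == "acceptor" & stream$excitation == "Dex",
    AA = band == "acceptor" & stream$excitation == "Aex")
  rates <- vapply(sel, function(k) {
    t_ch <- tt[which(k)]
    if (length(t_ch) < 100) {
      warning("fewer than 100 photons in a channel; background rate set to 0")
      return(0)
    }
    d <- diff(t_ch)
    d0 <- quantile(d, tail_quantile, names = FALSE)
    exc <- d[d > d0] - d0
    if (!length(exc)) return(0)
    1 / mean(exc)
  }, numeric(1))
  background_model(rates, method = sprintf(
    "inter-photon delay tail fit (quantile %.2f)", tail_quantile))
}

#' All-photon sliding-window burst search
#'
#' A photon is in a burst when the local photon rate estimated over `m`
#' consecutive photons exceeds `F` times the total background rate; runs of
#' in-burst photons are merged into bursts and bursts with fewer than
#' `L_min` photons are discarded. Dex and Aex photons are pooled for the
#' search and split for counting. The search is translation invariant.
#'
#' @param stream a labelled [photon_stream()].
#' @param bg a [background_model()] (total rate sets the threshold).
#' @param m sliding-window size in photons (>= 2).
#' @param F rate-threshold multiplier.
#' @param L_min minimum photons per burst.
#' @return a `burst_table` data frame with per-burst times, durations, the
#'   raw channel counts `DD`, `AD`, `AA` (plus `DA` and `flagged`) and photon
#'   index ranges `i0`, `i1` into the stream.
#' @export
search_bursts <- function(stream, bg, m = 10, F = 6, L_min = 30) {
  if (m < 2) stop("window size m must be at least 2")
  if (is.null(stream$excitation))
    stop("assign excitation before burst search")
  tt <- photon_times(stream)
  n <- length(tt)
  if (n < m) return(.empty_burst_table())
  rate_thresh <- F * sum(bg$rates)
  span <- tt[m:n] - tt[1:(n - m + 1)]    # duration of m-photon windows
  hit <- if (rate_thresh > 0) (m - 1) / span > rate_thresh else
    rep(TRUE, n - m + 1)
  # mark all photons covered by a hitting window
  delta <- integer(n + 1)
  hi <- which(hit)
  if (!length(hi)) return(.empty_burst_table())
  tab_s <- tabulate(hi, nbins = n + 1)
  tab_e <- tabulate(hi + m, nbins = n + 1)
  inb <- cumsum(tab_s - tab_e)[1:n] > 0
  r <- rle(inb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= L_min
  if (!any(keep)) return(.empty_burst_table())
  i0 <- starts[keep]; i1 <- ends[keep]
  band <- stream$map$band[match(stream$detector, stream$map$detector)]
  exc <- stream$excitation
  is_dd <- band == "donor" & !is.na(exc) & exc == "Dex"
  is_ad <- band == "acceptor" & !is.na(exc) & exc == "Dex"
  is_aa <- band == "acceptor" & !is.na(exc) & exc == "Aex"
  is_da <- band == "donor" & !is.na(exc) & exc == "Aex"
  csum <- function(x) c(0, cumsum(x))
  cdd <- csum(is_dd); cad <- csum(is_ad); caa <- csum(is_aa)
  cda <- csum(is_da); cfl <- csum(is.na(exc))
  ctdex <- csum(tt * (is_dd | is_ad)); ctaa <- csum(tt * is_aa)
  out <- data.frame(
    burst = seq_along(i0), i0 = i0, i1 = i1,
    t0 = tt[i0], t1 = tt[i1],
    duration_ms = (tt[i1] - tt[i0]) * 1e3,
    n = as.integer(i1 - i0 + 1),
    DD = as.integer(cdd[i1 + 1] - cdd[i0]),
    AD = as.integer(cad[i1 + 1] - cad[i0]),
    AA = as.integer(caa[i1 + 1] - caa[i0]),
    DA = as.integer(cda[i1 + 1] - cda[i0]),
    flagged = as.integer(cfl[i1 + 1] - cfl[i0]))
  # normalised offset between the mean Dex and mean Aex photon times:
  # near 0 for one molecule, large for sequential coincidences
  tdex <- (ctdex[i1 + 1] - ctdex[i0]) / pmax(out$DD + out$AD, 1)
  taa <- (ctaa[i1 + 1] - ctaa[i0]) / pmax(out$AA, 1)
  # defined only when both excitation tracks carry enough photons for the
  # mean times to be meaningful (a couple of background counts would give
  # an arbitrary offset)
  out$alex_offset <- ifelse(out$DD + out$AD >= 5 & out$AA >= 5,
                            abs(tdex - taa) / pmax(out$t1 - out$t0, 1e-12),
                            NA_real_)
  class(out) <- c("burst_table", "data.frame")
  attr(out, "search") <- list(m = m, F = F, L_min = L_min)
  out
}

.empty_burst_table <- function() {
  out <- data.frame(burst = integer(), i0 = integer(), i1 = integer(),
                    t0 = numeric(), t1 = numeric(), duration_ms = numeric(),
                    n = integer(), DD = integer(), AD = integer(),
                    AA = integer(), DA = integer(), flagged = integer())
  class(out) <- c("burst_table", "data.frame")
  out
}

#' ALEX-based burst selection
#'
#' Partitions bursts into FRET-pair, donor-only and acceptor-only subsets by
#' apparent stoichiometry computed from background-corrected counts:
#' donor-only above `d_only_min`, acceptor-only below `a_only_max`, FRET
#' pairs inside `fret_range` with at least `min_aa` acceptor-excitation
#' photons. The subsets are disjoint by construction.
#'
#' @param bursts a `burst_table` from [search_bursts()].
#' @param bg a [background_model()] used for per-burst subtraction
#'   (duration x rate).
#' @param d_only_min,a_only_max,fret_range stoichiometry thresholds.
#' @param min_aa minimum corrected Aex counts for the FRET-pair subset.
#' @param max_duration_ms transit-time sanity bound: bursts longer than
#'   this cannot be single diffusing molecules (they are chance
#'   coincidences merged by the search) and are dropped before
#'   partitioning.
#' @param max_alex_offset coincidence guard: bursts whose mean Dex and Aex
#'   photon times differ by more than this fraction of the burst duration
#'   are sequential two-molecule events and are dropped (set `Inf` to
#'   disable).
#' @return list with elements `fret`, `donor_only`, `acceptor_only`; each a
#'   data frame with corrected counts `DDc`, `ADc`, `AAc`, `E_app`, `S_app`.
#' @export
select_bursts <- function(bursts, bg, d_only_min = 0.8, a_only_max = 0.2,
                          fret_range = c(0.25, 0.75), min_aa = 10,
                          max_duration_ms = 10, max_alex_offset = 0.25) {
  if (a_only_max > fret_range[1] || fret_range[2] > d_only_min)
    stop("selection thresholds overlap: require a_only_max <= fret_range ",
         "<= d_only_min")
  bursts <- bursts[bursts$duration_ms <= max_duration_ms, , drop = FALSE]
  if (!is.null(bursts$alex_offset))
    bursts <- bursts[is.na(bursts$alex_offset) |
                       bursts$alex_offset <= max_alex_offset, ,
                     drop = FALSE]
  cc <- background_correct(
    data.frame(DD = bursts$DD, AD = bursts$AD, AA = bursts$AA),
    bg, bursts$duration_ms * 1e-3)
  b <- cbind(as.data.frame(bursts),
             DDc = cc[, "DD"], ADc = cc[, "AD"], AAc = cc[, "AA"])
  b$E_app <- apparent_E(b$DDc, b$ADc)
  b$S_app <- apparent_S(b$DDc, b$ADc, b$AAc)
  s <- b$S_app
  list(
    fret = b[!is.na(s) & s >= fret_range[1] & s <= fret_range[2] &
               b$AAc >= min_aa, , drop = FALSE],
    donor_only = b[!is.na(s) & s > d_only_min, , drop = FALSE],
    acceptor_only = b[!is.na(s) & s < a_only_max, , drop = FALSE])
}

#' Burst summary statistics
#'
#' Means, standard deviations and pairwise Pearson correlations of the
#' per-burst count rate (kHz), photon number and duration (ms).
#'
#' @param bursts a `burst_table`.
#' @export
burst_summary <- function(bursts) {
  if (nrow(bursts) < 2) stop("burst summary needs at least two bursts")
  rate <- bursts$n / bursts$duration_ms # kHz
  mat <- cbind(rate_khz = rate, photons = bursts$n,
               duration_ms = bursts$duration_ms)
  sds <- apply(mat, 2, sd)
  cors <- suppressWarnings(cor(mat))
  cors[!is.finite(cors)] <- NA
  list(n_bursts = nrow(bursts),
       mean = colMeans(mat), sd = sds, correlations = cors)
}
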