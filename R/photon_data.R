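# Photon-stream data model: timestamped photons with spectral/polarization
# channel labels, excitation-period assignment and optional TCSPC microtimes.

#' Detector channel map
#'
#' Maps detector identifiers to a spectral band (donor or acceptor) and an
#' optional polarization label. Every photon stream carries one of these; all
#' downstream channel bookkeeping (the three intensity channels
#' \eqn{I_{Dem|Dex}}, \eqn{I_{Aem|Dex}}, \eqn{I_{Aem|Aex}}) is derived from it.
#'
#' @param detector integer vector of detector ids.
#' @param band character vector, one of `"donor"` or `"acceptor"` per detector.
#' @param pol polarization per detector: `"parallel"`, `"perpendicular"` or
#'   `"none"` (default).
#' @return a `channel_map` data frame.
#' @export
channel_map <- function(detector, band, pol = rep("none", length(detector))) {
  detector <- as.integer(detector)
  band <- match.arg(band, c("donor", "acceptor"), several.ok = TRUE)
  band <- rep_len(band, length(detector))
  pol <- match.arg(pol, c("parallel", "perpendicular", "none"),
                   several.ok = TRUE)
  pol <- rep_len(pol, length(detector))
  if (anyDuplicated(detector))
    stop("duplicate detector ids in channel map")
  if (!any(band == "donor") || !any(band == "acceptor"))
    stop("channel map needs at least one donor and one acceptor detector")
  structure(data.frame(detector = detector, band = band, pol = pol,
                       stringsAsFactors = FALSE),
            class = c("channel_map", "data.frame"))
}

#' Microsecond-ALEX excitation scheme
#'
#' Defines the alternation period and the donor/acceptor excitation windows
#' (in clock ticks) used to assign each photon to `Dex` or `Aex` from its
#' macrotime phase. Windows are half-open `[lo, hi)` and must be disjoint;
#' photons falling outside both windows are flagged and excluded from channel
#' counts.
#'
#' @param period_ticks alternation period in clock ticks.
#' @param dex,aex two-element numeric `[lo, hi)` windows inside the period.
#' @export
alex_scheme <- function(period_ticks, dex, aex) {
  stopifnot(period_ticks > 0, length(dex) == 2, length(aex) == 2)
  if (dex[1] >= dex[2] || aex[1] >= aex[2])
    stop("excitation windows must satisfy lo < hi")
  if (max(dex[2], aex[2]) > period_ticks)
    stop("excitation windows must lie inside one period")
  if (max(dex[1], aex[1]) < min(dex[2], aex[2]))
    stop("Dex and Aex windows overlap")
  structure(list(mode = "usALEX", period_ticks = period_ticks,
                 dex = dex, aex = aex),
            class = "excitation_scheme")
}

#' Pulsed-interleaved excitation scheme
#'
#' Assigns excitation from the TCSPC microtime: photons within the donor-pulse
#' window are `Dex`, within the acceptor-pulse window `Aex`. Windows are in
#' nanoseconds within one TCSPC period, half-open and disjoint.
#'
#' @param dex_ns,aex_ns two-element `[lo, hi)` windows in ns.
#' @param period_ns TCSPC period in ns.
#' @export
pie_scheme <- function(dex_ns = c(0, 25), aex_ns = c(25, 50), period_ns = 50) {
  stopifnot(length(dex_ns) == 2, length(aex_ns) == 2)
  if (max(dex_ns[2], aex_ns[2]) > period_ns)
    stop("PIE windows must lie inside one TCSPC period")
  if (max(dex_ns[1], aex_ns[1]) < min(dex_ns[2], aex_ns[2]))
    stop("Dex and Aex PIE windows overlap")
  structure(list(mode = "PIE", period_ns = period_ns,
                 dex_ns = dex_ns, aex_ns = aex_ns),
            class = "excitation_scheme")
}

#' Photon stream
#'
#' The universal raw input of the package: macrotimes as integer clock ticks
#' with an explicit clock rate, a detector id per photon, an optional TCSPC
#' microtime per photon, and a channel map. Excitation labels (`Dex`/`Aex`)
#' are absent until [assign_excitation()] is applied.
#'
#' Macrotimes are stored as ticks (doubles holding integer values, so streams
#' longer than 2^31 ticks are representable); seconds appear only at API
#' boundaries. The default clock tick is 12.5 ns (80 MHz).
#'
#' @param ticks nondecreasing macrotimes in clock ticks.
#' @param detector integer detector id per photon.
#' @param map a [channel_map()].
#' @param clock_rate macrotime clock in Hz.
#' @param microtime_ns optional TCSPC microtime per photon, ns.
#' @param tcspc_period_ns TCSPC period (required when microtimes present).
#' @param excitation optional per-photon labels `"Dex"`/`"Aex"`/`NA`.
#' @param meta named list of free-form metadata (measurement id, duration).
#' @return a `photon_stream` object.
#' @export
photon_stream <- function(ticks, detector, map, clock_rate = 8e7,
                          microtime_ns = NULL, tcspc_period_ns = NULL,
                          excitation = NULL, meta = list()) {
  if (is.unsorted(ticks))
    stop("macrotimes must be nondecreasing")
  detector <- as.integer(detector)
  if (length(detector) != length(ticks))
    stop("detector and ticks lengths differ")
  if (!inherits(map, "channel_map")) stop("map must be a channel_map")
  if (!all(detector %in% map$detector))
    stop("detector ids absent from the channel map: ",
         paste(setdiff(detector, map$detector), collapse = ", "))
  if (!is.null(microtime_ns)) {
    if (is.null(tcspc_period_ns))
      stop("tcspc_period_ns required when microtimes are present")
    if (any(microtime_ns >= tcspc_period_ns | microtime_ns < 0, na.rm = TRUE))
      stop("microtimes must lie in [0, TCSPC period)")
  }
  if (!is.null(excitation) &&
      !all(excitation %in% c("Dex", "Aex") | is.na(excitation)))
    stop("excitation labels must be Dex, Aex or NA")
  structure(list(ticks = as.numeric(ticks), detector = detector, map = map,
                 clock_rate = clock_rate, microtime_ns = microtime_ns,
                 tcspc_period_ns = tcspc_period_ns,
                 excitation = excitation, meta = meta),
            class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("photon_stream: %d photons, %.2f s, clock %.3g Hz\n",
              length(x$ticks), stream_duration(x), x$clock_rate))
  cat(sprintf("  microtimes: %s; excitation: %s\n",
              if (is.null(x$microtime_ns)) "absent" else "present",
              if (is.null(x$excitation)) "unassigned" else "assigned"))
  invisible(x)
}

#' Stream duration in seconds
#' @param stream a [photon_stream()].
#' @export
stream_duration <- function(stream) {
  if (!is.null(stream$meta$duration_s)) return(stream$meta$duration_s)
  if (!length(stream$ticks)) return(0)
  diff(range(stream$ticks)) / stream$clock_rate
}

#' Photon arrival times in seconds
#' @param stream a [photon_stream()].
#' @export
photon_times <- function(stream) stream$ticks / stream$clock_rate

#' Assign excitation labels to a photon stream
#'
#' Labels each photon `Dex` or `Aex` according to the excitation scheme:
#' by macrotime phase within the alternation period (usALEX) or by TCSPC
#' microtime window (PIE). Photons outside all windows receive `NA` and are
#' excluded from channel counts.
#'
#' @param stream a [photon_stream()].
#' @param scheme an [alex_scheme()] or [pie_scheme()].
#' @return the stream with `$excitation` filled.
#' @export
assign_excitation <- function(stream, scheme) {
  stopifnot(inherits(scheme, "excitation_scheme"))
  if (scheme$mode == "usALEX") {
    phase <- stream$ticks %% scheme$period_ticks
    lab <- rep(NA_character_, length(phase))
    lab[phase >= scheme$dex[1] & phase < scheme$dex[2]] <- "Dex"
    lab[phase >= scheme$aex[1] & phase < scheme$aex[2]] <- "Aex"
  } else {
    if (is.null(stream$microtime_ns))
      stop("PIE excitation assignment requires microtimes")
    mt <- stream$microtime_ns
    lab <- rep(NA_character_, length(mt))
    lab[mt >= scheme$dex_ns[1] & mt < scheme$dex_ns[2]] <- "Dex"
    lab[mt >= scheme$aex_ns[1] & mt < scheme$aex_ns[2]] <- "Aex"
  }
  stream$excitation <- lab
  stream$meta$excitation_scheme <- scheme
  stream
}

#' Per-channel photon counts in an interval
#'
#' Counts photons per (emission band | excitation label) combination within a
#' time interval. The three canonical channels are `DD` (donor emission after
#' donor excitation), `AD` (acceptor emission after donor excitation, the
#' FRET signal) and `AA` (acceptor emission after acceptor excitation).
#' Donor-band photons during acceptor excitation are retained under `DA` but
#' unused by the correction formulas. Flagged photons (no excitation label)
#' are reported under `flagged`; `DD + AD + AA + DA + flagged` equals the
#' total photons in the interval.
#'
#' @param stream a labeled [photon_stream()].
#' @param interval `c(t0, t1)` in seconds (half-open), or `NULL` for all.
#' @param channel optionally a single channel name to return as a scalar.
#' @return named integer vector (or scalar if `channel` given).
#' @export
channel_counts <- function(stream, interval = NULL, channel = NULL) {
  if (is.null(stream$excitation))
    stop("excitation must be assigned before counting channels")
  tt <- photon_times(stream)
  keep <- if (is.null(interval)) rep(TRUE, length(tt)) else
    (tt >= interval[1] & tt < interval[2])
  band <- stream$map$band[match(stream$detector, stream$map$detector)]
  exc <- stream$excitation
  out <- c(
    DD = sum(keep & band == "donor" & exc == "Dex", na.rm = TRUE),
    AD = sum(keep & band == "acceptor" & exc == "Dex", na.rm = TRUE),
    AA = sum(keep & band == "acceptor" & exc == "Aex", na.rm = TRUE),
    DA = sum(keep & band == "donor" & exc == "Aex", na.rm = TRUE),
    flagged = sum(keep & is.na(exc))
  )
  if (!is.null(channel)) {
    if (!channel %in% names(out)) stop("unknown channel label: ", channel)
    return(out[[channel]])
  }
  out
}

#' Write a photon stream to the tabular text format
#'
#' One photon per row with columns `macrotime_ticks, detector, microtime_ns`;
#' header comment lines carry the clock rate, TCSPC period and channel map.
#' This plain-text layout is the package's zero-dependency on-disk format.
#'
#' @param stream a [photon_stream()].
#' @param path output file.
#' @export
write_photons <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fretburst photon stream v1", con)
  writeLines(sprintf("# clock_rate=%.17g", stream$clock_rate), con)
  if (!is.null(stream$tcspc_period_ns))
    writeLines(sprintf("# tcspc_period_ns=%.17g", stream$tcspc_period_ns), con)
  for (i in seq_len(nrow(stream$map)))
    writeLines(sprintf("# detector=%d,%s,%s", stream$map$detector[i],
                       stream$map$band[i], stream$map$pol[i]), con)
  df <- data.frame(macrotime_ticks = sprintf("%.0f", stream$ticks),
                   detector = stream$detector)
  df$microtime_ns <- if (is.null(stream$microtime_ns)) NA else
    stream$microtime_ns
  df$excitation <- if (is.null(stream$excitation)) NA else stream$excitation
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a photon stream from the tabular text format
#'
#' Inverse of [write_photons()]; the round trip is the identity on all
#' fields. Files missing a mandatory header field or with unsorted
#' macrotimes are rejected with an informative error.
#'
#' @param path input file.
#' @return a [photon_stream()].
#' @export
read_photons <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    as.numeric(sub(paste0("^# ", key, "="), "", m[1]))
  }
  clock <- get_field("clock_rate")
  if (is.null(clock)) stop("photon file format error: missing clock_rate")
  det_lines <- grep("^# detector=", hdr, value = TRUE)
  if (!length(det_lines)) stop("photon file format error: missing channel map")
  parts <- do.call(rbind, strsplit(sub("^# detector=", "", det_lines), ","))
  map <- channel_map(as.integer(parts[, 1]), parts[, 2], parts[, 3])
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  for (need in c("macrotime_ticks", "detector"))
    if (!need %in% names(df))
      stop("photon file format error: missing column ", need)
  if (is.unsorted(df$macrotime_ticks))
    stop("photon file ordering error: macrotimes not nondecreasing")
  mt <- if (all(is.na(df$microtime_ns))) NULL else df$microtime_ns
  exc <- if (all(is.na(df$excitation))) NULL else as.character(df$excitation)
  photon_stream(df$macrotime_ticks, df$detector, map, clock_rate = clock,
                microtime_ns = mt, tcspc_period_ns = get_field("tcspc_period_ns"),
                excitation = exc)
}
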