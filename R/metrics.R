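# Spike-train summaries: PSTHs, per-condition rates, first-spike latencies,
# frequency response areas (FRA) and frequency suppression areas (FSA).

matching_events <- function(session, role) {
  which(session$sequence$events$role %in% role)
}

#' Peri-stimulus time histogram
#'
#' Spike counts aligned to event onset in `bin_ms` bins, normalized to spikes
#' per stimulus (divided by the number of matching events, so duplicated
#' trials leave the PSTH unchanged).
#'
#' @param session A `recording_session`.
#' @param role Event role(s) to include (e.g. `"deviant"`).
#' @param bin_ms Bin width, ms.
#' @param window_ms Analysis window length, ms; defaults to the smallest
#'   event window.
#' @return A `psth`: list with `edges` (ms), `counts` (spikes per stimulus
#'   per bin) and `n_events`.
#' @export
compute_psth <- function(session, role = "deviant", bin_ms = 10,
                         window_ms = NULL) {
  idx <- matching_events(session, role)
  if (length(idx) == 0)
    stop_invalid("no events with role '%s' in the session",
                 paste(role, collapse = "/"))
  window_ms <- window_ms %||% min(session$windows[idx])
  edges <- seq(0, window_ms, by = bin_ms)
  if (edges[length(edges)] < window_ms) edges <- c(edges, window_ms)
  counts <- numeric(length(edges) - 1L)
  for (i in idx) {
    sp <- session$spikes[[i]]
    sp <- sp[sp >= 0 & sp < window_ms]
    if (length(sp))
      counts <- counts + hist(sp, breaks = edges, plot = FALSE)$counts
  }
  structure(list(edges = edges, counts = counts / length(idx),
                 n_events = length(idx)),
            class = "psth")
}

#' Evoked response in spikes per stimulus
#'
#' Total spikes within the analysis window across matching events divided by
#' the number of events, minus the expected spontaneous count in that window
#' (floored at zero).
#'
#' @inheritParams compute_psth
#' @param spont_rate Spontaneous rate in spikes/s used for the correction
#'   (default 0, i.e. no correction).
#' @param window_ms Analysis window, ms; defaults to each event's own window.
#' @return Mean evoked spikes per stimulus.
#' @export
event_rate <- function(session, role = "deviant", window_ms = NULL,
                       spont_rate = 0) {
  idx <- matching_events(session, role)
  if (length(idx) == 0)
    stop_invalid("no events with role '%s' in the session",
                 paste(role, collapse = "/"))
  counts <- vapply(idx, function(i) {
    w <- window_ms %||% session$windows[i]
    sp <- session$spikes[[i]]
    sum(sp >= 0 & sp < w) - spont_rate * w / 1000
  }, numeric(1))
  max(mean(counts), 0)
}

# Per-event spike counts (uncorrected) for bootstrap resampling.
event_counts <- function(session, role, window_ms = NULL) {
  idx <- matching_events(session, role)
  vapply(idx, function(i) {
    w <- window_ms %||% session$windows[i]
    sum(session$spikes[[i]] >= 0 & session$spikes[[i]] < w)
  }, numeric(1))
}

#' Estimate the spontaneous rate from silent slots
#'
#' @param session A `recording_session` containing `"silence"` events.
#' @return Spontaneous rate in spikes/s, or 0 when no silent slots exist.
#' @export
estimate_spont <- function(session) {
  idx <- matching_events(session, "silence")
  if (length(idx) == 0) return(0)
  tot <- sum(lengths(session$spikes[idx]))
  tot / sum(session$windows[idx]) * 1000
}

#' Median first-spike latency
#'
#' Per matching event, the latency of the first spike after onset within
#' `[0, duration + post_offset_ms]`; the median across spiking events is
#' returned.  Events without a spike in the window are skipped; if none
#' spike, `NA` is returned (missing values are never imputed as zero).
#' The conventional comparison is standard minus deviant: positive
#' differences mean the deviant response is earlier.
#'
#' @inheritParams compute_psth
#' @param post_offset_ms Extension past tone offset, ms (default 50).
#' @return Median latency in ms, or `NA_real_`.
#' @export
first_spike_latency <- function(session, role = "deviant",
                                post_offset_ms = 50) {
  idx <- matching_events(session, role)
  if (length(idx) == 0)
    stop_invalid("no events with role '%s' in the session",
                 paste(role, collapse = "/"))
  lat <- vapply(idx, function(i) {
    lim <- session$sequence$events$duration_ms[i] + post_offset_ms
    sp <- session$spikes[[i]]
    sp <- sp[sp >= 0 & sp <= lim]
    if (length(sp) == 0) NA_real_ else min(sp)
  }, numeric(1))
  lat <- lat[!is.na(lat)]
  if (length(lat) == 0) return(NA_real_)
  median(lat)
}

# --- FRA ------------------------------------------------------------------

geometric_edges <- function(freqs) {
  r <- exp(mean(diff(log(freqs))))
  c(freqs[1] / sqrt(r), sqrt(freqs[-length(freqs)] * freqs[-1]),
    freqs[length(freqs)] * sqrt(r))
}

run_containing <- function(supra, col) {
  if (!supra[col]) return(integer(0))
  lo <- col
  while (lo > 1 && supra[lo - 1]) lo <- lo - 1
  hi <- col
  while (hi < length(supra) && supra[hi + 1]) hi <- hi + 1
  lo:hi
}

band_extent <- function(freqs, cols) {
  if (length(cols) == 0) return(0)
  edges <- geometric_edges(freqs)
  edges[max(cols) + 1] - edges[min(cols)]
}

#' Construct a frequency-response-area surface
#'
#' Derives the response criterion (spontaneous level plus `crit_frac` of the
#' peak above it), the threshold (lowest level with any supra-criterion
#' cell), the best frequency (peak response at threshold + 10 dB) and the
#' per-level bandwidth (frequency extent, with geometric half-step cell
#' edges, of the contiguous supra-criterion run containing the BF).
#'
#' @param freqs Grid frequencies, kHz (ascending).
#' @param levels Grid levels, dB SPL (ascending).
#' @param rates Matrix `length(levels) x length(freqs)` of evoked rates in
#'   spikes per stimulus.
#' @param spont Spontaneous contribution on the same scale (default 0; rates
#'   are usually already spontaneous-corrected).
#' @param crit_frac Criterion fraction of the peak above spontaneous
#'   (default 0.2).
#' @return An `fra_surface`; `$responsive` is `FALSE` for flat surfaces, in
#'   which case no derived quantities are defined.
#' @export
fra_surface <- function(freqs, levels, rates, spont = 0, crit_frac = 0.2) {
  stopifnot(nrow(rates) == length(levels), ncol(rates) == length(freqs))
  peak <- max(rates)
  crit <- spont + crit_frac * (peak - spont)
  out <- list(freqs = freqs, levels = levels, rates = rates, spont = spont,
              criterion = crit, responsive = FALSE, bf = NA_real_,
              threshold_db = NA_real_,
              bandwidth = rep(NA_real_, length(levels)))
  if (peak <= spont || !any(rates >= crit & rates > 0)) {
    return(structure(out, class = "fra_surface"))
  }
  supra <- rates >= crit
  lev_ok <- which(apply(supra, 1, any))
  thr_i <- lev_ok[1]
  out$threshold_db <- levels[thr_i]
  bf_i <- min(thr_i + 1, length(levels))   # threshold + one level step
  out$bf <- freqs[which.max(rates[bf_i, ])]
  bf_col <- which.max(rates[bf_i, ])
  bw <- rep(NA_real_, length(levels))
  for (li in seq_along(levels)) {
    if (li < thr_i) next
    cols <- run_containing(supra[li, ], bf_col)
    bw[li] <- band_extent(freqs, cols)
  }
  out$bandwidth <- bw
  out$responsive <- TRUE
  structure(out, class = "fra_surface")
}

#' @export
print.fra_surface <- function(x, ...) {
  if (!x$responsive) cat("<fra_surface> unresponsive\n")
  else cat(sprintf("<fra_surface> BF %.3g kHz, threshold %g dB SPL\n",
                   x$bf, x$threshold_db))
  invisible(x)
}

#' Estimate the FRA from recorded sessions
#'
#' Averages the spontaneous-corrected evoked rate per frequency x level cell
#' of one or more FRA sessions (see [build_fra_grid()]) and derives the FRA
#' metrics via [fra_surface()].
#'
#' @param sessions A `recording_session` or list of them, built on FRA
#'   sequences.
#' @param spont_rate Spontaneous rate in spikes/s for the correction.
#' @param crit_frac Criterion fraction (see [fra_surface()]).
#' @return An `fra_surface`.
#' @export
estimate_fra <- function(sessions, spont_rate = 0, crit_frac = 0.2) {
  if (inherits(sessions, "recording_session")) sessions <- list(sessions)
  ev <- do.call(rbind, lapply(sessions, function(s) {
    cbind(s$sequence$events[c("freq_khz", "level_db")],
          count = vapply(seq_along(s$spikes), function(i)
            sum(s$spikes[[i]] >= 0 & s$spikes[[i]] < s$windows[i]),
            numeric(1)),
          window = s$windows)
  }))
  ev <- ev[!is.na(ev$freq_khz), ]
  if (nrow(ev) == 0) stop_invalid("sessions contain no tone events")
  freqs <- sort(unique(ev$freq_khz))
  levels <- sort(unique(ev$level_db))
  corr <- pmax(ev$count - spont_rate * ev$window / 1000, 0)
  rates <- matrix(0, length(levels), length(freqs))
  for (li in seq_along(levels)) for (fi in seq_along(freqs)) {
    sel <- ev$level_db == levels[li] & ev$freq_khz == freqs[fi]
    rates[li, fi] <- mean(corr[sel])
  }
  fra_surface(freqs, levels, rates,
              spont = 0, crit_frac = crit_frac)
}

#' Bandwidth relative to best frequency
#'
#' `bandwidth / bf`, the inverse of the quality factor `Q = bf / bandwidth`.
#'
#' @param bandwidth Bandwidth, kHz (>= 0).
#' @param bf Best frequency, kHz (> 0).
#' @return Dimensionless relative width.
#' @export
relative_width <- function(bandwidth, bf) {
  if (any(bf <= 0)) stop_invalid("best frequency must be positive")
  bandwidth / bf
}

# --- FSA ------------------------------------------------------------------

#' Construct a frequency-suppression-area surface
#'
#' From probe rates on an adaptor frequency x level grid: the baseline is the
#' mean probe rate over the `n_baseline_rows` lowest adaptor intensities
#' (where the adaptor evokes no discernible response), the suppression is
#' `1 - probe/baseline`, and the FSA is the region at or beyond the
#' suppression criterion (default 0.6, i.e. the probe falls to at most 40%
#' of baseline; `mode = "ratio"` instead thresholds `probe/baseline <= 0.6`).
#' FSA bandwidths are read at the adaptor levels nearest probe + 10 and
#' probe + 30 dB from the contiguous supra-criterion run containing the
#' adaptor frequency nearest the probe.
#'
#' @param freqs,levels Adaptor grid (kHz ascending, dB SPL ascending).
#' @param probe_rates Matrix `length(levels) x length(freqs)` of probe
#'   responses, spikes per stimulus.
#' @param probe_f,probe_i Probe frequency (kHz) and level (dB SPL).
#' @param criterion Suppression criterion (default 0.6).
#' @param mode `"one_minus_ratio"` (default) or `"ratio"`.
#' @param n_baseline_rows Number of lowest-intensity rows averaged for the
#'   baseline (default 1).
#' @param fra Optional `fra_surface` of the same unit; enables the
#'   FSA-to-FRA bandwidth ratio at matched absolute levels.
#' @return An `fsa_surface` with the suppression matrix, FSA mask,
#'   bandwidths (`bw10`, `bw30`) and, when `fra` is given, `ratio10`,
#'   `ratio30`.
#' @export
fsa_surface <- function(freqs, levels, probe_rates, probe_f, probe_i,
                        criterion = 0.6,
                        mode = c("one_minus_ratio", "ratio"),
                        n_baseline_rows = 1, fra = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(probe_rates) == length(levels),
            ncol(probe_rates) == length(freqs))
  base_rows <- seq_len(min(n_baseline_rows, length(levels)))
  baseline <- mean(probe_rates[base_rows, , drop = FALSE])
  if (!is.finite(baseline) || baseline <= 0)
    stop_invalid("FSA undefined: baseline probe response is not positive")
  suppression <- 1 - probe_rates / baseline
  mask <- if (mode == "one_minus_ratio") suppression >= criterion
          else probe_rates / baseline <= criterion
  probe_col <- which.min(abs(log(freqs) - log(probe_f)))
  bw_at <- function(target_level) {
    li <- which.min(abs(levels - target_level))
    band_extent(freqs, run_containing(mask[li, ], probe_col))
  }
  out <- list(freqs = freqs, levels = levels, probe_rates = probe_rates,
              baseline = baseline, suppression = suppression, mask = mask,
              probe_f = probe_f, probe_i = probe_i, criterion = criterion,
              mode = mode,
              bw10 = bw_at(probe_i + 10), bw30 = bw_at(probe_i + 30),
              ratio10 = NA_real_, ratio30 = NA_real_,
              exceeds_fra = NA)
  if (!is.null(fra) && fra$responsive) {
    fra_bw_at <- function(target_level) {
      li <- which.min(abs(fra$levels - target_level))
      fra$bandwidth[li]
    }
    f10 <- fra_bw_at(probe_i + 10)
    f30 <- fra_bw_at(probe_i + 30)
    out$ratio10 <- if (isTRUE(f10 > 0)) out$bw10 / f10 else NA_real_
    out$ratio30 <- if (isTRUE(f30 > 0)) out$bw30 / f30 else NA_real_
    # noise can push the FSA beyond the FRA; flag rather than forbid
    out$exceeds_fra <- isTRUE(out$bw10 > f10) || isTRUE(out$bw30 > f30)
  }
  structure(out, class = "fsa_surface")
}

#' @export
print.fsa_surface <- function(x, ...) {
  cat(sprintf(
    "<fsa_surface> baseline %.3g spikes/stim, BW+10 %.3g kHz, BW+30 %.3g kHz\n",
    x$baseline, x$bw10, x$bw30))
  invisible(x)
}

#' Estimate the FSA from RAP sessions
#'
#' Computes the spontaneous-corrected probe response of each RAP trial (see
#' [build_rap_trials()]), averages over the repeats of each adaptor cell and
#' derives the suppression surface via [fsa_surface()].
#'
#' @param sessions List of RAP `recording_session` objects (one per trial).
#' @param fra Optional `fra_surface` for bandwidth ratios.
#' @param spont_rate Spontaneous rate in spikes/s.
#' @param probe_window_ms Analysis window for the probe response, ms
#'   (default: the within-trial SOA).
#' @inheritParams fsa_surface
#' @return An `fsa_surface`.
#' @export
estimate_fsa <- function(sessions, fra = NULL, spont_rate = 0,
                         criterion = 0.6,
                         mode = c("one_minus_ratio", "ratio"),
                         n_baseline_rows = 1, probe_window_ms = NULL) {
  mode <- match.arg(mode)
  rows <- do.call(rbind, lapply(sessions, function(s) {
    cond <- s$sequence$condition
    w <- probe_window_ms %||% s$sequence$soa
    data.frame(
      adaptor_f = cond$adaptor_f, adaptor_i = cond$adaptor_i,
      probe_f = cond$probe_f, probe_i = cond$probe_i,
      rate = max(event_rate(s, "probe", window_ms = w,
                            spont_rate = spont_rate), 0)
    )
  }))
  freqs <- sort(unique(rows$adaptor_f))
  levels <- sort(unique(rows$adaptor_i))
  pr <- matrix(NA_real_, length(levels), length(freqs))
  for (li in seq_along(levels)) for (fi in seq_along(freqs)) {
    sel <- rows$adaptor_i == levels[li] & rows$adaptor_f == freqs[fi]
    pr[li, fi] <- mean(rows$rate[sel])
  }
  fsa_surface(freqs, levels, pr, probe_f = rows$probe_f[1],
              probe_i = rows$probe_i[1], criterion = criterion, mode = mode,
              n_baseline_rows = n_baseline_rows, fra = fra)
}
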