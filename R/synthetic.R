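# Virtual neurons and Poisson spike synthesis.  The generator is the study
# design: a population split into strong-SSA units (high adaptation slope M,
# narrow cochlear channels under a broad synaptic envelope) and weak-SSA
# units (low M, ~2.5x broader channels), log-normal best frequencies across
# the rat range, Poisson spiking with an onset-dominated envelope and
# drive-dependent first-spike latency.

#' Construct a virtual neuron
#'
#' Wraps a [model_neuron()] with the observation model used for spike
#' synthesis: Poisson spike counts (mean `fr * poisson_gain` per stimulus),
#' an exponential-onset within-trial envelope, first-spike latency
#' `latency_base + latency_slope * drive` (slope negative: stronger drive,
#' earlier spikes) with Gaussian jitter, and homogeneous spontaneous firing.
#'
#' @param model A [model_neuron()].
#' @param spont_rate Spontaneous rate, spikes/s (>= 0).
#' @param poisson_gain Spikes per stimulus per firing-rate unit (default 1).
#' @param latency_base Baseline first-spike latency, ms.
#' @param latency_slope Latency change per unit drive, ms (negative).
#' @param latency_jitter_sd Latency jitter SD, ms (>= 0).
#' @param envelope_tau Decay constant of the within-tone spike envelope, ms.
#' @param label `"strong_ssa"` or `"weak_ssa"`.
#' @param stim Anchor stimulus, a list with `f1` (kHz), `i1` (dB SPL), `bf`,
#'   `threshold_db`.
#' @param ground_truth List of generating parameters (kept for parameter-
#'   recovery studies; round-trips through serialization).
#' @param id Neuron identifier.
#' @return A `virtual_neuron`.
#' @export
virtual_neuron <- function(model, spont_rate = 2, poisson_gain = 1,
                           latency_base = 16, latency_slope = -1.2,
                           latency_jitter_sd = 1, envelope_tau = 20,
                           label = c("strong_ssa", "weak_ssa"),
                           stim = NULL, ground_truth = NULL, id = "vn1") {
  label <- match.arg(label)
  if (spont_rate < 0) stop_invalid("spont_rate must be >= 0")
  if (latency_jitter_sd < 0) stop_invalid("latency jitter SD must be >= 0")
  structure(
    list(model = model, spont_rate = spont_rate,
         poisson_gain = poisson_gain, latency_base = latency_base,
         latency_slope = latency_slope,
         latency_jitter_sd = latency_jitter_sd,
         envelope_tau = envelope_tau, label = label, stim = stim,
         ground_truth = ground_truth, id = id),
    class = "virtual_neuron"
  )
}

#' @export
print.virtual_neuron <- function(x, ...) {
  cat(sprintf("<virtual_neuron> %s (%s), BF %.3g kHz, spont %.2g sp/s\n",
              x$id, x$label, x$stim$bf %||% NA, x$spont_rate))
  invisible(x)
}

# Unadapted integrated input IN at (f, level) for a model neuron.
unadapted_in <- function(model, f, level) {
  fb <- model$filterbank
  sum(model$W * an_rate(bm_response(f, level, fb), config = fb))
}

# Threshold (lowest level on a 10-dB grid with appreciable input) and the
# input at 10 dB above it; used to anchor the oddball protocol per neuron.
model_tuning_anchor <- function(model, levels = seq(0, 80, 10),
                                crit_frac = 0.05) {
  bf <- model$ground_bf
  ins <- vapply(levels, function(L) unadapted_in(model, bf, L), numeric(1))
  crit <- crit_frac * max(ins)
  idx <- which(ins >= crit)
  if (length(idx) == 0) stop_invalid("model neuron is unresponsive")
  list(threshold_db = levels[idx[1]],
       i1 = min(levels[idx[1]] + 10, max(levels)))
}

#' Generate a virtual population
#'
#' Draws `n` neurons with an exact-count strong/weak split
#' (`round(n * p_strong)` strong).  Strong-SSA neurons get a high initial
#' adaptation slope `M` and narrow cochlear channels beneath a broad synaptic
#' envelope; weak-SSA neurons get a low `M` and channels broadened by
#' `weak_bw_factor`, so adaptation generalizes across the frequency pair.
#' Best frequencies are log-normal across the rat range.  Every generating
#' parameter is stored in `$ground_truth`.
#'
#' @param n Population size (>= 1).
#' @param p_strong Proportion of strong-SSA neurons (default 0.7).
#' @param seed Integer seed; the population is fully deterministic.
#' @param M_strong,M_weak Ranges (length 2) for the initial slope `M`.
#' @param m_range Range for the final slope `m`.
#' @param tau_strong,tau_weak Ranges for `tau` (synaptic-activity units) per
#'   label; the larger weak-SSA `tau` keeps the adaptation slope near `M` at
#'   the drives the paradigms reach, so weak units still accumulate
#'   criterion-level suppression while their broad channels keep it
#'   unspecific.
#' @param R Per-trial recovery fraction (default 0.1).
#' @param weak_bw_factor Channel-broadening factor of weak-SSA neurons.
#' @param n_channels Channels per filterbank.
#' @return A list of [virtual_neuron()] objects.
#' @export
make_population <- function(n, p_strong = 0.7, seed = 1L,
                            M_strong = c(0.55, 0.9),
                            M_weak = c(0.28, 0.45),
                            m_range = c(0.02, 0.08),
                            tau_strong = c(0.3, 0.6),
                            tau_weak = c(0.5, 1.0),
                            R = 0.1,
                            weak_bw_factor = 3,
                            n_channels = 40) {
  if (n < 1) stop_invalid("n must be >= 1")
  n_strong <- as.integer(round(n * p_strong))
  labels <- c(rep("strong_ssa", n_strong), rep("weak_ssa", n - n_strong))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      label <- labels[i]
      strong <- label == "strong_ssa"
      bf <- exp(pmin(pmax(rnorm(1, mean = log(sqrt(0.5 * 40)), sd = 0.7),
                          log(1.2)), log(28)))
      fb <- filterbank_config(
        n_channels = n_channels,
        nl_bw_scale = if (strong) 1.0 else weak_bw_factor,
        lin_bw_scale = if (strong) 2.5 else 2.5 * weak_bw_factor
      )
      sigma_oct <- runif(1, 0.8, 1.2)
      bf_h <- map_rat_to_human(bf, fb)
      W <- exp(-0.5 * (log2(fb$cfs / bf_h) / sigma_oct)^2)
      M <- if (strong) runif(1, M_strong[1], M_strong[2])
           else runif(1, M_weak[1], M_weak[2])
      m <- runif(1, m_range[1], m_range[2])
      tau <- if (strong) runif(1, tau_strong[1], tau_strong[2])
             else runif(1, tau_weak[1], tau_weak[2])
      model <- model_neuron(W, M = M, m = m, tau = tau, R = R,
                            out_theta = 1, out_rmax = runif(1, 4, 9),
                            filterbank = fb)
      model$ground_bf <- bf
      anchor <- model_tuning_anchor(model)
      # place the operating point mid-sigmoid at (f1, i1)
      f1 <- bf
      model$out_params$theta <- max(unadapted_in(model, f1, anchor$i1), 1e-6)
      virtual_neuron(
        model = model,
        spont_rate = runif(1, 0.5, 4),
        latency_base = runif(1, 12, 20),
        latency_slope = -1.2,
        latency_jitter_sd = 1,
        label = label,
        stim = list(f1 = f1, i1 = anchor$i1, bf = bf,
                    threshold_db = anchor$threshold_db),
        ground_truth = list(M = M, m = m, tau = tau, R = R, W = W,
                            sigma_oct = sigma_oct, bf = bf,
                            out_rmax = model$out_params$rmax,
                            out_theta = model$out_params$theta,
                            nl_bw_scale = fb$nl_bw_scale,
                            lin_bw_scale = fb$lin_bw_scale),
        id = sprintf("vn%03d", i)
      )
    })
  })
}

#' Draw spike times for one stimulus event
#'
#' Driven spikes: count `~ Poisson(fr * poisson_gain)`, placed after the
#' first-spike latency `L = max(0, latency_base + latency_slope * drive +
#' jitter)` with an exponential envelope decaying from tone onset over
#' `envelope_tau` ms, truncated to the tone duration.  Spontaneous spikes:
#' homogeneous Poisson at `spont_rate` over the whole `window_ms`.
#'
#' @param fr Driven firing rate, spikes per stimulus (>= 0).
#' @param event One-row event data frame (needs `duration_ms`).
#' @param neuron A [virtual_neuron()].
#' @param window_ms Length of the inter-onset window, ms.
#' @param seed Optional seed; when `NULL`, draws from the current RNG stream.
#' @return Sorted spike times in ms relative to event onset.
#' @export
generate_spikes <- function(fr, event, neuron, window_ms = 250, seed = NULL) {
  if (fr < 0) stop_invalid("firing rate must be >= 0")
  draw <- function() {
    n_driven <- rpois(1, fr * neuron$poisson_gain)
    times <- numeric(0)
    if (n_driven > 0) {
      L <- max(0, neuron$latency_base + neuron$latency_slope * fr +
                 rnorm(1, 0, neuron$latency_jitter_sd))
      # inverse-CDF draw from exp(rate 1/envelope_tau) truncated to the tone
      u <- runif(n_driven)
      dur <- event$duration_ms
      tmax_p <- 1 - exp(-dur / neuron$envelope_tau)
      times <- L - neuron$envelope_tau * log(1 - u * tmax_p)
    }
    n_spont <- rpois(1, neuron$spont_rate * window_ms / 1000)
    if (n_spont > 0) times <- c(times, runif(n_spont, 0, window_ms))
    sort(pmin(times, window_ms - 1e-9))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Inter-onset windows of a sequence; the last event keeps a full SOA plus any
# trailing recovery gap.
event_windows <- function(seq) {
  on <- seq$events$onset_ms
  n <- length(on)
  w <- if (n > 1) c(diff(on), seq$soa + seq$gap_ms) else seq$soa + seq$gap_ms
  w
}

new_session <- function(neuron_id, seq, spikes, windows, seed,
                        condition_id = NA_character_) {
  structure(
    list(neuron_id = neuron_id, sequence = seq, spikes = spikes,
         windows = windows, seed = seed, condition_id = condition_id),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %s: %d events, %d spikes (%s)\n",
              x$neuron_id, length(x$spikes),
              sum(lengths(x$spikes)), x$sequence$kind))
  invisible(x)
}

#' Run a stimulus protocol on a virtual neuron
#'
#' For each sequence, simulates the deterministic rate response (adaptation
#' state carries across events within a sequence and, by default, resets
#' between sequences, mimicking recording breaks) and then draws spike trains
#' per event.
#'
#' @param neuron A [virtual_neuron()].
#' @param protocol A list of `stimulus_sequence` objects (a single sequence
#'   is accepted).
#' @param seed Integer master seed; one sub-seed per sequence.
#' @param carry_state If `TRUE`, adaptation carries over between sequences.
#' @return A list of `recording_session` objects (spike times in ms relative
#'   to each event's onset).
#' @export
run_protocol <- function(neuron, protocol, seed = 1L, carry_state = FALSE) {
  stopifnot(inherits(neuron, "virtual_neuron"))
  if (inherits(protocol, "stimulus_sequence")) protocol <- list(protocol)
  state <- NULL
  out <- vector("list", length(protocol))
  for (i in seq_along(protocol)) {
    sq <- protocol[[i]]
    sim <- simulate_sequence(neuron$model, sq, state = state)
    if (carry_state) state <- sim$final_state
    wins <- event_windows(sq)
    sseed <- derive_seed(seed, i)
    spikes <- with_seed(sseed, {
      lapply(seq_len(nrow(sq$events)), function(j) {
        generate_spikes(sim$trace$fr[j], sq$events[j, ], neuron,
                        window_ms = wins[j])
      })
    })
    out[[i]] <- new_session(neuron$id, sq, spikes, wins, sseed,
                            condition_id = sq$kind)
  }
  out
}
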