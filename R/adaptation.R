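# Adaptation stages of the model: synaptic weighting of auditory-nerve
# activity, per-channel depression with recovery, integration across channels,
# and a saturating output nonlinearity giving the firing rate.

#' Define a model neuron
#'
#' Couples a filterbank to a synaptic weight vector `W` (one weight per
#' channel), the adaptation-function parameters (`M`, `m`, `tau`), the
#' per-trial recovery fraction `R`, and the output sigmoid.  Per trial the
#' model computes `SYN = W * AN`, subtracts the accumulated per-channel
#' adaptation (clamped at zero), sums the adapted activities and passes the
#' total through `out()` to obtain the firing rate in spikes per stimulus.
#'
#' @param W Non-negative per-channel synaptic weights (length
#'   `filterbank$n_channels`, at least one positive).
#' @param M Initial (low-activity) slope of the adaptation function.
#' @param m Final (high-activity) slope, `0 <= m <= M`.
#' @param tau Synaptic activity at which the slope is `(M + m)/2` (> 0).
#' @param R Per-trial recovery fraction in `[0, 1]` (default 0.1).
#' @param out_theta,out_rmax,out_hill Output sigmoid: half-saturation input,
#'   maximum rate (spikes per stimulus) and Hill exponent.
#' @param filterbank A [filterbank_config()].
#' @return A `model_neuron` object.
#' @export
model_neuron <- function(W, M, m, tau, R = 0.1,
                         out_theta = 1, out_rmax = 8, out_hill = 2,
                         filterbank = filterbank_config()) {
  if (length(W) != filterbank$n_channels)
    stop_invalid("W must have one weight per channel (%d)",
                 filterbank$n_channels)
  if (any(W < 0) || !any(W > 0))
    stop_invalid("W must be non-negative with at least one positive entry")
  if (!(M >= m && m >= 0)) stop_invalid("need M >= m >= 0")
  if (tau <= 0) stop_invalid("tau must be positive")
  if (R < 0 || R > 1) stop_invalid("R must lie in [0, 1]")
  structure(
    list(W = as.numeric(W), M = M, m = m, tau = tau, R = R,
         out_params = list(theta = out_theta, rmax = out_rmax,
                           hill = out_hill),
         filterbank = filterbank),
    class = "model_neuron"
  )
}

#' @export
print.model_neuron <- function(x, ...) {
  cat(sprintf(
    "<model_neuron> %d channels, M=%.3g m=%.3g tau=%.3g R=%.3g, out rmax=%.3g\n",
    length(x$W), x$M, x$m, x$tau, x$R, x$out_params$rmax))
  invisible(x)
}

out_rate <- function(x, p) {
  xh <- pmax(x, 0)^p$hill
  r <- p$rmax * xh / (xh + p$theta^p$hill)
  r[x <= 0] <- 0
  r
}

#' Adaptation generated by one trial of synaptic activity
#'
#' The monotone adaptation function `g(x) = alpha(x) * x` with
#' `alpha(x) = m + (M - m) * 2^(-x/tau)`: adaptation is proportional to
#' activity with slope `M` at low activity relaxing to `m` at high activity;
#' at `x = tau` the slope is `(M + m)/2`.
#'
#' @param x Synaptic activity (>= 0), vectorized.
#' @param M,m,tau Adaptation-function parameters (`M >= m >= 0`, `tau > 0`).
#' @return Adaptation increment, same units as `x`.
#' @export
adaptation_increment <- function(x, M, m, tau) {
  if (any(x < 0)) stop_invalid("synaptic activity must be >= 0")
  if (tau <= 0) stop_invalid("tau must be positive")
  (m + (M - m) * 2^(-x / tau)) * x
}

#' Closed-form steady state of the adaptation recursion
#'
#' For constant per-trial activity `S` and constant slope `alpha` (the
#' `M = m` case) the recursion `A <- (1 - R)(A + alpha * (S - A))` is affine
#' with fixed point `A* = (1 - R) alpha S / (1 - (1 - R)(1 - alpha))`.  Used
#' as an independent oracle for the iterated model.
#'
#' @param S Constant synaptic activity per trial.
#' @param alpha Constant adaptation slope in `[0, 1]`.
#' @param R Per-trial recovery fraction in `[0, 1]`.
#' @return The steady-state adaptation `A*`.
#' @export
steady_state_adaptation <- function(S, alpha, R) {
  if (alpha < 0 || alpha > 1 || R < 0 || R > 1)
    stop_invalid("alpha and R must lie in [0, 1]")
  if (alpha == 0 && R == 0)
    stop_invalid("degenerate steady state: alpha = R = 0")
  (1 - R) * alpha * S / (1 - (1 - R) * (1 - alpha))
}

#' Initial adaptation state
#'
#' @param neuron A [model_neuron()].
#' @return An `adaptation_state` with `A = 0` in every channel (trial 1).
#' @export
initial_state <- function(neuron) {
  structure(list(A = numeric(length(neuron$W)), trial_index = 1L),
            class = "adaptation_state")
}

#' Advance the adaptation recursion by one trial
#'
#' Computes the adapted synaptic activity `asyn = max(syn - A, 0)` per
#' channel (negative adapted activity is non-physical and is clamped before
#' both the output stage and the adaptation update), the firing rate
#' `fr = out(sum(asyn))`, and the next state
#' `A <- (1 - R) * (A + g(asyn))`.
#'
#' @param state An `adaptation_state` (see [initial_state()]).
#' @param syn Per-channel synaptic activity for this trial (>= 0).
#' @param neuron A [model_neuron()].
#' @return List with `asyn`, `fr`, and `state` (the advanced state).
#' @export
advance_trial <- function(state, syn, neuron) {
  if (any(syn < 0)) stop_invalid("synaptic activity must be >= 0")
  asyn <- pmax(syn - state$A, 0)
  fr <- out_rate(sum(asyn), neuron$out_params)
  A_next <- (1 - neuron$R) *
    (state$A + adaptation_increment(asyn, neuron$M, neuron$m, neuron$tau))
  list(asyn = asyn,
       fr = fr,
       state = structure(list(A = A_next,
                              trial_index = state$trial_index + 1L),
                         class = "adaptation_state"))
}

# Per-event synaptic drive matrix (events x channels); silence rows are zero.
# Independent of (M, m, tau, R), so fitting precomputes it once.  Sequences
# repeat a handful of distinct stimuli, so the front end runs once per
# unique (frequency, level) pair.
syn_matrix <- function(neuron, seq) {
  ev <- seq$events
  fb <- neuron$filterbank
  key <- paste(ev$freq_khz, ev$level_db)
  uniq <- !duplicated(key)
  urows <- t(vapply(which(uniq), function(i) {
    if (is.na(ev$freq_khz[i])) return(numeric(fb$n_channels))
    neuron$W * an_rate(bm_response(ev$freq_khz[i], ev$level_db[i], fb),
                       config = fb)
  }, numeric(fb$n_channels)))
  urows[match(key, key[uniq]), , drop = FALSE]
}

#' Simulate the deterministic rate response to a stimulus sequence
#'
#' Chains all model stages over the events of a sequence: filterbank,
#' auditory-nerve transfer, synaptic weighting, per-channel adaptation
#' recursion (silent slots contribute zero drive but still advance the
#' recovery), integration and output rate.  Fully deterministic.
#'
#' @param neuron A [model_neuron()].
#' @param seq A `stimulus_sequence`.
#' @param state Optional starting `adaptation_state` (default: fresh state,
#'   `A = 0`).
#' @return A `simulated_response`: data frame `trace` with per-event
#'   `trial`, `role`, `syn_total`, `in_total`, `fr`, plus matrices `syn`,
#'   `asyn` and the `final_state`.
#' @export
simulate_sequence <- function(neuron, seq, state = NULL) {
  stopifnot(inherits(neuron, "model_neuron"),
            inherits(seq, "stimulus_sequence"))
  syn <- syn_matrix(neuron, seq)
  A0 <- if (is.null(state)) numeric(length(neuron$W)) else state$A
  rec <- adapt_recursion_cpp(syn, neuron$M, neuron$m, neuron$tau, neuron$R,
                             A0)
  fr <- out_rate(rec$in_total, neuron$out_params)
  structure(
    list(trace = data.frame(trial = seq_len(nrow(syn)),
                            role = seq$events$role,
                            syn_total = rowSums(syn),
                            in_total = rec$in_total,
                            fr = fr,
                            stringsAsFactors = FALSE),
         syn = syn, asyn = rec$asyn,
         final_state = structure(list(A = rec$A_final,
                                      trial_index = nrow(syn) + 1L),
                                 class = "adaptation_state"),
         sequence = seq),
    class = "simulated_response"
  )
}

#' @export
print.simulated_response <- function(x, ...) {
  cat(sprintf("<simulated_response> %d events, mean FR %.3g spikes/stim\n",
              nrow(x$trace), mean(x$trace$fr)))
  invisible(x)
}
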