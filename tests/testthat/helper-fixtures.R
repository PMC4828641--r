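# Shared fixtures.  Populations are cached per test run because the
# generator evaluates the filterbank threshold scan per neuron.

fixture_env <- new.env(parent = emptyenv())

cached_population <- function(key, ...) {
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- make_population(...)
  fixture_env[[key]]
}

# A small deterministic neuron with a hand-built tuning envelope.
toy_neuron <- function(M = 0.7, m = 0.05, tau = 0.4, R = 0.1,
                       bf = 4, sigma_oct = 1, out_rmax = 6,
                       fb = filterbank_config()) {
  bf_h <- map_rat_to_human(bf, fb)
  W <- exp(-0.5 * (log2(fb$cfs / bf_h) / sigma_oct)^2)
  model_neuron(W, M = M, m = m, tau = tau, R = R,
               out_theta = 1, out_rmax = out_rmax, filterbank = fb)
}

# Session with hand-placed spikes on a synthetic sequence of `n` identical
# alone-role tones (soa windows), for deterministic metric arithmetic.
manual_session <- function(spikes, soa = 250, role = "alone",
                           freq = 4, level = 40) {
  n <- length(spikes)
  ev <- ssasim:::tone_events(onset_ms = (seq_len(n) - 1) * soa,
                             freq_khz = freq, level_db = level, role = role)
  sq <- ssasim:::new_sequence(ev, soa = soa, kind = "manual")
  ssasim:::new_session("fix1", sq, spikes, rep(soa, n), seed = 1L)
}

# Deterministic rate-model condition responses for one oddball condition.
rate_model_responses <- function(model, cond, seed = 11) {
  sa <- build_oddball_sequence(cond, seed = seed)            # f1 standard
  sb <- build_oddball_sequence(ssasim:::flip_swap(cond), seed = seed + 1)
  ra <- simulate_sequence(model, sa)
  rb <- simulate_sequence(model, sb)
  alone <- build_alone_sequence(sb, "deviant")
  u1 <- mean(simulate_sequence(model, alone)$trace$fr[
    alone$events$role == "alone"])
  list(
    d1 = mean(rb$trace$fr[sb$events$role == "deviant"]),
    s1 = mean(ra$trace$fr[sa$events$role == "standard"]),
    d2 = mean(ra$trace$fr[sa$events$role == "deviant"]),
    s2 = mean(rb$trace$fr[sb$events$role == "standard"]),
    u1 = u1
  )
}

# Gaussian-profile synthetic FRA surface with a V-shaped level dependence.
gaussian_fra <- function(bf = 4, sigma_oct = 0.5, threshold = 30,
                         peak = 6,
                         freqs = exp(seq(log(0.5), log(40),
                                         length.out = 25)),
                         levels = seq(0, 80, 10)) {
  rates <- t(vapply(freqs, function(f) {
    vapply(levels, function(L) {
      width <- sigma_oct * (1 + 0.02 * max(L - threshold, 0))
      gain <- min(max(L - threshold, 0) / 30, 1)
      peak * gain * exp(-0.5 * (log2(f / bf) / width)^2)
    }, numeric(1))
  }, numeric(length(levels))))
  fra_surface(freqs, levels, t(rates))
}
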