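# Cochlear front end: a steady-state, dual-path (linear + compressive
# nonlinear) filterbank evaluated per tone, followed by a threshold-saturating
# auditory-nerve transfer function.  Because the adaptation recursion indexes
# discrete trials, each tone is summarized by its steady-state magnitude in
# every channel rather than simulated sample-by-sample.

#' Configure the cochlear filterbank
#'
#' Defines the channel array and the two filter paths.  Channel centre
#' frequencies (CFs) are log-spaced over `cf_range` (the mapped human range by
#' default).  For a tone of pressure amplitude `10^(level/20)` the channel
#' response is the sum of
#' \itemize{
#'   \item a linear path: `lin_gain` times the tone amplitude weighted by a
#'     gammatone-like magnitude profile of width `lin_bw_scale` ERBs, and
#'   \item a nonlinear path: the same profile at the narrower width
#'     `nl_bw_scale` ERBs passed through broken-stick compression
#'     `min(a x, b x^nu)`.
#' }
#' At low levels the narrow compressive path dominates, so tuning is sharp; at
#' high levels compression caps that path and the broader linear path takes
#' over, so effective tuning widens with level -- the behaviour that drives
#' adaptation spread in intensity oddballs.  An optional explicit broadening
#' coefficient `bw_level_coef` scales both bandwidths by
#' `1 + bw_level_coef * level/100`.
#'
#' @param n_channels Number of channels (default 40).
#' @param cf_range CF range in kHz (default the mapped human range).
#' @param rat_range,human_range Frequency ranges (kHz) defining the log-linear
#'   rat-to-human map.
#' @param lin_gain Linear-path gain (default 0.03).
#' @param lin_bw_scale,nl_bw_scale Path bandwidths in ERB multiples.
#' @param nl_a Low-level slope of the compressive path.
#' @param nl_nu Compression exponent in (0, 1).
#' @param knee_db Level (dB SPL) of the compression knee for an on-CF tone;
#'   sets the broken-stick coefficient `b = a * x_knee^(1 - nu)`.
#' @param bw_level_coef Explicit bandwidth-versus-level broadening coefficient
#'   (default 0: broadening comes from the two-path structure).
#' @param gt_order Gammatone magnitude order (default 4).
#' @param an_theta,an_rmax,an_hill Auditory-nerve sigmoid: half-saturation
#'   input, maximum rate (normalized to 1) and Hill exponent.
#' @return A `filterbank_config` object (also carries the CF vector `cfs`).
#' @export
filterbank_config <- function(n_channels = 40,
                              cf_range = c(0.125, 10),
                              rat_range = c(0.5, 40),
                              human_range = c(0.125, 10),
                              lin_gain = 0.03,
                              lin_bw_scale = 2.5,
                              nl_bw_scale = 1.0,
                              nl_a = 1,
                              nl_nu = 0.25,
                              knee_db = 30,
                              bw_level_coef = 0,
                              gt_order = 4,
                              an_theta = 30,
                              an_rmax = 1,
                              an_hill = 2) {
  if (n_channels < 1) stop_invalid("n_channels must be >= 1")
  if (any(c(lin_bw_scale, nl_bw_scale) <= 0))
    stop_invalid("bandwidth scales must be positive")
  if (nl_nu <= 0 || nl_nu >= 1) stop_invalid("nl_nu must lie in (0, 1)")
  cfs <- exp(seq(log(cf_range[1]), log(cf_range[2]),
                 length.out = n_channels))
  structure(
    list(n_channels = as.integer(n_channels), cf_range = cf_range,
         cfs = cfs, rat_range = rat_range, human_range = human_range,
         lin_gain = lin_gain, lin_bw_scale = lin_bw_scale,
         nl_bw_scale = nl_bw_scale, nl_a = nl_a, nl_nu = nl_nu,
         knee_db = knee_db,
         nl_b = nl_a * (10^(knee_db / 20))^(1 - nl_nu),
         bw_level_coef = bw_level_coef, gt_order = gt_order,
         an_theta = an_theta, an_rmax = an_rmax, an_hill = an_hill),
    class = "filterbank_config"
  )
}

#' Map a rat-range frequency into the human hearing range
#'
#' Affine map in log-frequency taking `rat_range` onto `human_range`
#' (defaults: 0.5--40 kHz onto 0.125--10 kHz), so octave relations between
#' stimuli are preserved.  Frequencies outside the rat range are extrapolated
#' with a warning.
#'
#' @param f Frequency in kHz (rat range).
#' @param config A [filterbank_config()].
#' @return Mapped frequency in kHz.
#' @export
map_rat_to_human <- function(f, config = filterbank_config()) {
  if (any(f <= 0)) stop_invalid("frequencies must be positive")
  r <- config$rat_range
  h <- config$human_range
  if (any(f < r[1] | f > r[2]))
    warning("frequency outside the rat range; extrapolating the log-linear map")
  exp(log(h[1]) + (log(f) - log(r[1])) / (log(r[2]) - log(r[1])) *
        (log(h[2]) - log(h[1])))
}

# Inverse of map_rat_to_human (used to read tuning profiles back onto the
# stimulus axis during calibration).
map_human_to_rat <- function(f, config = filterbank_config()) {
  r <- config$rat_range
  h <- config$human_range
  exp(log(r[1]) + (log(f) - log(h[1])) / (log(h[2]) - log(h[1])) *
        (log(r[2]) - log(r[1])))
}

# ERB-style bandwidth (kHz) at a human-range CF in kHz.
erb_khz <- function(cf) 0.0247 + 0.108 * cf

gammatone_mag <- function(f, cf, bw, order) {
  (1 + ((f - cf) / bw)^2)^(-order / 2)
}

#' Basilar-membrane response of every channel to one tone
#'
#' Evaluates the two-path filterbank at steady state.  The stimulus frequency
#' (rat range) is first mapped into the human range; `SILENCE` (an `NA`
#' frequency) yields an all-zero excitation.
#'
#' @param freq_khz Tone frequency in kHz, or `NA` for silence.
#' @param level_db Tone level in dB SPL.
#' @param config A [filterbank_config()].
#' @return Numeric vector of non-negative per-channel excitation magnitudes
#'   (model units), aligned with `config$cfs`.
#' @export
bm_response <- function(freq_khz, level_db, config = filterbank_config()) {
  if (is.na(freq_khz)) return(numeric(config$n_channels))
  if (freq_khz <= 0) stop_invalid("tone frequency must be positive")
  fh <- map_rat_to_human(freq_khz, config)
  amp <- 10^(level_db / 20)
  broaden <- 1 + config$bw_level_coef * level_db / 100
  bw_lin <- config$lin_bw_scale * erb_khz(config$cfs) * broaden
  bw_nl <- config$nl_bw_scale * erb_khz(config$cfs) * broaden
  lin <- config$lin_gain * amp *
    gammatone_mag(fh, config$cfs, bw_lin, config$gt_order)
  x <- amp * gammatone_mag(fh, config$cfs, bw_nl, config$gt_order)
  nl <- pmin(config$nl_a * x, config$nl_b * x^config$nl_nu)
  lin + nl
}

#' Auditory-nerve activity from basilar-membrane excitation
#'
#' Elementwise threshold-saturating transfer
#' `rmax * x^h / (x^h + theta^h)`: zero at zero, monotone non-decreasing,
#' asymptote `rmax`.
#'
#' @param bm Per-channel excitation (from [bm_response()]).
#' @param io_params List with `theta`, `rmax`, `hill`; defaults taken from
#'   `config`.
#' @param config A [filterbank_config()] supplying defaults.
#' @return Per-channel activity in `[0, rmax]`.
#' @export
an_rate <- function(bm, io_params = NULL, config = filterbank_config()) {
  p <- io_params %||% list(theta = config$an_theta, rmax = config$an_rmax,
                           hill = config$an_hill)
  if (any(bm < 0)) stop_invalid("excitation must be non-negative")
  xh <- bm^p$hill
  out <- p$rmax * xh / (xh + p$theta^p$hill)
  out[bm == 0] <- 0
  out
}
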