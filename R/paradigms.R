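# Stimulus protocols: oddball sequences, alone controls, the repeated
# adaptation paradigm (RAP), forward suppression, and FRA grids.
#
# Events are rows of a data frame with columns onset_ms, freq_khz, level_db,
# duration_ms, ramp_ms, role.  Silent slots keep their row (freq/level = NA,
# role = "silence") so that trial indexing, and hence adaptation decay, stays
# aligned across conditions.

TONE_ROLES <- c("standard", "deviant", "alone", "adaptor", "probe", "silence")

tone_events <- function(onset_ms, freq_khz, level_db, role,
                        duration_ms = 75, ramp_ms = 5) {
  n <- length(onset_ms)
  ev <- data.frame(
    onset_ms = as.numeric(onset_ms),
    freq_khz = as.numeric(freq_khz),
    level_db = as.numeric(level_db),
    duration_ms = rep_len(as.numeric(duration_ms), n),
    ramp_ms = rep_len(as.numeric(ramp_ms), n),
    role = rep_len(as.character(role), n),
    stringsAsFactors = FALSE
  )
  validate_events(ev)
  ev
}

validate_events <- function(ev) {
  if (any(ev$onset_ms < 0)) stop_invalid("event onsets must be >= 0")
  if (any(ev$duration_ms <= 2 * ev$ramp_ms))
    stop_invalid("tone duration must exceed twice the ramp time")
  if (!all(ev$role %in% TONE_ROLES))
    stop_invalid("unknown event role: %s",
                 paste(setdiff(ev$role, TONE_ROLES), collapse = ", "))
  tone <- ev$role != "silence"
  if (any(tone & (!is.finite(ev$freq_khz) | ev$freq_khz <= 0)))
    stop_invalid("tone events need a positive frequency")
  if (any(!tone & (is.finite(ev$freq_khz) | is.finite(ev$level_db))))
    stop_invalid("silence events must not carry a frequency or level")
  invisible(ev)
}

new_sequence <- function(events, soa, condition = NULL, seed = NULL,
                         kind = "oddball", gap_ms = 0) {
  structure(
    list(events = events, soa = soa, condition = condition, seed = seed,
         kind = kind, gap_ms = gap_ms),
    class = "stimulus_sequence"
  )
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("<stimulus_sequence> kind=%s, %d events, SOA %g ms\n",
              x$kind, nrow(x$events), x$soa))
  print(table(x$events$role))
  invisible(x)
}

#' Relative frequency separation of two tones
#'
#' The dimensionless separation \eqn{\Delta f = (f_2 - f_1)/\sqrt{f_2 f_1}},
#' the standard measure used to place oddball frequency pairs symmetrically on
#' a logarithmic axis.  It is antisymmetric: swapping the arguments flips the
#' sign.
#'
#' @param f1,f2 Tone frequencies in kHz (> 0).
#' @return The relative separation (dimensionless).
#' @seealso [make_frequency_pair()] for the inverse, [octave_separation()].
#' @examples
#' relative_separation(10, 11.0512)  # ~0.1
#' @export
relative_separation <- function(f1, f2) {
  if (any(f1 <= 0) || any(f2 <= 0))
    stop_invalid("frequencies must be positive")
  (f2 - f1) / sqrt(f2 * f1)
}

#' Find the upper frequency of a pair at a given relative separation
#'
#' Inverts the \eqn{\Delta f} definition: given `f1` and a separation
#' `delta_f` >= 0 returns the `f2 >= f1` with
#' `relative_separation(f1, f2) == delta_f`.  Closed form:
#' \eqn{f_2 = f_1 s^2} with \eqn{s = (\Delta f + \sqrt{\Delta f^2 + 4})/2}.
#'
#' @param f1 Lower frequency, kHz.
#' @param delta_f Relative separation (>= 0).
#' @return `f2` in kHz.
#' @export
make_frequency_pair <- function(f1, delta_f) {
  if (any(f1 <= 0)) stop_invalid("frequencies must be positive")
  if (any(delta_f < 0)) stop_invalid("delta_f must be >= 0")
  s <- (delta_f + sqrt(delta_f^2 + 4)) / 2
  f1 * s^2
}

#' Separation of two frequencies in octaves
#'
#' @inheritParams relative_separation
#' @return `log2(f2/f1)` in octaves.
#' @export
octave_separation <- function(f1, f2) {
  if (any(f1 <= 0) || any(f2 <= 0))
    stop_invalid("frequencies must be positive")
  log2(f2 / f1)
}

#' Describe one oddball condition
#'
#' A condition fixes the lower-frequency/intensity stimulus (`f1`, `i1`) and
#' derives the higher one from the relative frequency separation `delta_f`
#' and the intensity difference `delta_i` (dB).  `swap = FALSE` presents
#' (`f1`, `i1`) as the standard; flipping `swap` yields the role-reversed
#' companion sequence.
#'
#' @param f1 Lower frequency, kHz.
#' @param i1 Lower level, dB SPL.
#' @param delta_f Relative frequency separation (>= 0).
#' @param delta_i Intensity difference in dB (>= 0).
#' @param swap If `TRUE`, (`f1`, `i1`) is the deviant.
#' @param kind Paradigm kind; inferred from the separations when `NULL`.
#' @return An object of class `oddball_condition`.
#' @export
oddball_condition <- function(f1, i1, delta_f = 0, delta_i = 0,
                              swap = FALSE, kind = NULL) {
  if (f1 <= 0) stop_invalid("f1 must be positive")
  if (delta_f < 0 || delta_i < 0)
    stop_invalid("delta_f and delta_i must be >= 0")
  f2 <- make_frequency_pair(f1, delta_f)
  i2 <- i1 + delta_i
  if (is.null(kind)) {
    kind <- if (delta_f > 0 && delta_i > 0) "double"
            else if (delta_f > 0) "frequency"
            else "intensity"
  }
  ok <- c("frequency", "intensity", "double", "deviant_alone",
          "standard_alone")
  if (!kind %in% ok) stop_invalid("unknown paradigm kind '%s'", kind)
  structure(
    list(f1 = f1, i1 = i1, f2 = f2, i2 = i2,
         delta_f = delta_f, delta_i = delta_i,
         swap = isTRUE(swap), paradigm_kind = kind),
    class = "oddball_condition"
  )
}

#' @export
print.oddball_condition <- function(x, ...) {
  cat(sprintf(
    "<oddball_condition> %s: f1=%.3g kHz @ %g dB, f2=%.3g kHz @ %g dB (df=%g, di=%g dB, swap=%s)\n",
    x$paradigm_kind, x$f1, x$i1, x$f2, x$i2, x$delta_f, x$delta_i, x$swap))
  invisible(x)
}

flip_swap <- function(cond) {
  cond$swap <- !cond$swap
  cond
}

#' Build a random oddball sequence
#'
#' Generates `n_stimuli` tones at a fixed stimulus onset asynchrony with
#' exactly `n_stimuli * p_deviant` deviants placed by a seeded uniformly
#' random permutation (no spacing constraint).  With `cond$swap = FALSE` the
#' (`f1`, `i1`) stimulus is the standard presented on the remaining trials.
#'
#' @param cond An [oddball_condition()].
#' @param n_stimuli Number of tones (default 400).
#' @param p_deviant Deviant probability (default 0.1); `n_stimuli * p_deviant`
#'   must be an integer.
#' @param soa Stimulus onset asynchrony in ms (default 250, i.e. 4 Hz).
#' @param seed Integer seed; the sequence is reproducible bit-for-bit.
#' @return A `stimulus_sequence`.
#' @export
build_oddball_sequence <- function(cond, n_stimuli = 400, p_deviant = 0.1,
                                   soa = 250, seed = 1L) {
  stopifnot(inherits(cond, "oddball_condition"))
  if (p_deviant <= 0 || p_deviant >= 1)
    stop_invalid("p_deviant must be in (0, 1)")
  n_dev <- n_stimuli * p_deviant
  if (abs(n_dev - round(n_dev)) > 1e-9)
    stop_invalid("n_stimuli * p_deviant must be an integer (got %g)", n_dev)
  n_dev <- as.integer(round(n_dev))
  roles <- c(rep("deviant", n_dev), rep("standard", n_stimuli - n_dev))
  roles <- with_seed(seed, sample(roles))
  std <- if (cond$swap) c(cond$f2, cond$i2) else c(cond$f1, cond$i1)
  dev <- if (cond$swap) c(cond$f1, cond$i1) else c(cond$f2, cond$i2)
  is_dev <- roles == "deviant"
  ev <- tone_events(
    onset_ms = (seq_len(n_stimuli) - 1) * soa,
    freq_khz = ifelse(is_dev, dev[1], std[1]),
    level_db = ifelse(is_dev, dev[2], std[2]),
    role = roles
  )
  new_sequence(ev, soa = soa, condition = cond, seed = seed, kind = "oddball")
}

#' Replace one oddball role by silence
#'
#' Derives the deviant-alone (`keep_role = "deviant"`) or standard-alone
#' control from an oddball sequence: events of the other role become explicit
#' silent slots so the timing grid is unchanged.
#'
#' @param oddball A `stimulus_sequence` from [build_oddball_sequence()].
#' @param keep_role `"standard"` or `"deviant"`.
#' @return A `stimulus_sequence` with kind `"deviant_alone"` or
#'   `"standard_alone"`; kept events are tagged `"alone"`.
#' @export
build_alone_sequence <- function(oddball, keep_role = c("deviant", "standard")) {
  stopifnot(inherits(oddball, "stimulus_sequence"))
  keep_role <- match.arg(keep_role)
  ev <- oddball$events
  keep <- ev$role %in% c(keep_role, "alone")
  if (!any(keep))
    stop_invalid("role '%s' not present in the sequence", keep_role)
  drop <- !keep
  ev$freq_khz[drop] <- NA_real_
  ev$level_db[drop] <- NA_real_
  ev$role[drop] <- "silence"
  ev$role[keep] <- "alone"
  out <- new_sequence(ev, soa = oddball$soa, condition = oddball$condition,
                      seed = oddball$seed,
                      kind = paste0(keep_role, "_alone"))
  out
}

#' Enumerate the complete oddball protocol
#'
#' The full condition set for one neuron: the frequency oddball
#' (`delta_f = freq_oddball_delta_f`, same level), every combination of the
#' intensity differences with the frequency separations (intensity oddballs
#' at `delta_f = 0`, double oddballs otherwise), and one deviant-/standard-
#' alone control descriptor.  With the defaults this yields the canonical 14
#' conditions (1 + 3 x 4 + 1); each condition expands to two role-swapped
#' sequences at build time.
#'
#' @param f1 Lower frequency, kHz.
#' @param i1 Lower level, dB SPL.
#' @param delta_f_set Frequency separations (default `c(0, 0.04, 0.1, 0.37)`).
#' @param delta_i_set Intensity differences in dB (default `c(10, 30, 50)`).
#' @param freq_oddball_delta_f Separation of the pure frequency oddball
#'   (default 0.1).
#' @return A list of `oddball_condition` objects.
#' @export
build_protocol <- function(f1, i1,
                           delta_f_set = c(0, 0.04, 0.1, 0.37),
                           delta_i_set = c(10, 30, 50),
                           freq_oddball_delta_f = 0.1) {
  if (length(delta_f_set) == 0 || length(delta_i_set) == 0)
    stop_invalid("delta_f_set and delta_i_set must be non-empty")
  conds <- list(oddball_condition(f1, i1, delta_f = freq_oddball_delta_f,
                                  delta_i = 0, kind = "frequency"))
  for (di in sort(delta_i_set))
    for (df in sort(delta_f_set))
      conds[[length(conds) + 1L]] <- oddball_condition(f1, i1, df, di)
  conds[[length(conds) + 1L]] <-
    oddball_condition(f1, i1, delta_f = freq_oddball_delta_f, delta_i = 0,
                      kind = "deviant_alone")
  conds
}

#' Build repeated-adaptation-paradigm (RAP) trials
#'
#' Each trial is a discrete `a a a p` sequence: three identical adaptors
#' followed by the fixed probe, onsets `{0, soa, 2 soa, 3 soa}`, then a
#' recovery gap, making each trial `4 * soa + gap` ms long (2000 ms by
#' default).  The adaptor roves over `adaptor_grid`: intensities ascending,
#' frequencies in seeded random order within each intensity, every grid cell
#' visited `repeats` times.
#'
#' @param probe_f,probe_i Probe frequency (kHz) and level (dB SPL).
#' @param adaptor_grid Data frame with columns `freq_khz` and `level_db`, or a
#'   list with elements `freqs` and `levels` whose outer product is used.
#' @param soa Onset asynchrony within a trial, ms.
#' @param gap Recovery gap after the probe, ms.
#' @param repeats Repetitions per grid cell.
#' @param seed Integer seed.
#' @return A list of 4-event `stimulus_sequence` trials; each carries the
#'   adaptor cell in `$condition`.
#' @export
build_rap_trials <- function(probe_f, probe_i, adaptor_grid,
                             soa = 250, gap = 1000, repeats = 4, seed = 1L) {
  if (repeats < 1) stop_invalid("repeats must be >= 1")
  grid <- as_grid(adaptor_grid)
  if (nrow(grid) == 0) stop_invalid("adaptor grid is empty")
  order_tab <- with_seed(seed, {
    out <- list()
    for (lv in sort(unique(grid$level_db))) {
      fs <- grid$freq_khz[grid$level_db == lv]
      for (r in seq_len(repeats))
        out[[length(out) + 1L]] <-
          data.frame(freq_khz = fs[sample.int(length(fs))], level_db = lv)
    }
    do.call(rbind, out)
  })
  lapply(seq_len(nrow(order_tab)), function(i) {
    af <- order_tab$freq_khz[i]
    al <- order_tab$level_db[i]
    ev <- tone_events(
      onset_ms = c(0, soa, 2 * soa, 3 * soa),
      freq_khz = c(af, af, af, probe_f),
      level_db = c(al, al, al, probe_i),
      role = c("adaptor", "adaptor", "adaptor", "probe")
    )
    new_sequence(ev, soa = soa,
                 condition = list(adaptor_f = af, adaptor_i = al,
                                  probe_f = probe_f, probe_i = probe_i),
                 seed = seed, kind = "rap", gap_ms = gap)
  })
}

#' Build forward-suppression trials
#'
#' Like [build_rap_trials()] but with a single adaptor per trial and the
#' probe onset at the adaptor offset plus `gap` ms (0 by default).
#'
#' @inheritParams build_rap_trials
#' @param gap Silent interval between adaptor offset and probe onset, ms
#'   (>= 0).
#' @param trial_gap Recovery gap after the probe, ms.
#' @param duration_ms Tone duration, ms.
#' @return A list of 2-event `stimulus_sequence` trials.
#' @export
build_forward_suppression_trials <- function(probe_f, probe_i, adaptor_grid,
                                             gap = 0, repeats = 4, seed = 1L,
                                             trial_gap = 1000,
                                             duration_ms = 75) {
  if (gap < 0) stop_invalid("gap must be >= 0")
  if (repeats < 1) stop_invalid("repeats must be >= 1")
  grid <- as_grid(adaptor_grid)
  if (nrow(grid) == 0) stop_invalid("adaptor grid is empty")
  probe_onset <- duration_ms + gap
  order_tab <- with_seed(seed, {
    out <- list()
    for (lv in sort(unique(grid$level_db))) {
      fs <- grid$freq_khz[grid$level_db == lv]
      for (r in seq_len(repeats))
        out[[length(out) + 1L]] <-
          data.frame(freq_khz = fs[sample.int(length(fs))], level_db = lv)
    }
    do.call(rbind, out)
  })
  lapply(seq_len(nrow(order_tab)), function(i) {
    af <- order_tab$freq_khz[i]
    al <- order_tab$level_db[i]
    ev <- tone_events(
      onset_ms = c(0, probe_onset),
      freq_khz = c(af, probe_f),
      level_db = c(al, probe_i),
      role = c("adaptor", "probe"),
      duration_ms = duration_ms
    )
    new_sequence(ev, soa = probe_onset,
                 condition = list(adaptor_f = af, adaptor_i = al,
                                  probe_f = probe_f, probe_i = probe_i),
                 seed = seed, kind = "forward", gap_ms = trial_gap)
  })
}

as_grid <- function(g) {
  if (is.data.frame(g)) {
    stopifnot(all(c("freq_khz", "level_db") %in% names(g)))
    return(g[c("freq_khz", "level_db")])
  }
  expand.grid(freq_khz = g$freqs, level_db = g$levels,
              KEEP.OUT.ATTRS = FALSE)
}

#' Build the FRA measurement sequence
#'
#' Tones on a frequency x level grid: `n_freq` logarithmic frequency steps
#' between `fmin` and `fmax` (endpoints included), levels in `level_step` dB
#' steps presented from lowest to highest, frequencies shuffled within each
#' level pass, every cell repeated `repeats` times.
#'
#' @param fmin,fmax Frequency range, kHz.
#' @param n_freq Number of logarithmic frequency steps (default 25).
#' @param level_step Level step, dB (default 10).
#' @param level_range Two-element level range in dB SPL (default `c(0, 80)`).
#' @param repeats Repetitions per cell (default 5).
#' @param soa Onset asynchrony, ms.
#' @param seed Integer seed.
#' @return A `stimulus_sequence` of role-`"alone"` tones (kind `"fra"`).
#' @export
build_fra_grid <- function(fmin = 0.5, fmax = 40, n_freq = 25,
                           level_step = 10, level_range = c(0, 80),
                           repeats = 5, soa = 250, seed = 1L) {
  if (fmin >= fmax) stop_invalid("fmin must be < fmax")
  if (n_freq < 2) stop_invalid("n_freq must be >= 2")
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_freq))
  levels <- seq(level_range[1], level_range[2], by = level_step)
  tab <- with_seed(seed, {
    out <- list()
    for (lv in levels)
      for (r in seq_len(repeats))
        out[[length(out) + 1L]] <-
          data.frame(freq_khz = freqs[sample.int(length(freqs))], level_db = lv)
    do.call(rbind, out)
  })
  ev <- tone_events(
    onset_ms = (seq_len(nrow(tab)) - 1) * soa,
    freq_khz = tab$freq_khz,
    level_db = tab$level_db,
    role = "alone"
  )
  out <- new_sequence(ev, soa = soa, seed = seed, kind = "fra")
  out$grid <- list(freqs = freqs, levels = levels, repeats = repeats)
  out
}
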