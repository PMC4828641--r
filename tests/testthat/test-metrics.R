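test_that("PSTHs normalize to spikes per stimulus", {
  ses <- manual_session(list(c(20.5), numeric(0), c(110, 240)))
  ps <- compute_psth(ses, "alone", bin_ms = 10)
  expect_equal(ps$counts[3], 1 / 3)        # bin [20, 30)
  expect_equal(sum(ps$counts), 3 / 3)
  expect_equal(ps$n_events, 3)

  # duplicating every trial leaves the PSTH unchanged
  dup <- manual_session(rep(list(c(20.5), numeric(0), c(110, 240)), 2))
  expect_equal(compute_psth(dup, "alone", bin_ms = 10)$counts, ps$counts)

  empty <- manual_session(list(numeric(0), numeric(0)))
  expect_true(all(compute_psth(empty, "alone")$counts == 0))
  expect_error(compute_psth(ses, "probe"), "no events")
})

test_that("event rates count the analysis window with spontaneous correction", {
  # 40 events, 120 spikes total, no spontaneous activity -> 3.0
  ses <- manual_session(rep(list(c(10, 20, 30)), 40))
  expect_equal(event_rate(ses, "alone"), 3.0)
  expect_equal(event_rate(ses, "alone", spont_rate = 4), 3 - 4 * 0.25)

  # pure spontaneous activity: corrected rate unbiased within 2 SE
  spont_hz <- 8
  n_ev <- 400
  spikes <- ssasim:::with_seed(12, {
    lapply(seq_len(n_ev), function(i)
      sort(runif(rpois(1, spont_hz * 0.25), 0, 250)))
  })
  ses_sp <- manual_session(spikes)
  se <- sqrt(spont_hz * 0.25 / n_ev)
  expect_lt(abs(event_rate(ses_sp, "alone", spont_rate = spont_hz)), 2 * se)
})

test_that("spontaneous rate is estimated from silent slots", {
  cond <- oddball_condition(4, 40, delta_f = 0.1, swap = TRUE)
  sq <- build_alone_sequence(build_oddball_sequence(cond, n_stimuli = 100,
                                                    seed = 2), "deviant")
  spikes <- ssasim:::with_seed(3, {
    lapply(seq_len(100), function(i) sort(runif(rpois(1, 1), 0, 250)))
  })
  ses <- ssasim:::new_session("x", sq, spikes, rep(250, 100), 1L)
  est <- estimate_spont(ses)
  expect_gt(est, 1)   # 4 Hz true rate; rough agreement is enough here
  expect_lt(est, 8)
  expect_equal(estimate_spont(manual_session(list(c(1)))), 0)
})

test_that("first-spike latencies use the median over spiking trials", {
  ses <- manual_session(list(c(12, 40), c(15), c(30, 31)))
  expect_equal(first_spike_latency(ses, "alone"), 15)

  # identical standard and deviant trains: zero difference
  expect_equal(first_spike_latency(ses, "alone") -
                 first_spike_latency(ses, "alone"), 0)

  # adapted deviant responds later: standard minus deviant is negative
  std <- manual_session(rep(list(c(11, 30), c(13)), 10))
  dev <- manual_session(rep(list(c(24), c(26, 40)), 10))
  expect_lt(first_spike_latency(std, "alone") -
              first_spike_latency(dev, "alone"), 0)

  # spikes beyond duration + 50 ms are not first-spike candidates
  late <- manual_session(list(c(200), c(240)))
  expect_true(is.na(first_spike_latency(late, "alone")))
  none <- manual_session(list(numeric(0)))
  expect_true(is.na(first_spike_latency(none, "alone")))
})

test_that("FRA surfaces recover tuning metrics from synthetic profiles", {
  fra <- gaussian_fra(bf = 4, threshold = 30)
  expect_true(fra$responsive)
  expect_equal(fra$threshold_db, 40, tolerance = 0)  # first level above 30
  step <- (40 / 0.5)^(1 / 24)
  expect_lt(abs(log(fra$bf / 4)), log(step) * 1.01)

  # bandwidth defined only at/above threshold, monotone for a V shape
  bw <- fra$bandwidth
  expect_true(all(is.na(bw[fra$levels < fra$threshold_db])))
  bw_def <- bw[!is.na(bw)]
  expect_true(all(diff(bw_def) >= 0))

  flat <- fra_surface(fra$freqs, fra$levels,
                      matrix(0, length(fra$levels), length(fra$freqs)))
  expect_false(flat$responsive)
  expect_true(is.na(flat$bf))
})

test_that("estimate_fra reproduces the model tuning from spikes", {
  pop <- cached_population("p10", n = 10, p_strong = 0.7, seed = 77)
  vn <- pop[[2]]
  sq <- build_fra_grid(n_freq = 13, level_range = c(20, 70), repeats = 3,
                       seed = 6)
  ses <- run_protocol(vn, sq, seed = 41)[[1]]
  fra <- estimate_fra(ses, spont_rate = vn$spont_rate)
  expect_true(fra$responsive)
  expect_equal(dim(fra$rates), c(6, 13))
  # BF within one grid step of the generating best frequency
  step <- (40 / 0.5)^(1 / 12)
  expect_lt(abs(log(fra$bf / vn$stim$bf)), log(step) * 1.5)
})

test_that("relative width is the inverse quality factor", {
  expect_equal(relative_width(2, 10), 0.2)
  expect_equal(relative_width(0, 10), 0)
  q <- 10 / 2
  expect_equal(relative_width(2, 10), 1 / q)
  expect_error(relative_width(1, 0), "positive")
})

test_that("FSA surfaces threshold suppression against the low-level baseline", {
  freqs <- c(1, 2, 4, 8, 16)
  levels <- c(0, 30, 50)
  pr <- rbind(c(10, 10, 10, 10, 10),     # baseline row: no suppression
              c(10, 6, 2, 6, 10),
              c(8, 3, 1, 3, 8))
  fsa <- fsa_surface(freqs, levels, pr, probe_f = 4, probe_i = 20)
  expect_equal(fsa$baseline, 10)
  expect_equal(fsa$suppression[2, 3], 0.8)
  expect_true(fsa$mask[2, 3])
  expect_false(fsa$mask[2, 1])  # far-off adaptor: suppression ~ 0
  expect_gt(fsa$bw10, 0)
  expect_gt(fsa$bw30, fsa$bw10)

  # the alternative criterion reading thresholds the ratio itself
  alt <- fsa_surface(freqs, levels, pr, probe_f = 4, probe_i = 20,
                     mode = "ratio")
  expect_true(alt$mask[2, 2])     # 6/10 <= 0.6
  expect_false(fsa$mask[2, 2])    # suppression 0.4 < 0.6

  expect_error(fsa_surface(freqs, levels, pr * 0, probe_f = 4,
                           probe_i = 20), "baseline")
})

test_that("estimate_fsa aggregates RAP trials per adaptor cell", {
  grid <- list(freqs = c(2, 4, 8), levels = c(0, 50))
  trials <- build_rap_trials(4, 40, grid, repeats = 2, seed = 9)
  # hand-built spikes: probe responds with 6 spikes unless the adaptor is
  # 4 kHz at 50 dB, where it is suppressed to 1 spike
  sessions <- lapply(trials, function(tr) {
    suppressed <- tr$events$freq_khz[1] == 4 && tr$events$level_db[1] == 50
    n <- if (suppressed) 1 else 6
    spikes <- c(rep(list(numeric(0)), 3), list(seq_len(n) * 10))
    ssasim:::new_session("x", tr, spikes, ssasim:::event_windows(tr), 1L)
  })
  fsa <- estimate_fsa(sessions)
  expect_equal(fsa$baseline, 6)
  pc <- which(fsa$freqs == 4)
  expect_equal(fsa$suppression[2, pc], 1 - 1 / 6)
  expect_true(fsa$mask[2, pc])
  expect_false(any(fsa$mask[1, ]))
})
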