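test_that("relative separation, frequency pairs and octave conversion agree", {
  expect_equal(relative_separation(10, 10), 0)
  expect_equal(relative_separation(10, 11.05125), 0.1, tolerance = 1e-4)
  expect_equal(relative_separation(10, 14.4493), 0.37, tolerance = 1e-3)
  expect_equal(relative_separation(5, 10), -relative_separation(10, 5))

  expect_equal(make_frequency_pair(10, 0), 10)
  expect_equal(make_frequency_pair(10, 0.1), 11.0512, tolerance = 1e-4)
  expect_equal(make_frequency_pair(8, 0.04), 8.3265, tolerance = 1e-4)

  expect_equal(octave_separation(10, 20), 1)
  expect_equal(octave_separation(10, 10), 0)
  expect_equal(octave_separation(10, 11.0512), 0.1443, tolerance = 1e-3)

  expect_error(relative_separation(-1, 5), "positive")
  expect_error(make_frequency_pair(10, -0.1), ">= 0")
  expect_error(octave_separation(0, 5), "positive")

  # round trip across the full separation range
  for (d in seq(0, 1, by = 0.1)) {
    expect_equal(relative_separation(10, make_frequency_pair(10, d)), d,
                 tolerance = 1e-9)
  }
})

test_that("oddball sequences have exact role counts on a fixed SOA grid", {
  cond <- oddball_condition(4, 40, delta_f = 0.1)
  sq <- build_oddball_sequence(cond, seed = 3)
  expect_equal(sum(sq$events$role == "standard"), 360)
  expect_equal(sum(sq$events$role == "deviant"), 40)
  expect_equal(sq$events$onset_ms, seq(0, 99750, by = 250))

  # reproducibility and seed sensitivity
  sq2 <- build_oddball_sequence(cond, seed = 3)
  expect_identical(sq$events, sq2$events)
  sq3 <- build_oddball_sequence(cond, seed = 4)
  expect_false(identical(sq$events$role, sq3$events$role))

  # the swap flag exchanges which stimulus plays which role
  sw <- build_oddball_sequence(ssasim:::flip_swap(cond), seed = 3)
  dev_f <- unique(sw$events$freq_khz[sw$events$role == "deviant"])
  expect_equal(dev_f, cond$f1)

  expect_error(build_oddball_sequence(cond, n_stimuli = 10,
                                      p_deviant = 0.15),
               "integer")
  expect_error(build_oddball_sequence(cond, p_deviant = 0), "p_deviant")
})

test_that("alone sequences silence the other role and keep the timing", {
  cond <- oddball_condition(4, 40, delta_f = 0.1, swap = TRUE)
  sq <- build_oddball_sequence(cond, seed = 9)
  dev <- build_alone_sequence(sq, "deviant")
  expect_equal(sum(dev$events$role == "alone"), 40)
  expect_equal(sum(dev$events$role == "silence"), 360)
  expect_true(all(is.na(dev$events$freq_khz[dev$events$role == "silence"])))
  expect_equal(dev$events$onset_ms, sq$events$onset_ms)
  kept <- which(sq$events$role == "deviant")
  expect_equal(dev$events$freq_khz[kept], sq$events$freq_khz[kept])

  std <- build_alone_sequence(sq, "standard")
  expect_equal(sum(std$events$role == "alone"), 360)

  # idempotent under re-application
  dev2 <- build_alone_sequence(dev, "deviant")
  expect_identical(dev2$events, dev$events)

  rap <- build_rap_trials(4, 40, list(freqs = 2, levels = 50), seed = 1)[[1]]
  expect_error(build_alone_sequence(rap, "deviant"), "not present")
})

test_that("the complete protocol enumerates to the expected condition set", {
  conds <- build_protocol(4, 40)
  expect_length(conds, 14)
  kinds <- vapply(conds, function(x) x$paradigm_kind, character(1))
  expect_equal(sum(kinds == "frequency"), 1)
  expect_equal(sum(kinds == "intensity"), 3)   # delta_f = 0 per delta_i
  expect_equal(sum(kinds == "double"), 9)
  expect_equal(sum(kinds == "deviant_alone"), 1)

  small <- build_protocol(4, 40, delta_f_set = 0, delta_i_set = 10)
  expect_length(small, 3)

  # protocol size = 1 + |df| * |di| + 1 for arbitrary non-empty sets
  expect_length(build_protocol(4, 40, delta_f_set = c(0, 0.1),
                               delta_i_set = c(10, 20, 30, 40)), 10)
  expect_error(build_protocol(4, 40, delta_f_set = numeric(0)), "non-empty")
})

test_that("RAP trials are a-a-a-p with a 2000-ms trial and an ordered rove", {
  grid <- list(freqs = c(1, 2, 4, 8, 16), levels = c(20, 40))
  trials <- build_rap_trials(4, 40, grid, repeats = 3, seed = 5)
  expect_length(trials, 5 * 2 * 3)

  tr <- trials[[1]]
  expect_equal(tr$events$onset_ms, c(0, 250, 500, 750))
  expect_equal(tr$events$role, c("adaptor", "adaptor", "adaptor", "probe"))
  expect_equal(length(unique(tr$events$freq_khz[1:3])), 1)
  expect_equal(tr$events$freq_khz[4], 4)
  # trial span: 4 SOA slots plus the recovery gap
  expect_equal(max(tr$events$onset_ms) + sum(ssasim:::event_windows(tr)[4]),
               2000)

  # intensities ascend; every cell appears exactly `repeats` times
  lv <- vapply(trials, function(t) t$events$level_db[1], numeric(1))
  expect_true(!is.unsorted(lv))
  cells <- table(vapply(trials, function(t)
    paste(t$events$freq_khz[1], t$events$level_db[1]), character(1)))
  expect_true(all(cells == 3))

  # full-size protocol: 25 x 8 x 4 = 800 trials
  big <- build_rap_trials(4, 40,
                          list(freqs = exp(seq(log(0.5), log(40),
                                               length.out = 25)),
                               levels = seq(0, 70, 10)),
                          repeats = 4, seed = 1)
  expect_length(big, 800)
})

test_that("forward-suppression trials place the probe at adaptor offset + gap", {
  grid <- list(freqs = 2, levels = 50)
  tr0 <- build_forward_suppression_trials(4, 40, grid, gap = 0,
                                          repeats = 4, seed = 2)
  expect_length(tr0, 4)
  expect_equal(tr0[[1]]$events$onset_ms, c(0, 75))
  expect_equal(tr0[[1]]$events$role, c("adaptor", "probe"))

  tr <- build_forward_suppression_trials(4, 40, grid, gap = 175,
                                         repeats = 1, seed = 2)
  expect_equal(tr[[1]]$events$onset_ms[2], 250)
  expect_error(build_forward_suppression_trials(4, 40, grid, gap = -1),
               ">= 0")
})

test_that("the FRA grid is log-spaced with level-blocked random order", {
  sq <- build_fra_grid(repeats = 2, seed = 8)
  freqs <- sq$grid$freqs
  expect_length(freqs, 25)
  expect_equal(freqs[1], 0.5)
  expect_equal(freqs[25], 40)
  ratios <- freqs[-1] / freqs[-25]
  expect_equal(ratios, rep((40 / 0.5)^(1 / 24), 24), tolerance = 1e-12)

  ev <- sq$events
  expect_true(!is.unsorted(ev$level_db))
  cells <- table(paste(ev$freq_khz, ev$level_db))
  expect_true(all(cells == 2))
  expect_error(build_fra_grid(fmin = 10, fmax = 5), "fmin")
})
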