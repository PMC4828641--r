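test_that("the adaptation function has the stated slope structure", {
  expect_equal(adaptation_increment(0, 1, 0.1, 0.5), 0)
  # at x = tau the slope is (M + m)/2 by construction
  expect_equal(adaptation_increment(0.5, 1, 0, 0.5), 0.5 / 2)
  # constant-slope limit M = m
  x <- seq(0, 3, by = 0.25)
  expect_equal(adaptation_increment(x, 0.3, 0.3, 0.7), 0.3 * x)
  # slope M near zero, slope m at large x
  h <- 1e-6
  expect_equal(adaptation_increment(h, 0.8, 0.1, 0.5) / h, 0.8,
               tolerance = 1e-5)
  expect_equal(adaptation_increment(100, 0.8, 0.1, 0.5) / 100, 0.1,
               tolerance = 1e-6)
  expect_error(adaptation_increment(-1, 0.8, 0.1, 0.5), ">= 0")
})

test_that("closed-form steady state matches its limiting cases", {
  expect_equal(steady_state_adaptation(2, 0.5, 0), 2)
  expect_equal(steady_state_adaptation(2, 0, 0.3), 0)
  expect_equal(steady_state_adaptation(1, 0.5, 0.5), 1 / 3)
  expect_error(steady_state_adaptation(1, 0, 0), "degenerate")
})

test_that("the trial recursion starts unadapted and decays geometrically", {
  nrn <- toy_neuron()
  st <- initial_state(nrn)
  expect_equal(st$A, numeric(40))
  syn <- nrn$W * 0.5
  step1 <- advance_trial(st, syn, nrn)
  expect_equal(step1$asyn, syn)            # A_1 = 0

  # zero drive: A decays by (1 - R) per trial
  st <- step1$state
  A0 <- st$A
  for (t in 1:5) st <- advance_trial(st, numeric(40), nrn)$state
  expect_equal(st$A, A0 * (1 - nrn$R)^5, tolerance = 1e-12)
  expect_error(advance_trial(st, rep(-1, 40), nrn), ">= 0")
})

test_that("with constant slope the recursion converges to the closed form", {
  nrn <- toy_neuron(M = 0.4, m = 0.4, tau = 1)   # constant alpha
  S <- 0.8
  syn <- numeric(40); syn[10] <- S
  st <- initial_state(nrn)
  for (t in 1:500) st <- advance_trial(st, syn, nrn)$state
  expect_lt(abs(st$A[10] - steady_state_adaptation(S, 0.4, nrn$R)), 1e-9)
  expect_equal(st$A[-10], numeric(39))
})

test_that("the compiled recursion matches the per-trial reference step", {
  nrn <- toy_neuron()
  set.seed(42)
  syn <- matrix(runif(30 * 40, 0, 0.8), 30, 40)
  rec <- ssasim:::adapt_recursion_cpp(syn, nrn$M, nrn$m, nrn$tau, nrn$R,
                                      numeric(40))
  st <- initial_state(nrn)
  for (t in 1:30) {
    step <- advance_trial(st, syn[t, ], nrn)
    expect_equal(step$asyn, rec$asyn[t, ], tolerance = 1e-12)
    st <- step$state
  }
  expect_equal(st$A, rec$A_final, tolerance = 1e-12)
  expect_equal(ssasim:::adapt_in_total_cpp(syn, nrn$M, nrn$m, nrn$tau,
                                           nrn$R),
               rec$in_total, tolerance = 1e-12)
})

test_that("simulated responses respect the adaptation invariants", {
  nrn <- toy_neuron()
  cond <- oddball_condition(4, 40, delta_f = 0.1)
  sq <- build_oddball_sequence(cond, n_stimuli = 100, seed = 7)
  sim <- simulate_sequence(nrn, sq)
  expect_true(all(sim$asyn >= 0))
  expect_true(all(sim$asyn <= sim$syn + 1e-12))
  expect_true(all(sim$final_state$A >= 0))

  # identical-tone train: deterministic, monotone non-increasing rate
  ev <- ssasim:::tone_events(onset_ms = (0:99) * 250, freq_khz = 4,
                             level_db = 40, role = "alone")
  train <- ssasim:::new_sequence(ev, soa = 250, kind = "train")
  tsim <- simulate_sequence(nrn, train)
  expect_true(all(diff(tsim$trace$fr) <= 1e-12))
  # first response is the unadapted rate out(sum(W * AN))
  fb <- nrn$filterbank
  in1 <- sum(nrn$W * an_rate(bm_response(4, 40, fb), config = fb))
  expect_equal(tsim$trace$fr[1], ssasim:::out_rate(in1, nrn$out_params))
})

test_that("adaptation in one channel set leaves distant stimuli unaffected", {
  fb <- filterbank_config()
  nrn <- model_neuron(rep(1, 40), M = 0.8, m = 0.05, tau = 0.4, R = 0.1,
                      out_theta = 1, out_rmax = 6, filterbank = fb)
  mk <- function(freqs) {
    ev <- ssasim:::tone_events(onset_ms = (seq_along(freqs) - 1) * 250,
                               freq_khz = freqs, level_db = 40,
                               role = "alone")
    ssasim:::new_sequence(ev, soa = 250, kind = "train")
  }
  probe_after_train <- simulate_sequence(nrn, mk(c(rep(1, 20), 28)))
  probe_fresh <- simulate_sequence(nrn, mk(28))
  fr_after <- probe_after_train$trace$fr[21]
  fr_fresh <- probe_fresh$trace$fr[1]
  expect_equal(fr_after, fr_fresh, tolerance = 1e-4)
})
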