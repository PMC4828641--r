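test_that("calibration recovers the synaptic envelope from a model FRA", {
  pop <- cached_population("p10", n = 10, p_strong = 0.7, seed = 77)
  vn <- pop[[3]]
  fra <- model_fra_surface(vn$model)
  cal <- calibrate_neuron(fra, vn$model$filterbank)
  expect_gte(cor(cal$W, vn$model$W), 0.9)

  # tuning contract: BF within one grid step, threshold within one level step
  refit <- model_fra_surface(cal$scaffold)
  step <- (40 / 0.5)^(1 / 24)
  expect_lt(abs(log(refit$bf / fra$bf)), log(step) * 1.01)
  expect_lte(abs(refit$threshold_db - fra$threshold_db), 10)

  # scaling all rates is absorbed by the output stage, not by W
  fra2 <- fra_surface(fra$freqs, fra$levels, fra$rates * 2)
  cal2 <- calibrate_neuron(fra2, vn$model$filterbank)
  expect_equal(cal2$W, cal$W, tolerance = 1e-12)
  expect_equal(cal2$out_params$rmax, 2 * cal$out_params$rmax,
               tolerance = 1e-9)

  flat <- fra_surface(fra$freqs, fra$levels, fra$rates * 0)
  expect_error(calibrate_neuron(flat), "unresponsive")
})

test_that("a symmetric tuning profile calibrates to a near-symmetric W", {
  fra <- gaussian_fra(bf = 4, sigma_oct = 0.8, threshold = 20)
  fb <- filterbank_config()
  cal <- calibrate_neuron(fra, fb)
  bf_h <- map_rat_to_human(4, fb)
  oct <- log2(fb$cfs / bf_h)
  # compare the W mass on mirrored flanks around the best frequency
  left <- sum(cal$W[oct < -0.2 & oct > -1.2])
  right <- sum(cal$W[oct > 0.2 & oct < 1.2])
  expect_lt(abs(left - right) / max(left, right), 0.35)
})

test_that("adaptation parameters are recovered from noise-free indices", {
  pop <- cached_population("p10", n = 10, p_strong = 0.7, seed = 77)
  for (vn in pop[c(2, 9)]) {            # one strong, one weak unit
    m <- vn$model
    conds <- Filter(function(cc) cc$paradigm_kind != "deviant_alone",
                    build_protocol(vn$stim$f1, vn$stim$i1))
    prep <- prepare_nri_problem(m, conds, seed = 55)
    obs <- simulated_nri_d(prep, m$M, m$m, m$tau, m$R)
    fit <- fit_adaptation_params(obs, prep, n_starts = 4, seed = 66)
    expect_lt(abs(fit$M - m$M) / m$M, 0.10)
    expect_lt(abs(fit$m - m$m) / m$m, 0.10)
    expect_lt(abs(fit$tau - m$tau) / m$tau, 0.25)
    expect_true(fit$converged)
    # the running best objective never increases across starts
    expect_true(all(diff(fit$objective_trace) <= 0))
  }
})

test_that("flat observed NRI implies no adaptation and seeds do not matter", {
  pop <- cached_population("p10", n = 10, p_strong = 0.7, seed = 77)
  vn <- pop[[2]]
  conds <- Filter(function(cc) cc$paradigm_kind != "deviant_alone",
                  build_protocol(vn$stim$f1, vn$stim$i1))
  prep <- prepare_nri_problem(vn$model, conds, seed = 55)

  flat <- fit_adaptation_params(rep(1, length(conds) - 1), prep,
                                n_starts = 4, seed = 1)
  expect_lt(flat$M, 0.01)

  obs <- simulated_nri_d(prep, vn$model$M, vn$model$m, vn$model$tau,
                         vn$model$R)
  f1 <- fit_adaptation_params(obs, prep, n_starts = 4, seed = 10)
  f2 <- fit_adaptation_params(obs, prep, n_starts = 4, seed = 20)
  expect_equal(f1$M, f2$M, tolerance = 1e-3)
  expect_equal(f1$tau, f2$tau, tolerance = 1e-2)

  expect_error(fit_adaptation_params(c(0.5, NA, NA, 0.2), prep),
               ">= 3 conditions")
})

test_that("population adaptation-function fits recover known curves", {
  x <- seq(0.2, 4, length.out = 30)
  g <- function(x, M, m, tau) (m + (M - m) * 2^(-x / tau)) * x
  y <- g(x, M = 0.8, m = 0.1, tau = 1.2)
  fit <- fit_population_g(x, y)
  expect_equal(fit$M, 0.8, tolerance = 0.02)
  expect_equal(fit$m, 0.1, tolerance = 0.02)
  expect_equal(fit$tau, 1.2, tolerance = 0.1)
  expect_lt(fit$mse, 1e-8)

  z <- fit_population_g(x, rep(0, 30))
  expect_equal(z$M, 0)
  expect_equal(z$m, 0)

  expect_error(fit_population_g(1:3, 1:3), ">= 5")
})

test_that("population fits separate strong from weak adaptation", {
  pop <- cached_population("pg12", n = 12, p_strong = 0.5, seed = 19)
  pairs <- t(vapply(pop, function(vn) {
    cond <- oddball_condition(vn$stim$f1, vn$stim$i1, delta_f = 0.1)
    r <- rate_model_responses(vn$model, cond, seed = 31)
    sa <- build_oddball_sequence(cond, seed = 31)
    alone_std <- build_alone_sequence(sa, "standard")
    s1a <- mean(simulate_sequence(vn$model, alone_std)$trace$fr[
      alone_std$events$role == "alone"])
    c(x = r$u1, y = r$u1 - s1a)
  }, numeric(2)))
  lab <- vapply(pop, function(v) v$label, character(1))
  fs <- fit_population_g(pairs[lab == "strong_ssa", "x"],
                         pairs[lab == "strong_ssa", "y"])
  fw <- fit_population_g(pairs[lab == "weak_ssa", "x"],
                         pairs[lab == "weak_ssa", "y"])
  expect_gt(fs$M, fw$M)
  # the strong curve lies above the weak curve over the shared range
  xs <- seq(min(pairs[, "x"]), max(pairs[, "x"]), length.out = 20)
  g <- function(p, x) (p$m + (p$M - p$m) * 2^(-x / p$tau)) * x
  expect_true(all(g(fs, xs) > g(fw, xs)))
})
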