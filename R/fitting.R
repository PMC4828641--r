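# Calibration of model neurons to measured tuning and nonlinear
# least-squares fitting of the adaptation-function parameters (M, m, tau),
# per neuron and at the population level.

#' Noise-free, unadapted FRA of a model neuron
#'
#' Evaluates the rate model once per frequency x level cell with no
#' adaptation history; useful for calibration targets and deterministic
#' checks.
#'
#' @param model A [model_neuron()].
#' @param freqs Grid frequencies, kHz (default the standard 25-step log
#'   grid over 0.5--40 kHz).
#' @param levels Grid levels, dB SPL.
#' @param crit_frac Criterion fraction passed to [fra_surface()].
#' @return An `fra_surface`.
#' @export
model_fra_surface <- function(model,
                              freqs = exp(seq(log(0.5), log(40),
                                              length.out = 25)),
                              levels = seq(0, 80, 10),
                              crit_frac = 0.2) {
  rates <- matrix(0, length(levels), length(freqs))
  for (li in seq_along(levels)) for (fi in seq_along(freqs)) {
    rates[li, fi] <- out_rate(unadapted_in(model, freqs[fi], levels[li]),
                              model$out_params)
  }
  fra_surface(freqs, levels, rates, spont = 0, crit_frac = crit_frac)
}

#' Deterministic FSA of a model neuron
#'
#' Runs the rate model over a RAP grid (one trial per adaptor cell; the
#' model is deterministic so repeats are redundant) and builds the
#' suppression surface from the probe-trial firing rates.
#'
#' @param model A [model_neuron()].
#' @param probe_f,probe_i Probe frequency (kHz) and level (dB SPL).
#' @param freqs,levels Adaptor grid.
#' @param fra Optional `fra_surface` for bandwidth ratios.
#' @inheritParams fsa_surface
#' @return An `fsa_surface`.
#' @export
model_fsa_surface <- function(model, probe_f, probe_i,
                              freqs = exp(seq(log(0.5), log(40),
                                              length.out = 25)),
                              levels = seq(0, 80, 10),
                              fra = NULL, criterion = 0.6,
                              mode = c("one_minus_ratio", "ratio"),
                              n_baseline_rows = 1) {
  mode <- match.arg(mode)
  pr <- matrix(NA_real_, length(levels), length(freqs))
  for (li in seq_along(levels)) for (fi in seq_along(freqs)) {
    ev <- tone_events(onset_ms = c(0, 250, 500, 750),
                      freq_khz = c(rep(freqs[fi], 3), probe_f),
                      level_db = c(rep(levels[li], 3), probe_i),
                      role = c(rep("adaptor", 3), "probe"))
    sq <- new_sequence(ev, soa = 250, kind = "rap", gap_ms = 1000)
    sim <- simulate_sequence(model, sq)
    pr[li, fi] <- sim$trace$fr[4]
  }
  fsa_surface(freqs, levels, pr, probe_f = probe_f, probe_i = probe_i,
              criterion = criterion, mode = mode,
              n_baseline_rows = n_baseline_rows, fra = fra)
}

#' Calibrate synaptic weights and the output stage to a measured FRA
#'
#' Sets the per-channel weights `W` from the measured tuning profile at
#' threshold + 10 dB and the output sigmoid so that the model reproduces the
#' measured response threshold and peak rate.  The profile is first
#' interpolated in log-frequency onto the channel CFs (read back through the
#' rat-to-human map) and then refined by a small number of multiplicative
#' Richardson-Lucy updates against the filterbank's own excitation spread,
#' so the model's noise-free tuning curve reproduces the measured profile
#' (BF within one grid step, threshold within one level step) instead of a
#' version smeared by the cochlear filters.  The output stage uses
#' `theta = 2 * IN(BF, threshold)` (placing the 20% response criterion at
#' the measured threshold for a Hill exponent of 2) and `rmax` such that
#' `out(IN_peak)` equals the measured peak rate.  Deterministic given its
#' inputs; doubling all FRA rates doubles `rmax` but leaves the shape of
#' `W` unchanged.
#'
#' @param fra An `fra_surface` (must be responsive).
#' @param filterbank A [filterbank_config()].
#' @param out_hill Output Hill exponent (default 2).
#' @param n_iter Richardson-Lucy refinement iterations (default 12).
#' @return List with `W`, `out_params`, and `scaffold`, a [model_neuron()]
#'   with placeholder adaptation parameters ready for
#'   [fit_adaptation_params()].
#' @export
calibrate_neuron <- function(fra, filterbank = filterbank_config(),
                             out_hill = 2, n_iter = 12) {
  stopifnot(inherits(fra, "fra_surface"))
  if (!fra$responsive) stop_invalid("cannot calibrate an unresponsive FRA")
  ref_i <- which.min(abs(fra$levels - (fra$threshold_db + 10)))
  profile <- pmax(fra$rates[ref_i, ] - fra$spont, 0)
  if (max(profile) <= 0) profile <- pmax(fra$rates[ref_i, ], 0)
  cf_rat <- map_human_to_rat(filterbank$cfs, filterbank)
  W <- approx(log(fra$freqs), profile, xout = log(cf_rat), rule = 2)$y
  W <- pmax(W, 0)
  if (max(W) <= 0) stop_invalid("calibration produced an all-zero W")
  W <- W / max(W)
  # excitation spread matrix at the reference level: P[f, k] = AN activity
  # of channel k for a grid tone at frequency f
  P <- t(vapply(fra$freqs, function(f)
    an_rate(bm_response(f, fra$levels[ref_i], filterbank),
            config = filterbank),
    numeric(filterbank$n_channels)))
  target <- profile / max(profile)
  col_sum <- pmax(colSums(P), 1e-12)
  for (it in seq_len(n_iter)) {
    pred <- as.numeric(P %*% W)
    if (max(pred) <= 0) break
    pred <- pred / max(pred)
    ratio <- ifelse(pred > 1e-9, target / pred, 1)
    W <- W * as.numeric(crossprod(P, ratio)) / col_sum
    W <- pmax(W, 0)
    if (max(W) <= 0) stop_invalid("calibration produced an all-zero W")
    W <- W / max(W)
  }
  scaffold <- model_neuron(W, M = 0.5, m = 0.05, tau = 0.3, R = 0.1,
                           out_theta = 1, out_rmax = 1, out_hill = out_hill,
                           filterbank = filterbank)
  in_thr <- unadapted_in(scaffold, fra$bf, fra$threshold_db)
  theta <- max(2 * in_thr, 1e-6)
  in_grid <- vapply(fra$levels, function(L)
    unadapted_in(scaffold, fra$bf, L), numeric(1))
  in_peak <- max(in_grid)
  peak_rate <- max(fra$rates)
  rmax <- peak_rate * (in_peak^out_hill + theta^out_hill) / in_peak^out_hill
  out_params <- list(theta = theta, rmax = rmax, hill = out_hill)
  scaffold$out_params <- out_params
  list(W = W, out_params = out_params, scaffold = scaffold)
}

#' Precompute the simulation scaffolding for NRI fitting
#'
#' The synaptic drive matrices of the fitting sequences depend only on the
#' stimuli and `W`, not on `(M, m, tau, R)`, so they are computed once; the
#' optimizer then only re-runs the cheap adaptation recursion.
#'
#' @param neuron A [model_neuron()].
#' @param conditions List of [oddball_condition()]s (alone descriptors are
#'   skipped).
#' @param n_stimuli,p_deviant,soa Sequence parameters.
#' @param seed Seed used for all sequence permutations.
#' @return An `nri_problem` for [simulated_nri_d()].
#' @export
prepare_nri_problem <- function(neuron, conditions, n_stimuli = 400,
                                p_deviant = 0.1, soa = 250, seed = 1L) {
  conditions <- Filter(function(cc)
    cc$paradigm_kind %in% c("frequency", "intensity", "double"), conditions)
  if (length(conditions) == 0) stop_invalid("no oddball conditions supplied")
  # the deviant-alone sequence is shared across conditions (f1, i1 is fixed)
  c1 <- conditions[[1]]
  dev_odd <- build_oddball_sequence(flip_swap(c1), n_stimuli, p_deviant,
                                    soa, seed = derive_seed(seed, 0))
  alone <- build_alone_sequence(dev_odd, "deviant")
  probs <- lapply(seq_along(conditions), function(i) {
    cond <- flip_swap(conditions[[i]])  # (f1, i1) as deviant -> d1
    sq <- build_oddball_sequence(cond, n_stimuli, p_deviant, soa,
                                 seed = derive_seed(seed, i))
    sq_std <- build_oddball_sequence(conditions[[i]], n_stimuli, p_deviant,
                                     soa, seed = derive_seed(seed, 500 + i))
    list(syn = syn_matrix(neuron, sq),
         dev_idx = which(sq$events$role == "deviant"),
         syn_std = syn_matrix(neuron, sq_std),
         std_idx = which(sq_std$events$role == "standard"),
         condition = conditions[[i]])
  })
  structure(list(neuron = neuron, problems = probs,
                 alone_syn = syn_matrix(neuron, alone),
                 alone_idx = which(alone$events$role == "alone")),
            class = "nri_problem")
}

#' Simulated NRI_d values for given adaptation parameters
#'
#' @param prep An `nri_problem` from [prepare_nri_problem()].
#' @param M,m,tau Adaptation parameters.
#' @param R Recovery fraction (default: the scaffold neuron's).
#' @return Numeric vector of simulated `NRI_d`, one per condition.
#' @export
simulated_nri_d <- function(prep, M, m, tau, R = NULL) {
  R <- R %||% prep$neuron$R
  op <- prep$neuron$out_params
  u1 <- mean(out_rate(adapt_in_total_cpp(prep$alone_syn, M, m, tau,
                                         R)[prep$alone_idx], op))
  if (u1 <= 0) return(rep(NA_real_, length(prep$problems)))
  vapply(prep$problems, function(pb) {
    it <- adapt_in_total_cpp(pb$syn, M, m, tau, R)
    mean(out_rate(it[pb$dev_idx], op)) / u1
  }, numeric(1))
}

#' Simulated NRI_d and NRI_s values
#'
#' Like [simulated_nri_d()] but also runs the role-swapped companion
#' sequence of each condition, in which (`f1`, `i1`) is the standard, and
#' returns both normalized response indices.
#'
#' @inheritParams simulated_nri_d
#' @return List with numeric vectors `nri_d` and `nri_s` (one per
#'   condition) and the scalar `u1`.
#' @export
simulated_nri <- function(prep, M, m, tau, R = NULL) {
  R <- R %||% prep$neuron$R
  op <- prep$neuron$out_params
  u1 <- mean(out_rate(adapt_in_total_cpp(prep$alone_syn, M, m, tau,
                                         R)[prep$alone_idx], op))
  if (u1 <= 0)
    return(list(nri_d = rep(NA_real_, length(prep$problems)),
                nri_s = rep(NA_real_, length(prep$problems)), u1 = u1))
  nri_d <- vapply(prep$problems, function(pb) {
    it <- adapt_in_total_cpp(pb$syn, M, m, tau, R)
    mean(out_rate(it[pb$dev_idx], op)) / u1
  }, numeric(1))
  nri_s <- vapply(prep$problems, function(pb) {
    it <- adapt_in_total_cpp(pb$syn_std, M, m, tau, R)
    mean(out_rate(it[pb$std_idx], op)) / u1
  }, numeric(1))
  list(nri_d = nri_d, nri_s = nri_s, u1 = u1)
}

#' Fit the adaptation-function parameters to observed NRI_d values
#'
#' Minimizes the summed squared difference between observed and simulated
#' `NRI_d` across conditions over `(M, m, tau)` with `M >= m >= 0`,
#' `tau > 0` (`m` is parameterized as a fraction of `M`, `tau` on a log
#' scale), using bounded L-BFGS-B from `n_starts` seeded multi-starts
#' (log-spaced in `tau`) and keeping the best optimum.  `R` stays fixed at
#' its configured value by default.
#'
#' @param observed_nri Observed `NRI_d` values, one per condition in `prep`
#'   (`NA`s dropped; at least 3 usable conditions required).
#' @param prep An `nri_problem` from [prepare_nri_problem()].
#' @param R Recovery fraction held fixed during the fit.
#' @param n_starts Number of multi-starts (default 8).
#' @param seed Seed for the start jitter.
#' @param M_max Upper bound on `M`.
#' @param tau_range Box bounds on `tau`.  Synaptic activity is normalized to
#'   at most 1 per channel, so half-transition values far outside this range
#'   make the slope transition unobservable and the decomposition of `g`
#'   into (`M`, `m`, `tau`) degenerate.
#' @return A `fit_result`: list with `M`, `m`, `tau`, `R`, `mse`,
#'   `converged`, `bounds_hit`, `n_starts`, `objective_trace` (best value
#'   after each start; non-increasing).
#' @export
fit_adaptation_params <- function(observed_nri, prep, R = NULL,
                                  n_starts = 8, seed = 1L, M_max = 3,
                                  tau_range = c(0.1, 3)) {
  stopifnot(inherits(prep, "nri_problem"))
  R <- R %||% prep$neuron$R
  use <- which(!is.na(observed_nri))
  if (length(use) < 3)
    stop_invalid("need >= 3 conditions with a defined NRI_d (got %d)",
                 length(use))
  sub <- prep
  sub$problems <- prep$problems[use]
  obs <- observed_nri[use]
  lower <- c(log(1e-8), -20, log(tau_range[1]))
  upper <- c(log(M_max), 20, log(tau_range[2]))
  objective <- function(p) {
    p <- pmin(pmax(p, lower), upper)   # box projection (polish stage)
    M <- exp(p[1]); f <- stats::plogis(p[2]); tau <- exp(p[3])
    sim <- simulated_nri_d(sub, M, f * M, tau, R)
    if (any(is.na(sim))) return(1e6)
    sum((obs - sim)^2)
  }
  tau_starts <- exp(seq(log(tau_range[1] * 1.2), log(tau_range[2] / 1.2),
                        length.out = n_starts))
  M_starts <- rep(c(0.15, 0.4, 0.7, 1.2), length.out = n_starts)
  jit <- with_seed(seed, matrix(runif(3 * n_starts, -0.1, 0.1), ncol = 3))
  best <- NULL
  trace <- numeric(0)
  for (s in seq_len(n_starts)) {
    p0 <- c(log(M_starts[s]), stats::qlogis(0.1), log(tau_starts[s])) +
      jit[s, ]
    fit <- tryCatch(
      optim(p0, objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500, factr = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    trace <- c(trace, best$value)
  }
  if (is.null(best)) stop_invalid("all optimizer starts failed")
  # derivative-free polish: the objective is nearly flat along the
  # (m, tau) trade-off, where finite-difference gradients lose accuracy
  pol <- tryCatch(
    optim(best$par, objective, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) {
    pol$convergence <- best$convergence
    pol$par <- pmin(pmax(pol$par, lower), upper)
    best <- pol
    trace <- c(trace, best$value)
  }
  M <- exp(best$par[1]); m <- stats::plogis(best$par[2]) * M
  tau <- exp(best$par[3])
  structure(
    list(M = M, m = m, tau = tau, R = R,
         mse = best$value / length(obs),
         converged = best$convergence == 0,
         bounds_hit = c(M_upper = M > 0.99 * M_max,
                        tau_lower = tau < 1.01 * tau_range[1],
                        tau_upper = tau > 0.99 * tau_range[2]),
         n_starts = n_starts, objective_trace = trace, seed = seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> M=%.4g m=%.4g tau=%.4g (R=%.3g fixed), MSE=%.3g\n",
              x$M, x$m, x$tau, x$R, x$mse))
  invisible(x)
}

#' Population-level fit of the adaptation function
#'
#' Least-squares fit of `y = g(x)` to per-neuron pairs where `x` is the
#' deviant-alone firing rate (a proxy for the unadapted synaptic activity)
#' and `y` the deviant-alone minus standard-alone rate (the accumulated
#' adaptation).  Negative `y` values (noise) are retained and the fit is
#' unweighted.  Uses bounded Levenberg-Marquardt with `M = m + dM`
#' (`dM >= 0`) so `M >= m >= 0` always holds; multi-started over `tau`.
#'
#' @param x Deviant-alone rates (spikes per stimulus), one per neuron.
#' @param y Deviant-alone minus standard-alone rates.
#' @param n_tau Size of the `tau` profile grid.
#' @return List with `M`, `m`, `tau`, `mse`, `converged`, `n`.
#' @export
fit_population_g <- function(x, y, n_tau = 60) {
  if (length(x) < 5 || length(x) != length(y))
    stop_invalid("need >= 5 (x, y) pairs")
  if (all(abs(y) < 1e-12)) {
    return(list(M = 0, m = 0, tau = stats::median(x[x > 0]) %||% 1,
                mse = 0, converged = TRUE, n = length(x)))
  }
  # for fixed tau the model y = m*x + dM*(2^(-x/tau) x) is linear in
  # (m, dM) >= 0: profile tau on a log grid and solve the constrained LS
  # in closed form (interior solution, or one of the two boundary fits)
  xr <- stats::median(x[x > 0])
  taus <- exp(seq(log(xr / 50), log(xr * 50), length.out = n_tau))
  solve_fixed_tau <- function(tau) {
    z <- 2^(-x / tau) * x
    fits <- list()
    G <- rbind(c(sum(x * x), sum(x * z)), c(sum(x * z), sum(z * z)))
    b <- c(sum(x * y), sum(z * y))
    if (abs(det(G)) > 1e-12) {
      cf <- solve(G, b)
      if (all(cf >= 0)) fits <- c(fits, list(cf))
    }
    fits <- c(fits, list(c(max(sum(x * y) / sum(x * x), 0), 0)),
              list(c(0, max(sum(z * y) / sum(z * z), 0))))
    rss <- vapply(fits, function(cf)
      sum((y - cf[1] * x - cf[2] * z)^2), numeric(1))
    cf <- fits[[which.min(rss)]]
    list(m = cf[1], dM = cf[2], rss = min(rss))
  }
  prof <- lapply(taus, solve_fixed_tau)
  best_i <- which.min(vapply(prof, `[[`, numeric(1), "rss"))
  best <- prof[[best_i]]
  tau <- taus[best_i]
  # optional Levenberg-Marquardt polish from the profiled optimum
  polished <- tryCatch({
    fit <- minpack.lm::nlsLM(
      y ~ (m + dM * 2^(-x / tau)) * x,
      data = data.frame(x = x, y = y),
      start = list(m = best$m, dM = best$dM, tau = tau),
      lower = c(m = 0, dM = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(m = unname(cf["m"]), dM = unname(cf["dM"]),
         tau = unname(cf["tau"]), rss = sum(stats::residuals(fit)^2))
  }, error = function(e) NULL)
  if (!is.null(polished) && polished$rss <= best$rss) {
    best <- polished
    tau <- polished$tau
  }
  list(M = best$m + best$dM, m = best$m, tau = tau,
       mse = best$rss / length(x), converged = TRUE, n = length(x))
}
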