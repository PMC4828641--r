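# SSA and monotonicity indices, bootstrap reliability, and the strong/weak
# and monotonic/non-monotonic classifications.

#' Bundle condition responses for index computation
#'
#' `d1`/`s1` (`d2`/`s2`) are the responses in spikes per stimulus to the
#' lower- (higher-) frequency/intensity stimulus when presented as deviant or
#' standard; `u1` is the unadapted response from the deviant-alone condition.
#' Per-trial spike counts can be attached for bootstrap resampling.
#'
#' @param d1,s1,d2,s2 Condition responses (>= 0; `NA` when not measured).
#' @param u1 Unadapted (deviant-alone) response (>= 0 or `NA`).
#' @param trials Optional named list of per-trial count vectors
#'   (`d1`, `s1`, ...).
#' @param spont Expected spontaneous count per trial window (default 0).
#' @return A `condition_responses` object.
#' @export
condition_responses <- function(d1, s1, d2 = NA_real_, s2 = NA_real_,
                                u1 = NA_real_, trials = NULL, spont = 0) {
  vals <- c(d1 = d1, s1 = s1, d2 = d2, s2 = s2, u1 = u1)
  if (any(vals < 0, na.rm = TRUE))
    stop_invalid("condition responses must be >= 0")
  structure(list(d1 = d1, s1 = s1, d2 = d2, s2 = s2, u1 = u1,
                 trials = trials, spont = spont),
            class = "condition_responses")
}

#' Compute the SSA index set
#'
#' \itemize{
#'   \item `CSI = (d1 + d2 - s1 - s2) / (d1 + d2 + s1 + s2)`
#'   \item `SI1 = (d1 - s1) / (d1 + s1)`, `SI2 = (d2 - s2) / (d2 + s2)`
#'   \item `NRI_d = d1 / u1`, `NRI_s = s1 / u1`
#' }
#' CSI and SI lie in `[-1, 1]`; NRI is 1 for an unadapted and 0 for a fully
#' suppressed response.  Singular denominators (both responses zero, or
#' `u1 = 0`) make the corresponding index `NA` with a reason recorded in
#' `$flags`; undefined indices are never imputed as zero.
#'
#' @param resp A [condition_responses()].
#' @return An `index_set`: list with `csi`, `si1`, `si2`, `nri_d`, `nri_s`
#'   and a character vector `flags`.
#' @export
compute_ssa_indices <- function(resp) {
  stopifnot(inherits(resp, "condition_responses"))
  flags <- character(0)
  ratio_idx <- function(num, den, name) {
    if (any(is.na(c(num, den)))) {
      flags <<- c(flags, paste0(name, ": missing input"))
      return(NA_real_)
    }
    if (den <= 0) {
      flags <<- c(flags, paste0(name, ": zero denominator"))
      return(NA_real_)
    }
    num / den
  }
  csi <- ratio_idx(resp$d1 + resp$d2 - resp$s1 - resp$s2,
                   resp$d1 + resp$d2 + resp$s1 + resp$s2, "CSI")
  si1 <- ratio_idx(resp$d1 - resp$s1, resp$d1 + resp$s1, "SI1")
  si2 <- ratio_idx(resp$d2 - resp$s2, resp$d2 + resp$s2, "SI2")
  nri_d <- ratio_idx(resp$d1, resp$u1, "NRI_d")
  nri_s <- ratio_idx(resp$s1, resp$u1, "NRI_s")
  structure(list(csi = csi, si1 = si1, si2 = si2,
                 nri_d = nri_d, nri_s = nri_s, flags = flags),
            class = "index_set")
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("<index_set> CSI=%.3g SI1=%.3g SI2=%.3g NRI_d=%.3g NRI_s=%.3g\n",
              x$csi, x$si1, x$si2, x$nri_d, x$nri_s))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Monotonicity index of the rate-intensity function
#'
#' At the FRA column for frequency `f1`: the rate at the highest tested
#' level divided by the maximal rate across all levels,
#' `MI = FR(f1, max i) / max_i FR(f1, i)`.  Values below 0.75 mark
#' non-monotonic (intensity-tuned) units.
#'
#' @param fra An `fra_surface`.
#' @param f1 Frequency on the FRA grid, kHz.
#' @param tol Relative tolerance for matching `f1` to the grid.
#' @return MI in `[0, 1]`, or `NA` when the column never responds.
#' @export
monotonicity_index <- function(fra, f1, tol = 0.05) {
  stopifnot(inherits(fra, "fra_surface"))
  col <- which.min(abs(log(fra$freqs) - log(f1)))
  if (abs(log(fra$freqs[col]) - log(f1)) > log(1 + tol))
    stop_invalid("f1 = %g kHz is not on the FRA grid", f1)
  rates <- fra$rates[, col]
  if (max(rates) <= 0) return(NA_real_)
  rates[length(rates)] / max(rates)
}

#' Classify a neuron by SSA strength and monotonicity
#'
#' Strong SSA iff `CSI >= csi_cut` (default 0.18, boundary inclusive);
#' monotonic iff `MI >= mi_cut` (default 0.75, inclusive).  Undefined inputs
#' yield `"unclassified"`.
#'
#' @param csi CSI value (or an `index_set`).
#' @param mi Monotonicity index.
#' @param csi_cut,mi_cut Classification cutoffs.
#' @return List with `ssa` (`"strong_ssa"`/`"weak_ssa"`/`"unclassified"`)
#'   and `monotonicity` (`"monotonic"`/`"non_monotonic"`/`"unclassified"`).
#' @export
classify_neuron <- function(csi, mi = NA_real_, csi_cut = 0.18,
                            mi_cut = 0.75) {
  if (inherits(csi, "index_set")) csi <- csi$csi
  ssa <- if (is.na(csi)) "unclassified"
         else if (csi >= csi_cut) "strong_ssa" else "weak_ssa"
  mono <- if (is.na(mi)) "unclassified"
          else if (mi >= mi_cut) "monotonic" else "non_monotonic"
  list(ssa = ssa, monotonicity = mono)
}

#' Bootstrap reliability of an SI value
#'
#' Resamples trials with replacement within role (`n_resamples` within-neuron
#' resamples), recomputes `SI = (mean(d) - mean(s)) / (mean(d) + mean(s))`
#' per resample, and returns the percentile confidence interval.  The value
#' is flagged unreliable when the resampled summed response is not clearly
#' above the spontaneous expectation: the lower 5th percentile of
#' `mean(d) + mean(s)` must exceed `spont_expect` (the expected spontaneous
#' count sum for the two windows).
#'
#' @param d_counts,s_counts Per-trial spike counts for the deviant and
#'   standard role (>= 2 trials each).
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param ci Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param spont_expect Expected spontaneous count sum per trial pair
#'   (default 0).
#' @return List with `si`, `ci` (length 2, possibly `NA`), `reliable`,
#'   `n_resamples`.
#' @export
bootstrap_si <- function(d_counts, s_counts, n_resamples = 1000, ci = 0.95,
                         seed = 1L, spont_expect = 0) {
  nd <- length(d_counts); ns <- length(s_counts)
  if (nd < 2 || ns < 2) stop_invalid("need >= 2 trials per role")
  dbar <- mean(d_counts); sbar <- mean(s_counts)
  si <- if (dbar + sbar > 0) (dbar - sbar) / (dbar + sbar) else NA_real_
  if (all(d_counts == 0) && all(s_counts == 0)) {
    return(list(si = si, ci = c(NA_real_, NA_real_), reliable = FALSE,
                n_resamples = n_resamples))
  }
  res <- with_seed(seed, {
    dmat <- matrix(sample(d_counts, nd * n_resamples, replace = TRUE),
                   nrow = nd)
    smat <- matrix(sample(s_counts, ns * n_resamples, replace = TRUE),
                   nrow = ns)
    list(d = colMeans(dmat), s = colMeans(smat))
  })
  tot <- res$d + res$s
  si_b <- ifelse(tot > 0, (res$d - res$s) / tot, NA_real_)
  si_ok <- si_b[!is.na(si_b)]
  alpha <- (1 - ci) / 2
  ci_v <- if (length(si_ok) < 2) c(NA_real_, NA_real_)
          else unname(quantile(si_ok, c(alpha, 1 - alpha)))
  reliable <- unname(quantile(tot, 0.05)) > spont_expect &&
    length(si_ok) == n_resamples
  list(si = si, ci = ci_v, reliable = reliable, n_resamples = n_resamples)
}
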