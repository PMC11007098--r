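#' Trial simulation specification
#'
#' Conditions for generating trial-like individual patient data with known
#' ground truth: a generating survival distribution, sample size, uniform
#' accrual over an accrual window with administrative censoring at the end
#' of follow-up, and an optional independent exponential censoring process.
#'
#' @param model Generating [parametric_survival()].
#' @param n Number of patients (`>= 10`).
#' @param accrual_months Uniform accrual window (months); a patient entering
#'   at time `a` is administratively censored `accrual_months + followup_months - a`
#'   months after entry.
#' @param followup_months Follow-up beyond the end of accrual (months).
#' @param dropout_rate Rate (per month) of an independent exponential
#'   dropout-censoring process; 0 disables it.
#' @param seed Integer seed used by [simulate_ipd()].
#' @return Object of class `trial_sim_spec`.
#' @export
trial_sim_spec <- function(model, n = 250L,
                           accrual_months = 24,
                           followup_months = 60,
                           dropout_rate = 0,
                           seed = 1L) {
  stopifnot_model(model)
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  if (accrual_months < 0 || followup_months < 0) {
    stop("accrual and follow-up windows must be non-negative", call. = FALSE)
  }
  structure(list(model = model, n = as.integer(n),
                 accrual_months = accrual_months,
                 followup_months = followup_months,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "trial_sim_spec")
}

#' Simulate trial-like individual patient data
#'
#' Event times are drawn from the generating distribution by inverse
#' transform; each patient's censoring time is the minimum of the
#' administrative cutoff implied by their accrual time and, when enabled, an
#' independent exponential dropout draw. Reproducible under the spec's seed.
#'
#' @param spec A [trial_sim_spec()].
#' @return A [pseudo_ipd()].
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n
  x <- quantile_at(spec$model, stats::runif(n))
  entry <- stats::runif(n, 0, spec$accrual_months)
  cens <- spec$accrual_months + spec$followup_months - entry
  if (spec$dropout_rate > 0) {
    cens <- pmin(cens, stats::rexp(n, spec$dropout_rate))
  }
  cens <- pmax(cens, 1e-9)
  time <- pmin(x, cens)
  pseudo_ipd(time, as.integer(x <= cens))
}

#' Emulate graph-digitizer output from individual patient data
#'
#' Computes the Kaplan-Meier step curve of the data, samples it at its step
#' points, optionally perturbs the survival ordinates with truncated Gaussian
#' jitter (re-monotonized, clipped to `[0, 1]`, origin pinned at 1) to mimic
#' manual digitization error, and tabulates exact at-risk counts at the
#' requested times.
#'
#' @param ipd A [pseudo_ipd()].
#' @param risk_times Sorted times (months) for the numbers-at-risk table.
#' @param jitter Standard deviation of the digitization noise on the
#'   survival scale; 0 returns the exact step curve.
#' @return A [digitized_curve()].
#' @export
digitize <- function(ipd, risk_times = NULL, jitter = 0) {
  km <- km_estimator(ipd, risk_times)
  if (jitter > 0) {
    s <- km$points$survival
    noise <- stats::rnorm(length(s) - 1, 0, jitter)
    noise <- pmin(pmax(noise, -3 * jitter), 3 * jitter)
    s[-1] <- pmin(pmax(s[-1] + noise, 0), 1)
    km$points$survival <- cummin(s)
  }
  km
}
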