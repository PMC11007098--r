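#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the valuation with each uncertain parameter at its low and high
#' bound in turn, all others held at baseline, and ranks parameters by the
#' absolute ICER spread. The survival curves are not varied, so the cohort
#' traces are computed once and reused, except that varying the discount
#' rate re-discounts the accrual streams.
#'
#' @inheritParams run_base_case
#' @param table Uncertain-parameter table; see [parameter_table()].
#' @return `data.frame` sorted by decreasing `spread` with columns
#'   `parameter`, `low`, `high`, `icer_at_low`, `icer_at_high`, `spread`.
#' @export
one_way_tornado <- function(params = default_parameters(),
                            spec = model_spec(),
                            life_table = default_life_table(),
                            table = parameter_table(params)) {
  traces <- build_traces(params, spec, life_table)
  icer_with <- function(name, value) {
    p <- set_parameter(params, name, value)
    s <- if (name == "discount_rate") {
      sp <- spec; sp$annual_discount_rate <- value; sp
    } else spec
    evaluate_arms(traces, p, s)$icer
  }
  lo <- mapply(icer_with, table$parameter, table$low)
  hi <- mapply(icer_with, table$parameter, table$high)
  out <- data.frame(parameter = table$parameter,
                    low = table$low, high = table$high,
                    icer_at_low = lo, icer_at_high = hi,
                    spread = abs(hi - lo))
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  out
}

# Moment-matched sampling distributions. Every distribution is matched to
# mean = baseline with the parameter's (low, high) range read as its central
# 95% interval, sd = (high - low) / (2 * 1.96) -- one convention across
# gamma, beta and normal draws. Beta-moment infeasibility (sd too large for
# the unit interval) is a configuration error raised when the sampler is
# built, not at draw time.
.psa_sampler <- function(row) {
  m <- row$baseline
  sd <- (row$high - row$low) / (2 * stats::qnorm(0.975))
  switch(row$distribution,
    gamma = {
      shape <- (m / sd)^2
      function(n) stats::rgamma(n, shape = shape, scale = m / shape)
    },
    beta = {
      v <- sd^2
      if (v >= m * (1 - m)) {
        stop(sprintf("beta moments infeasible for '%s' (mean %.3f, sd %.3f)",
                     row$parameter, m, sd), call. = FALSE)
      }
      k <- m * (1 - m) / v - 1
      function(n) stats::rbeta(n, shape1 = m * k, shape2 = (1 - m) * k)
    },
    normal = function(n) stats::rnorm(n, mean = m, sd = sd),
    stop("no sampler for distribution: ", row$distribution, call. = FALSE)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo resampling of the uncertain parameters: unit costs from gamma
#' distributions, utilities and subsequent-therapy proportions from beta
#' distributions, body surface area from a normal distribution -- each
#' moment-matched to mean = baseline with the parameter's range read as its
#' central 95% interval -- while the discount rate and survival parameters
#' are held fixed. Each draw re-values both arms on the fixed cohort
#' traces. Reproducible for a fixed seed.
#'
#' @inheritParams one_way_tornado
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @param sd_scale Multiplier on every sampled parameter's dispersion; 0
#'   collapses all distributions to their baselines (degenerate draws).
#' @return `data.frame` with one row per draw: the drawn parameter values,
#'   `delta_cost` and `delta_qalys`.
#' @export
run_psa <- function(params = default_parameters(),
                    spec = model_spec(),
                    life_table = default_life_table(),
                    n_draws = 1000L,
                    seed = 20240328L,
                    sd_scale = 1) {
  table <- parameter_table(params)
  table <- table[table$sampled, ]
  traces <- build_traces(params, spec, life_table)
  set.seed(seed)
  draws <- as.data.frame(lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    if (sd_scale == 0) return(rep(row$baseline, n_draws))
    x <- .psa_sampler(row)(n_draws)
    if (sd_scale != 1) x <- row$baseline + sd_scale * (x - row$baseline)
    x
  }))
  names(draws) <- table$parameter
  res <- vapply(seq_len(n_draws), function(i) {
    p <- params
    for (nm in names(draws)) p <- set_parameter(p, nm, draws[[nm]][i])
    ev <- evaluate_arms(traces, p, spec)
    c(ev$delta_cost, ev$delta_qalys)
  }, numeric(2))
  draws$delta_cost <- res[1, ]
  draws$delta_qalys <- res[2, ]
  draws
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive net monetary benefit,
#' `wtp * delta_qalys - delta_cost > 0`, at each willingness-to-pay value.
#'
#' @param samples PSA draws from [run_psa()] (needs `delta_cost`,
#'   `delta_qalys`).
#' @param wtp_grid Vector of willingness-to-pay values (USD/QALY).
#' @return `data.frame(wtp, probability_cost_effective)`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 400000, by = 10000)) {
  if (nrow(samples) == 0L) stop("no PSA samples", call. = FALSE)
  prob <- vapply(wtp_grid, function(w) {
    mean(w * samples$delta_qalys - samples$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = prob)
}

#' Threshold-price search for the active drug
#'
#' Bisects the daily 80 mg drug price until the base-case ICER equals the
#' willingness-to-pay threshold, all other inputs at baseline. Requires the
#' threshold to be bracketed: ICER at price zero below `wtp`, baseline ICER
#' above it.
#'
#' @inheritParams one_way_tornado
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param rel_tol Relative tolerance on `|ICER - wtp| / wtp`.
#' @return Price in USD per daily 80 mg dose.
#' @export
threshold_price <- function(params = default_parameters(),
                            spec = model_spec(),
                            life_table = default_life_table(),
                            wtp = 150000,
                            rel_tol = 1e-6) {
  traces <- build_traces(params, spec, life_table)
  icer_at <- function(price) {
    evaluate_arms(traces, set_parameter(params, "cost_osimertinib", price), spec)$icer
  }
  p0 <- 0
  p1 <- get_parameter(params, "cost_osimertinib")
  i0 <- icer_at(p0); i1 <- icer_at(p1)
  if (is.na(i0)) i0 <- -Inf  # dominant at price zero: below any threshold
  if (is.na(i1) || i0 >= wtp || i1 < wtp) {
    stop(sprintf(
      "threshold not bracketed: ICER is %.2f at price 0 and %.2f at baseline price",
      i0, i1), call. = FALSE)
  }
  repeat {
    mid <- (p0 + p1) / 2
    im <- icer_at(mid)
    if (abs(im - wtp) / wtp < rel_tol) return(mid)
    if (im < wtp) p0 <- mid else p1 <- mid
    if ((p1 - p0) < 1e-10 * max(1, p1)) return(mid)
  }
}

#' Sensitivity-analysis plots
#'
#' Standard displays of the sensitivity analyses: a tornado diagram of ICER
#' ranges, the PSA incremental cost-effectiveness scatter with the
#' willingness-to-pay line, and the acceptability curve. Requires ggplot2.
#'
#' @param tornado Output of [one_way_tornado()].
#' @param base_icer Base-case ICER (vertical reference).
#' @param n_top Number of parameters displayed.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, base_icer, n_top = 10) {
  .need_ggplot()
  df <- utils::head(tornado, n_top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = pmin(icer_at_low, icer_at_high),
      xend = pmax(icer_at_low, icer_at_high),
      y = parameter, yend = parameter), linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL)
}

#' @rdname plot_tornado
#' @param samples PSA draws from [run_psa()].
#' @param wtp Willingness-to-pay threshold drawn as a line through the origin.
#' @export
plot_psa_scatter <- function(samples, wtp = 150000) {
  .need_ggplot()
  ggplot2::ggplot(samples, ggplot2::aes(delta_qalys, delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)")
}

#' @rdname plot_tornado
#' @param curve Output of [ceac()].
#' @export
plot_ceac <- function(curve) {
  .need_ggplot()
  ggplot2::ggplot(curve, ggplot2::aes(wtp, probability_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective")
}

utils::globalVariables(c("icer_at_low", "icer_at_high", "parameter",
                         "delta_qalys", "delta_cost", "wtp",
                         "probability_cost_effective"))

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
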