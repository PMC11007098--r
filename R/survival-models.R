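#' Parametric survival distributions for extrapolation
#'
#' Constructs a parametric time-to-event distribution of one of the seven
#' candidate families used for survival extrapolation. Time is measured in
#' months throughout the package. The generalized gamma uses the Prentice
#' `(mu, sigma, Q)` parameterization, under which `Q -> 0` recovers the
#' log-normal and `Q = 1` the Weibull; this is the convention in which fitted
#' triplets are conventionally reported in survival-extrapolation work.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gamma"`, `"gengamma"`,
#'   `"lognormal"`, `"loglogistic"`, `"gompertz"`.
#' @param ... Named numeric parameters of the family:
#'   \describe{
#'     \item{exponential}{`rate > 0`}
#'     \item{weibull}{`shape > 0`, `scale > 0`}
#'     \item{gamma}{`shape > 0`, `rate > 0`}
#'     \item{gengamma}{`mu`, `sigma > 0`, `Q` (any real)}
#'     \item{lognormal}{`meanlog`, `sdlog > 0`}
#'     \item{loglogistic}{`shape > 0`, `scale > 0` (the scale is the median)}
#'     \item{gompertz}{`shape` (any real), `rate > 0`}
#'   }
#' @return An object of class `parametric_survival`.
#' @examples
#' m <- parametric_survival("loglogistic", shape = 1.63351, scale = 112.73457)
#' survival_at(m, 112.73457)  # 0.5: the scale parameter is the median
#' @export
parametric_survival <- function(family, ...) {
  family <- match.arg(family, names(.sv_families))
  params <- c(...)
  info <- .sv_families[[family]]
  missing <- setdiff(info$pars, names(params))
  if (length(missing) > 0L) {
    stop(sprintf("family '%s' requires parameter(s): %s",
                 family, paste(missing, collapse = ", ")), call. = FALSE)
  }
  params <- params[info$pars]
  bad <- info$positive[!vapply(info$positive, function(p) params[[p]] > 0, logical(1))]
  if (length(bad) > 0L) {
    stop(sprintf("family '%s': parameter(s) %s must be strictly positive",
                 family, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(family = family, params = params, time_unit = "months"),
            class = "parametric_survival")
}

# Family dispatch table: parameter names, positivity constraints, and the
# p/d/q functions (flexsurv supplies llogis, gengamma and gompertz).
.sv_families <- list(
  exponential = list(
    pars = "rate", positive = "rate",
    p = function(q, p, ...) stats::pexp(q, p[["rate"]], ...),
    d = function(x, p, ...) stats::dexp(x, p[["rate"]], ...),
    q = function(u, p, ...) stats::qexp(u, p[["rate"]], ...)),
  weibull = list(
    pars = c("shape", "scale"), positive = c("shape", "scale"),
    p = function(q, p, ...) stats::pweibull(q, p[["shape"]], p[["scale"]], ...),
    d = function(x, p, ...) stats::dweibull(x, p[["shape"]], p[["scale"]], ...),
    q = function(u, p, ...) stats::qweibull(u, p[["shape"]], p[["scale"]], ...)),
  gamma = list(
    pars = c("shape", "rate"), positive = c("shape", "rate"),
    p = function(q, p, ...) stats::pgamma(q, p[["shape"]], p[["rate"]], ...),
    d = function(x, p, ...) stats::dgamma(x, p[["shape"]], p[["rate"]], ...),
    q = function(u, p, ...) stats::qgamma(u, p[["shape"]], p[["rate"]], ...)),
  gengamma = list(
    pars = c("mu", "sigma", "Q"), positive = "sigma",
    p = function(q, p, ...) flexsurv::pgengamma(q, p[["mu"]], p[["sigma"]], Q = p[["Q"]], ...),
    d = function(x, p, ...) flexsurv::dgengamma(x, p[["mu"]], p[["sigma"]], Q = p[["Q"]], ...),
    q = function(u, p, ...) flexsurv::qgengamma(u, p[["mu"]], p[["sigma"]], Q = p[["Q"]], ...)),
  lognormal = list(
    pars = c("meanlog", "sdlog"), positive = "sdlog",
    p = function(q, p, ...) stats::plnorm(q, p[["meanlog"]], p[["sdlog"]], ...),
    d = function(x, p, ...) stats::dlnorm(x, p[["meanlog"]], p[["sdlog"]], ...),
    q = function(u, p, ...) stats::qlnorm(u, p[["meanlog"]], p[["sdlog"]], ...)),
  loglogistic = list(
    pars = c("shape", "scale"), positive = c("shape", "scale"),
    p = function(q, p, ...) flexsurv::pllogis(q, p[["shape"]], scale = p[["scale"]], ...),
    d = function(x, p, ...) flexsurv::dllogis(x, p[["shape"]], scale = p[["scale"]], ...),
    q = function(u, p, ...) flexsurv::qllogis(u, p[["shape"]], scale = p[["scale"]], ...)),
  gompertz = list(
    pars = c("shape", "rate"), positive = "rate",
    p = function(q, p, ...) flexsurv::pgompertz(q, p[["shape"]], p[["rate"]], ...),
    d = function(x, p, ...) flexsurv::dgompertz(x, p[["shape"]], p[["rate"]], ...),
    q = function(u, p, ...) flexsurv::qgompertz(u, p[["shape"]], p[["rate"]], ...))
)

#' Supported survival families
#' @return Character vector of the seven family names.
#' @export
survival_families <- function() names(.sv_families)

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("<parametric_survival> %s (time in %s)\n", x$family, x$time_unit))
  cat(paste(sprintf("  %s = %g", names(x$params), x$params), collapse = "\n"), "\n")
  invisible(x)
}

stopifnot_model <- function(model) {
  if (!inherits(model, "parametric_survival")) {
    stop("expected a 'parametric_survival' object", call. = FALSE)
  }
}

#' Survival function S(t)
#'
#' @param model A [parametric_survival()] object.
#' @param t Vector of non-negative times (months).
#' @return `P(T > t)` for each element of `t`.
#' @export
survival_at <- function(model, t) {
  stopifnot_model(model)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  .sv_families[[model$family]]$p(t, model$params, lower.tail = FALSE)
}

#' Density f(t)
#' @inheritParams survival_at
#' @return Density at each element of `t`.
#' @export
density_at <- function(model, t) {
  stopifnot_model(model)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  .sv_families[[model$family]]$d(t, model$params)
}

#' Quantile function (inverse survival)
#' @inheritParams survival_at
#' @param p Vector of probabilities; returns `t` with `P(T <= t) = p`.
#' @return Quantiles in months.
#' @export
quantile_at <- function(model, p) {
  stopifnot_model(model)
  .sv_families[[model$family]]$q(p, model$params)
}

#' Conditional per-cycle event probability
#'
#' Probability that the event occurs during cycle `k` given it had not
#' occurred by the start of the cycle: `1 - S(k * delta) / S((k-1) * delta)`.
#' For the exponential family this is constant in `k` (memorylessness).
#'
#' When survival at the start of the cycle has been numerically exhausted the
#' conditional probability is undefined; an error of class
#' `"exhausted_survival"` is signalled so the cohort engine can treat the
#' state as emptied.
#'
#' @inheritParams survival_at
#' @param cycle_index Integer cycle index, `k >= 1`.
#' @param cycle_length Cycle length in months.
#' @return Conditional event probability in `[0, 1]`.
#' @export
interval_event_prob <- function(model, cycle_index, cycle_length) {
  stopifnot_model(model)
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1", call. = FALSE)
  if (cycle_length <= 0) stop("cycle_length must be positive", call. = FALSE)
  s0 <- survival_at(model, (cycle_index - 1) * cycle_length)
  s1 <- survival_at(model, cycle_index * cycle_length)
  if (any(s0 <= .Machine$double.xmin)) {
    stop(structure(class = c("exhausted_survival", "error", "condition"),
                   list(message = "survival exhausted at start of cycle",
                        call = sys.call(-1))))
  }
  pmin(pmax(1 - s1 / s0, 0), 1)
}

#' Median survival time
#'
#' Closed-form where the family admits one (exponential, Weibull, log-normal,
#' log-logistic), otherwise through the family's quantile function.
#'
#' @inheritParams survival_at
#' @return Time `t` (months) with `S(t) = 0.5`.
#' @export
median_survival <- function(model) {
  stopifnot_model(model)
  p <- model$params
  switch(model$family,
    exponential = log(2) / p[["rate"]],
    weibull     = p[["scale"]] * log(2)^(1 / p[["shape"]]),
    lognormal   = exp(p[["meanlog"]]),
    loglogistic = p[["scale"]],
    quantile_at(model, 0.5)
  )
}

#' Base-case fitted survival curves
#'
#' The four fitted disease-free survival (DFS) and overall survival (OS)
#' curves of the base case, one per arm and endpoint: log-logistic DFS and
#' generalized-gamma OS for the osimertinib arm; generalized-gamma DFS and
#' log-normal OS for the placebo arm. Parameters are read from the supplied
#' registry (defaulting to the shipped base-case values, time in months).
#'
#' @param params Parameter registry, see [default_parameters()].
#' @return Named list with elements `dfs_active`, `dfs_control`, `os_active`,
#'   `os_control`, each a [parametric_survival()].
#' @export
base_case_survival <- function(params = default_parameters()) {
  sv <- params$survival
  needed <- c("dfs_active", "dfs_control", "os_active", "os_control")
  missing <- setdiff(needed, names(sv))
  if (length(missing) > 0L) {
    stop("parameter registry lacks survival curve(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(sv[needed], function(s) {
    do.call(parametric_survival, c(list(family = s$family),
                                   s[setdiff(names(s), "family")]))
  })
}
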