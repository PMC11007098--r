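#' Maximum-likelihood fit of one survival family
#'
#' Fits a parametric family to right-censored pseudo individual-patient data
#' by maximizing the censored log-likelihood (events contribute `log f(t)`,
#' censored records `log S(t)`). Fitting is delegated to
#' `flexsurv::flexsurvreg`; the generalized gamma additionally tries starting
#' values derived from log-normal (`Q = 0`) and Weibull (`Q = 1`) fits and
#' keeps the best optimum, which stabilizes an otherwise fragile surface.
#'
#' @param ipd A [pseudo_ipd()]: at least 10 records with at least 3 events.
#' @param family One of [survival_families()].
#' @return Object of class `fit_result`: list with `model`
#'   ([parametric_survival()] at the MLE, `NULL` on failure), `loglik`,
#'   `aic` (`2k - 2 loglik`), `bic` (`k log n - 2 loglik`), `n`, `k`,
#'   `converged` and `message`.
#' @export
fit_family <- function(ipd, family) {
  family <- match.arg(family, survival_families())
  if (nrow(ipd) < 10 || sum(ipd$event) < 3) {
    stop("need at least 10 records with at least 3 events", call. = FALSE)
  }
  dist <- c(exponential = "exp", weibull = "weibull", gamma = "gamma",
            gengamma = "gengamma", lognormal = "lnorm",
            loglogistic = "llogis", gompertz = "gompertz")[[family]]
  dat <- as.data.frame(ipd)

  try_fit <- function(inits = NULL) {
    args <- list(survival::Surv(time, event) ~ 1, data = dat, dist = dist)
    if (!is.null(inits)) args$inits <- inits
    tryCatch(suppressWarnings(do.call(flexsurv::flexsurvreg, args)),
             error = function(e) e)
  }
  fits <- list(try_fit())
  if (family == "gengamma") {
    ln <- try_fit_quiet(dat, "lnorm")
    wb <- try_fit_quiet(dat, "weibull")
    if (!is.null(ln)) fits <- c(fits, list(try_fit(c(ln[1], ln[2], 0))))
    if (!is.null(wb)) {
      fits <- c(fits, list(try_fit(c(log(wb[["scale"]]), 1 / wb[["shape"]], 1))))
    }
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) {
    msgs <- vapply(fits, conditionMessage, character(1))
    return(structure(list(model = NULL, family = family, loglik = NA_real_,
                          aic = NA_real_, bic = NA_real_, n = nrow(dat),
                          k = NA_integer_, converged = FALSE,
                          message = paste(unique(msgs), collapse = "; ")),
                     class = "fit_result"))
  }
  fit <- fits[ok][[which.max(vapply(fits[ok], function(f) f$loglik, numeric(1)))]]
  est <- fit$res[, "est"]
  pars <- as.list(est)
  names(pars) <- .flexsurv_par_map[[family]]
  model <- do.call(parametric_survival, c(list(family = family), pars))
  k <- fit$npars
  structure(list(model = model, family = family, loglik = fit$loglik,
                 aic = 2 * k - 2 * fit$loglik,
                 bic = k * log(fit$N) - 2 * fit$loglik,
                 n = fit$N, k = k,
                 converged = isTRUE(fit$opt$convergence == 0),
                 message = "ok"),
            class = "fit_result")
}

try_fit_quiet <- function(dat, dist) {
  f <- tryCatch(
    suppressWarnings(flexsurv::flexsurvreg(
      survival::Surv(time, event) ~ 1, data = dat, dist = dist)),
    error = function(e) NULL)
  if (is.null(f)) NULL else f$res[, "est"]
}

.flexsurv_par_map <- list(
  exponential = "rate", weibull = c("shape", "scale"),
  gamma = c("shape", "rate"), gengamma = c("mu", "sigma", "Q"),
  lognormal = c("meanlog", "sdlog"), loglogistic = c("shape", "scale"),
  gompertz = c("shape", "rate"))

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: loglik %.3f, AIC %.2f, BIC %.2f, n %d%s\n",
              x$family, x$loglik, x$aic, x$bic, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Fit all candidate families
#'
#' @inheritParams fit_family
#' @param families Families to fit (default: all seven).
#' @return Named list of `fit_result` objects.
#' @export
fit_all_families <- function(ipd, families = survival_families()) {
  stats::setNames(lapply(families, function(f) fit_family(ipd, f)), families)
}

#' Select the best fit by information criterion
#'
#' Returns the converged fit minimizing the criterion; ties (within 1e-9)
#' are broken by fewer free parameters, then by family name order.
#'
#' @param fits List of `fit_result` objects.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @return The selected `fit_result`.
#' @export
select_best <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0L) stop("no converged fits", call. = FALSE)
  crit <- vapply(fits, function(f) f[[criterion]], numeric(1))
  ks <- vapply(fits, function(f) f$k, integer(1))
  fam <- vapply(fits, function(f) f$family, character(1))
  fits[[order(round(crit / 1e-9) * 1e-9, ks, fam)[1]]]
}

#' Tabulate fit results
#'
#' @param fits List of `fit_result` objects (see [fit_all_families()]).
#' @return `data.frame` with family, parameter estimates (as a
#'   comma-separated string), log-likelihood, AIC, BIC and convergence flag.
#' @export
fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      family = f$family,
      parameters = if (is.null(f$model)) NA_character_ else {
        paste(sprintf("%s=%.5f", names(f$model$params), f$model$params),
              collapse = ", ")
      },
      loglik = f$loglik, aic = f$aic, bic = f$bic, n = f$n,
      converged = f$converged, row.names = NULL)
  }))
}
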