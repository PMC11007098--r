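#' Digitized Kaplan-Meier curve with numbers at risk
#'
#' Container for step-curve coordinates read off a published Kaplan-Meier
#' plot together with its numbers-at-risk table, the input to pseudo
#' individual-patient-data reconstruction.
#'
#' @param points `data.frame(time, survival)`: the step-curve coordinates in
#'   months, starting at `(0, 1)` (a missing origin is prepended).
#' @param risk_table `data.frame(time, n_risk)`: numbers at risk at selected
#'   times; at least two rows, non-increasing counts.
#' @return Object of class `digitized_curve`.
#' @export
digitized_curve <- function(points, risk_table) {
  stopifnot(all(c("time", "survival") %in% names(points)),
            all(c("time", "n_risk") %in% names(risk_table)))
  points <- points[order(points$time), c("time", "survival")]
  risk_table <- risk_table[order(risk_table$time), c("time", "n_risk")]
  if (nrow(points) == 0L || points$time[1] > 0) {
    points <- rbind(data.frame(time = 0, survival = 1), points)
  }
  if (abs(points$survival[1] - 1) > 1e-9) {
    stop("curve must start at survival 1 at time 0", call. = FALSE)
  }
  if (any(points$survival < -1e-9 | points$survival > 1 + 1e-9)) {
    stop("survival values must lie in [0, 1]", call. = FALSE)
  }
  rises <- which(diff(points$survival) > 1e-9)
  if (length(rises) > 0L) {
    stop(sprintf("survival rises between digitized points %d and %d (t = %g to %g)",
                 rises[1], rises[1] + 1,
                 points$time[rises[1]], points$time[rises[1] + 1]), call. = FALSE)
  }
  if (nrow(risk_table) < 2L) stop("risk table needs at least 2 rows", call. = FALSE)
  if (any(diff(risk_table$n_risk) > 0)) {
    stop("numbers at risk must be non-increasing", call. = FALSE)
  }
  if (any(risk_table$n_risk < 0) || any(risk_table$n_risk != round(risk_table$n_risk))) {
    stop("numbers at risk must be non-negative integers", call. = FALSE)
  }
  structure(list(points = points, risk_table = risk_table),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %d step points over [0, %g] months, n0 = %d\n",
              nrow(x$points), max(x$points$time, x$risk_table$time),
              x$risk_table$n_risk[1]))
  invisible(x)
}

#' Pseudo individual-patient data
#'
#' @param time Positive event/censoring times (months).
#' @param event 1 for an event, 0 for censoring.
#' @return `data.frame(time, event)` of class `pseudo_ipd`.
#' @export
pseudo_ipd <- function(time, event) {
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  structure(data.frame(time = time, event = as.integer(event)),
            class = c("pseudo_ipd", "data.frame"))
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Interval-allocation reconstruction in the spirit of the published
#' algorithms for regenerating patient-level data from digitized
#' Kaplan-Meier curves and at-risk tables. Within each interval between
#' consecutive risk-table times, integer event counts at the digitized step
#' times and a censoring count are chosen iteratively so that (a) the
#' product-limit estimate recomputed from the output tracks the digitized
#' survival and (b) the at-risk count at the next risk-table time is matched
#' exactly; censoring times are spread uniformly within the interval. Events
#' precede censorings at tied times. After the last risk-table time, events
#' are allocated at the remaining step points and all remaining subjects are
#' censored at the observation-window end.
#'
#' @param curve A [digitized_curve()].
#' @return A [pseudo_ipd()] with exactly `risk_table$n_risk[1]` records.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  pts <- curve$points
  rt <- curve$risk_table
  t_end <- max(pts$time, rt$time)
  times <- numeric(0); events <- integer(0)

  s_run <- 1        # reconstructed survival entering the interval
  n_run <- rt$n_risk[1]
  ivals <- rbind(
    data.frame(lo = rt$time[-nrow(rt)], hi = rt$time[-1],
               n_lo = rt$n_risk[-nrow(rt)], n_hi = rt$n_risk[-1]),
    data.frame(lo = rt$time[nrow(rt)], hi = t_end,
               n_lo = rt$n_risk[nrow(rt)], n_hi = NA)
  )
  for (iv in seq_len(nrow(ivals))) {
    lo <- ivals$lo[iv]; hi <- ivals$hi[iv]
    n_start <- n_run
    if (!is.na(ivals$n_hi[iv]) && ivals$n_hi[iv] > n_start) {
      stop(sprintf(
        "interval %d (t in [%g, %g]): at-risk count %d exceeds the %d survivors of the prior interval",
        iv, lo, hi, ivals$n_hi[iv], n_start), call. = FALSE)
    }
    last <- iv == nrow(ivals)
    sel <- pts$time > lo & pts$time <= hi & pts$survival < s_run - 1e-12
    st <- pts$time[sel]; sv <- pts$survival[sel]
    m <- length(st)

    alloc <- function(n_cens) {
      # censor times spread uniformly over the interval
      ct <- if (n_cens > 0) lo + seq_len(n_cens) * (hi - lo) / (n_cens + 1) else numeric(0)
      n <- n_start; s <- s_run
      d <- integer(m)
      if (m > 0) for (k in seq_len(m)) {
        n_k <- n - sum(ct < st[k])          # censors before this step left the risk set
        d[k] <- if (s > 0 && n_k > 0) round(n_k * min(max(1 - sv[k] / s, 0), 1)) else 0
        d[k] <- min(d[k], n_k)
        if (n_k > 0 && d[k] > 0) s <- s * (1 - d[k] / n_k)
        n <- n - d[k]
      }
      list(d = d, ct = ct, s = s, n_left = n_start - sum(d) - n_cens)
    }

    if (last) {
      a <- alloc(0L)
      d <- a$d; s_run <- a$s
      # everyone still at risk is administratively censored at the window end
      n_cens <- n_start - sum(d)
      ct <- rep(max(hi, lo), n_cens)
      if (n_cens > 0 && max(hi, lo) <= lo) ct <- rep(lo + 1e-9, n_cens)
    } else {
      n_cens <- max(0L, n_start - ivals$n_hi[iv])
      for (it in 1:50) {
        a <- alloc(n_cens)
        new_cens <- n_start - sum(a$d) - ivals$n_hi[iv]
        if (new_cens < 0) {
          stop(sprintf(
            "interval %d (t in (%g, %g]): digitized drops require more exits than the risk table allows",
            iv, lo, hi), call. = FALSE)
        }
        if (new_cens == n_cens) break
        n_cens <- new_cens
      }
      d <- a$d; ct <- a$ct; s_run <- a$s
      n_run <- ivals$n_hi[iv]
    }
    times <- c(times, rep(st, d), ct)
    events <- c(events, rep(1L, sum(d)), rep(0L, length(ct)))
  }
  ord <- order(times, -events)  # events precede censorings at ties
  pseudo_ipd(times[ord], events[ord])
}

#' Kaplan-Meier estimate of pseudo individual-patient data
#'
#' Standard product-limit estimate (via `survival::survfit`), returned as a
#' [digitized_curve()] with step points at the event times and at-risk counts
#' at caller-specified times.
#'
#' @param ipd A [pseudo_ipd()] (or any `data.frame(time, event)`).
#' @param risk_times Times at which to tabulate numbers at risk; defaults to
#'   time 0 and the last observation.
#' @return A [digitized_curve()].
#' @export
km_estimator <- function(ipd, risk_times = NULL) {
  if (nrow(ipd) == 0L) stop("no records", call. = FALSE)
  if (is.null(risk_times)) risk_times <- c(0, max(ipd$time))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  keep <- fit$n.event > 0
  points <- data.frame(time = c(0, fit$time[keep]), survival = c(1, fit$surv[keep]))
  n_risk <- vapply(risk_times, function(tt) sum(ipd$time >= tt), numeric(1))
  digitized_curve(points, data.frame(time = risk_times, n_risk = n_risk))
}

#' Evaluate a digitized step curve at arbitrary times
#'
#' Right-continuous step interpolation of the curve's survival values.
#'
#' @param curve A [digitized_curve()].
#' @param t Times (months).
#' @return Survival values.
#' @export
curve_survival <- function(curve, t) {
  stats::stepfun(curve$points$time[-1], curve$points$survival)(t)
}

#' Read / write digitized curves and pseudo-IPD as CSV
#'
#' A digitized curve is stored as a pair of CSVs: step points
#' (`time, survival`) and risk table (`time, n_risk`); pseudo-IPD as a single
#' CSV (`time, event`).
#'
#' @param points_path,risk_path,path CSV file paths.
#' @param curve,ipd Objects to write.
#' @return Readers return the object; writers return their path(s), invisibly.
#' @export
read_digitized_curve <- function(points_path, risk_path) {
  digitized_curve(utils::read.csv(points_path), utils::read.csv(risk_path))
}

#' @rdname read_digitized_curve
#' @export
write_digitized_curve <- function(curve, points_path, risk_path) {
  utils::write.csv(curve$points, points_path, row.names = FALSE)
  utils::write.csv(curve$risk_table, risk_path, row.names = FALSE)
  invisible(c(points_path, risk_path))
}

#' @rdname read_digitized_curve
#' @export
read_ipd <- function(path) {
  df <- utils::read.csv(path)
  pseudo_ipd(df$time, df$event)
}

#' @rdname read_digitized_curve
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(as.data.frame(ipd), path, row.names = FALSE)
  invisible(path)
}
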