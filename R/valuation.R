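#' Disease-management monitoring schedule
#'
#' Assessment calendar used for cost accrual. While disease-free, tumour
#' imaging, laboratory testing and a physician visit occur at weeks 12 and 24
#' (cycles 4 and 8 under 3-week cycles), then every 24 weeks (8 cycles)
#' through year 5, then annually (every 17 cycles). In the recurrence state,
#' administration, laboratory testing and a physician visit accrue every
#' cycle and imaging every `imaging_interval` cycles.
#'
#' @param spec A [model_spec()].
#' @param first_cycles Cycles of the initial assessments.
#' @param q24_interval,q24_through Interval (cycles) and last cycle of the
#'   24-weekly phase.
#' @param annual_interval Interval (cycles) of the annual phase.
#' @param imaging_interval Recurrence-state imaging interval in cycles.
#' @return Object of class `monitoring_schedule` with the DFS assessment
#'   cycles and the recurrence imaging interval.
#' @export
monitoring_schedule <- function(spec = model_spec(),
                                first_cycles = c(4L, 8L),
                                q24_interval = 8L,
                                q24_through = 87L,
                                annual_interval = 17L,
                                imaging_interval = 2L) {
  n <- spec$n_cycles
  seq_safe <- function(from, to, by) if (from > to) integer(0) else seq(from, to, by = by)
  q24 <- seq_safe(first_cycles[length(first_cycles)] + q24_interval, q24_through,
                  q24_interval)
  annual <- seq_safe(max(c(first_cycles, q24)) + annual_interval, n, annual_interval)
  cyc <- sort(unique(c(first_cycles, q24, annual)))
  cyc <- cyc[cyc >= 1 & cyc <= n]
  structure(list(dfs_assessment_cycles = as.integer(cyc),
                 imaging_interval = as.integer(imaging_interval)),
            class = "monitoring_schedule")
}

# Ceiling-rounded billing units (10 mg) for a body-surface-area scaled dose.
.dose_units_10mg <- function(dose_mg_m2, bsa) ceiling(dose_mg_m2 * bsa / 10)

#' Accrue discounted costs and QALYs for one arm
#'
#' Walks a [run_cohort()] trace cycle by cycle, valuing state occupancy with
#' the half-cycle-corrected occupancies of the trace's specification.
#'
#' QALYs: `(u_dfs * dfs + u_rec * recurrence) * cycle-length-in-years`,
#' discounted at the end-of-cycle factor.
#'
#' Costs per cycle:
#' \itemize{
#'   \item Active arm only: daily osimertinib price x 21 days x DFS
#'     occupancy, while the cycle is within the treatment cap.
#'   \item DFS monitoring (imaging + laboratory + physician visit) x DFS
#'     occupancy at scheduled assessment cycles.
#'   \item Recurrence, subsequent-therapy fraction: pemetrexed every cycle;
#'     cisplatin added for the induction phase, costed on cohort fractions
#'     newly entered within the last `induction_cycles` cycles (entrants are
#'     approximated by DFS exits); doses are BSA-scaled and rounded up to
#'     10 mg units. An optional maintenance cap stops pemetrexed after the
#'     configured number of cycles since model entry.
#'   \item Recurrence, remaining fraction: best-supportive-care cost every
#'     cycle.
#'   \item Recurrence, all patients: administration + laboratory + physician
#'     visit every cycle, imaging every second cycle.
#'   \item Terminal care: one-time cost x incident deaths in the cycle of
#'     death.
#' }
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param spec The [model_spec()] used to build the trace.
#' @param params Parameter registry (costs, utilities, patient, treatment
#'   sections are used); see [default_parameters()].
#' @param schedule A [monitoring_schedule()].
#' @param arm `"active"` (osimertinib) or `"control"` (placebo).
#' @return Object of class `arm_result`: list with `total_cost`,
#'   `total_qalys`, a per-cycle `cycles` data frame (`cycle`, `cost`,
#'   `qalys`, both discounted) and a named `components` cost breakdown.
#' @export
accrue_arm <- function(trace, spec, params = default_parameters(),
                       schedule = monitoring_schedule(spec),
                       arm = c("active", "control")) {
  arm <- match.arg(arm)
  stopifnot(inherits(trace, "cohort_trace"), inherits(spec, "model_spec"))
  n <- spec$n_cycles
  if (nrow(trace) != n + 1L) {
    stop("trace horizon does not match the model specification", call. = FALSE)
  }
  if (max(schedule$dfs_assessment_cycles) > n) {
    stop("monitoring schedule extends beyond the model horizon", call. = FALSE)
  }
  co <- params$costs; ut <- params$utilities; tr <- params$treatment
  bsa <- params$patient$body_surface_area

  disc <- discount_factor(spec, 1:n)
  dfs_m <- .accrual_occupancy(trace, spec, "dfs")
  rec_m <- .accrual_occupancy(trace, spec, "recurrence")
  inc_death <- trace$incident_deaths[2:(n + 1)]

  qalys <- (ut$dfs * dfs_m + ut$recurrence * rec_m) * spec$cycle_length_years * disc

  # drug acquisition, active arm, within the treatment cap
  on_tx <- as.numeric(seq_len(n) <= spec$treatment_cap_cycles)
  drug <- if (arm == "active") {
    co$osimertinib_80mg_day * spec$cycle_length_days * dfs_m * on_tx
  } else numeric(n)

  # scheduled DFS assessments
  mon_unit <- co$imaging_event + co$laboratory_event + co$physician_visit
  mon <- numeric(n)
  mon[schedule$dfs_assessment_cycles] <- mon_unit * dfs_m[schedule$dfs_assessment_cycles]

  # subsequent therapy in recurrence
  frac <- if (arm == "active") tr$subsequent_fraction_active else tr$subsequent_fraction_control
  pem_cost <- .dose_units_10mg(tr$pemetrexed_dose_mg_m2, bsa) * co$pemetrexed_10mg
  cis_cost <- .dose_units_10mg(tr$cisplatin_dose_mg_m2, bsa) * co$cisplatin_10mg
  entrants <- pmax(0, -diff(trace$dfs))
  ind_win <- max(1L, as.integer(tr$induction_cycles))
  cs <- cumsum(entrants)
  roll <- cs - c(rep(0, ind_win), cs)[seq_len(n)]  # entrants in the last ind_win cycles
  induction_mass <- pmin(roll, rec_m)
  pem_on <- as.numeric(seq_len(n) <= tr$maintenance_cap_cycles)
  chemo <- frac * (pem_cost * rec_m * pem_on + cis_cost * induction_mass)
  bsc <- (1 - frac) * co$bsc_cycle * rec_m

  # recurrence-state disease management
  mgmt_unit <- co$administration_cycle + co$laboratory_event + co$physician_visit
  imaging_on <- as.numeric(seq_len(n) %% schedule$imaging_interval == 0)
  mgmt <- (mgmt_unit + co$imaging_event * imaging_on) * rec_m

  terminal <- co$terminal_care * inc_death

  undisc <- cbind(drug = drug, monitoring = mon, chemotherapy = chemo,
                  bsc = bsc, management = mgmt, terminal = terminal)
  cost_cycle <- rowSums(undisc) * disc

  structure(list(
    arm = arm,
    total_cost = sum(cost_cycle),
    total_qalys = sum(qalys),
    cycles = data.frame(cycle = 1:n, cost = cost_cycle, qalys = qalys),
    components = colSums(undisc * disc)
  ), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s arm: cost $%s, %.4f QALYs (discounted)\n",
              x$arm, format(round(x$total_cost, 2), big.mark = ","), x$total_qalys))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' @param active,control [accrue_arm()] results for the compared strategies.
#' @param tol Absolute tolerance below which a delta is treated as zero for
#'   classification.
#' @return List with `delta_cost`, `delta_qalys`, `icer` and
#'   `classification`: `"ratio"` when incremental QALYs are positive (and
#'   `"dominant"` when additionally cheaper), `"equivalent"` when both deltas
#'   vanish, `"dominated"` when the active strategy is costlier and no more
#'   effective, `"less_effective_cheaper"` otherwise (no ratio reported in
#'   the non-positive-QALY cases).
#' @export
compute_icer <- function(active, control, tol = 1e-9) {
  dc <- active$total_cost - control$total_cost
  dq <- active$total_qalys - control$total_qalys
  if (abs(dc) <= tol && abs(dq) <= tol) {
    cls <- "equivalent"; icer <- NA_real_
  } else if (dq > tol) {
    icer <- dc / dq
    cls <- if (dc < -tol) "dominant" else "ratio"
  } else {
    icer <- NA_real_
    cls <- if (dc > tol) "dominated" else "less_effective_cheaper"
  }
  list(delta_cost = dc, delta_qalys = dq, icer = icer, classification = cls)
}
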