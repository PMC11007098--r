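#' Run the base-case cost-effectiveness comparison
#'
#' Builds both arms' cohort traces from the registry's survival curves,
#' accrues discounted costs and QALYs, and forms the incremental summary.
#'
#' @param params Parameter registry; see [default_parameters()].
#' @param spec Model specification; see [model_spec()].
#' @param life_table Background-mortality table; see [default_life_table()].
#' @param schedule Monitoring schedule; see [monitoring_schedule()].
#' @return Object of class `cea_result`: list with `active` and `control`
#'   [accrue_arm()] results, `delta_cost`, `delta_qalys`, `icer`,
#'   `classification`, and the inputs used.
#' @examples
#' res <- run_base_case()
#' res$icer
#' @export
run_base_case <- function(params = default_parameters(),
                          spec = model_spec(),
                          life_table = default_life_table(),
                          schedule = monitoring_schedule(spec)) {
  .validate_params(params)
  traces <- build_traces(params, spec, life_table)
  evaluate_arms(traces, params, spec, schedule)
}

#' Build both arms' cohort traces
#'
#' The traces depend only on the survival curves, the model specification and
#' the life table -- not on costs or utilities -- so sensitivity analyses over
#' economic parameters reuse them unchanged.
#'
#' @inheritParams run_base_case
#' @return List with `cohort_trace` elements `active` and `control`.
#' @export
build_traces <- function(params, spec = model_spec(),
                         life_table = default_life_table()) {
  curves <- base_case_survival(params)
  list(active = run_cohort(spec, curves$dfs_active, curves$os_active, life_table),
       control = run_cohort(spec, curves$dfs_control, curves$os_control, life_table))
}

#' Value a pair of traces under a parameter registry
#'
#' @param traces Output of [build_traces()].
#' @inheritParams run_base_case
#' @return A `cea_result`, as for [run_base_case()].
#' @export
evaluate_arms <- function(traces, params, spec = model_spec(),
                          schedule = monitoring_schedule(spec)) {
  active <- accrue_arm(traces$active, spec, params, schedule, arm = "active")
  control <- accrue_arm(traces$control, spec, params, schedule, arm = "control")
  inc <- compute_icer(active, control)
  structure(c(list(active = active, control = control), inc,
              list(params = params, spec = spec)),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  fmt <- function(v) format(round(v), big.mark = ",", scientific = FALSE)
  cat("Cost-effectiveness summary (discounted)\n")
  cat(sprintf("  %-12s cost $%11s   QALYs %6.2f\n", "control:",
              fmt(x$control$total_cost), x$control$total_qalys))
  cat(sprintf("  %-12s cost $%11s   QALYs %6.2f\n", "active:",
              fmt(x$active$total_cost), x$active$total_qalys))
  cat(sprintf("  incremental: cost $%11s   QALYs %6.2f\n",
              fmt(x$delta_cost), x$delta_qalys))
  if (x$classification %in% c("ratio", "dominant")) {
    cat(sprintf("  ICER: $%s per QALY\n", format(round(x$icer, 2), big.mark = ",")))
  } else {
    cat(sprintf("  ICER: not reported (%s)\n", x$classification))
  }
  invisible(x)
}

#' Run the full analysis and write a report bundle
#'
#' Base case, one-way tornado, probabilistic sensitivity analysis,
#' cost-effectiveness acceptability curve and threshold-price search, written
#' as CSV/JSON files plus a run manifest (input digest, seed, package
#' version). Reruns with an identical configuration produce identical files.
#'
#' @inheritParams run_base_case
#' @param out_dir Output directory (created if needed).
#' @param n_draws Number of PSA draws.
#' @param seed Integer seed for the PSA.
#' @param wtp Willingness-to-pay threshold (USD/QALY) for the threshold-price
#'   search and CEAC annotation.
#' @param wtp_grid CEAC willingness-to-pay grid.
#' @return Invisibly, a list with all computed objects and `manifest`.
#' @export
run_full_report <- function(out_dir,
                            params = default_parameters(),
                            spec = model_spec(),
                            life_table = default_life_table(),
                            n_draws = 1000L,
                            seed = 20240328L,
                            wtp = params$wtp %||% 150000,
                            wtp_grid = seq(0, 400000, by = 10000)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- run_base_case(params, spec, life_table)
  tornado <- one_way_tornado(params, spec, life_table)
  psa <- run_psa(params, spec, life_table, n_draws = n_draws, seed = seed)
  acc <- ceac(psa, wtp_grid)
  thr <- tryCatch(threshold_price(params, spec, life_table, wtp = wtp),
                  error = function(e) {
                    message("threshold-price search skipped: ", conditionMessage(e))
                    NA_real_
                  })

  manifest <- list(
    package = "osimCEA",
    version = as.character(utils::packageVersion("osimCEA")),
    seed = seed, n_draws = n_draws, wtp = wtp,
    engine = spec$engine,
    inputs_digest = .digest_inputs(params, spec)
  )

  summary_df <- data.frame(
    arm = c("control", "active"),
    cost = c(base$control$total_cost, base$active$total_cost),
    qalys = c(base$control$total_qalys, base$active$total_qalys),
    delta_cost = c(NA, base$delta_cost),
    delta_qalys = c(NA, base$delta_qalys),
    icer = c(NA, base$icer)
  )
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# manifest: %s", manifest$inputs_digest), con)
    utils::write.csv(df, con, row.names = FALSE)
    path
  }
  wr(summary_df, "base_case.csv")
  wr(tornado, "tornado.csv")
  wr(data.frame(draw = seq_len(nrow(psa)), psa), "psa_samples.csv")
  wr(acc, "ceac.csv")
  jsonlite::write_json(
    c(manifest, list(threshold_price = thr,
                     base_case = summary_df[2, c("delta_cost", "delta_qalys", "icer")])),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(list(base = base, tornado = tornado, psa = psa, ceac = acc,
                 threshold = thr, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic digest of the run configuration: md5 of its serialized YAML.
.digest_inputs <- function(params, spec) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(list(params = rapply(params, unclass, how = "replace"),
                        spec = unclass(spec)), tmp)
  unname(tools::md5sum(tmp))
}
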