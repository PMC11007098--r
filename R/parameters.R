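#' Base-case parameter registry
#'
#' All model inputs of the base case as a nested list: fitted survival
#' parameters (time in months), per-year health-state utilities, 2023 USD
#' unit costs, patient characteristics, subsequent-treatment structure and
#' the annual discount rate. The same document, serialized as YAML, ships in
#' `inst/extdata/base_case_parameters.yaml` and can be round-tripped with
#' [read_parameters()] / [write_parameters()].
#'
#' Unit-cost semantics: `osimertinib_80mg_day` is the price of one daily
#' 80 mg dose; `pemetrexed_10mg` and `cisplatin_10mg` are prices per 10 mg
#' billing unit (doses are body-surface-area scaled and rounded up to whole
#' units); `*_event` costs accrue per scheduled assessment;
#' `administration_cycle` and `bsc_cycle` accrue per 3-week cycle in the
#' recurrence state; `terminal_care` is a one-time cost at death.
#'
#' @return Nested named list of parameters.
#' @export
default_parameters <- function() {
  list(
    survival = list(
      dfs_active  = list(family = "loglogistic", shape = 1.63351, scale = 112.73457),
      dfs_control = list(family = "gengamma", mu = 2.88767, sigma = 1.45261, Q = -1.30760),
      os_active   = list(family = "gengamma", mu = 4.36038, sigma = 1.26750, Q = -3.13596),
      os_control  = list(family = "lognormal", meanlog = 4.83614, sdlog = 1.01581)
    ),
    utilities = list(dfs = 0.83, recurrence = 0.74, death = 0),
    costs = list(
      osimertinib_80mg_day = 566.64,
      pemetrexed_10mg      = 7.51,
      cisplatin_10mg       = 3.17,
      administration_cycle = 155.09,
      imaging_event        = 249.48,
      laboratory_event     = 340.20,
      terminal_care        = 10187.64,
      physician_visit      = 160.20,
      bsc_cycle            = 481.57
    ),
    patient = list(body_surface_area = 1.82, start_age = 63),
    treatment = list(
      subsequent_fraction_active  = 0.671,
      subsequent_fraction_control = 0.663,
      pemetrexed_dose_mg_m2 = 500,
      cisplatin_dose_mg_m2  = 75,
      induction_cycles      = 4,
      maintenance_cap_cycles = Inf
    ),
    discount = list(annual_rate = 0.03),
    wtp = 150000
  )
}

# Accessor map between flat sensitivity-analysis parameter names and their
# position in the nested registry.
.param_paths <- list(
  utility_dfs                 = c("utilities", "dfs"),
  utility_recurrence          = c("utilities", "recurrence"),
  cost_osimertinib            = c("costs", "osimertinib_80mg_day"),
  cost_pemetrexed             = c("costs", "pemetrexed_10mg"),
  cost_cisplatin              = c("costs", "cisplatin_10mg"),
  cost_administration         = c("costs", "administration_cycle"),
  cost_imaging                = c("costs", "imaging_event"),
  cost_laboratory             = c("costs", "laboratory_event"),
  cost_terminal_care          = c("costs", "terminal_care"),
  cost_physician_visit        = c("costs", "physician_visit"),
  cost_bsc                    = c("costs", "bsc_cycle"),
  body_surface_area           = c("patient", "body_surface_area"),
  subsequent_fraction_active  = c("treatment", "subsequent_fraction_active"),
  subsequent_fraction_control = c("treatment", "subsequent_fraction_control"),
  discount_rate               = c("discount", "annual_rate")
)

#' Get or set a sensitivity-analysis parameter by flat name
#'
#' @param params Parameter registry.
#' @param name One of the names in `parameter_table()$parameter`.
#' @param value Replacement value (for `set_parameter`).
#' @return `get_parameter`: the numeric value; `set_parameter`: the modified
#'   registry.
#' @export
set_parameter <- function(params, name, value) {
  path <- .param_paths[[name]]
  if (is.null(path)) stop("unknown parameter: ", name, call. = FALSE)
  params[[path[1]]][[path[2]]] <- value
  params
}

#' @rdname set_parameter
#' @export
get_parameter <- function(params, name) {
  path <- .param_paths[[name]]
  if (is.null(path)) stop("unknown parameter: ", name, call. = FALSE)
  params[[path[1]]][[path[2]]]
}

#' Uncertain-parameter table for sensitivity analysis
#'
#' One row per parameter varied in the one-way and probabilistic sensitivity
#' analyses: baseline value, low/high bounds and sampling distribution.
#' Utilities and drug/management unit costs carry the explicit bounds of the
#' base-case registry (plus/minus 20% of baseline); subsequent-therapy
#' proportions use plus/minus 20%; the discount rate spans 0 to 5% and is
#' held fixed in the probabilistic analysis. Costs sample from gamma
#' distributions, utilities and proportions from beta distributions, body
#' surface area from a normal distribution.
#'
#' @param params Parameter registry, see [default_parameters()].
#' @return `data.frame` with columns `parameter`, `baseline`, `low`, `high`,
#'   `distribution`, `sampled` (logical: drawn in PSA).
#' @export
parameter_table <- function(params = default_parameters()) {
  base <- vapply(names(.param_paths), function(nm) get_parameter(params, nm),
                 numeric(1))
  tab <- data.frame(
    parameter = names(.param_paths),
    baseline = unname(base),
    stringsAsFactors = FALSE
  )
  # Explicit bounds where the base case states them; +/-20% elsewhere.
  explicit <- list(
    utility_dfs = c(0.67, 0.99),
    utility_recurrence = c(0.59, 0.89),
    cost_osimertinib = c(453.31, 679.97),
    cost_pemetrexed = c(6.01, 9.01),
    cost_cisplatin = c(2.54, 3.80),
    cost_administration = c(124.07, 186.11),
    cost_imaging = c(199.58, 299.38),
    cost_laboratory = c(272.16, 408.24),
    cost_terminal_care = c(8150.11, 12225.17),
    cost_physician_visit = c(128.16, 192.24),
    cost_bsc = c(385.26, 577.88),
    body_surface_area = c(1.46, 2.18),
    discount_rate = c(0, 0.05)
  )
  bounds <- t(vapply(tab$parameter, function(nm) {
    if (!is.null(explicit[[nm]])) explicit[[nm]]
    else get_parameter(params, nm) * c(0.8, 1.2)
  }, numeric(2)))
  tab$low <- bounds[, 1]
  tab$high <- bounds[, 2]
  tab$distribution <- ifelse(
    grepl("^cost_", tab$parameter), "gamma",
    ifelse(grepl("^utility_|^subsequent_", tab$parameter), "beta",
           ifelse(tab$parameter == "body_surface_area", "normal", "fixed")))
  tab$sampled <- tab$distribution != "fixed"
  tab
}

.validate_params <- function(params) {
  stopifnot(is.list(params))
  needed <- c("survival", "utilities", "costs", "patient", "treatment", "discount")
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0L) {
    stop("parameter document lacks section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("dfs_active", "dfs_control", "os_active", "os_control")) {
    s <- params$survival[[nm]]
    if (is.null(s$family) || !s$family %in% survival_families()) {
      stop("survival curve '", nm, "' has a missing or unknown family", call. = FALSE)
    }
    # constructor errors on incomplete or invalid parameters
    do.call(parametric_survival,
            c(list(family = s$family), s[setdiff(names(s), "family")]))
  }
  u <- params$utilities
  if (any(unlist(u) < 0 | unlist(u) > 1)) stop("utilities must lie in [0, 1]", call. = FALSE)
  if (u$dfs <= u$recurrence) stop("utility of DFS must exceed recurrence utility", call. = FALSE)
  if (any(unlist(params$costs) < 0)) stop("unit costs must be non-negative", call. = FALSE)
  fr <- params$treatment[c("subsequent_fraction_active", "subsequent_fraction_control")]
  if (any(unlist(fr) < 0 | unlist(fr) > 1)) {
    stop("subsequent-therapy fractions must lie in [0, 1]", call. = FALSE)
  }
  invisible(params)
}

#' Read / write the parameter registry as YAML
#'
#' @param path File path of a YAML parameter document.
#' @param params Parameter registry to serialize.
#' @return `read_parameters`: the validated registry; `write_parameters`:
#'   `path`, invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path, call. = FALSE)
  params <- yaml::read_yaml(path)
  # YAML has no native Inf; the maintenance cap may arrive as ".inf" or NULL
  cap <- params$treatment$maintenance_cap_cycles
  if (is.null(cap) || (is.character(cap) && grepl("inf", cap, ignore.case = TRUE))) {
    params$treatment$maintenance_cap_cycles <- Inf
  }
  .validate_params(params)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  .validate_params(params)
  p <- params
  if (is.infinite(p$treatment$maintenance_cap_cycles)) {
    p$treatment$maintenance_cap_cycles <- ".inf"
  }
  yaml::write_yaml(p, path)
  invisible(path)
}
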