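#' Abridged background-mortality life table (synthetic stand-in)
#'
#' An abridged all-cause period life table mapping single years of age to
#' annual death probabilities, used as a floor on the modelled death hazard
#' so that extrapolated overall survival never implies mortality below that
#' of the general population. The bundled table is a synthetic stand-in:
#' ages 60-100 with probabilities Gompertz-smoothed to track the magnitude
#' of recent U.S. period life tables (about 1.2% at age 63 rising to about
#' 15% at age 90). Within the model's horizon (cohort ages 63 to 78.8) the
#' floor almost never binds, so results are insensitive to its exact values.
#'
#' @return `data.frame` with columns `age` (years) and `qx` (annual death
#'   probability).
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "life_table_synthetic.csv", package = "osimCEA")
  if (!nzchar(path)) stop("bundled life table not found", call. = FALSE)
  read_life_table(path)
}

#' Read a life table from CSV
#'
#' @param path CSV with columns `age`, `qx`.
#' @return Validated `data.frame(age, qx)`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  .validate_life_table(lt)
}

.validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns 'age' and 'qx'", call. = FALSE)
  }
  lt <- lt[order(lt$age), c("age", "qx")]
  if (any(lt$qx <= 0 | lt$qx >= 1)) {
    stop("life-table death probabilities must lie in (0, 1)", call. = FALSE)
  }
  if (any(diff(lt$age) <= 0)) stop("life-table ages must be strictly increasing", call. = FALSE)
  lt
}

# Annual death probability at a (possibly fractional) age; age is floored to
# the last tabulated year at or below it. Errors if outside table coverage.
.lt_annual_q <- function(lt, age) {
  i <- findInterval(age, lt$age)
  if (any(i == 0L) || any(age > max(lt$age) + 1)) {
    stop(sprintf("life table does not cover age range [%.1f, %.1f]",
                 min(age), max(age)), call. = FALSE)
  }
  lt$qx[pmin(i, nrow(lt))]
}

# Convert an annual death probability to a per-cycle probability over
# cycle_years, assuming a constant hazard within the year.
.per_cycle_q <- function(q_annual, cycle_years) {
  1 - (1 - q_annual)^cycle_years
}
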