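# Shared fixtures built in code.

# Life table with negligible background mortality, for closed-form checks.
null_life_table <- function(q = 1e-12) {
  data.frame(age = 0:120, qx = q)
}

# Registry with every unit cost zeroed (utility accrual only).
zero_cost_params <- function(params = default_parameters()) {
  params$costs[] <- lapply(params$costs, function(x) 0)
  params
}

base_curves <- base_case_survival(default_parameters())

# Small deterministic pseudo-IPD used across KM tests.
hand_ipd <- function() {
  pseudo_ipd(time = c(1, 2, 3, 4, 5), event = c(1, 0, 1, 0, 1))
}
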