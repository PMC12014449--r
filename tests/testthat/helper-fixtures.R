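# Shared fixtures: small deterministic assay/scenario builders.

make_assay <- function(c_iv = 10, c_av = 9.93, v_iv = 5e-4, t_s = 8.56,
                       m_s = 1e-4, food = "chili", roast_day = 0,
                       teer_ok = TRUE, assay_id = "a1") {
  transport_assay(assay_id, food, roast_day, c_iv = c_iv, c_av = c_av,
                  v_iv = v_iv, t_s = t_s, m_s = m_s, teer_ok = teer_ok)
}

# assay engineered to return exactly `rba` through the depletion formula
assay_for_rba <- function(rba, t_s = 8.56, c_iv = 10, v_iv = 5e-4,
                          m_s = 1e-4, ...) {
  make_assay(c_iv = c_iv, c_av = c_iv - rba * t_s * m_s / v_iv,
             v_iv = v_iv, t_s = t_s, m_s = m_s, ...)
}

point_dist <- function(value) {
  fitted_distribution("normal", c(location = value, scale = 0))
}

degenerate_scenario <- function(c_value, ir_value, group = "children",
                                food = "corn", params = NULL) {
  if (is.null(params)) params <- population_parameters(group, food)
  scenario_spec(food, 30, group, point_dist(c_value), point_dist(ir_value),
                params)
}

# true parameter sets used in recovery tests, one per family
recovery_truths <- list(
  normal     = c(location = 5, scale = 2),
  lognormal  = c(meanlog = -3.5, sdlog = 0.5),
  logistic   = c(location = 0.01, scale = 0.004),
  gumbel_max = c(location = 10, scale = 2),
  weibull    = c(shape = 1.5, scale = 0.07))
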