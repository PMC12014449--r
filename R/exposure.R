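# Deterministic EPA-style risk arithmetic.
#
#   ADD = C * IR * EF * ED / (BW * AT)     average daily dose, mg/kg/d
#   HQ  = ADD / RfD                        hazard quotient
#   HI  = sum of HQ over co-consumed foods
#   IR_Max = HQ_target * RfD * BW * AT / (C_eff * EF * ED)
#
# With EF = 365 d/a and AT = ED * 365 d the dose reduces to C * IR / BW.
# The RBA-corrected intake limit replaces the total concentration C by the
# bioavailable concentration C * RBA.

#' Population exposure parameters
#'
#' Constants of the average-daily-dose model for one population group and
#' one food. `at` defaults to `ed * 365` (chronic non-carcinogenic
#' convention) and the fluoride oral reference dose defaults to
#' 0.06 mg/kg/d.
#'
#' @param ir oral intake of the food, kg/d (`>= 0`).
#' @param bw body weight, kg.
#' @param ed exposure duration, years.
#' @param ef exposure frequency, d/year.
#' @param at averaging time, days.
#' @param rfd oral reference dose, mg/kg/d.
#' @param group label (`"children"`, `"adults"`, or custom).
#' @return A list of class `exposure_parameters`.
#' @export
exposure_parameters <- function(ir, bw, ed, ef = 365, at = ed * 365,
                                rfd = 0.06, group = "custom") {
  check_nonnegative(ir, "ir")
  check_positive(bw, "bw")
  check_positive(ed, "ed")
  check_positive(ef, "ef")
  check_positive(at, "at")
  check_positive(rfd, "rfd")
  structure(list(group = group, ir = ir, bw = bw, ef = ef, ed = ed,
                 at = at, rfd = rfd),
            class = "exposure_parameters")
}

# Survey constants for the two study populations: per-food daily intake
# (median and range, kg/d), body weight (kg), averaging time (d), exposure
# frequency (d/a) and duration (a).
POPULATION_DEFAULTS <- list(
  children = list(
    bw = 25.9, at = 3285, ef = 365, ed = 9, rfd = 0.06,
    ir = list(
      tofu  = c(median = 0.012, min = 0.000, max = 0.05),
      corn  = c(median = 0.010, min = 0.000, max = 0.08),
      pork  = c(median = 0.033, min = 0.004, max = 0.10),
      chili = c(median = 0.028, min = 0.002, max = 0.08))),
  adults = list(
    bw = 56.8, at = 25550, ef = 365, ed = 70, rfd = 0.06,
    ir = list(
      tofu  = c(median = 0.023, min = 0.000, max = 0.10),
      corn  = c(median = 0.021, min = 0.000, max = 0.17),
      pork  = c(median = 0.067, min = 0.008, max = 0.20),
      chili = c(median = 0.056, min = 0.004, max = 0.17))))

#' Default population exposure constants
#'
#' The dietary-survey constants used throughout: per-food intake medians and
#' ranges, body weight, averaging time, exposure frequency and duration for
#' children and adults, with the fluoride RfD of 0.06 mg/kg/d.
#'
#' @return Nested list keyed by group (`children`, `adults`).
#' @export
default_population_config <- function() POPULATION_DEFAULTS

#' Exposure parameters for a study population and food
#'
#' Convenience constructor pulling [default_population_config()] values.
#'
#' @param group `"children"` or `"adults"`.
#' @param food one of `"tofu"`, `"corn"`, `"pork"`, `"chili"`.
#' @param statistic which intake statistic to use as `ir`.
#' @param config population config (defaults to the built-in constants).
#' @return An [exposure_parameters()] object.
#' @export
population_parameters <- function(group = c("children", "adults"),
                                  food = c("tofu", "corn", "pork", "chili"),
                                  statistic = c("median", "min", "max"),
                                  config = default_population_config()) {
  group <- match.arg(group, names(config))
  food <- match.arg(food, names(config[[group]]$ir))
  statistic <- match.arg(statistic)
  g <- config[[group]]
  exposure_parameters(ir = unname(g$ir[[food]][[statistic]]), bw = g$bw,
                      ed = g$ed, ef = g$ef, at = g$at, rfd = g$rfd,
                      group = group)
}

#' Average daily dose
#'
#' @param c fluoride concentration in the food, mg/kg.
#' @param params an [exposure_parameters()] object.
#' @return ADD in mg/kg/d.
#' @export
average_daily_dose <- function(c, params) {
  check_nonnegative(c, "c")
  stopifnot(inherits(params, "exposure_parameters"))
  c * params$ir * params$ef * params$ed / (params$bw * params$at)
}

#' Hazard quotient
#'
#' @param add average daily dose, mg/kg/d.
#' @param rfd oral reference dose, mg/kg/d.
#' @return HQ (dimensionless) with attribute `at_risk` (`HQ >= 1`).
#' @export
hazard_quotient <- function(add, rfd = 0.06) {
  check_nonnegative(add, "add")
  check_positive(rfd, "rfd")
  hq <- add / rfd
  structure(hq, at_risk = hq >= 1)
}

#' Point hazard quotient for one food/stage/group
#'
#' @param c fluoride concentration, mg/kg (optionally already
#'   bioavailability-adjusted).
#' @param params an [exposure_parameters()] object.
#' @return HQ with attribute `at_risk`.
#' @export
point_hq <- function(c, params) {
  hazard_quotient(average_daily_dose(c, params), params$rfd)
}

#' Hazard index across co-consumed foods
#'
#' Sum of per-food hazard quotients sharing one population group and
#' roasting stage.
#'
#' @param hqs numeric vector of hazard quotients, or a data frame with
#'   columns `hq`, `group`, `roast_day` (mixed groups/stages are rejected).
#' @return HI with attribute `at_risk` (`HI > 1`).
#' @export
hazard_index <- function(hqs) {
  if (is.data.frame(hqs)) {
    if (length(unique(hqs$group)) > 1L || length(unique(hqs$roast_day)) > 1L) {
      stop("hazard_index requires a single group and roasting stage",
           call. = FALSE)
    }
    hqs <- hqs$hq
  }
  stopifnot(is.numeric(hqs), all(is.finite(hqs)), all(hqs >= 0))
  hi <- sum(hqs)
  structure(hi, at_risk = hi > 1)
}

#' Per-food contribution shares to the hazard index
#'
#' `share_i = HQ_i / HI`. The same arithmetic serves both weighting modes of
#' the study: pass HQs computed from total concentrations, or from absorbed
#' (bioavailability-adjusted) concentrations.
#'
#' @param hqs named numeric vector of non-negative per-food HQs (any
#'   HQ-proportional weight works, e.g. absorbed dose times intake).
#' @return Named fractions summing to 1.
#' @export
contribution_shares <- function(hqs) {
  stopifnot(is.numeric(hqs), all(is.finite(hqs)), all(hqs >= 0))
  hi <- sum(hqs)
  if (hi <= 0) stop("shares undefined: hazard index is zero", call. = FALSE)
  hqs / hi
}

#' Maximum allowable daily intake for a target hazard quotient
#'
#' Inverts the dose model at `HQ = hq_target`:
#' `IR_Max = hq_target * RfD * BW * AT / (C_eff * EF * ED)` with
#' `C_eff = c` (total concentration) or `c * rba` (bioavailable
#' concentration) when `rba` is supplied — the RBA-corrected limit.
#' Substituting the result back as the intake reproduces `hq_target`
#' exactly.
#'
#' @param c fluoride concentration, mg/kg (`> 0`).
#' @param params an [exposure_parameters()] object (its `ir` is ignored).
#' @param hq_target target hazard quotient (default 1, the just-at-risk
#'   threshold).
#' @param rba optional relative bioavailability fraction in `(0, 1]`.
#' @return Maximum intake, kg/d.
#' @export
ir_max <- function(c, params, hq_target = 1, rba = NULL) {
  check_positive(c, "c")
  check_positive(hq_target, "hq_target")
  stopifnot(inherits(params, "exposure_parameters"))
  c_eff <- c
  if (!is.null(rba)) {
    check_fraction(rba, "rba", open_left = TRUE)
    c_eff <- c * rba
  }
  hq_target * params$rfd * params$bw * params$at /
    (c_eff * params$ef * params$ed)
}
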