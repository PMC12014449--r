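# Seeded Monte Carlo propagation of concentration and intake uncertainty
# through the hazard-quotient model.
#
# Per iteration k:  HQ_k = C_k * IR_k * EF * ED / (BW * AT * RfD)
# with C_k and IR_k drawn independently from their fitted distributions by
# inverse-CDF sampling of a seeded uniform stream. One master seed spawns an
# independent substream per (food, roast_day, group, variable), so adding a
# scenario never perturbs another scenario's draws.

#' Monte Carlo simulation configuration
#'
#' @param seed master integer seed; required (no silent clock seeding).
#' @param n_iter number of iterations (study convention: 10,000).
#' @param truncate_negative clamp negative sampled concentrations/intakes to
#'   0? Default `FALSE`: the study's reported 5th percentiles are negative,
#'   so its simulation did not truncate.
#' @param percentiles summary percentiles as fractions in `(0, 1)`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_iter = 10000, truncate_negative = FALSE,
                              percentiles = c(0.05, 0.95)) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("an explicit integer 'seed' is required", call. = FALSE)
  }
  stopifnot(n_iter >= 1, all(percentiles > 0 & percentiles < 1),
            is.logical(truncate_negative))
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 truncate_negative = truncate_negative,
                 percentiles = sort(percentiles)),
            class = "simulation_config")
}

#' Monte Carlo scenario: one food, stage and population group
#'
#' @param food food name.
#' @param roast_day roasting day.
#' @param group population group label.
#' @param c_dist [fitted_distribution()] of the food fluoride concentration
#'   (normal from the stage replicates in the study design).
#' @param ir_dist [fitted_distribution()] of the population intake (the
#'   survey best-fit family).
#' @param params an [exposure_parameters()] object supplying EF, ED, BW, AT
#'   and RfD (its point `ir` is unused).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(food, roast_day, group, c_dist, ir_dist, params) {
  stopifnot(inherits(c_dist, "fitted_distribution"),
            inherits(ir_dist, "fitted_distribution"),
            inherits(params, "exposure_parameters"))
  structure(list(food = as.character(food), roast_day = as.integer(roast_day),
                 group = as.character(group), c_dist = c_dist,
                 ir_dist = ir_dist, params = params),
            class = "scenario_spec")
}

#' Draw from a fitted distribution by inverse-CDF sampling
#'
#' Applies the family quantile function to a seeded uniform stream;
#' identical seeds give identical draws. A zero scale parameter yields a
#' degenerate point mass.
#'
#' @param dist a [fitted_distribution()].
#' @param n number of draws.
#' @param seed integer seed for this stream.
#' @return Numeric vector of `n` draws.
#' @export
sample_family <- function(dist, n, seed) {
  stopifnot(inherits(dist, "fitted_distribution"), n >= 0)
  if (n == 0L) return(numeric(0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  family_quantile(u, dist$family, dist$params)
}

#' Linear-interpolation percentile
#'
#' The convention placing the k-th order statistic at probability
#' `(k - 1) / (n - 1)` ([stats::quantile()] type 7), fixed package-wide so
#' summaries are reproducible across tools.
#'
#' @param values non-empty numeric vector.
#' @param q probability in `(0, 1)` (vectorised).
#' @return Percentile value(s).
#' @export
percentile <- function(values, q) {
  if (length(values) == 0L) stop("empty vector", call. = FALSE)
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)", call. = FALSE)
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

scenario_hq_draws <- function(scenario, config) {
  key <- paste(scenario$food, scenario$roast_day, scenario$group, sep = "|")
  c_k <- sample_family(scenario$c_dist, config$n_iter,
                       derive_seed(config$seed, paste0(key, "|C")))
  ir_k <- sample_family(scenario$ir_dist, config$n_iter,
                        derive_seed(config$seed, paste0(key, "|IR")))
  if (config$truncate_negative) {
    c_k <- pmax(c_k, 0)
    ir_k <- pmax(ir_k, 0)
  }
  p <- scenario$params
  c_k * ir_k * p$ef * p$ed / (p$bw * p$at * p$rfd)
}

summarize_draws <- function(hq, scenario, config) {
  if (config$n_iter < 20L && length(config$percentiles) > 0L) {
    warning("fewer than 20 iterations: percentile estimates are unstable",
            call. = FALSE)
  }
  pct <- percentile(hq, config$percentiles)
  names(pct) <- paste0("p", sub("^0\\.", "", formatC(config$percentiles,
                                                     format = "fg")))
  structure(
    list(food = scenario$food, roast_day = scenario$roast_day,
         group = scenario$group, mean = mean(hq), percentiles = pct,
         p05 = if ("p05" %in% names(pct)) pct[["p05"]] else NA_real_,
         p95 = if ("p95" %in% names(pct)) pct[["p95"]] else NA_real_,
         prob_hq_above_1 = mean(hq > 1), n_iter = config$n_iter,
         seed = config$seed),
    class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf("<risk_summary> %s day %d (%s): mean %.3f [%s], Pr(>1) = %.3f (n = %d, seed %d)\n",
              x$food, x$roast_day, x$group, x$mean,
              paste(sprintf("%s = %.3f", names(x$percentiles), x$percentiles),
                    collapse = ", "),
              x$prob_hq_above_1, x$n_iter, x$seed))
  invisible(x)
}

#' Monte Carlo hazard-quotient simulation for one scenario
#'
#' Draws `n_iter` concentration/intake pairs and summarises the resulting
#' hazard-quotient distribution. With zero-variance (degenerate)
#' distributions the summary collapses to the deterministic point estimate.
#'
#' @param scenario a [scenario_spec()].
#' @param config a [simulation_config()].
#' @return A `risk_summary`: mean, requested percentiles (`p05`/`p95`
#'   surfaced directly), `prob_hq_above_1`, `n_iter` and `seed`.
#' @export
simulate_hq <- function(scenario, config) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(config, "simulation_config"))
  summarize_draws(scenario_hq_draws(scenario, config), scenario, config)
}

#' Monte Carlo hazard-index simulation across foods
#'
#' Per iteration, sums independent per-food hazard-quotient draws (each food
#' keeps its own substream, so single-food results match [simulate_hq()]).
#' All scenarios must share one group and roasting stage.
#'
#' @param scenarios list of [scenario_spec()] objects, one per food.
#' @param config a [simulation_config()].
#' @return A `risk_summary` with `food = "ALL"`.
#' @export
simulate_hi <- function(scenarios, config) {
  stopifnot(length(scenarios) >= 1L,
            all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
  groups <- unique(vapply(scenarios, `[[`, character(1), "group"))
  days <- unique(vapply(scenarios, `[[`, integer(1), "roast_day"))
  if (length(groups) > 1L || length(days) > 1L) {
    stop("all scenarios must share one group and one roasting stage",
         call. = FALSE)
  }
  hi <- Reduce(`+`, lapply(scenarios, scenario_hq_draws, config = config))
  template <- scenarios[[1L]]
  template$food <- "ALL"
  summarize_draws(hi, template, config)
}
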