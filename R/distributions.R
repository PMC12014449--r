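# Candidate distribution families and maximum-likelihood fitting.
#
# Five two-parameter families are supported, matching the candidate set used
# in probabilistic dietary exposure software: normal, lognormal, logistic,
# Gumbel-max (type-I extreme value, maximum convention) and Weibull.
# Parameterisations:
#   normal, logistic, gumbel_max : location, scale (scale > 0)
#   lognormal                    : meanlog, sdlog  (sdlog > 0)
#   weibull                      : shape, scale    (both > 0)

DIST_FAMILIES <- c("normal", "lognormal", "logistic", "gumbel_max", "weibull")

#' Supported distribution families
#'
#' @return Character vector of family names accepted throughout the package.
#' @export
dist_families <- function() DIST_FAMILIES

check_family <- function(family) {
  if (!is.character(family) || length(family) != 1L ||
      !family %in% DIST_FAMILIES) {
    stop("'family' must be one of: ", paste(DIST_FAMILIES, collapse = ", "),
         call. = FALSE)
  }
  family
}

#' Support of a distribution family
#'
#' @param family family name (see [dist_families()]).
#' @return `"positive"` for lognormal and Weibull, `"real"` otherwise.
#' @export
family_support <- function(family) {
  check_family(family)
  if (family %in% c("lognormal", "weibull")) "positive" else "real"
}

check_params <- function(family, params) {
  wanted <- switch(family,
    normal = , logistic = , gumbel_max = c("location", "scale"),
    lognormal = c("meanlog", "sdlog"),
    weibull = c("shape", "scale"))
  if (!is.numeric(params) || !all(wanted %in% names(params))) {
    stop(sprintf("family '%s' needs named parameters: %s", family,
                 paste(wanted, collapse = ", ")), call. = FALSE)
  }
  p <- params[wanted]
  if (any(!is.finite(p))) stop("distribution parameters must be finite", call. = FALSE)
  scale_par <- p[[2L]]
  if (scale_par < 0) stop("scale parameter must be non-negative", call. = FALSE)
  if (family == "weibull" && p[["shape"]] <= 0) {
    stop("weibull shape must be positive", call. = FALSE)
  }
  p
}

#' Cumulative distribution function of a supported family
#'
#' @param x numeric vector of evaluation points.
#' @param family family name.
#' @param params named parameter vector (see package-level parameterisations).
#' @return CDF values in `[0, 1]`.
#' @export
family_cdf <- function(x, family, params) {
  family <- check_family(family)
  p <- check_params(family, params)
  switch(family,
    normal     = stats::pnorm(x, p[["location"]], p[["scale"]]),
    lognormal  = stats::plnorm(x, p[["meanlog"]], p[["sdlog"]]),
    logistic   = stats::plogis(x, p[["location"]], p[["scale"]]),
    gumbel_max = exp(-exp(-(x - p[["location"]]) / p[["scale"]])),
    weibull    = stats::pweibull(x, p[["shape"]], p[["scale"]]))
}

#' Quantile function of a supported family
#'
#' A zero scale (`sdlog` for lognormal) is treated as a degenerate point
#' mass: every quantile equals the distribution's location (or `exp(meanlog)`
#' for lognormal, `scale` for Weibull, i.e. the zero-spread limit).
#'
#' @inheritParams family_cdf
#' @param q vector of probabilities in `(0, 1)`.
#' @return Quantiles.
#' @export
family_quantile <- function(q, family, params) {
  family <- check_family(family)
  p <- check_params(family, params)
  if (any(q <= 0 | q >= 1)) stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  scale_par <- p[[2L]]
  if (scale_par == 0) {
    point <- switch(family,
      normal = , logistic = , gumbel_max = p[["location"]],
      lognormal = exp(p[["meanlog"]]),
      weibull = p[["scale"]])
    return(rep(point, length(q)))
  }
  switch(family,
    normal     = stats::qnorm(q, p[["location"]], p[["scale"]]),
    lognormal  = stats::qlnorm(q, p[["meanlog"]], p[["sdlog"]]),
    logistic   = stats::qlogis(q, p[["location"]], p[["scale"]]),
    gumbel_max = p[["location"]] - p[["scale"]] * log(-log(q)),
    weibull    = stats::qweibull(q, p[["shape"]], p[["scale"]]))
}

#' Mean of a supported family
#'
#' Analytic expectation; used for Monte Carlo convergence diagnostics.
#'
#' @inheritParams family_cdf
#' @return The distribution mean.
#' @export
family_mean <- function(family, params) {
  family <- check_family(family)
  p <- check_params(family, params)
  euler_gamma <- 0.57721566490153286
  switch(family,
    normal     = p[["location"]],
    lognormal  = exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2),
    logistic   = p[["location"]],
    gumbel_max = p[["location"]] + euler_gamma * p[["scale"]],
    weibull    = p[["scale"]] * gamma(1 + 1 / p[["shape"]]))
}

family_logdens <- function(x, family, params) {
  p <- check_params(family, params)
  switch(family,
    normal     = stats::dnorm(x, p[["location"]], p[["scale"]], log = TRUE),
    lognormal  = stats::dlnorm(x, p[["meanlog"]], p[["sdlog"]], log = TRUE),
    logistic   = stats::dlogis(x, p[["location"]], p[["scale"]], log = TRUE),
    gumbel_max = {
      z <- (x - p[["location"]]) / p[["scale"]]
      -log(p[["scale"]]) - z - exp(-z)
    },
    weibull    = stats::dweibull(x, p[["shape"]], p[["scale"]], log = TRUE))
}

# method-of-moments starting values for the iterative families
mom_start <- function(x, family) {
  m <- mean(x); s <- stats::sd(x)
  switch(family,
    logistic = c(location = m, scale = s * sqrt(3) / pi),
    gumbel_max = {
      beta <- s * sqrt(6) / pi
      c(location = m - 0.57721566490153286 * beta, scale = beta)
    },
    weibull = {
      # Justus' closed-form shape approximation from the coefficient of variation
      k <- max((s / m)^(-1.086), 0.1)
      c(shape = k, scale = m / gamma(1 + 1 / k))
    })
}

#' Construct a fitted-distribution object
#'
#' @param family family name.
#' @param params named parameter vector.
#' @param n sample size the fit is based on (`NA` for externally specified
#'   distributions, e.g. degenerate point masses in Monte Carlo scenarios).
#' @param loglik maximised log-likelihood (`NA` if not applicable).
#' @param converged logical convergence flag.
#' @return An object of class `fitted_distribution`.
#' @export
fitted_distribution <- function(family, params, n = NA_integer_,
                                loglik = NA_real_, converged = TRUE) {
  family <- check_family(family)
  check_params(family, params)
  structure(
    list(family = family, params = params, n = n, loglik = loglik,
         converged = converged),
    class = "fitted_distribution")
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat(sprintf("<fitted_distribution> %s(%s)%s\n", x$family,
              paste(sprintf("%s = %.6g", names(x$params), x$params),
                    collapse = ", "),
              if (isTRUE(x$converged)) "" else "  [NOT converged]"))
  if (!is.na(x$n)) cat(sprintf("  n = %d, loglik = %.4f\n", x$n, x$loglik))
  invisible(x)
}

#' Fit a distribution family by maximum likelihood
#'
#' Normal and lognormal fits are closed-form (mean and population standard
#' deviation of the data or log-data). Logistic, Gumbel-max and Weibull fits
#' run Nelder-Mead on the negative log-likelihood from method-of-moments
#' starting values, restarting from the incumbent until the parameter vector
#' moves by less than `tol` between rounds (at most `max_iter` function-
#' evaluation iterations per round). Fitting is deterministic: no randomness
#' is used.
#'
#' Zeros are dropped (with a warning reporting the count) before fitting a
#' positive-support family; negative values there are an error.
#'
#' @param samples numeric vector, `length >= 3`, non-degenerate.
#' @param family family name (see [dist_families()]).
#' @param tol convergence tolerance on the maximum absolute parameter change.
#' @param max_iter iteration cap passed to the optimiser per round.
#' @return A [fitted_distribution()]; `converged` is `FALSE` (with a warning)
#'   if the tolerance was not reached.
#' @export
fit_mle <- function(samples, family, tol = 1e-8, max_iter = 200) {
  family <- check_family(family)
  x <- samples[!is.na(samples)]
  if (length(x) < 3L) stop("need at least 3 non-missing samples", call. = FALSE)
  if (family_support(family) == "positive") {
    if (any(x < 0)) {
      stop(sprintf("family '%s' requires non-negative samples", family),
           call. = FALSE)
    }
    nzero <- sum(x == 0)
    if (nzero > 0) {
      warning(sprintf("dropped %d zero value(s) before fitting '%s'",
                      nzero, family), call. = FALSE)
      x <- x[x > 0]
      if (length(x) < 3L) stop("fewer than 3 positive samples remain", call. = FALSE)
    }
  }
  if (stats::sd(x) == 0) {
    stop("samples have zero variance; cannot fit a two-parameter family",
         call. = FALSE)
  }
  n <- length(x)

  if (family == "normal") {
    params <- c(location = mean(x), scale = sqrt(mean((x - mean(x))^2)))
    return(fitted_distribution(family, params, n,
                               sum(family_logdens(x, family, params)), TRUE))
  }
  if (family == "lognormal") {
    lx <- log(x)
    params <- c(meanlog = mean(lx), sdlog = sqrt(mean((lx - mean(lx))^2)))
    return(fitted_distribution(family, params, n,
                               sum(family_logdens(x, family, params)), TRUE))
  }

  # iterative families: optimise over unconstrained (location, log scale)
  # or (log shape, log scale)
  start <- mom_start(x, family)
  to_theta <- function(p) if (family == "weibull") log(p) else c(p[1L], log(p[2L]))
  from_theta <- function(th) {
    p <- if (family == "weibull") exp(th) else c(th[1L], exp(th[2L]))
    names(p) <- names(start)
    p
  }
  nll <- function(th) {
    v <- -sum(family_logdens(x, family, from_theta(th)))
    if (!is.finite(v)) 1e10 else v
  }
  theta <- to_theta(start)
  converged <- FALSE
  for (round in seq_len(25L)) {
    opt <- stats::optim(theta, nll, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-14))
    delta <- max(abs(from_theta(opt$par) - from_theta(theta)))
    theta <- opt$par
    if (round > 1L && delta < tol) { converged <- TRUE; break }
  }
  params <- from_theta(theta)
  if (!converged) {
    warning(sprintf("MLE for family '%s' did not reach tolerance %g",
                    family, tol), call. = FALSE)
  }
  fitted_distribution(family, params, n, -nll(theta), converged)
}

#' Anderson-Darling statistic against a fitted or specified CDF
#'
#' Computes the tail-weighted empirical-distribution-function discrepancy
#' \deqn{A^2 = -n - \frac{1}{n}\sum_{i=1}^{n}(2i-1)\left[\ln u_{(i)} +
#'   \ln(1 - u_{(n+1-i)})\right]}
#' where \eqn{u_{(i)}} are the sorted CDF values of the sample. CDF values of
#' exactly 0 or 1 are clipped to `[1e-12, 1 - 1e-12]` with a warning. Used
#' here as a ranking score among candidate families, not as a formal test
#' (critical values with estimated parameters are family-specific).
#'
#' @param samples numeric vector, `length >= 3`.
#' @param cdf either a [fitted_distribution()] or a vectorised CDF function.
#' @return The statistic \eqn{A^2} (non-negative up to numerical floor).
#' @export
anderson_darling_statistic <- function(samples, cdf) {
  x <- samples[!is.na(samples)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  F <- if (inherits(cdf, "fitted_distribution")) {
    function(v) family_cdf(v, cdf$family, cdf$params)
  } else if (is.function(cdf)) {
    cdf
  } else {
    stop("'cdf' must be a function or a fitted_distribution", call. = FALSE)
  }
  u <- sort(F(x))
  if (any(u <= 0 | u >= 1)) {
    warning("CDF values at 0 or 1 clipped to [1e-12, 1 - 1e-12]", call. = FALSE)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  }
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around [stats::shapiro.test()] (Royston's algorithm) that
#' records the method used; applied to stage-level concentration replicates
#' before they are summarised as normal in the simulation step.
#'
#' @param samples numeric vector with `3 <= n <= 5000`.
#' @return A list with `statistic` (W), `p_value`, `n` and `method`.
#' @export
normality_test <- function(samples) {
  x <- samples[!is.na(samples)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       n = length(x), method = "Shapiro-Wilk (Royston 1995 approximation)")
}

#' Fit candidate families and rank them by the Anderson-Darling statistic
#'
#' Each candidate is fitted by [fit_mle()]; families whose support excludes
#' the sample, or whose fit fails, are dropped with their reason recorded.
#' Survivors are ranked by ascending \eqn{A^2}; ties (difference below 1e-9)
#' are broken by higher log-likelihood, then alphabetically by family name.
#'
#' @param samples numeric vector.
#' @param candidates character vector of family names to try.
#' @return A list of class `distribution_ranking`: fitted candidates in rank
#'   order, each carrying `ad_stat` and `rank`; attribute `failures` maps
#'   failed family names to their error messages. The best fit is the first
#'   element.
#' @export
select_distribution <- function(samples, candidates = dist_families()) {
  stopifnot(length(candidates) >= 1L)
  fits <- list(); failures <- character()
  for (fam in candidates) {
    res <- tryCatch({
      f <- fit_mle(samples, fam)
      f$ad_stat <- anderson_darling_statistic(
        if (family_support(fam) == "positive") samples[samples > 0] else samples, f)
      f
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures[fam] <- res else fits[[fam]] <- res
  }
  if (length(fits) == 0L) {
    stop("no candidate family could be fitted:\n",
         paste(sprintf("  %s: %s", names(failures), failures), collapse = "\n"),
         call. = FALSE)
  }
  ad <- vapply(fits, `[[`, numeric(1), "ad_stat")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  # rank by A2; near-ties resolved by loglik (higher first) then name
  ord <- order(round(ad / 1e-9) * 1e-9, -ll, names(fits))
  fits <- fits[ord]
  for (k in seq_along(fits)) fits[[k]]$rank <- k
  structure(fits, class = "distribution_ranking", failures = failures)
}

#' @export
print.distribution_ranking <- function(x, ...) {
  cat("<distribution_ranking>\n")
  for (f in x) {
    cat(sprintf("  %d. %-10s A2 = %.5f  loglik = %.3f\n",
                f$rank, f$family, f$ad_stat, f$loglik))
  }
  fails <- attr(x, "failures")
  if (length(fails)) {
    cat("  failed:", paste(names(fails), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate a distribution ranking
#'
#' @param x a `distribution_ranking`.
#' @param ... unused.
#' @return A data frame with one row per fitted candidate (family, parameter
#'   names and values, loglik, A-squared, rank, convergence flag).
#' @export
as.data.frame.distribution_ranking <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(f) {
    data.frame(family = f$family,
               param1_name = names(f$params)[1L], param1 = unname(f$params[1L]),
               param2_name = names(f$params)[2L], param2 = unname(f$params[2L]),
               loglik = f$loglik, ad_stat = f$ad_stat, rank = f$rank,
               converged = f$converged)
  }))
}
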