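#' Construct a dose--response curve
#'
#' Continuous dose (or concentration) versus response data with replicate
#' structure, used both for in-vitro benchmark concentrations (BMC) and
#' for predicted in-vivo benchmark doses (BMD).
#'
#' @param dose numeric, non-negative; a usable curve includes a 0 control
#'   and at least 4 distinct dose levels.
#' @param response numeric, continuous, same length as `dose`.
#' @param replicate integer replicate index (default: all 1).
#' @param direction `"decreasing"` (e.g. viability) or `"increasing"`
#'   (e.g. ROS, reporter induction).
#' @param units dose-unit label (e.g. `"uM"`, `"mg/kg bw"`).
#' @return an object of class `dose_response_curve` (a data frame).
#' @export
dose_response_curve <- function(dose, response, replicate = NULL,
                                direction = c("decreasing", "increasing"),
                                units = "uM") {
  direction <- match.arg(direction)
  stopifnot(length(dose) == length(response))
  if (any(dose < 0)) stop("doses must be non-negative")
  if (is.null(replicate)) replicate <- rep(1L, length(dose))
  structure(
    data.frame(dose = as.numeric(dose), response = as.numeric(response),
               replicate = as.integer(replicate)),
    class = c("dose_response_curve", "data.frame"),
    direction = direction, units = units)
}

check_curve_fittable <- function(curve) {
  if (!0 %in% curve$dose) stop("curve must include a dose-0 control row")
  if (length(unique(curve$dose)) < 4)
    stop("need at least 4 distinct dose levels including the control")
  invisible(curve)
}

# EFSA-style continuous model families (x >= 0):
#   hill:        y = a * (1 + (c - 1) * x^d / (b^d + x^d))
#   exponential: y = a * (c - (c - 1) * exp(-(x/b)^d))
# a: background; b: potency (dose scale); c: fold change at infinite dose
# (c < 1 decreasing, c > 1 increasing), d: steepness.
dr_mean <- function(family, x, a, b, c, d) {
  if (family == "hill") {
    frac <- ifelse(x > 0, x^d / (b^d + x^d), 0)
    a * (1 + (c - 1) * frac)
  } else {
    a * (c - (c - 1) * exp(-(x / b)^d))
  }
}

# theta = (log a, log b, c-transform, log d); the c transform keeps the
# fold change on the correct side of 1 for the endpoint direction.
c_transform <- function(direction) {
  if (direction == "decreasing")
    list(fwd = function(z) 1 / (1 + exp(-z)),
         inv = function(c) log(c / (1 - c)))
  else
    list(fwd = function(z) 1 + exp(z),
         inv = function(c) log(c - 1))
}

theta_unpack <- function(theta, direction) {
  tr <- c_transform(direction)
  c(a = exp(theta[1]), b = exp(theta[2]), c = tr$fwd(theta[3]),
    d = exp(theta[4]))
}

make_sse <- function(family, direction, x, y, var_model = "constant") {
  tr <- c_transform(direction)
  if (var_model == "constant") {
    function(theta) {
      mu <- dr_mean(family, x, exp(theta[1]), exp(theta[2]),
                    tr$fwd(theta[3]), exp(theta[4]))
      sum((y - mu)^2)
    }
  } else {
    # constant CV: residuals scaled by the mean (sd_i = cv * mu_i)
    function(theta) {
      mu <- dr_mean(family, x, exp(theta[1]), exp(theta[2]),
                    tr$fwd(theta[3]), exp(theta[4]))
      if (any(mu <= 0)) return(1e30)
      sum(((y - mu) / mu)^2)
    }
  }
}

#' Fit a continuous dose--response model
#'
#' Maximum-likelihood fit (normal residuals, constant variance; equivalent
#' to least squares) of the EFSA-style continuous Hill or exponential
#' family, parameterised by background `a`, dose scale `b`, maximal fold
#' change `c` and steepness `d`.  Censored rows (from curve conversion)
#' are dropped before fitting; a flat curve is rejected as unidentifiable.
#'
#' @param curve a [dose_response_curve()].
#' @param family `"hill"` or `"exponential"`.
#' @param var_model `"constant"` (homoscedastic residuals; default) or
#'   `"proportional"` (constant coefficient of variation, sd
#'   proportional to the mean -- the usual structure of multiplicative
#'   assay noise).
#' @param fallback when `TRUE` (default), a non-converging fit falls back
#'   to the other family with a warning.
#' @return an object of class `drc_fit`: list with `family`, `params`
#'   (a, b, c, d), `sigma` (residual sd, or residual CV under the
#'   proportional model), `logLik`, `aic`, `n`, `direction`, `converged`,
#'   and the data used.
#' @export
fit_dose_response <- function(curve, family = c("hill", "exponential"),
                              var_model = c("constant", "proportional"),
                              fallback = TRUE) {
  family <- match.arg(family)
  var_model <- match.arg(var_model)
  stopifnot(inherits(curve, "dose_response_curve"))
  df <- as.data.frame(curve)
  if (!is.null(df$censored)) df <- df[!df$censored, ]
  df <- df[!is.na(df$dose) & !is.na(df$response), ]
  check_curve_fittable(df)
  direction <- attr(curve, "direction")

  x <- df$dose; y <- df$response
  mu0 <- mean(y[x == 0])
  mu_top <- mean(y[x == max(x)])
  if (abs(mu_top - mu0) < 1e-9 * max(abs(mu0), 1) &&
      sd(y) < 1e-9 * max(abs(mu0), 1))
    stop("flat curve: potency is unidentifiable")

  c_start <- max(mu_top / mu0, 1e-3)
  if (direction == "decreasing") c_start <- min(c_start, 0.999)
  else c_start <- max(c_start, 1.001)
  tr <- c_transform(direction)

  fit_one <- function(fam) {
    obj <- make_sse(fam, direction, x, y, var_model)
    starts <- list(
      c(log(mu0), log(stats::median(x[x > 0])), tr$inv(c_start), log(1)),
      c(log(mu0), log(max(x) / 4), tr$inv(c_start), log(2)))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) return(NULL)
    # polish with BFGS
    o2 <- tryCatch(optim(best$par, obj, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-14)),
                   error = function(e) best)
    if (o2$value <= best$value) best <- o2
    best
  }

  o <- fit_one(family)
  used <- family
  if (is.null(o) && fallback) {
    used <- setdiff(c("hill", "exponential"), family)
    warning("fit did not converge for the ", family,
            " family; falling back to ", used)
    o <- fit_one(used)
  }
  if (is.null(o)) stop("dose-response fit failed to converge")

  n <- length(y)
  pars <- theta_unpack(o$par, direction)
  sigma <- sqrt(o$value / n)   # residual sd, or residual CV if proportional
  if (var_model == "constant") {
    ll <- -n / 2 * (log(2 * pi * sigma^2) + 1)
  } else {
    mu_hat <- dr_mean(used, x, pars[["a"]], pars[["b"]], pars[["c"]],
                      pars[["d"]])
    ll <- -n / 2 * (log(2 * pi * sigma^2) + 1) - sum(log(mu_hat))
  }
  structure(
    list(family = used, theta = o$par, params = pars,
         var_model = var_model,
         sigma = sigma, logLik = ll, aic = -2 * ll + 2 * 5,
         n = n, direction = direction,
         converged = is.null(o$convergence) || o$convergence %in% c(0, 1),
         data = df),
    class = "drc_fit")
}

#' @export
print.drc_fit <- function(x, ...) {
  cat(sprintf("Continuous dose-response fit: %s family (%s)\n",
              x$family, x$direction))
  cat(sprintf("  a = %.4g  b = %.4g  c = %.4g  d = %.4g\n",
              x$params[["a"]], x$params[["b"]], x$params[["c"]],
              x$params[["d"]]))
  cat(sprintf("  sigma %.4g, logLik %.4g, AIC %.4g (n = %d)\n",
              x$sigma, x$logLik, x$aic, x$n))
  invisible(x)
}

#' Benchmark dose of a fitted curve
#'
#' The dose at which the fitted mean response differs from the fitted
#' background by a fraction `bmr` of background (10% by default):
#' `f(bmd) = a * (1 - bmr)` for decreasing and `a * (1 + bmr)` for
#' increasing endpoints.  Closed form for both families.
#'
#' @param fit a [fit_dose_response()] result.
#' @param bmr benchmark response as a fraction of background.
#' @return the benchmark dose, or `NA` with a warning when the fitted
#'   curve never reaches the benchmark response.
#' @export
bmd_point <- function(fit, bmr = 0.10) {
  stopifnot(inherits(fit, "drc_fit"), bmr >= 0)
  if (bmr == 0) return(0)
  p <- fit$params
  u <- bmr / abs(p[["c"]] - 1)
  if (u >= 1) {
    warning("benchmark response outside the fitted response range")
    return(NA_real_)
  }
  if (fit$family == "hill") {
    unname(p[["b"]] * (u / (1 - u))^(1 / p[["d"]]))
  } else {
    unname(p[["b"]] * (-log(1 - u))^(1 / p[["d"]]))
  }
}

#' Bootstrap confidence bounds for the benchmark dose
#'
#' Parametric bootstrap: responses are regenerated from the fitted mean
#' curve with normal residuals (unbiased residual sd, with its chi-square
#' uncertainty propagated per replicate), the model is refitted, and the
#' benchmark dose recomputed.  Two-sided 90% bounds (the BMDL10/BMDU10
#' convention) are formed by the basic bootstrap on the log-dose scale:
#' the 5th/95th bootstrap percentiles are reflected about the point
#' estimate, `bmdl = bmd^2 / q95` and `bmdu = bmd^2 / q5`, which corrects
#' the bias that plain percentile bounds inherit from the skewed BMD
#' sampling distribution.  Deterministic under a fixed seed; failed or
#' out-of-range refits are dropped, and if they exceed 20% the bounds are
#' widened to the reflected bootstrap extremes with a warning.
#'
#' @param fit a [fit_dose_response()] result.
#' @param n_boot number of bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @param bmr benchmark response fraction.
#' @param level two-sided confidence level (default 0.90).
#' @return list with `bmdl`, `bmdu`, `n_failed`, `bmds` (the bootstrap
#'   draws).
#' @export
bmd_bounds <- function(fit, n_boot = 1000, seed = 1L, bmr = 0.10,
                       level = 0.90) {
  stopifnot(inherits(fit, "drc_fit"))
  if (n_boot < 200) stop("n_boot must be >= 200")
  x <- fit$data$dose
  mu <- dr_mean(fit$family, x, fit$params[["a"]], fit$params[["b"]],
                fit$params[["c"]], fit$params[["d"]])
  # refits are warm-started from the original optimum: the bootstrap
  # perturbs the data only by the fitted noise level, so the new optimum
  # is near theta-hat and a single quasi-Newton polish suffices
  var_model <- fit$var_model %||% "constant"
  refit_bmd <- function(y_star) {
    obj <- make_sse(fit$family, fit$direction, x, y_star, var_model)
    o <- tryCatch(optim(fit$theta, obj, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(o)) return(NA_real_)
    f_star <- list(family = fit$family,
                   params = theta_unpack(o$par, fit$direction))
    class(f_star) <- "drc_fit"
    suppressWarnings(bmd_point(f_star, bmr))
  }
  # unbiased residual sd (4 mean parameters) rather than the MLE, and a
  # scaled-inverse-chi-square draw of the variance per replicate so the
  # bounds also reflect the uncertainty in sigma itself
  n <- length(mu)
  dfree <- max(n - 4, 1)
  sigma_hat <- fit$sigma * sqrt(n / dfree)
  sd_unit <- if (var_model == "constant") rep(1, n) else mu
  spec_seed <- list(seed = as.integer(seed))
  draws <- with_spec_seed(spec_seed, {
    vapply(seq_len(n_boot), function(i) {
      sigma_i <- sigma_hat * sqrt(dfree / stats::rchisq(1, dfree))
      refit_bmd(mu + rnorm(n, 0, sigma_i * sd_unit))
    }, numeric(1))
  })
  ok <- draws[is.finite(draws) & draws > 0]
  n_failed <- n_boot - length(ok)
  if (length(ok) == 0) stop("all bootstrap refits failed")
  bmd_hat <- bmd_point(fit, bmr)
  if (!is.finite(bmd_hat) || bmd_hat <= 0)
    stop("point estimate of the benchmark dose is undefined; no bounds")
  alpha <- (1 - level) / 2
  if (n_failed > 0.2 * n_boot) {
    warning(n_failed, " of ", n_boot, " bootstrap refits failed; ",
            "returning widened (extreme-reflected) bounds")
    q <- range(ok)
  } else {
    q <- unname(quantile(ok, c(alpha, 1 - alpha), type = 7))
  }
  bounds <- c(min(bmd_hat^2 / q[2], bmd_hat), max(bmd_hat^2 / q[1], bmd_hat))
  list(bmdl = bounds[1], bmdu = bounds[2], n_failed = n_failed, bmds = draws)
}

#' Full benchmark-dose analysis of one curve
#'
#' Convenience wrapper: fit the model family, compute the benchmark dose
#' and its bootstrap confidence bounds.
#'
#' @inheritParams fit_dose_response
#' @inheritParams bmd_bounds
#' @return an object of class `bmd_result`: list with `model_name`,
#'   `params`, `bmd`, `bmdl`, `bmdu`, `bmr`, `aic`, `converged`,
#'   `n_boot`, `seed`.
#' @export
bmd_analysis <- function(curve, family = "hill", bmr = 0.10,
                         n_boot = 1000, seed = 1L,
                         var_model = "constant") {
  fit <- fit_dose_response(curve, family, var_model)
  bmd <- bmd_point(fit, bmr)
  bounds <- bmd_bounds(fit, n_boot = n_boot, seed = seed, bmr = bmr)
  structure(
    list(model_name = fit$family, params = fit$params,
         bmd = bmd, bmdl = bounds$bmdl, bmdu = bounds$bmdu, bmr = bmr,
         aic = fit$aic, converged = fit$converged,
         n_boot = n_boot, seed = seed, n_failed = bounds$n_failed,
         fit = fit),
    class = "bmd_result")
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf("BMD analysis (%s family, BMR %g%%)\n",
              x$model_name, 100 * x$bmr))
  cat(sprintf("  BMD %.4g  [BMDL %.4g, BMDU %.4g]  (%d bootstrap, seed %d)\n",
              x$bmd, x$bmdl, x$bmdu, x$n_boot, x$seed))
  invisible(x)
}
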