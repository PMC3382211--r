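# First-order transfer-function learning-curve model and per-series fitting.

#' Construct and validate learning-curve model parameters
#'
#' The learning curve is modelled as the step response of a first-order
#' system, `Y(X) = B3 * exp(-B2*(X-1)) + B4 * (1 - exp(-B2*(X-1)))`, where
#' `X` is the trial number and `Y` the number of correctly recalled words.
#' `B3` is the predicted recall on trial 1 ("readiness to learn"), `B4` the
#' asymptotic recall ("ability to learn") and `B2` the learning rate, the
#' inverse of the time constant: `1/B2` trials (after trial 1) cover 63% of
#' the gap between `B3` and `B4`.
#'
#' @param B2 learning rate per trial; must be > 0.
#' @param B3 predicted recall at trial 1 (words); must be >= 0.
#' @param B4 asymptotic recall (words); must be >= 0.
#' @return A named numeric vector `c(B2, B3, B4)`.
#' @examples
#' lc_params(0.65, 7.28, 14.17)
#' @export
lc_params <- function(B2, B3, B4) {
  p <- c(B2 = as.numeric(B2), B3 = as.numeric(B3), B4 = as.numeric(B4))
  check_lc_params(p)
  p
}

check_lc_params <- function(params) {
  if (is.list(params)) params <- unlist(params)
  if (!all(c("B2", "B3", "B4") %in% names(params))) {
    stop("params must contain named elements B2, B3 and B4", call. = FALSE)
  }
  params <- params[c("B2", "B3", "B4")]
  if (any(!is.finite(params))) {
    stop("model parameters must be finite", call. = FALSE)
  }
  if (params[["B2"]] <= 0) {
    stop("B2 (learning rate) must be > 0", call. = FALSE)
  }
  if (params[["B3"]] < 0 || params[["B4"]] < 0) {
    stop("B3 and B4 (words recalled) must be >= 0", call. = FALSE)
  }
  invisible(params)
}

#' Evaluate the learning-curve model
#'
#' Predicted recall at trial `x` under parameters `(B2, B3, B4)`. At
#' `x = 1` the value is exactly `B3`; as `x` grows the curve approaches
#' `B4` exponentially at rate `B2`.
#'
#' @param params named vector or list with elements `B2`, `B3`, `B4`
#'   (see [lc_params()]).
#' @param x trial number(s), numeric, `>= 1`.
#' @return Predicted recall (words, real-valued), same length as `x`.
#' @examples
#' evaluate_model(lc_params(0.65, 7.28, 14.17), 1:5)
#' @export
evaluate_model <- function(params, x) {
  p <- check_lc_params(params)
  if (any(!is.finite(x)) || any(x < 1)) {
    stop("trial numbers x must be finite and >= 1", call. = FALSE)
  }
  e <- exp(-p[["B2"]] * (x - 1))
  unname(p[["B3"]] * e + p[["B4"]] * (1 - e))
}

# Shared validation for a single subject's recall series. Real-valued
# counts are allowed (averaged curves use non-integer means); integer
# checks on raw data live in the CSV reader.
validate_recall_series <- function(counts, trials, min_points = 1L,
                                   max_count = 16) {
  if (length(counts) == 0) stop("empty recall series", call. = FALSE)
  if (length(trials) != length(counts)) {
    stop("trials and counts must have equal length", call. = FALSE)
  }
  if (length(counts) < min_points) {
    stop(sprintf("recall series must have at least %d trials", min_points),
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(!is.finite(trials))) {
    stop("recall series must be finite", call. = FALSE)
  }
  if (any(diff(trials) <= 0)) {
    stop("trial numbers must be strictly increasing", call. = FALSE)
  }
  if (any(counts < 0) || any(counts > max_count)) {
    stop(sprintf("recall counts must lie in [0, %s]", max_count),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Default coefficient bounds. B4 gets headroom above the list length so an
# asymptote near ceiling is not censored; unbounded fits of nearly flat
# curves can blow up (B2 with SE several times its estimate).
default_lc_bounds <- function(max_count = 16) {
  list(lower = c(B2 = 1e-4, B3 = 0, B4 = 0),
       upper = c(B2 = 10, B3 = max_count, B4 = max_count + 4))
}

# Analytic Jacobian of the model at params, rows = trials.
lc_jacobian <- function(params, x) {
  e <- exp(-params[["B2"]] * (x - 1))
  cbind(B2 = (params[["B4"]] - params[["B3"]]) * (x - 1) * e,
        B3 = e,
        B4 = 1 - e)
}

# A few damped Gauss-Newton steps from the solver's optimum so the
# result is identical (to ~1e-10) across starting values; keeps within
# bounds, backs off on any SSE increase, and leaves the input untouched
# if the Jacobian is singular (flat-curve degeneracy).
polish_lc_fit <- function(params, x, y, lo, hi, max_iter = 50) {
  sse <- function(p) sum((y - evaluate_model(p, x))^2)
  cur <- sse(params)
  for (it in seq_len(max_iter)) {
    J <- lc_jacobian(params, x)
    r <- y - evaluate_model(params, x)
    step <- try(solve(crossprod(J), crossprod(J, r)), silent = TRUE)
    if (inherits(step, "try-error") || any(!is.finite(step))) break
    step <- drop(step)
    moved <- FALSE
    for (damp in c(1, 0.5, 0.25, 0.1)) {
      cand <- pmin(pmax(params + damp * step, lo + c(1e-8, 0, 0)), hi)
      val <- sse(cand)
      if (val <= cur + 1e-14) {
        params <- cand
        if (cur - val < 1e-14 * (1 + cur)) max_iter <- 0  # converged
        cur <- val
        moved <- TRUE
        break
      }
    }
    if (!moved || max_iter == 0) break
  }
  params
}

# Gauss-Newton asymptotic covariance: s^2 (J'J)^-1 with
# s^2 = SS_res / (n - 3). With exactly 3 points (zero df) the residuals
# are zero by interpolation and the SEs are reported as 0.
lc_asymptotic_se <- function(params, x, ss_res) {
  n <- length(x)
  s2 <- if (n > 3) ss_res / (n - 3) else 0
  J <- lc_jacobian(params, x)
  JtJ <- crossprod(J)
  cov <- try(s2 * solve(JtJ), silent = TRUE)
  if (inherits(cov, "try-error")) {
    return(c(B2 = NA_real_, B3 = NA_real_, B4 = NA_real_))
  }
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- c("B2", "B3", "B4")
  se
}

#' Fit the learning-curve model to one recall series
#'
#' Nonlinear least squares for `(B2, B3, B4)` minimising the residual sum
#' of squares of observed recall against the model, via bounded
#' Gauss-Newton (`nls`, port algorithm). Starting values default to
#' `B3 = Y(1)`, `B4 = Y(last trial)`, `B2 = 0.5`; on failure a restart grid
#' over `B2 in {0.1, 0.5, 1, 2}` is tried, then a bounded quasi-Newton
#' minimisation of the sum of squares as a last resort. Asymptotic standard
#' errors come from the curvature of the residual surface at the optimum
#' (`s^2 (J'J)^-1`, `s^2 = SS_res/(n-3)`), and fit quality is
#' `R^2 = 1 - SS_res/SS_tot` about the mean of the fitted points.
#'
#' When the curve is nearly flat, `B2` is weakly identified; the fit is
#' still returned but flagged `b2_unreliable` whenever `se(B2) > B2`.
#'
#' @param counts recalled words per trial (real-valued allowed, so that
#'   averaged curves of group means can be fitted).
#' @param trials trial numbers, strictly increasing; default `1..n`.
#' @param init optional named starting values `c(B2=, B3=, B4=)`.
#' @param bounds optional `list(lower=, upper=)` named coefficient bounds;
#'   default `B2 in (1e-4, 10]`, `B3 in [0, max_count]`,
#'   `B4 in [0, max_count + 4]`.
#' @param max_count maximum possible recall (list length), default 16.
#' @return An object of class `"lc_fit"`: a list with elements `params`,
#'   `se`, `r_squared`, `residuals`, `fitted`, `converged`, `n_points`,
#'   `b2_unreliable`, `method`, `ss_res`, `ss_tot` and the input `data`.
#' @examples
#' fit_learning_curve(c(7.26, 10.67, 12.22, 13.09, 13.76))
#' @export
fit_learning_curve <- function(counts, trials = seq_along(counts),
                               init = NULL, bounds = NULL, max_count = 16) {
  counts <- unname(as.numeric(counts))
  trials <- unname(as.numeric(trials))
  validate_recall_series(counts, trials, min_points = 3L,
                         max_count = max_count)
  if (length(unique(trials)) < 3) {
    stop("at least 3 distinct trials are needed to fit 3 parameters",
         call. = FALSE)
  }
  if (is.null(bounds)) bounds <- default_lc_bounds(max_count)
  lo <- bounds$lower[c("B2", "B3", "B4")]
  hi <- bounds$upper[c("B2", "B3", "B4")]
  clamp <- function(p) pmin(pmax(p, lo + c(1e-6, 0, 0)), hi)

  starts <- list()
  if (!is.null(init)) starts <- c(starts, list(clamp(unlist(init)[c("B2", "B3", "B4")])))
  for (b2 in c(0.5, 0.1, 1, 2)) {
    starts <- c(starts, list(clamp(c(B2 = b2, B3 = counts[1],
                                     B4 = counts[length(counts)]))))
  }

  dat <- data.frame(x = trials, y = counts)
  fit <- NULL
  method <- NA_character_
  for (st in starts) {
    res <- try(suppressWarnings(stats::nls(
      y ~ B3 * exp(-B2 * (x - 1)) + B4 * (1 - exp(-B2 * (x - 1))),
      data = dat, start = as.list(st), algorithm = "port",
      lower = lo, upper = hi,
      control = stats::nls.control(maxiter = 200, warnOnly = FALSE)
    )), silent = TRUE)
    if (!inherits(res, "try-error") && res$convInfo$isConv) {
      fit <- res
      method <- "nls-port"
      break
    }
  }

  if (is.null(fit)) {
    # last-resort direct minimisation of the sum of squares
    sse <- function(p) {
      names(p) <- c("B2", "B3", "B4")
      sum((counts - evaluate_model(p, trials))^2)
    }
    op <- try(stats::optim(starts[[1]], sse, method = "L-BFGS-B",
                           lower = lo, upper = hi), silent = TRUE)
    if (!inherits(op, "try-error") && op$convergence == 0) {
      params <- op$par
      names(params) <- c("B2", "B3", "B4")
      method <- "optim-lbfgsb"
      converged <- TRUE
    } else {
      params <- c(B2 = NA_real_, B3 = NA_real_, B4 = NA_real_)
      method <- "failed"
      converged <- FALSE
    }
  } else {
    params <- stats::coef(fit)[c("B2", "B3", "B4")]
    converged <- TRUE
  }

  if (converged) {
    params <- polish_lc_fit(params, trials, counts, lo, hi)
    fitted_vals <- evaluate_model(params, trials)
    resid_vals <- counts - fitted_vals
    ss_res <- sum(resid_vals^2)
    ss_tot <- sum((counts - mean(counts))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    se <- lc_asymptotic_se(params, trials, ss_res)
  } else {
    fitted_vals <- rep(NA_real_, length(counts))
    resid_vals <- fitted_vals
    ss_res <- NA_real_
    ss_tot <- sum((counts - mean(counts))^2)
    r2 <- NA_real_
    se <- c(B2 = NA_real_, B3 = NA_real_, B4 = NA_real_)
  }

  structure(list(
    params = params,
    se = se,
    r_squared = r2,
    residuals = resid_vals,
    fitted = fitted_vals,
    converged = converged,
    n_points = length(counts),
    b2_unreliable = isTRUE(converged && is.finite(se[["B2"]]) &&
                             se[["B2"]] > abs(params[["B2"]])),
    method = method,
    ss_res = ss_res,
    ss_tot = ss_tot,
    data = list(trials = trials, counts = counts)
  ), class = "lc_fit")
}

#' @export
print.lc_fit <- function(x, digits = 4, ...) {
  cat("Learning-curve model fit (", x$n_points, " trials)\n", sep = "")
  if (!x$converged) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  tab <- cbind(Estimate = x$params, `Asymp. SE` = x$se)
  print(round(tab, digits))
  cat("R-squared:", format(round(x$r_squared, digits)), "\n")
  if (x$b2_unreliable) {
    cat("note: B2 unreliable (SE exceeds estimate; curve nearly flat)\n")
  }
  invisible(x)
}

#' @export
coef.lc_fit <- function(object, ...) object$params

#' @export
residuals.lc_fit <- function(object, ...) object$residuals

#' @export
fitted.lc_fit <- function(object, ...) object$fitted

#' @export
predict.lc_fit <- function(object, x = object$data$trials, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit",
                              call. = FALSE)
  evaluate_model(object$params, x)
}

#' Compare one coefficient between two fitted learning curves
#'
#' Wald z-test using the asymptotic standard errors of the two fits:
#' `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)` with a standard-normal
#' reference (degrees of freedom for averaged-curve fits are small and the
#' reference is a documented convention, so the interpretable surface is
#' direction of effect and p < alpha rather than exact p-values).
#'
#' @param fit_a,fit_b objects of class `"lc_fit"`, both converged.
#' @param which coefficient to compare: `"B2"`, `"B3"` or `"B4"`.
#' @return An `htest` object with `statistic` (z), `p.value` and
#'   `estimate` (the two coefficient values).
#' @export
compare_coefficients <- function(fit_a, fit_b, which = c("B3", "B4", "B2")) {
  which <- match.arg(which)
  for (f in list(fit_a, fit_b)) {
    if (!inherits(f, "lc_fit")) stop("inputs must be lc_fit objects",
                                     call. = FALSE)
    if (!f$converged) stop("both fits must have converged", call. = FALSE)
  }
  se2 <- fit_a$se[[which]]^2 + fit_b$se[[which]]^2
  if (!is.finite(se2) || se2 <= 0) {
    stop("degenerate comparison: zero or undefined standard error for ",
         which, call. = FALSE)
  }
  z <- (fit_a$params[[which]] - fit_b$params[[which]]) / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  est <- c(fit_a$params[[which]], fit_b$params[[which]])
  names(est) <- paste0(which, c(" (a)", " (b)"))
  structure(list(
    statistic = c(z = z), p.value = p, estimate = est,
    alternative = "two.sided",
    method = sprintf("Wald z-test for learning-curve coefficient %s", which),
    data.name = "two lc_fit objects"
  ), class = "htest")
}

#' Learning slope (words gained per trial)
#'
#' Ordinary-least-squares slope of recall on trial number, the standard
#' CVLT-II learning-slope score. Unlike `B2`, the slope is confounded by a
#' high trial-1 score (ceiling leaves little room to climb).
#'
#' @inheritParams fit_learning_curve
#' @return Slope in words per trial.
#' @examples
#' learning_slope(c(2, 4, 6, 8, 10))  # 2
#' @export
learning_slope <- function(counts, trials = seq_along(counts)) {
  validate_recall_series(counts, trials, min_points = 2L, max_count = Inf)
  vx <- sum((trials - mean(trials))^2)
  if (vx == 0) stop("trial numbers are constant", call. = FALSE)
  sum((trials - mean(trials)) * (counts - mean(counts))) / vx
}

#' Maximal recall gain over trial 1
#'
#' `max(counts) - counts[1]`, the difference between the best trial and the
#' first. Correlates with the learning slope; zero when trial 1 is already
#' the maximum.
#'
#' @inheritParams fit_learning_curve
#' @return Words (>= 0).
#' @export
max_minus_first <- function(counts, trials = seq_along(counts)) {
  validate_recall_series(counts, trials, min_points = 1L, max_count = Inf)
  max(counts) - counts[1]
}
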