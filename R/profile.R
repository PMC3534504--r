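#' Profile-likelihood confidence intervals
#'
#' For each requested parameter the profile is traced by scanning the
#' parameter over an adaptive grid away from the estimate (rate parameters on
#' log scale) while re-optimizing all other parameters at each point,
#' warm-started from the neighbouring optimum. The confidence interval at
#' level `l` is the sub-level set
#' \eqn{\{\theta : \chi^2_{prof}(\theta) - \chi^2_{min} \le q_l\}} with
#' `q_l` the 1-dof chi-square quantile (0.989 for 68%, 2.706 for 90%); the
#' crossing points are located by bisection between scan grid points. A
#' profile that fails to cross the largest threshold inside the scan bounds
#' yields a one-sided interval flagged open.
#'
#' @param fit a converged [fit_variational()]/[fit_fixed_input()] result.
#' @param levels nominal confidence levels.
#' @param parameters parameter names to profile (rates and/or initial
#'   values); default all.
#' @param step_factor initial scan step in units of the Wald standard error.
#' @param max_steps maximum scan points per direction.
#' @param bisect_tol tolerance on `delta chi2 - q` at the located bound.
#' @return An object of class `profile_ci`: per parameter the estimate,
#'   a `lower`/`upper` bound per level, open-end flags, and the profile
#'   curve (parameter value on its natural scale, profile chi-square).
#' @export
profile_likelihood_ci <- function(fit, levels = c(0.68, 0.90),
                                  parameters = NULL, step_factor = 0.5,
                                  max_steps = 30L, bisect_tol = 0.01) {
  stopifnot(inherits(fit, "vode_fit"))
  if (!isTRUE(fit$converged))
    warning("profiling a fit that did not report convergence")
  model <- fit$model
  r <- model$r; n <- model$n
  all_names <- c(model$parameter_names, model$species_names)
  if (is.null(parameters)) parameters <- all_names
  stopifnot(all(parameters %in% all_names))
  levels <- sort(levels)
  qs <- qchisq(levels, df = 1)
  qmax <- max(qs)

  theta_hat <- fit$theta_hat
  chi2_min <- fit$chi2
  ses <- profile_theta_se(fit)

  out <- list()
  for (par in parameters) {
    j <- match(par, all_names)           # theta index; log scale for rates
    is_rate <- j <= r
    to_nat <- if (is_rate) exp else identity
    se <- ses[j]
    step0 <- max(step_factor * se, 1e-4)

    curve <- data.frame(theta = theta_hat[j], chi2 = chi2_min)
    bounds <- matrix(NA_real_, length(levels), 2,
                     dimnames = list(paste0(levels * 100, "%"),
                                     c("lower", "upper")))
    open <- c(lower = FALSE, upper = FALSE)

    for (dir in c(-1, 1)) {
      th_warm <- theta_hat
      step <- step0
      tjs <- theta_hat[j]
      chis <- chi2_min
      crossed <- FALSE
      for (k in seq_len(max_steps)) {
        tj <- tjs[length(tjs)] + dir * step
        pr <- profile_refit(fit, j, tj, th_warm)
        th_warm <- pr$theta
        curve <- rbind(curve, data.frame(theta = tj, chi2 = pr$chi2))
        tjs <- c(tjs, tj)
        chis <- c(chis, pr$chi2)
        if (pr$chi2 - chi2_min >= qmax + 0.25) {
          ## per level: first scan interval (outward) bracketing the threshold
          for (il in seq_along(qs)) {
            target <- chi2_min + qs[il]
            hit <- which(chis >= target)[1]
            b <- bisect_crossing(fit, j, tjs[hit - 1], chis[hit - 1],
                                 tjs[hit], chis[hit], target, th_warm,
                                 bisect_tol)
            bounds[il, if (dir < 0) 1 else 2] <- to_nat(b)
          }
          crossed <- TRUE
          break
        }
        step <- step * 1.5
      }
      if (!crossed) {
        open[if (dir < 0) "lower" else "upper"] <- TRUE
        bounds[, if (dir < 0) 1 else 2] <- if (dir < 0) -Inf else Inf
        if (is_rate && dir < 0) bounds[, 1] <- 0
      }
    }
    curve <- curve[order(curve$theta), ]
    curve$value <- to_nat(curve$theta)
    est <- to_nat(theta_hat[j])
    ## intervals are sub-level sets around the estimate; enforce ordering
    bounds[, 1] <- pmin(bounds[, 1], est)
    bounds[, 2] <- pmax(bounds[, 2], est)
    out[[par]] <- list(estimate = est, levels = levels, bounds = bounds,
                       open = open, curve = curve)
  }
  structure(list(parameters = out, levels = levels, chi2_min = chi2_min,
                 method = fit$method),
            class = "profile_ci")
}

## Wald standard errors on the internal theta scale, with fallback.
profile_theta_se <- function(fit) {
  d <- length(fit$theta_hat)
  ses <- rep(0.2, d)
  if (!is.null(fit$vcov_theta)) {
    v <- diag(fit$vcov_theta)
    ses[fit$gn$free] <- sqrt(pmax(v, 1e-12))
  }
  ses
}

## Re-optimize all parameters but theta[j], held at value tj.
profile_refit <- function(fit, j, tj, theta_start) {
  th0 <- theta_start
  th0[j] <- tj
  gn <- gauss_newton(fit$resid_fn, th0, fixed = j,
                     control = fit$options[c("max_iter", "fd_step", "lambda0",
                                             "tol_chi2", "tol_step")])
  gn
}

## Bisect the crossing of the profile with threshold `target` between
## (tlo, chi_lo) below and (thi, chi_hi) above.
bisect_crossing <- function(fit, j, tlo, chi_lo, thi, chi_hi, target,
                            th_warm, tol, max_it = 12L) {
  for (it in seq_len(max_it)) {
    tm <- (tlo + thi) / 2
    pr <- profile_refit(fit, j, tm, th_warm)
    th_warm <- pr$theta
    if (abs(pr$chi2 - target) < tol) return(tm)
    if (pr$chi2 < target) { tlo <- tm; chi_lo <- pr$chi2 }
    else { thi <- tm; chi_hi <- pr$chi2 }
    if (abs(thi - tlo) < 1e-10) break
  }
  ## final linear interpolation inside the last bracket
  if (chi_hi > chi_lo)
    tlo + (target - chi_lo) / (chi_hi - chi_lo) * (thi - tlo)
  else (tlo + thi) / 2
}

#' Profile chi-square increase at a fixed parameter value
#'
#' Re-optimizes all other parameters with one parameter held at `value`
#' (natural scale) and returns the increase of the discrete chi-square above
#' its minimum. The value lies inside the profile-likelihood interval at
#' level `l` exactly when the returned increase is at most the 1-dof
#' chi-square quantile of `l` — the containment test used by
#' [coverage_study()].
#'
#' @param fit a `vode_fit`.
#' @param parameter a rate-parameter or species (initial value) name.
#' @param value the value to test, on the natural scale.
#' @return scalar `delta chi2 >= 0` (clamped at 0).
#' @export
profile_delta_chi2 <- function(fit, parameter, value) {
  model <- fit$model
  all_names <- c(model$parameter_names, model$species_names)
  j <- match(parameter, all_names)
  if (is.na(j)) stop("unknown parameter ", sQuote(parameter))
  tj <- if (j <= model$r) log(value) else value
  pr <- profile_refit(fit, j, tj, fit$theta_hat)
  max(pr$chi2 - fit$chi2, 0)
}

#' @export
print.profile_ci <- function(x, ...) {
  cat("profile-likelihood confidence intervals (", x$method, " fit)\n", sep = "")
  for (par in names(x$parameters)) {
    pp <- x$parameters[[par]]
    cat(" ", par, ": estimate ", signif(pp$estimate, 5), "\n", sep = "")
    for (il in seq_along(pp$levels)) {
      cat("    ", format(pp$levels[il] * 100), "%: [",
          signif(pp$bounds[il, 1], 5), ", ", signif(pp$bounds[il, 2], 5), "]",
          if (pp$open["lower"] || pp$open["upper"]) "  (open end)" else "",
          "\n", sep = "")
    }
  }
  invisible(x)
}
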