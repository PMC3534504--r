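#' @export
print.vode_fit <- function(x, ...) {
  cat("ODE input/parameter fit (", x$method, ")\n", sep = "")
  cat("  rates:          ", paste(names(x$p_hat), signif(x$p_hat, 5),
                                  sep = " = ", collapse = ", "), "\n", sep = "")
  cat("  initial values: ", paste(names(x$y0_hat), signif(x$y0_hat, 5),
                                  sep = " = ", collapse = ", "), "\n", sep = "")
  cat("  chi2 = ", format(x$chi2), " after ", x$n_iter, " iterations (",
      if (isTRUE(x$converged)) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' @export
coef.vode_fit <- function(object, ...) c(object$p_hat, object$y0_hat)

#' @export
summary.vode_fit <- function(object, ...) {
  est <- coef(object)
  se <- rep(NA_real_, length(est))
  if (!is.null(object$vcov_theta)) {
    s <- sqrt(pmax(diag(object$vcov_theta), 0))
    se[object$gn$free] <- s
    ## delta method back to natural scale for the log-rate block
    r <- object$model$r
    se[seq_len(r)] <- se[seq_len(r)] * est[seq_len(r)]
  }
  out <- list(method = object$method,
              coefficients = cbind(Estimate = est, `Wald SE` = se),
              chi2 = object$chi2, n_data = nrow(object$data),
              n_iter = object$n_iter, converged = object$converged)
  class(out) <- "summary.vode_fit"
  out
}

#' @export
print.summary.vode_fit <- function(x, ...) {
  cat("ODE input/parameter fit (", x$method, ")\n\n", sep = "")
  print(signif(x$coefficients, 5))
  cat("\ndiscrete chi2 = ", format(x$chi2), " on ", x$n_data,
      " measurements; ", x$n_iter, " Gauss-Newton iterations (",
      if (isTRUE(x$converged)) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Predicted component courses of a fit
#'
#' @param object a `vode_fit`.
#' @param times evaluation times; default 201 points over the data span.
#' @param ... unused.
#' @return data frame with columns `component`, `time`, `value`. For a
#'   variational fit the reconstructed input course is included; for a
#'   fixed-input fit the frozen input course is included (marked by its
#'   input name as well).
#' @export
predict.vode_fit <- function(object, times = NULL, ...) {
  model <- object$model
  traj <- object$trajectory
  if (is.null(times))
    times <- seq(min(traj$times), max(traj$times), length.out = 201)
  if (inherits(traj, "augmented_trajectory")) {
    pq <- predict(traj, times)
    courses <- rbind(pq$y, pq$x)
  } else {
    Y <- hermite_interp(traj$times, traj$y, traj$f, times)
    X <- eval_input_course(object$input_course, times, model$m)
    courses <- rbind(Y, X)
  }
  comp <- c(model$species_names, model$input_names)
  data.frame(component = rep(comp, each = length(times)),
             time = rep(times, length(comp)),
             value = as.numeric(t(courses)))
}

#' @export
residuals.vode_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- object$gn$residuals
  if (type == "raw") {
    used <- if (object$method == "variational") object$data else
      object$data[object$data$component %in% object$model$species_names, ]
    r <- r * used$sigma
  }
  r
}

#' @export
plot.vode_fit <- function(x, ...) {
  model <- x$model
  pr <- predict(x)
  comps <- unique(pr$component)
  old <- par(mfrow = c(1, length(comps)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (comp in comps) {
    pc <- pr[pr$component == comp, ]
    dc <- x$data[x$data$component == comp, ]
    ylim <- range(pc$value, dc$value)
    plot(pc$time, pc$value, type = "l", xlab = "time", ylab = comp,
         main = comp, ylim = ylim, ...)
    if (nrow(dc)) {
      points(dc$time, dc$value, pch = 16, col = "grey40")
      segments(dc$time, dc$value - dc$sigma, dc$time, dc$value + dc$sigma,
               col = "grey40")
    }
  }
  invisible(x)
}

#' @export
profile.vode_fit <- function(fitted, ...) profile_likelihood_ci(fitted, ...)

#' Profile-likelihood confidence intervals for a fit
#'
#' @param object a `vode_fit`.
#' @param parm parameter names (rates or initial values); default all.
#' @param level single confidence level.
#' @param ... passed to [profile_likelihood_ci()].
#' @return matrix with one row per parameter, columns `lower`, `upper`.
#' @export
confint.vode_fit <- function(object, parm = NULL, level = 0.90, ...) {
  pr <- profile_likelihood_ci(object, levels = level, parameters = parm, ...)
  t(vapply(pr$parameters, function(pp) pp$bounds[1, ], numeric(2)))
}

#' Simulate new datasets from a fitted model
#'
#' Draws measurement replicates at the fit's own design (components, times,
#' sigmas) around the fitted courses, with i.i.d. Gaussian noise.
#'
#' @param object a `vode_fit`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of `nsim` measurement data frames.
#' @export
simulate.vode_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  data <- object$data
  traj <- object$trajectory
  pred <- predict_rows(traj, data,
                       species_only = !inherits(traj, "augmented_trajectory"))
  if (anyNA(pred)) {
    X <- eval_input_course(object$input_course, data$time, object$model$m)
    for (i in which(is.na(pred))) {
      nu <- match(data$component[i], object$model$input_names)
      pred[i] <- X[nu, i]
    }
  }
  lapply(seq_len(nsim), function(s) {
    out <- data
    out$value <- pred + rnorm(nrow(data), 0, data$sigma)
    out
  })
}
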