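#' @export
print.fatigue_fit <- function(x, digits = 4, ...) {
  cat("Fatigue model fit (", x$readout, " readout, ", x$model, " model",
      if (x$readout == "effort") paste0(", ", x$combination), ")\n", sep = "")
  cat("  trials fitted:", x$n_obs, " baseline F_start:",
      format(x$F_start, digits = digits), "\n")
  cat("  parameters:\n")
  print(round(x$params, digits))
  cat("  RSS:", format(x$rss, digits = digits),
      " AIC:", format(x$aic, digits = digits),
      " R^2:", format(x$r_squared, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.fatigue_fit <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(
    model = object$model, readout = object$readout,
    combination = object$combination, params = object$params,
    rss = object$rss, n_obs = object$n_obs, n_params = object$n_params,
    aic = object$aic, r_squared = object$r_squared,
    F_start = object$F_start,
    sigma = sqrt(object$rss / object$n_obs),
    residual_range = range(res),
    n_starts = object$n_starts,
    converged_fraction = object$converged_fraction,
    n_ties = object$n_ties
  )
  class(out) <- "summary.fatigue_fit"
  out
}

#' @export
print.summary.fatigue_fit <- function(x, digits = 4, ...) {
  cat("Fatigue model fit summary\n")
  cat("  model:", x$model, "| readout:", x$readout,
      if (x$readout == "effort") paste("|", x$combination), "\n")
  cat("  parameters:\n")
  print(round(x$params, digits))
  cat("  n =", x$n_obs, " d =", x$n_params,
      " RSS =", format(x$rss, digits = digits),
      " sigma =", format(x$sigma, digits = digits), "\n")
  cat("  AIC =", format(x$aic, digits = digits),
      " R^2 =", format(x$r_squared, digits = digits), "\n")
  cat("  multi-start: ", x$n_starts, " starts, ",
      round(100 * x$converged_fraction), "% converged",
      if (x$n_ties > 0) paste0(", ", x$n_ties, " RSS ties"), "\n", sep = "")
  invisible(x)
}

#' @export
coef.fatigue_fit <- function(object, ...) object$params

#' @export
fitted.fatigue_fit <- function(object, ...) object$trajectory$predicted

#' @export
residuals.fatigue_fit <- function(object, ...) {
  r <- object$trajectory$observed - object$trajectory$predicted
  r[!object$fit_mask] <- NA_real_
  r
}

#' Predict ratings from a fitted fatigue model
#'
#' Recomputes the latent trajectory with the fitted parameters, either on
#' the original trials or on a new trial table (e.g. a longer task or a
#' different work/rest schedule).
#'
#' @param object A `fatigue_fit`.
#' @param newdata Optional trial table with `trial_type` and `exertion_E`
#'   (or `auc_norm`) columns.
#' @param type `"rating"` returns the predicted rating vector; `"trajectory"`
#'   the full latent-state data frame.
#' @param ... Unused.
#' @export
predict.fatigue_fit <- function(object, newdata = NULL,
                                type = c("rating", "trajectory"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    traj <- object$trajectory
  } else {
    newdata <- validate_trial_table(newdata, need_rating = FALSE)
    traj <- fatigue_trajectory(object$params, newdata, object$F_start,
                               model = object$model, readout = object$readout,
                               combination = object$combination,
                               state_timing = object$state_timing)
  }
  if (type == "rating") {
    traj$predicted
  } else {
    traj[c("trial", "RF", "UF", "F", "predicted")]
  }
}

#' Simulate replicate rating series from a fitted model
#'
#' Draws `nsim` replicate rating vectors from the fitted trajectory plus
#' Gaussian noise at the residual standard deviation, quantized and
#' censored to the rating scale — the parametric-bootstrap analogue of the
#' generator used for recovery studies.
#'
#' @param object A `fatigue_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed (required for reproducibility).
#' @param scale_max Rating-scale maximum (default 100 for the fatigue
#'   readout, 20 for effort).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated ratings.
#' @export
simulate.fatigue_fit <- function(object, nsim = 1, seed = 1,
                                 scale_max = NULL, ...) {
  scale_max <- scale_max %||% if (object$readout == "fatigue") 100L else 20L
  mu <- object$trajectory$predicted
  sigma <- sqrt(object$rss / object$n_obs)
  sims <- with_local_seed(seed, {
    replicate(nsim, quantize_rating(mu + stats::rnorm(length(mu), 0, sigma),
                                    scale_max = scale_max))
  })
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted fatigue trajectory
#'
#' Observed ratings against the model's predicted trajectory, with the
#' latent recoverable and unrecoverable components in a lower panel.
#'
#' @param x A `fatigue_fit`.
#' @param components Also draw the latent RF/UF components (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fatigue_fit <- function(x, components = TRUE, ...) {
  traj <- x$trajectory
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (components) graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  graphics::plot(traj$trial, traj$observed, pch = 16, cex = 0.6,
                 col = "grey40", xlab = "trial", ylab = "rating",
                 main = paste0(x$model, " model (", x$readout, ")"), ...)
  graphics::lines(traj$trial, traj$predicted, col = "firebrick", lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = c(NA, 2), pch = c(16, NA),
                   col = c("grey40", "firebrick"),
                   legend = c("observed", "predicted"))
  if (components) {
    graphics::plot(traj$trial, traj$UF, type = "l", col = "steelblue",
                   lwd = 2, xlab = "trial", ylab = "latent fatigue",
                   ylim = range(0, traj$UF, traj$RF))
    graphics::lines(traj$trial, traj$RF, col = "darkorange", lwd = 2)
    graphics::legend("topleft", bty = "n", lwd = 2,
                     col = c("steelblue", "darkorange"),
                     legend = c("UF (unrecoverable)", "RF (recoverable)"))
  }
  invisible(x)
}
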