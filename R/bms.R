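#' Convert per-subject AICs to approximate log model evidences
#'
#' Random-effects Bayesian model selection consumes per-subject log model
#' evidences; the AIC provides the standard approximation
#' \eqn{\ln p(y|m) \approx -AIC/2} ("inverted AIC").
#'
#' @param aic Numeric matrix, subjects x models, of AIC values.
#' @return Matrix of approximate log evidences (`-aic / 2`).
#' @export
invert_aic <- function(aic) {
  aic <- as.matrix(aic)
  if (any(!is.finite(aic))) stop("AIC matrix must be finite", call. = FALSE)
  -aic / 2
}

#' Random-effects Bayesian model selection
#'
#' Variational estimation of the population distribution over models:
#' model frequencies follow a Dirichlet whose posterior is found by
#' iterating subject responsibilities
#' \deqn{u_{nk} \propto \exp(\ln p(y_n|m_k) + \psi(\alpha_k) -
#'   \psi(\textstyle\sum_j \alpha_j))}
#' (row-normalized, computed in log space with per-row max subtraction for
#' numerical stability) and Dirichlet counts
#' \eqn{\alpha_k = \alpha_0 + \sum_n u_{nk}}, until the largest change in
#' \eqn{\alpha} falls below `tol`.
#'
#' @param log_evidence Numeric matrix, subjects x models, of log model
#'   evidences (see [invert_aic()]).
#' @param prior_alpha Symmetric Dirichlet prior mass per model (default 1).
#' @param tol Convergence tolerance on `max(abs(diff(alpha)))`
#'   (default 1e-6).
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return List with `alpha` (posterior Dirichlet parameters),
#'   `expected_frequency` (`alpha / sum(alpha)`), `responsibility` (the
#'   subjects x models matrix), and `n_iter`.
#' @export
rfx_bms <- function(log_evidence, prior_alpha = 1, tol = 1e-6,
                    max_iter = 10000L) {
  lev <- as.matrix(log_evidence)
  if (any(!is.finite(lev))) {
    stop("log evidences must be finite", call. = FALSE)
  }
  n <- nrow(lev)
  k <- ncol(lev)
  if (k < 2L) stop("need at least 2 models", call. = FALSE)
  stopifnot_scalar_number(prior_alpha, "prior_alpha", lower = 0)
  if (prior_alpha <= 0) stop("`prior_alpha` must be > 0", call. = FALSE)
  alpha <- rep(prior_alpha, k)
  u <- matrix(NA_real_, n, k)
  if (n == 0L) {
    return(list(alpha = alpha, expected_frequency = alpha / sum(alpha),
                responsibility = u, n_iter = 0L))
  }
  for (iter in seq_len(max_iter)) {
    lognum <- sweep(lev, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    lognum <- lognum - apply(lognum, 1L, max)
    u <- exp(lognum)
    u <- u / rowSums(u)
    alpha_new <- prior_alpha + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      return(list(alpha = alpha_new,
                  expected_frequency = alpha_new / sum(alpha_new),
                  responsibility = u, n_iter = iter))
    }
    alpha <- alpha_new
  }
  stop("rfx_bms did not converge in ", max_iter,
       " iterations (last max |delta alpha| = ",
       format(max(abs(alpha_new - alpha))), ")", call. = FALSE)
}

#' Exceedance probabilities of a Dirichlet frequency posterior
#'
#' The exceedance probability of model k is the posterior probability that
#' its population frequency exceeds that of every other model, estimated by
#' Monte-Carlo sampling from the Dirichlet (via independent Gamma draws).
#'
#' @param alpha Positive Dirichlet parameters, one per model.
#' @param n_samples Number of Monte-Carlo draws (default 1e6).
#' @param seed Integer seed; the estimate is reproducible given the seed.
#' @return Numeric vector of exceedance probabilities summing to 1 (up to
#'   tie-splitting on a null set).
#' @examples
#' exceedance_prob(c(8, 2), seed = 1) # ~ 1 - pbeta(0.5, 8, 2)
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = 1) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("all `alpha` must be positive and finite", call. = FALSE)
  }
  k <- length(alpha)
  with_local_seed(seed, {
    # sample in manageable chunks to bound memory at ~ k * 1e5 doubles
    chunk <- 1e5L
    counts <- integer(k)
    left <- n_samples
    while (left > 0) {
      m <- as.integer(min(chunk, left))
      g <- matrix(stats::rgamma(m * k, shape = rep(alpha, each = m)), m, k)
      counts <- counts + tabulate(max.col(g, ties.method = "first"), k)
      left <- left - m
    }
    counts / n_samples
  })
}

#' Count, per model, the subjects it fits best
#'
#' @param scores Numeric matrix, subjects x models, of fit scores where
#'   lower is better (AIC or RSS).
#' @param criterion Label recorded on the result, `"aic"` or `"rss"`.
#' @return Integer vector of best-fit counts (summing to the number of
#'   subjects). Exact ties are awarded to the lowest-indexed model; the
#'   number of tied subjects is attached as attribute `n_ties` and reported
#'   via a message.
#' @export
best_fit_counts <- function(scores, criterion = c("aic", "rss")) {
  criterion <- match.arg(criterion)
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  k <- ncol(scores)
  winner <- apply(scores, 1L, which.min) # which.min takes the first minimum
  ties <- apply(scores, 1L, function(r) sum(r == min(r)) > 1L)
  if (any(ties)) {
    message(sum(ties), " subject(s) had tied best ", criterion,
            "; awarded to the lowest-indexed model")
  }
  counts <- tabulate(winner, k)
  names(counts) <- colnames(scores)
  attr(counts, "n_ties") <- sum(ties)
  attr(counts, "criterion") <- criterion
  counts
}

#' Group-level comparison of fatigue models
#'
#' Aggregates per-subject fits of several candidate models into the three
#' group-level views used to pick a winning model: summed AIC, best-fit
#' counts (by AIC and by RSS), and random-effects Bayesian model selection
#' ([rfx_bms()]) on inverted AICs with Monte-Carlo exceedance
#' probabilities.
#'
#' @param fits Either a `fatigue_cohort_fits` object from [fit_cohort()] or
#'   a data frame with columns `participant`, `model`, `aic`, `rss`.
#' @param prior_alpha,tol Passed to [rfx_bms()].
#' @param ep_samples,seed Passed to [exceedance_prob()].
#' @return An object of class `fatigue_bms`: list with `models`,
#'   `n_subjects`, `summed_aic`, `best_count_aic`, `best_count_rss`,
#'   `alpha`, `expected_frequency`, `exceedance_probability`, and BMS
#'   convergence info.
#' @export
compare_fatigue_models <- function(fits, prior_alpha = 1, tol = 1e-6,
                                   ep_samples = 1e6, seed = 1) {
  tab <- if (inherits(fits, "fatigue_cohort_fits")) fits$table else fits
  needed <- c("participant", "model", "aic", "rss")
  if (!all(needed %in% names(tab))) {
    stop("`fits` must contain columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  models <- unique(tab$model)
  subjects <- unique(tab$participant)
  aic <- matrix(NA_real_, length(subjects), length(models),
                dimnames = list(subjects, models))
  rss <- aic
  for (i in seq_len(nrow(tab))) {
    aic[as.character(tab$participant[i]), tab$model[i]] <- tab$aic[i]
    rss[as.character(tab$participant[i]), tab$model[i]] <- tab$rss[i]
  }
  if (any(is.na(aic))) {
    stop("incomplete fits: every participant needs every model", call. = FALSE)
  }
  bms <- rfx_bms(invert_aic(aic), prior_alpha = prior_alpha, tol = tol)
  ep <- exceedance_prob(bms$alpha, n_samples = ep_samples, seed = seed)
  names(ep) <- models
  names(bms$alpha) <- models
  names(bms$expected_frequency) <- models
  structure(list(
    models = models, n_subjects = length(subjects),
    summed_aic = colSums(aic),
    best_count_aic = suppressMessages(best_fit_counts(aic, "aic")),
    best_count_rss = suppressMessages(best_fit_counts(rss, "rss")),
    alpha = bms$alpha,
    expected_frequency = bms$expected_frequency,
    exceedance_probability = ep,
    bms_n_iter = bms$n_iter,
    prior_alpha = prior_alpha, ep_samples = ep_samples, seed = seed
  ), class = "fatigue_bms")
}

#' @export
print.fatigue_bms <- function(x, digits = 3, ...) {
  cat("Group-level fatigue model comparison (", x$n_subjects,
      " subjects, ", length(x$models), " models)\n", sep = "")
  tab <- data.frame(
    model = x$models,
    summed_AIC = round(unname(x$summed_aic), 1),
    best_AIC = unname(as.integer(x$best_count_aic)),
    best_RSS = unname(as.integer(x$best_count_rss)),
    exp_freq = round(unname(x$expected_frequency), digits),
    exceedance_p = round(unname(x$exceedance_probability), digits)
  )
  print(tab, row.names = FALSE)
  win <- x$models[which.max(x$exceedance_probability)]
  cat("Winning model by exceedance probability:", win, "\n")
  invisible(x)
}
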