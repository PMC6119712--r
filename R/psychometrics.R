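# two-parameter logistic detection curve: P(t) = 1 / (1 + exp(-a (t - ddt)))
predict_logistic <- function(steepness, ddt, t) {
  1 / (1 + exp(-steepness * (t - ddt)))
}

#' Per-delay detection proportions for one patient and condition
#'
#' Aggregates raw forced-choice responses into the observed detection
#' probability at each delay level: the fraction of "delayed" answers
#' among the sets run at that level.
#'
#' @param trials data.frame of trials for a single patient x condition
#'   (columns delay_ms, response; extra columns ignored).
#' @param delays expected delay levels; every level must be present.
#' @return object of class `detection_curve`: data.frame with columns
#'   `delay_ms` (ascending) and `prob`, plus attributes
#'   `trials_per_point`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' tr <- generate_trials(cohort$patients[1, ], cohort$truth, seed = 1)
#' detection_curve(tr[tr$condition == "active", ])
#' @export
detection_curve <- function(trials, delays = vmti_delays()) {
  if (!all(trials$response %in% c("delayed", "not_delayed"))) {
    stop("responses must be 'delayed' or 'not_delayed'")
  }
  if (length(unique(trials$patient_id)) > 1 ||
      length(unique(trials$condition)) > 1) {
    stop("detection_curve expects trials from a single patient x condition")
  }
  if (!all(delays %in% trials$delay_ms)) {
    stop("missing delay level(s): ",
         paste(setdiff(delays, trials$delay_ms), collapse = ", "))
  }
  counts <- table(factor(trials$delay_ms, levels = sort(delays)),
                  factor(trials$response, levels = c("delayed", "not_delayed")))
  n_per <- rowSums(counts)
  out <- data.frame(delay_ms = sort(delays),
                    prob = as.numeric(counts[, "delayed"] / n_per))
  attr(out, "trials_per_point") <- as.integer(n_per)
  class(out) <- c("detection_curve", "data.frame")
  out
}

#' Fit the logistic psychometric function to a detection curve
#'
#' Minimises the unweighted residual sum of squares between the observed
#' per-delay detection proportions and
#' \eqn{P(t) = 1/(1 + \exp(-a [t - t_{DDT}]))} with a bounded
#' Levenberg-Marquardt least-squares optimiser, multi-started from three
#' initial values to guard against local minima. Degenerate curves that
#' never or always report a delay leave both parameters unidentified and
#' are returned as failed fits rather than boundary estimates.
#'
#' @param curve a [detection_curve()] (or data.frame with `delay_ms`,
#'   `prob`).
#' @param lower,upper bounds on (steepness, ddt); defaults
#'   `c(1e-4, 0)` and `c(1, 1200)` so the threshold may exceed the
#'   largest tested delay.
#' @param starts matrix of initial values, one row per start
#'   (columns steepness, ddt).
#' @return object of class `psychometric_fit`: list with `steepness`
#'   (1/ms), `ddt` (ms), `rss`, `converged`, `boundary_hit`, and the
#'   fitted `curve`.
#' @examples
#' d <- vmti_delays()
#' curve <- data.frame(delay_ms = d, prob = predict_logistic(0.02, 300, d))
#' fit_psychometric(curve)
#' @export
fit_psychometric <- function(curve, lower = c(1e-4, 0), upper = c(1, 1200),
                             starts = rbind(c(0.01, 300), c(0.005, 150),
                                            c(0.05, 450))) {
  t <- curve$delay_ms
  p <- curve$prob
  if (anyNA(p) || any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  fail <- structure(list(steepness = NA_real_, ddt = NA_real_,
                         rss = NA_real_, converged = FALSE,
                         boundary_hit = TRUE, curve = curve),
                    class = "psychometric_fit")
  if (all(p == 0) || all(p == 1)) return(fail)  # unidentifiable
  resid_fun <- function(par) p - predict_logistic(par[1], par[2], t)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ], lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                           maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) return(fail)
  tol <- 1e-8
  boundary <- any(abs(best$par - lower) < tol * pmax(1, abs(lower)) + 1e-12) ||
    any(abs(best$par - upper) < tol * pmax(1, abs(upper)) + 1e-12)
  structure(list(steepness = unname(best$par[1]), ddt = unname(best$par[2]),
                 rss = best$rss,
                 # info 1-4: converged; 6-8: tolerances tighter than
                 # attainable precision; 5 with an (essentially) exact fit:
                 # the optimiser keeps polishing machine-level residuals
                 converged = (best$info %in% c(1:4, 6:8) ||
                                (best$info == 5 && best$rss < 1e-8)) &&
                   best$par[1] > 0,
                 boundary_hit = boundary, curve = curve),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Logistic psychometric fit\n")
  cat(sprintf("  steepness a : %.5f /ms\n", x$steepness))
  cat(sprintf("  DDT         : %.1f ms\n", x$ddt))
  cat(sprintf("  RSS         : %.6g\n", x$rss))
  cat(sprintf("  converged   : %s   boundary: %s\n",
              x$converged, x$boundary_hit))
  invisible(x)
}

#' Predicted detection probability from a fitted curve
#'
#' Evaluates \eqn{P(t) = 1/(1 + \exp(-a [t - t_{DDT}]))} at new delays;
#' strictly increasing in `t` for positive steepness, with
#' \eqn{P(t_{DDT}) = 0.5} by definition of the delay detection
#' threshold.
#'
#' @param fit a converged [fit_psychometric()] result.
#' @param t delay(s) in ms.
#' @return probability vector.
#' @export
predict_detection <- function(fit, t) {
  if (!isTRUE(fit$converged)) stop("fit did not converge; no prediction")
  predict_logistic(fit$steepness, fit$ddt, t)
}

#' Fit psychometric curves for every patient and condition
#'
#' @param trials trial data.frame as from [generate_trials()].
#' @param ... passed to [fit_psychometric()].
#' @return data.frame with one row per patient x condition: patient_id,
#'   condition, steepness, ddt, rss, converged, boundary_hit.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' trials <- generate_trials(cohort$patients, cohort$truth, seed = 1)
#' head(fit_cohort(trials))
#' @export
fit_cohort <- function(trials, ...) {
  cells <- unique(trials[, c("patient_id", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$patient_id == cells$patient_id[i] &
                    trials$condition == cells$condition[i], ]
    fit <- fit_psychometric(detection_curve(sub), ...)
    data.frame(patient_id = cells$patient_id[i],
               condition = cells$condition[i],
               steepness = fit$steepness, ddt = fit$ddt, rss = fit$rss,
               converged = fit$converged, boundary_hit = fit$boundary_hit)
  }))
  rownames(out) <- NULL
  out
}

#' Trial-level Bernoulli-likelihood cross-check fit
#'
#' Optional maximum-likelihood fit of the same two-parameter logistic to
#' the raw binary responses, provided as a cross-check on the default
#' least-squares fit to aggregated proportions.
#'
#' @param trials trials for one patient x condition.
#' @param lower,upper parameter bounds as in [fit_psychometric()].
#' @return list with `steepness`, `ddt`, `logLik`, `converged`.
#' @export
fit_psychometric_mle <- function(trials, lower = c(1e-4, 0),
                                 upper = c(1, 1200)) {
  y <- as.integer(trials$response == "delayed")
  t <- trials$delay_ms
  nll <- function(par) {
    p <- pmin(pmax(predict_logistic(par[1], par[2], t), 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- stats::optim(c(0.01, 300), nll, method = "L-BFGS-B",
                      lower = lower, upper = upper)
  list(steepness = opt$par[1], ddt = opt$par[2], logLik = -opt$value,
       converged = opt$convergence == 0)
}
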