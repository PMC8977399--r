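# stratified fold labels: cases and controls each split as evenly as possible
stratified_folds <- function(y, folds) {
  lab <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    lab[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  lab
}

# every fold must leave a training set with both classes and a test set that
# can score sNB (at least one case)
folds_usable <- function(y, lab, folds) {
  for (f in seq_len(folds)) {
    test <- lab == f
    if (sum(y[test] == 1L) == 0L || sum(y[test] == 0L) == 0L) return(FALSE)
    if (sum(y[!test] == 1L) == 0L || sum(y[!test] == 0L) == 0L) return(FALSE)
  }
  TRUE
}

spec_with_candidate <- function(template, candidate) {
  if (template$form == "exponential") {
    weight_spec("exponential", lambda = candidate, delta = template$delta,
                interval = template$interval)
  } else {
    weight_spec("step", lambda = template$lambda, delta = candidate,
                interval = template$interval)
  }
}

#' Cross-validated tuning of the recalibration weight function
#'
#' Selects the single tuning parameter of the weight family (`lambda` for
#' the exponential form, `delta` for the step form) by repeated stratified
#' k-fold cross-validation. For each candidate and each replication, smoothed
#' event rates and weights are computed on the training folds only, a
#' weighted recalibration is fitted there, and the held-out fold is scored by
#' the sNB of the recalibrated scores at the clinical threshold. Selection
#' uses a 1-SE rule oriented toward standard recalibration: among candidates
#' whose mean CV sNB is within one standard error of the best, the one whose
#' weights are closest to all-ones wins (largest `lambda`, or `delta`
#' closest to 1), so the weighted method falls back towards the standard fit
#' when the data do not support targeted weighting.
#'
#' @inheritParams snb_at_cutpoint
#' @param spec_template A [weight_spec()] whose tuning parameter will be
#'   replaced by each candidate in turn.
#' @param candidates Numeric vector of candidate values for the tuning
#'   parameter. Defaults: log-spaced `lambda` in \[1e-4, 10\] for the
#'   exponential form; `delta` in {0.01, 0.1, 0.25, 0.5, 0.75, and the
#'   largest admissible value} for the step form.
#' @param reps Number of cross-validation replications.
#' @param folds Number of folds per replication.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param span LOESS span for the training-fold event-rate smoother.
#' @return A `cv_result`: list with `results` (tibble of candidate, mean CV
#'   sNB, SE over replications), `selected`, the selected `spec`, `reps`,
#'   `folds`.
#' @export
cv_select <- function(data, spec_template, candidates = NULL, threshold,
                      reps = 25, folds = 5, seed = NULL, span = 0.75) {
  check_threshold(threshold)
  data <- as_cohort(data)
  require_both_classes(data, "cross-validated tuning")
  stopifnot(inherits(spec_template, "weight_spec"))
  if (is.null(candidates)) {
    candidates <- if (spec_template$form == "exponential") {
      10^seq(-4, 1, length.out = 7)
    } else {
      dmax <- exp(-max((spec_template$interval - threshold)^2) /
                    spec_template$lambda)
      sort(unique(pmin(c(0.01, 0.1, 0.25, 0.5, 0.75, dmax), dmax)))
    }
  }
  candidates <- sort(unique(as.double(candidates)))
  run <- function() {
    if (length(candidates) == 1) {
      return(cv_result(candidates, NA_real_, NA_real_, candidates[1],
                       spec_template, reps, folds, threshold))
    }
    n <- nrow(data)
    per_rep <- matrix(NA_real_, nrow = reps, ncol = length(candidates))
    for (r in seq_len(reps)) {
      lab <- NULL
      for (attempt in seq_len(100)) {
        cand_lab <- stratified_folds(data$y, folds)
        if (folds_usable(data$y, cand_lab, folds)) { lab <- cand_lab; break }
      }
      if (is.null(lab)) {
        stop("could not draw stratified folds with both classes in every fold.",
             call. = FALSE)
      }
      fold_snb <- matrix(NA_real_, nrow = folds, ncol = length(candidates))
      for (f in seq_len(folds)) {
        train <- data[lab != f, , drop = FALSE]
        test <- data[lab == f, , drop = FALSE]
        o_train <- smoothed_event_rate(train, span = span)
        for (ci in seq_along(candidates)) {
          spec <- spec_with_candidate(spec_template, candidates[ci])
          w <- compute_weights(o_train, spec, threshold)
          fit <- tryCatch(fit_weighted(train, w), error = function(e) NULL)
          if (is.null(fit)) next
          fold_snb[f, ci] <- snb_of_model(test, fit, threshold)
        }
      }
      per_rep[r, ] <- colMeans(fold_snb, na.rm = TRUE)
    }
    cv_mean <- colMeans(per_rep, na.rm = TRUE)
    cv_se <- apply(per_rep, 2, function(v) stats::sd(v, na.rm = TRUE)) /
      sqrt(reps)
    if (reps == 1) cv_se <- rep(0, length(candidates))
    best <- which.max(cv_mean)
    within <- which(cv_mean >= cv_mean[best] - cv_se[best])
    # toward standard recalibration: largest lambda / delta closest to 1
    selected <- if (spec_template$form == "exponential") {
      max(candidates[within])
    } else {
      candidates[within][which.min(abs(candidates[within] - 1))]
    }
    cv_result(candidates, cv_mean, cv_se, selected, spec_template, reps,
              folds, threshold)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

cv_result <- function(candidates, cv_mean, cv_se, selected, template, reps,
                      folds, threshold) {
  structure(
    list(results = tibble::tibble(candidate = candidates,
                                  cv_snb_mean = cv_mean,
                                  cv_snb_se = cv_se),
         selected = selected,
         spec = spec_with_candidate(template, selected),
         form = template$form, reps = reps, folds = folds,
         threshold = threshold),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  par_name <- if (x$form == "exponential") "lambda" else "delta"
  cat(sprintf("CV tuning of %s (%d x %d-fold, R = %g): selected %s = %g\n",
              par_name, x$reps, x$folds, x$threshold, par_name, x$selected))
  print(x$results)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$results

#' Plot cross-validation results for the weight tuning parameter
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot of mean held-out sNB (with 1-SE bars) per candidate; the
#'   selected candidate is highlighted.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$results
  par_name <- if (object$form == "exponential") "lambda" else "delta"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$candidate,
                                        y = .data$cv_snb_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$cv_snb_mean - .data$cv_snb_se,
      ymax = .data$cv_snb_mean + .data$cv_snb_se)) +
    ggplot2::geom_vline(xintercept = object$selected, linetype = "dotted") +
    ggplot2::labs(x = par_name, y = "held-out sNB at R") +
    ggplot2::theme_minimal()
  if (object$form == "exponential") p <- p + ggplot2::scale_x_log10()
  p
}
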