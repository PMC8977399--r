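#' Bootstrap optimism correction for sNB of a recalibration procedure
#'
#' Harrell-style internal validation. The apparent sNB of a fitting procedure
#' is optimistic because the model is evaluated on the data that trained it.
#' For each of `B` bootstrap resamples the full procedure (including any
#' cross-validated tuning it contains) is refitted; the optimism of that
#' replicate is the model's sNB on its own resample minus its sNB on the
#' original sample. The mean optimism is subtracted from the apparent sNB.
#' Percentile confidence intervals are formed from the bootstrap apparent
#' sNB values. Several procedures can be validated on one shared resampling
#' stream for paired comparison.
#'
#' @inheritParams snb_at_cutpoint
#' @param fit_procedure A function `data -> recal_model` (for example
#'   `fit_standard`, or a closure wrapping tuning plus [fit_weighted()]), or
#'   a named list of such functions evaluated on the same resamples. A fixed
#'   `recal_model` may also be passed: it is then never refitted and its
#'   optimism is pure Monte-Carlo noise around zero.
#' @param B Number of bootstrap replications.
#' @param seed Integer seed making the resampling stream reproducible.
#' @param conf_level Level of the percentile interval.
#' @return A `boot_result` (or a named list of them): fields `apparent_snb`,
#'   `optimism`, `corrected_snb`, `ci_lower`, `ci_upper`, `replications`,
#'   plus bootstrap-mean `tpr_boot`/`fpr_boot` and apparent `tpr`/`fpr` at
#'   the threshold.
#' @examples
#' set.seed(2)
#' p <- rbeta(300, 2, 5)
#' dat <- data.frame(y = rbinom(300, 1, p), s = p)
#' bootstrap_optimism(dat, fit_standard, threshold = 0.3, B = 25, seed = 1)
#' @export
bootstrap_optimism <- function(data, fit_procedure, threshold, B = 500,
                               seed = NULL, conf_level = 0.95) {
  check_threshold(threshold)
  data <- as_cohort(data)
  require_both_classes(data, "bootstrap validation")
  single <- !is.list(fit_procedure) || inherits(fit_procedure, "recal_model")
  procs <- if (single) list(model = fit_procedure) else fit_procedure
  procs <- lapply(procs, function(p) {
    if (inherits(p, "recal_model")) {
      force(p)
      function(d) p   # frozen map: never refitted
    } else if (is.function(p)) p else
      stop("`fit_procedure` must be a function, a recal_model, or a list of them.",
           call. = FALSE)
  })
  n <- nrow(data)
  run <- function() {
    apparent <- lapply(procs, function(fp) {
      m <- fp(data)
      sc <- recal_as_scores(data, m)
      rates <- classification_rates(sc, threshold)
      list(snb = snb_at_cutpoint(sc, threshold), tpr = rates$tpr,
           fpr = rates$fpr)
    })
    opt <- matrix(NA_real_, B, length(procs))
    boot_app <- matrix(NA_real_, B, length(procs))
    boot_tpr <- matrix(NA_real_, B, length(procs))
    boot_fpr <- matrix(NA_real_, B, length(procs))
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- data$y[idx]
        if (any(yb == 1L) && any(yb == 0L)) break
        redraws <- redraws + 1L
        if (redraws > 0.1 * B) {
          stop("more than 10% of bootstrap resamples lacked both classes.",
               call. = FALSE)
        }
      }
      boot <- data[idx, , drop = FALSE]
      for (j in seq_along(procs)) {
        m <- tryCatch(procs[[j]](boot), error = function(e) NULL)
        if (is.null(m)) next
        sc_boot <- recal_as_scores(boot, m)
        boot_app[b, j] <- snb_at_cutpoint(sc_boot, threshold)
        opt[b, j] <- boot_app[b, j] - snb_of_model(data, m, threshold)
        rb <- classification_rates(sc_boot, threshold)
        boot_tpr[b, j] <- rb$tpr
        boot_fpr[b, j] <- rb$fpr
      }
    }
    a <- (1 - conf_level) / 2
    res <- lapply(seq_along(procs), function(j) {
      optimism <- mean(opt[, j], na.rm = TRUE)
      ci <- stats::quantile(boot_app[, j], c(a, 1 - a), na.rm = TRUE,
                            names = FALSE)
      structure(list(apparent_snb = apparent[[j]]$snb,
                     optimism = optimism,
                     corrected_snb = apparent[[j]]$snb - optimism,
                     ci_lower = ci[1], ci_upper = ci[2],
                     conf_level = conf_level,
                     replications = B,
                     tpr = apparent[[j]]$tpr, fpr = apparent[[j]]$fpr,
                     tpr_boot = mean(boot_tpr[, j], na.rm = TRUE),
                     fpr_boot = mean(boot_fpr[, j], na.rm = TRUE),
                     threshold = threshold),
                class = "boot_result")
    })
    names(res) <- names(procs)
    if (single) res[[1]] else res
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("bootstrap internal validation (B = %d, R = %g)\n",
              x$replications, x$threshold))
  cat(sprintf("  apparent sNB  : %.3f (%.0f%% CI %.3f, %.3f)\n",
              x$apparent_snb, 100 * x$conf_level, x$ci_lower, x$ci_upper))
  cat(sprintf("  optimism      : %.3f\n", x$optimism))
  cat(sprintf("  corrected sNB : %.3f\n", x$corrected_snb))
  cat(sprintf("  TPR/FPR at R  : %.3f / %.3f (bootstrap means %.3f / %.3f)\n",
              x$tpr, x$fpr, x$tpr_boot, x$fpr_boot))
  invisible(x)
}

#' @export
glance.boot_result <- function(x, ...) {
  tibble::tibble(apparent_snb = x$apparent_snb, optimism = x$optimism,
                 corrected_snb = x$corrected_snb, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, replications = x$replications,
                 tpr = x$tpr, fpr = x$fpr,
                 tpr_boot = x$tpr_boot, fpr_boot = x$fpr_boot)
}
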