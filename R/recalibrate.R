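ALPHA1_MIN <- 1e-6

new_recal_model <- function(alpha0, alpha1, method, eff, converged,
                            loglik, n, constraint_bound = NA_real_) {
  structure(list(alpha0 = alpha0, alpha1 = alpha1, method = method,
                 effective_sample_proportion = eff, converged = converged,
                 loglik = loglik, n = n, constraint_bound = constraint_bound),
            class = "recal_model")
}

#' Apply a logistic recalibration map to risk scores
#'
#' The two-parameter Cox family: s' = expit(alpha0 + alpha1 * logit(s)).
#' With a positive slope the map is strictly increasing, so the rank order
#' of the scores is preserved and the result is a valid recalibration.
#'
#' @param model A fitted `recal_model`, or a numeric vector
#'   `c(alpha0, alpha1)`.
#' @param s Risk scores in (0, 1); values at the boundary are clipped.
#' @return Recalibrated risks in (0, 1).
#' @examples
#' apply_recal(c(-0.911, 0.856), 0.5)  # expit(-0.911)
#' @export
apply_recal <- function(model, s) {
  if (inherits(model, "recal_model")) {
    a0 <- model$alpha0; a1 <- model$alpha1
  } else {
    stopifnot(is.numeric(model), length(model) == 2)
    a0 <- model[1]; a1 <- model[2]
  }
  if (!is.finite(a1) || a1 <= 0) {
    stop("recalibration slope must be positive for a valid (monotone) map.",
         call. = FALSE)
  }
  s <- pmin(pmax(s, 1e-10), 1 - 1e-10)
  plogis(a0 + a1 * qlogis(s))
}

#' Recalibrate the scores of a cohort
#'
#' Pipeline-friendly wrapper around [apply_recal()]: returns the cohort with
#' an `s_recal` column holding the recalibrated risks.
#'
#' @inheritParams snb_at_cutpoint
#' @inheritParams apply_recal
#' @return The cohort tibble with an `s_recal` column.
#' @export
recalibrate <- function(data, model) {
  data <- as_cohort(data)
  data$s_recal <- apply_recal(model, data$s)
  data
}

# weighted Bernoulli negative log-likelihood and gradient on the logit scale;
# log(1 + e^eta) computed in its overflow-safe form
wnll <- function(par, z, y, w) {
  eta <- par[1] + par[2] * z
  softplus <- pmax(eta, 0) + log1p(exp(-abs(eta)))
  -sum(w * (y * eta - softplus))
}
wnll_grad <- function(par, z, y, w) {
  eta <- par[1] + par[2] * z
  resid <- w * (y - plogis(eta))
  -c(sum(resid), sum(resid * z))
}

fit_weighted_core <- function(z, y, w, start = c(0, 1)) {
  opt <- stats::optim(start, fn = wnll, gr = wnll_grad, z = z, y = y, w = w,
                      method = "L-BFGS-B",
                      lower = c(-Inf, ALPHA1_MIN),
                      control = list(maxit = 500, factr = 1e4))
  g <- wnll_grad(opt$par, z, y, w)
  # at an interior optimum the gradient vanishes; on the slope bound only the
  # intercept component must
  at_bound <- opt$par[2] <= ALPHA1_MIN * (1 + 1e-8)
  gnorm <- if (at_bound) abs(g[1]) else sqrt(sum(g^2))
  # complete separation of the (positively weighted) classes on the logit
  # score: the likelihood has no finite maximizer
  separated <- min(z[y == 1L & w > 0]) > max(z[y == 0L & w > 0])
  list(par = opt$par, loglik = -opt$value,
       converged = !separated && opt$convergence == 0 && is.finite(gnorm) &&
         gnorm < 1e-4 * max(1, length(y)))
}

#' Standard (Cox) logistic recalibration
#'
#' Regresses the outcome on the logit-transformed risk score; the fitted
#' intercept and slope define the recalibration map
#' `expit(alpha0 + alpha1 * logit(s))`. Identical to [fit_weighted()] with
#' all weights equal to 1.
#'
#' @inheritParams snb_at_cutpoint
#' @return A `recal_model` with fields `alpha0`, `alpha1`, `method`,
#'   `effective_sample_proportion`, `converged`, `loglik`. Under complete
#'   separation the likelihood has no finite maximizer and `converged` is
#'   `FALSE`.
#' @examples
#' set.seed(1)
#' p <- rbeta(400, 2, 5)
#' dat <- data.frame(y = rbinom(400, 1, p), s = p)
#' fit_standard(dat)  # close to the identity map (0, 1)
#' @export
fit_standard <- function(data) {
  data <- as_cohort(data)
  require_both_classes(data, "logistic recalibration")
  if (length(unique(data$s)) < 2) {
    stop("need at least 2 distinct risk scores to fit a recalibration slope.",
         call. = FALSE)
  }
  fit <- fit_weighted_core(qlogis(data$s), data$y, rep(1, nrow(data)))
  new_recal_model(fit$par[1], fit$par[2], "standard", 1, fit$converged,
                  fit$loglik, nrow(data))
}

#' Weighted logistic recalibration
#'
#' Maximizes the weighted Bernoulli likelihood
#' \deqn{\prod_i p(z_i)^{w_i y_i} (1 - p(z_i))^{w_i (1 - y_i)}}
#' with \eqn{p(z) = expit(\alpha_0 + \alpha_1 z)}, z the logit score.
#' Subjects whose smoothed event rate sits near the clinical threshold carry
#' full weight, so the fit prioritizes calibration where treatment decisions
#' are made. With all weights 1 this is standard logistic recalibration.
#'
#' @inheritParams snb_at_cutpoint
#' @param w Weights in \[0, 1\], one per row of `data` (see
#'   [compute_weights()]); alternatively `data` may carry a `weight` column.
#' @return A `recal_model`; `effective_sample_proportion` records the mean
#'   weight.
#' @export
fit_weighted <- function(data, w = NULL) {
  data <- as_cohort(data)
  require_both_classes(data, "weighted logistic recalibration")
  if (is.null(w)) {
    if (!"weight" %in% names(data)) {
      stop("supply `w` or a `weight` column (see add_weights()).", call. = FALSE)
    }
    w <- data$weight
  }
  if (length(w) != nrow(data)) {
    stop("`w` must have one weight per subject.", call. = FALSE)
  }
  eff <- effective_sample_proportion(w)
  if (sum(w) < 10) {
    stop(sprintf(
      "effective sample too small (sum of weights %.2f < 10) to identify intercept and slope.",
      sum(w)), call. = FALSE)
  }
  fit <- fit_weighted_core(qlogis(data$s), data$y, w)
  new_recal_model(fit$par[1], fit$par[2], "weighted", eff, fit$converged,
                  fit$loglik, nrow(data))
}

# sNB of the rule z > c as a step function of the cutpoint c (logit scale).
# Returns the knots u (distinct sorted z) and the value on each piece:
# value[j] is the sNB on [u[j], u[j+1]) ; value[0-th] (treat z > -Inf ... )
# handled by the caller via the leading piece (-Inf, u[1]).
snb_step_logit <- function(z, y, threshold) {
  u <- sort(unique(z))
  n_case <- sum(y == 1L); n_ctrl <- sum(y == 0L)
  k <- snb_discount(n_case / length(y), threshold)
  zc <- sort(z[y == 1L]); zn <- sort(z[y == 0L])
  # piece values at cutpoints u[j] (rule z > u[j]) plus the treat-all piece
  cuts <- c(min(u) - 1, u)
  tpr <- (n_case - findInterval(cuts, zc)) / n_case
  fpr <- (n_ctrl - findInterval(cuts, zn)) / n_ctrl
  list(knots = u, cuts = cuts, value = tpr - k * fpr)
}

# maximal intervals [lo, hi) of the cutpoint axis where the step sNB >= bound
feasible_cutpoint_intervals <- function(step, bound) {
  ok <- step$value >= bound - 1e-12
  if (!any(ok)) return(list())
  # piece j covers [cuts[j], next knot); the first piece extends to -Inf
  lo_all <- c(-Inf, step$knots)
  hi_all <- c(step$knots, Inf)
  runs <- rle(ok)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  out <- list()
  for (r in seq_along(runs$values)) {
    if (runs$values[r]) {
      out[[length(out) + 1]] <- c(lo_all[idx_start[r]], hi_all[idx_end[r]])
    }
  }
  out
}

#' Constrained logistic recalibration
#'
#' Maximizes the (unweighted) logistic recalibration likelihood subject to
#' the recalibrated model's plug-in sNB being within one standard error of
#' the maximum achievable sNB. Because the recalibrated treatment rule
#' `expit(a0 + a1 z) > R` is equivalent to `z > c` with
#' `c = (logit R - a0)/a1`, the sNB constraint restricts only the induced
#' cutpoint c to the set of cutpoints whose step-function sNB clears the
#' bound. Each maximal feasible cutpoint interval translates into two linear
#' constraints on (a0, a1); the likelihood is concave, so the global optimum
#' is the best of the per-interval solutions. When the standard solution is
#' already feasible it is returned exactly.
#'
#' @inheritParams snb_at_cutpoint
#' @return A `recal_model` with `method = "constrained"` and the 1-SE bound
#'   recorded in `constraint_bound`.
#' @export
fit_constrained <- function(data, threshold) {
  check_threshold(threshold)
  data <- as_cohort(data)
  require_both_classes(data, "constrained logistic recalibration")
  curve <- snb_curve(data, threshold)
  bound <- snb_constraint_bound(curve$snb_max, curve$se_max)
  z <- qlogis(data$s); y <- data$y
  step <- snb_step_logit(z, y, threshold)
  ivs <- feasible_cutpoint_intervals(step, bound)
  # the argmax cutpoint is always feasible, so ivs is non-empty by construction
  std <- fit_standard(data)
  logitR <- qlogis(threshold)
  c_std <- (logitR - std$alpha0) / std$alpha1
  std_feasible <- any(vapply(ivs, function(iv) c_std >= iv[1] && c_std < iv[2],
                             logical(1)))
  if (std_feasible && std$converged) {
    out <- new_recal_model(std$alpha0, std$alpha1, "constrained", 1,
                           std$converged, std$loglik, nrow(data),
                           constraint_bound = bound)
    return(out)
  }
  zr <- range(z)
  pad <- max(1, diff(zr))
  eps <- 1e-8 * max(1, max(abs(zr)))
  cands <- list()
  for (iv in ivs) {
    lo <- if (is.finite(iv[1])) iv[1] else zr[1] - pad
    hi <- (if (is.finite(iv[2])) iv[2] else zr[2] + pad) - eps
    if (hi <= lo) hi <- lo + eps / 2
    # c(a) in [lo, hi]:  a0 + a1*lo <= logitR  and  a0 + a1*hi >= logitR
    ui <- rbind(c(-1, -lo), c(1, hi), c(0, 1))
    ci <- c(-logitR, logitR, ALPHA1_MIN)
    c0 <- (lo + hi) / 2
    start <- c(logitR - c0, 1)
    if (any(ui %*% start - ci <= 0)) start <- c(logitR - c0, max(1, ALPHA1_MIN * 2))
    opt <- tryCatch(
      stats::constrOptim(start, f = wnll, grad = wnll_grad,
                         ui = ui, ci = ci, method = "BFGS",
                         outer.iterations = 200, outer.eps = 1e-8,
                         z = z, y = y, w = rep(1, length(y))),
      error = function(e) NULL)
    if (!is.null(opt)) {
      cands[[length(cands) + 1]] <-
        list(par = opt$par, loglik = -opt$value,
             converged = opt$convergence == 0,
             cut = (logitR - opt$par[1]) / opt$par[2])
    }
  }
  if (length(cands) == 0) {
    stop("constrained recalibration failed on every feasible cutpoint interval.",
         call. = FALSE)
  }
  ll <- vapply(cands, `[[`, numeric(1), "loglik")
  best <- which(ll >= max(ll) - 1e-9)
  if (length(best) > 1) {
    # likelihood ties: prefer the solution whose induced cutpoint is nearest R
    cutd <- vapply(cands[best], function(cc) abs(cc$cut - logitR), numeric(1))
    best <- best[which.min(cutd)]
  } else {
    best <- best[1]
  }
  ch <- cands[[best]]
  new_recal_model(ch$par[1], ch$par[2], "constrained", 1, ch$converged,
                  ch$loglik, nrow(data), constraint_bound = bound)
}

#' Fit a recalibration model by method name
#'
#' One entry point over the three estimators. For `"weighted"`, either a
#' `weight_spec` is supplied (weights computed from smoothed event rates) or
#' tuning candidates are cross-validated first via [cv_select()].
#'
#' @inheritParams snb_at_cutpoint
#' @param method `"standard"`, `"weighted"` or `"constrained"`.
#' @param spec A [weight_spec()] (weighted method only).
#' @param w Optional explicit weights (weighted method only).
#' @param span LOESS span used when weights are derived from `spec`.
#' @return A `recal_model`.
#' @export
fit_recal <- function(data, method = c("standard", "weighted", "constrained"),
                      threshold = NULL, spec = NULL, w = NULL, span = 0.75) {
  method <- match.arg(method)
  switch(method,
    standard = fit_standard(data),
    constrained = {
      if (is.null(threshold)) stop("constrained recalibration needs `threshold`.",
                                   call. = FALSE)
      fit_constrained(data, threshold)
    },
    weighted = {
      if (is.null(w)) {
        if (is.null(spec) || is.null(threshold)) {
          stop("weighted recalibration needs `w`, or a `spec` plus `threshold`.",
               call. = FALSE)
        }
        o <- smoothed_event_rate(data, span = span)
        w <- compute_weights(o, spec, threshold)
      }
      fit_weighted(data, w)
    })
}

#' Plug-in sNB of a recalibration map
#'
#' Evaluates the sNB of the treatment rule `expit(alpha0 + alpha1 z) > R`
#' on a cohort; equal to [snb_at_cutpoint()] applied to the recalibrated
#' scores at cutpoint R.
#'
#' @inheritParams snb_at_cutpoint
#' @inheritParams apply_recal
#' @return Scalar sNB.
#' @export
snb_of_model <- function(data, model, threshold) {
  snb_at_cutpoint(recal_as_scores(data, model), threshold)
}

recal_as_scores <- function(data, model) {
  data <- as_cohort(data)
  tibble::tibble(y = data$y, s = apply_recal(model, data$s))
}

#' @export
print.recal_model <- function(x, ...) {
  cat(sprintf("%s logistic recalibration (n = %d)\n", x$method, x$n))
  cat(sprintf("  alpha0 = %.4f, alpha1 = %.4f\n", x$alpha0, x$alpha1))
  cat(sprintf("  effective sample proportion = %.2f, log-lik = %.3f, converged: %s\n",
              x$effective_sample_proportion, x$loglik, x$converged))
  if (is.finite(x$constraint_bound)) {
    cat(sprintf("  sNB constraint bound = %.4f\n", x$constraint_bound))
  }
  invisible(x)
}

#' @export
tidy.recal_model <- function(x, ...) {
  tibble::tibble(term = c("alpha0", "alpha1"),
                 estimate = c(x$alpha0, x$alpha1))
}

#' @export
glance.recal_model <- function(x, ...) {
  tibble::tibble(method = x$method, alpha0 = x$alpha0, alpha1 = x$alpha1,
                 effective_sample_proportion = x$effective_sample_proportion,
                 loglik = x$loglik, converged = x$converged,
                 constraint_bound = x$constraint_bound, n = x$n)
}

#' @export
predict.recal_model <- function(object, newdata, ...) {
  s <- if (is.data.frame(newdata)) newdata$s else newdata
  apply_recal(object, s)
}
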