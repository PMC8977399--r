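#' Graphical assessment of the potential gain in sNB from recalibration
#'
#' Computes the sNB-vs-cutpoint curve, the sNB of the original score and of
#' the score after standard logistic recalibration, and applies the 1-SE
#' rule: a model whose sNB falls more than one standard error below the
#' maximum achievable sNB is flagged as having room for improvement. When
#' the original score is flagged but the standard recalibration is not,
#' standard recalibration suffices; when both are flagged, recalibration
#' methods that target the threshold (weighted or constrained) may be
#' worthwhile.
#'
#' @inheritParams snb_at_cutpoint
#' @return A `potential_gain` object: the `snb_curve`, `snb_original`,
#'   `snb_standard`, `one_se_line`, the two flags, and the standard fit.
#' @examples
#' dat <- simulate_cohort(make_scenario("example1"), n = 2000, seed = 3)
#' assess_potential_gain(dat, threshold = 0.3)
#' @export
assess_potential_gain <- function(data, threshold) {
  data <- as_cohort(data)
  curve <- snb_curve(data, threshold)
  std <- fit_standard(data)
  snb_original <- curve$snb_at_R
  snb_standard <- snb_of_model(data, std, threshold)
  one_se <- snb_constraint_bound(curve$snb_max, curve$se_max)
  structure(list(curve = curve,
                 snb_original = snb_original,
                 snb_standard = snb_standard,
                 one_se_line = one_se,
                 flag_original_below = snb_original < one_se,
                 flag_standard_below = snb_standard < one_se,
                 standard_fit = std,
                 threshold = threshold),
            class = "potential_gain")
}

#' @export
print.potential_gain <- function(x, ...) {
  cat(sprintf("potential sNB under recalibration (R = %g)\n", x$threshold))
  cat(sprintf("  original score        : sNB = %.3f%s\n", x$snb_original,
              if (x$flag_original_below) "  [> 1 SE below max]" else ""))
  cat(sprintf("  standard recalibration: sNB = %.3f%s\n", x$snb_standard,
              if (x$flag_standard_below) "  [> 1 SE below max]" else ""))
  cat(sprintf("  max achievable        : %.3f (1-SE line at %.3f)\n",
              x$curve$snb_max, x$one_se_line))
  msg <- if (!x$flag_original_below) {
    "the original score is already near the maximum; recalibration offers little."
  } else if (!x$flag_standard_below) {
    "standard logistic recalibration reaches near-maximal sNB."
  } else {
    "standard recalibration stays > 1 SE below the maximum; threshold-targeted methods may help."
  }
  cat("  interpretation: ", msg, "\n", sep = "")
  invisible(x)
}

#' @export
glance.potential_gain <- function(x, ...) {
  tibble::tibble(snb_original = x$snb_original,
                 snb_standard = x$snb_standard,
                 snb_max = x$curve$snb_max,
                 se_max = x$curve$se_max,
                 one_se_line = x$one_se_line,
                 flag_original_below = x$flag_original_below,
                 flag_standard_below = x$flag_standard_below,
                 threshold = x$threshold)
}

#' Plot the potential-gain assessment
#'
#' The sNB-vs-cutpoint curve with the dotted 1-SE line and labelled points
#' for the original and standard-recalibrated models.
#'
#' @param object A `potential_gain`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potential_gain <- function(object, ...) {
  pts <- tibble::tibble(
    cutpoint = object$threshold,
    snb = c(object$snb_original, object$snb_standard),
    model = c("original", "standard recal."))
  autoplot(object$curve) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$cutpoint, y = .data$snb,
                                     shape = .data$model), size = 2.5) +
    ggplot2::labs(shape = NULL)
}

#' Write analysis artifacts to disk
#'
#' Writes, next to every plot, the machine-readable data behind it: an
#' `snb_curve` becomes a TSV of (cutpoint, snb), a JSON summary and a PNG; a
#' `cal_curve` a TSV and PNG; a `recal_model` or `boot_result` a JSON; a
#' `potential_gain` all of the above.
#'
#' @param x Object to render.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files.
#' @param ... Unused.
#' @return Character vector of the paths written, invisibly.
#' @export
render_outputs <- function(x, dir, name, ...) UseMethod("render_outputs")

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  dir
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

save_plot <- function(p, path) {
  ggplot2::ggsave(path, plot = p, width = 6, height = 4.5, dpi = 150)
  path
}

#' @export
render_outputs.snb_curve <- function(x, dir, name = "snb_curve", ...) {
  ensure_dir(dir)
  if (nrow(x$curve) == 0) stop("empty sNB curve; nothing to render.",
                               call. = FALSE)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(x$curve, tsv, progress = FALSE)
  js <- write_json_file(list(snb_at_R = x$snb_at_R, snb_max = x$snb_max,
                             r_star = x$r_star, se_max = x$se_max,
                             threshold = x$threshold),
                        file.path(dir, paste0(name, ".json")))
  png <- save_plot(autoplot(x), file.path(dir, paste0(name, ".png")))
  invisible(c(tsv, js, png))
}

#' @export
render_outputs.cal_curve <- function(x, dir, name = "calibration_curve", ...) {
  ensure_dir(dir)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(tibble::as_tibble(x), tsv, progress = FALSE)
  png <- save_plot(autoplot(x), file.path(dir, paste0(name, ".png")))
  invisible(c(tsv, png))
}

#' @export
render_outputs.recal_model <- function(x, dir, name = "recal_model", ...) {
  ensure_dir(dir)
  js <- write_json_file(
    list(alpha0 = x$alpha0, alpha1 = x$alpha1, method = x$method,
         effective_sample_proportion = x$effective_sample_proportion,
         converged = x$converged, loglik = x$loglik, n = x$n,
         constraint_bound = if (is.finite(x$constraint_bound))
           x$constraint_bound else NULL),
    file.path(dir, paste0(name, ".json")))
  invisible(js)
}

#' @export
render_outputs.boot_result <- function(x, dir, name = "validation", ...) {
  ensure_dir(dir)
  js <- write_json_file(glance(x), file.path(dir, paste0(name, ".json")))
  invisible(js)
}

#' @export
render_outputs.potential_gain <- function(x, dir, name = "potential_gain", ...) {
  ensure_dir(dir)
  paths <- render_outputs(x$curve, dir, paste0(name, "_curve"))
  js <- write_json_file(glance(x), file.path(dir, paste0(name, ".json")))
  png <- save_plot(autoplot(x), file.path(dir, paste0(name, ".png")))
  invisible(c(paths, js, png))
}

#' Read a recalibration model back from its JSON serialization
#'
#' @param path Path written by [render_outputs()] for a `recal_model`.
#' @return A `recal_model`.
#' @export
read_recal_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_recal_model(j$alpha0, j$alpha1, j$method,
                  j$effective_sample_proportion, j$converged, j$loglik, j$n,
                  constraint_bound = if (!is.null(j$constraint_bound))
                    j$constraint_bound else NA_real_)
}
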