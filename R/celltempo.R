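#' Supervised pseudotime from time-stamped single-cell data
#'
#' Fits the full supervised-pseudotime pipeline: one margin classifier per
#' observed collection time point (one-vs-rest, soft-margin kernel SVM),
#' Platt-calibrated pairwise probabilities coupled into a per-cell
#' probability vector over the time points, and each cell's pseudotime as
#' the conditional expectation \eqn{E(Y \mid X = x) = \sum_d p_d T_d} of its
#' collection time. By default predictions come from nested cross-validation
#' (an outer loop for unbiased out-of-fold prediction around an inner loop
#' for hyperparameter selection), so the reported pseudotimes do not overfit
#' the data; `mode = "nocv"` gives the in-sample variant for comparison.
#'
#' @param x Numeric cells-by-features matrix (cells in rows). Raw count
#'   matrices should first go through [preprocess_rna()] or
#'   [preprocess_atac()].
#' @param times Per-cell numeric collection time, one per row of `x`.
#' @param mode `"nested"` (default) for nested cross-validated out-of-fold
#'   predictions, `"nocv"` for the in-sample fit.
#' @param cv A [cv_config()].
#' @param grid A [hyper_grid()].
#' @param probability_mode `"pairwise"` (default) or `"ovr"`; see
#'   [predict_proba()].
#' @param refit For `mode = "nested"`, additionally fit a final model on all
#'   cells (hyperparameters from a plain inner CV) so that [predict.celltempo()]
#'   can score new cells (default `FALSE`).
#' @return An object of class `celltempo` with components `probabilities`
#'   (N-by-D calibrated matrix, columns in ascending time order),
#'   `pseudotime`, `predicted_class`, `times` (the input labels), `classes`
#'   (ascending observed time points), `fold`, `hyper` (chosen candidate per
#'   outer fold), `mode`, `model` (final full-data model or `NULL`), and
#'   `call`.
#' @seealso [summary.celltempo()], [leave_one_timepoint_out()],
#'   [simulate_linear()]
#' @examples
#' \donttest{
#' sim <- simulate_linear(sim_config(n_cells = 60, n_genes = 50, seed = 1))
#' fit <- celltempo(sim$matrix, sim$time_labels, cv = cv_config(seed = 1))
#' summary(fit)
#' }
#' @export
celltempo <- function(x, times, mode = c("nested", "nocv"),
                      cv = cv_config(), grid = hyper_grid(),
                      probability_mode = c("pairwise", "ovr"),
                      refit = FALSE) {
  mode <- match.arg(mode)
  probability_mode <- match.arg(probability_mode)
  x <- as.matrix(x)
  if (!is.numeric(times)) {
    stop("'times' must be numeric; map ordinal stages to numbers first ",
         "(see read_labels(ordinal = TRUE))")
  }
  classes <- sort(unique(times))
  res <- if (mode == "nested") {
    nested_cv_predict(x, times, cv = cv, grid = grid,
                      probability_mode = probability_mode)
  } else {
    fit_full_no_cv(x, times, grid = grid, inner_folds = cv$inner_folds,
                   probability_mode = probability_mode, seed = cv$seed)
  }
  model <- res$model
  if (is.null(model) && refit) {
    model <- fit_full_no_cv(x, times, grid = grid,
                            inner_folds = cv$inner_folds,
                            probability_mode = probability_mode,
                            seed = cv$seed)$model
  }
  structure(list(probabilities = res$probabilities,
                 pseudotime = res$pseudotime,
                 predicted_class = res$predicted_class,
                 times = times, classes = classes,
                 fold = res$fold, hyper = res$hyper,
                 mode = if (mode == "nested") "nestedCV" else "noCV",
                 probability_mode = probability_mode,
                 cv = cv, model = model, call = match.call()),
            class = "celltempo")
}

#' @export
print.celltempo <- function(x, ...) {
  cat("Supervised pseudotime fit (", x$mode, ")\n", sep = "")
  cat(sprintf("  %d cells over %d time points: %s\n", length(x$times),
              length(x$classes), paste(x$classes, collapse = ", ")))
  acc <- accuracy(confusion_matrix(x$times, x$predicted_class))
  cat(sprintf("  classification accuracy: %.2f%%%s\n", acc,
              if (x$mode == "noCV") " (in-sample)" else " (out-of-fold)"))
  cat(sprintf("  pseudotime range: [%.3g, %.3g]\n",
              min(x$pseudotime), max(x$pseudotime)))
  invisible(x)
}

#' Summarize a supervised pseudotime fit
#'
#' @param object A [celltempo()] fit.
#' @param ... Unused.
#' @return An object of class `summary.celltempo` holding the confusion
#'   matrix, classification accuracy (percent), the tie-corrected Kendall
#'   rank correlation between pseudotime and the observed times, and the
#'   hyperparameters chosen per fold.
#' @export
summary.celltempo <- function(object, ...) {
  cm <- confusion_matrix(object$times, object$predicted_class)
  structure(list(confusion = cm, accuracy = accuracy(cm),
                 kendall_tau = kendall_tau_b(object$pseudotime, object$times),
                 hyper = object$hyper, mode = object$mode,
                 classes = object$classes),
            class = "summary.celltempo")
}

#' @export
print.summary.celltempo <- function(x, ...) {
  cat("Mode:", x$mode, "\n")
  cat(sprintf("Accuracy: %.2f%%   Kendall tau-b (pseudotime vs time): %.3f\n",
              x$accuracy, x$kendall_tau))
  cat("Confusion matrix (rows = observed time):\n")
  print(x$confusion)
  hy <- vapply(x$hyper, function(h)
    sprintf("R=%d C=%g", h$R, h$C), character(1))
  cat("Chosen hyperparameters per fold:", paste(hy, collapse = "; "), "\n")
  invisible(x)
}

#' @export
fitted.celltempo <- function(object, ...) object$pseudotime

#' Residuals of a supervised pseudotime fit
#'
#' Defined as pseudotime minus the observed collection time; a cell ahead of
#' (behind) its collection day has a positive (negative) residual.
#'
#' @param object A [celltempo()] fit.
#' @param ... Unused.
#' @export
residuals.celltempo <- function(object, ...) {
  object$pseudotime - object$times
}

#' Predict pseudotime for new cells
#'
#' Requires a final full-data model: fit with `mode = "nocv"` or
#' `refit = TRUE`.
#'
#' @param object A [celltempo()] fit.
#' @param newdata Cells-by-features matrix; omitted returns the stored
#'   (out-of-fold or in-sample) pseudotime.
#' @param type As in [predict.celltempo_model()].
#' @param ... Unused.
#' @export
predict.celltempo <- function(object, newdata = NULL,
                              type = c("pseudotime", "prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(switch(type, pseudotime = object$pseudotime,
                  prob = object$probabilities,
                  class = object$predicted_class))
  }
  if (is.null(object$model)) {
    stop("no full-data model stored; refit with mode = \"nocv\" or refit = TRUE")
  }
  predict(object$model, newdata, type = type)
}

#' Plot pseudotime against observed collection time
#'
#' Draws one box per observed time point with the per-cell pseudotimes
#' overlaid (jittered), plus the identity line: a faithful fit tracks the
#' diagonal with within-time-point spread reflecting asynchrony.
#'
#' @param x A [celltempo()] fit.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.celltempo <- function(x, ...) {
  f <- factor(x$times, levels = x$classes)
  graphics::boxplot(x$pseudotime ~ f, at = x$classes, boxwex = 0.8,
                    outline = FALSE, xlab = "observed time",
                    ylab = "pseudotime", ...)
  graphics::points(jitter(x$times, amount = 0.3), x$pseudotime,
                   pch = 16, cex = 0.5,
                   col = grDevices::adjustcolor("steelblue", 0.6))
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}
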