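# Hyperparameter selection and the cross-validation protocols.

#' Inner-loop hyperparameter selection
#'
#' Scores every grid candidate by mean classification accuracy over
#' stratified inner folds and returns the best one; ties are broken by grid
#' order, which favours the simpler linear kernel and smaller cost. When the
#' smallest class cannot support the requested number of folds, the fold
#' count is reduced with a warning.
#'
#' @param x Training cells-by-features matrix.
#' @param times Training time labels.
#' @param grid A [hyper_grid()].
#' @param inner_folds Number of inner folds (default 4).
#' @param stratified Stratify folds by time label.
#' @param seed Integer seed for the fold split.
#' @return The selected candidate, with attributes `accuracy` (mean inner
#'   accuracy per candidate) and `folds_used`.
#' @export
inner_select <- function(x, times, grid = hyper_grid(), inner_folds = 4L,
                         stratified = TRUE, seed = 0L) {
  x <- as.matrix(x)
  if (length(grid) == 0L) stop("the grid must be nonempty")
  if (length(grid) == 1L) return(grid[[1L]])
  min_class <- min(table(times))
  k <- inner_folds
  if (min_class < k) {
    k <- max(2L, as.integer(min_class))
    warning(sprintf(
      "smallest class has %d cells; using %d inner folds instead of %d",
      min_class, k, inner_folds))
  }
  fold <- make_folds(times, k, stratified = stratified, seed = seed)
  acc <- numeric(length(grid))
  for (g in seq_along(grid)) {
    correct <- 0L; total <- 0L
    for (fd in seq_len(k)) {
      tr <- which(fold != fd); te <- which(fold == fd)
      if (min(table(times[tr])) < 2L) next
      # candidates are scored as fitted, even if the dual solve hit its
      # iteration cap (a degenerate candidate simply scores what it earns)
      m <- suppressWarnings(
        celltempo_fit(x[tr, , drop = FALSE], times[tr], grid[[g]],
                      probability = FALSE))
      pred <- predict(m, x[te, , drop = FALSE], type = "class")
      correct <- correct + sum(pred == times[te])
      total <- total + length(te)
    }
    acc[g] <- if (total > 0L) correct / total else -Inf
  }
  best <- grid[[which.max(acc)]]  # which.max: first maximum = grid order
  attr(best, "accuracy") <- acc
  attr(best, "folds_used") <- k
  best
}

#' Nested cross-validated prediction
#'
#' The outer loop splits the cells into `cv$outer_folds` stratified folds;
#' for each fold, hyperparameters are chosen by an inner
#' `cv$inner_folds`-fold cross-validation on the training portion only, a
#' model is fitted on the full training portion with the chosen candidate,
#' and the held-out cells are predicted. Every cell thus receives exactly one
#' out-of-fold probability vector and pseudotime, with no leakage between
#' the test cells and any data used to select or fit their model.
#'
#' @param x Cells-by-features matrix.
#' @param times Per-cell time labels.
#' @param cv A [cv_config()].
#' @param grid A [hyper_grid()].
#' @param probability_mode Passed to [celltempo_fit()].
#' @return List with `probabilities` (N-by-D, original row order),
#'   `pseudotime`, `predicted_class`, `fold` (outer fold id per cell),
#'   `hyper` (chosen candidate per fold), and `train_index` (per-fold
#'   training row indices, for leakage auditing).
#' @export
nested_cv_predict <- function(x, times, cv = cv_config(),
                              grid = hyper_grid(),
                              probability_mode = "pairwise") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n != length(times)) stop("one time label per row of 'x' required")
  classes <- sort(unique(times))
  if (cv$stratified && min(table(times)) < cv$outer_folds) {
    stop("every class needs at least 'outer_folds' cells for stratified CV")
  }
  fold <- make_folds(times, cv$outer_folds, cv$stratified, seed = cv$seed)
  P <- matrix(NA_real_, n, length(classes))
  pred <- rep(NA_real_, n)
  hyper <- vector("list", cv$outer_folds)
  train_index <- vector("list", cv$outer_folds)
  for (fd in seq_len(cv$outer_folds)) {
    tr <- which(fold != fd); te <- which(fold == fd)
    train_index[[fd]] <- tr
    hyper[[fd]] <- inner_select(x[tr, , drop = FALSE], times[tr], grid,
                                inner_folds = cv$inner_folds,
                                stratified = cv$stratified,
                                seed = cv$seed + 1000L + fd)
    m <- celltempo_fit(x[tr, , drop = FALSE], times[tr], hyper[[fd]],
                       probability = TRUE,
                       probability_mode = probability_mode,
                       seed = cv$seed + 2000L + fd)
    P[te, ] <- predict_proba(m, x[te, , drop = FALSE])
    pred[te] <- predict(m, x[te, , drop = FALSE], type = "class")
  }
  colnames(P) <- format(classes, trim = TRUE)
  rownames(P) <- rownames(x)
  list(probabilities = P, pseudotime = pseudotime(P, classes),
       predicted_class = pred, fold = fold, hyper = hyper,
       train_index = train_index)
}

#' In-sample fit without the outer cross-validation loop
#'
#' Hyperparameters are chosen by a plain `inner_folds`-fold cross-validation
#' on all cells, a single model is fitted on all cells, and the same cells
#' are predicted in-sample. Because the evaluation data coincide with the
#' training data, the resulting accuracy is optimistic; the output is
#' flagged `mode = "noCV"` so downstream reports carry that caveat.
#'
#' @inheritParams nested_cv_predict
#' @param inner_folds Folds for the plain hyperparameter selection.
#' @param seed Integer seed.
#' @return As [nested_cv_predict()], plus the fitted `model`; `fold` is all
#'   zeros and the list carries `mode = "noCV"`.
#' @export
fit_full_no_cv <- function(x, times, grid = hyper_grid(), inner_folds = 4L,
                           probability_mode = "pairwise", seed = 0L) {
  x <- as.matrix(x)
  classes <- sort(unique(times))
  hyper <- inner_select(x, times, grid, inner_folds = inner_folds,
                        seed = seed + 1000L)
  m <- celltempo_fit(x, times, hyper, probability = TRUE,
                     probability_mode = probability_mode,
                     seed = seed + 2000L)
  P <- predict_proba(m, x)
  list(probabilities = P, pseudotime = pseudotime(P, classes),
       predicted_class = predict(m, x, type = "class"),
       fold = rep(0L, nrow(x)), hyper = list(hyper), model = m,
       mode = "noCV")
}

#' Leave-one-time-point-out validation
#'
#' Iteratively withholds one entire time point, trains on the remaining
#' classes (re-running inner hyperparameter selection on that training set,
#' unless a fixed candidate is supplied), and predicts the held-out cells
#' among the training classes. A model that has learned temporal structure —
#' rather than per-time-point batch signatures — should place held-out cells
#' overwhelmingly into the *adjacent* time points; compare the observed
#' [adjacency_proportion()] against [expected_uniform_adjacency()].
#'
#' @param x Cells-by-features matrix.
#' @param times Per-cell time labels with at least three distinct values.
#' @param grid A [hyper_grid()].
#' @param hyper Optional fixed candidate; when supplied, inner selection is
#'   skipped for every held-out class.
#' @param inner_folds Inner folds for per-class hyperparameter selection.
#' @param seed Integer seed.
#' @return An object of class `celltempo_loto`: list with `confusion` (D-by-D
#'   counts, true class in rows, structurally zero diagonal),
#'   `probabilities` (per held-out class, columns are the training classes),
#'   `classes`, and `hyper` (candidate used per held-out class).
#' @export
leave_one_timepoint_out <- function(x, times, grid = hyper_grid(),
                                    hyper = NULL, inner_folds = 4L,
                                    seed = 0L) {
  x <- as.matrix(x)
  classes <- sort(unique(times))
  D <- length(classes)
  if (D < 3L) stop("leave-one-time-point-out needs at least 3 time points")
  cm <- matrix(0L, D, D, dimnames = list(true = format(classes, trim = TRUE),
                                         predicted = format(classes, trim = TRUE)))
  probs <- vector("list", D)
  used <- vector("list", D)
  for (d in seq_len(D)) {
    held <- which(times == classes[d])
    tr <- which(times != classes[d])
    hd <- hyper
    if (is.null(hd)) {
      hd <- inner_select(x[tr, , drop = FALSE], times[tr], grid,
                         inner_folds = inner_folds,
                         seed = seed + 3000L + d)
    }
    m <- celltempo_fit(x[tr, , drop = FALSE], times[tr], hd,
                       probability = TRUE, seed = seed + 4000L + d)
    pred <- predict(m, x[held, , drop = FALSE], type = "class")
    probs[[d]] <- predict_proba(m, x[held, , drop = FALSE])
    used[[d]] <- hd
    for (p in pred) cm[d, which(classes == p)] <- cm[d, which(classes == p)] + 1L
  }
  structure(list(confusion = cm, probabilities = probs, classes = classes,
                 hyper = used),
            class = "celltempo_loto")
}

#' @export
print.celltempo_loto <- function(x, ...) {
  cat("Leave-one-time-point-out confusion matrix (rows = held-out class):\n")
  print(x$confusion)
  obs <- adjacency_proportion(x$confusion, x$classes)
  exp0 <- expected_uniform_adjacency(rowSums(x$confusion))
  cat(sprintf("Adjacent predictions: %.1f%% (uniform-error expectation %.1f%%)\n",
              100 * obs, 100 * exp0))
  invisible(x)
}
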