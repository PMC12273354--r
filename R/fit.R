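#' Hyperparameter grid
#'
#' The default grid crosses the kernel indicator `R` (0 = linear, 1 = RBF)
#' with the soft-margin cost `C`, giving six candidates in a deterministic
#' order: `R` ascending (linear first), then `C` ascending. The RBF width
#' `gamma` is resolved from each training matrix (see [default_gamma()])
#' rather than searched.
#'
#' @param R Kernel indicators, subset of `c(0, 1)`.
#' @param C Positive soft-margin costs.
#' @param gamma `"auto"` or a fixed positive number used for every RBF
#'   candidate.
#' @return List of hyperparameter candidates, each a list with elements
#'   `R`, `C`, `gamma`; class `hyper_grid`.
#' @examples
#' length(hyper_grid())  # 6
#' @export
hyper_grid <- function(R = c(0, 1), C = c(0.1, 1, 10), gamma = "auto") {
  R <- sort(unique(as.integer(R)))
  C <- sort(unique(as.numeric(C)))
  if (length(R) == 0L || length(C) == 0L) stop("the grid must be nonempty")
  if (!all(R %in% c(0L, 1L))) stop("'R' entries must be 0 or 1")
  if (any(C <= 0)) stop("'C' entries must be positive")
  g <- list()
  for (r in R) for (cc in C) {
    g[[length(g) + 1L]] <- list(R = r, C = cc, gamma = gamma)
  }
  structure(g, class = "hyper_grid")
}

#' Cross-validation configuration
#'
#' @param outer_folds Outer folds of the nested scheme (default 5, i.e. train
#'   on 80\% and test on the held-out 20\%).
#' @param inner_folds Inner folds used for hyperparameter selection
#'   (default 4).
#' @param stratified Stratify folds by time label (default `TRUE`).
#' @param seed Integer seed controlling all fold shuffling.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 5L, inner_folds = 4L, stratified = TRUE,
                      seed = 0L) {
  if (outer_folds < 2L || inner_folds < 2L) stop("folds must be >= 2")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_config")
}

# Stratified (or plain) k-fold assignment; returns an integer fold id per
# observation. Round-robin within each shuffled class keeps classes balanced
# across folds; the starting fold rotates per class so remainders do not
# pile onto the first fold.
make_folds <- function(labels, k, stratified = TRUE, seed = 0L) {
  n <- length(labels)
  withr::with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      groups <- split(seq_len(n), labels)
      for (ci in seq_along(groups)) {
        idx <- groups[[ci]]
        ids <- ((seq_along(idx) - 1L + ci - 1L) %% k) + 1L
        fold[sample(idx)] <- ids
      }
    } else {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    }
    fold
  })
}

kernel_from_hyper <- function(hyper, x) {
  if (hyper$R == 0) return(kernel_spec("linear"))
  gamma <- hyper$gamma
  if (identical(gamma, "auto")) gamma <- default_gamma(x)
  kernel_spec("rbf", gamma = gamma)
}

# Platt calibration for one binary subproblem, by default on cross-validated
# decision values (platt_cv folds) to avoid calibration optimism. Folds whose
# training part loses a class are skipped; if cross-validation is impossible
# the in-sample decision values are used.
calibrate_pair <- function(K, y, C, platt_cv = 3L, seed = 0L) {
  f <- rep(NA_real_, length(y))
  if (platt_cv >= 2L && min(table(y)) >= 2L) {
    k <- min(platt_cv, min(table(y)))
    fold <- make_folds(y, k, stratified = TRUE, seed = seed)
    for (fd in seq_len(k)) {
      tr <- which(fold != fd); te <- which(fold == fd)
      if (length(unique(y[tr])) < 2L) next  # skip degenerate fold
      m <- train_binary_svm(K[tr, tr, drop = FALSE], y[tr], C)
      f[te] <- svm_decision(m, K[te, tr, drop = FALSE])
    }
  }
  model <- train_binary_svm(K, y, C)
  miss <- is.na(f)
  if (any(miss)) f[miss] <- svm_decision(model, K[miss, , drop = FALSE])
  list(model = model, platt = fit_platt(f, y))
}

#' Fit the per-time-point classifier ensemble
#'
#' Trains one soft-margin SVM per observed time point with a one-vs-rest
#' labelling (+1 for the time point, -1 for the pooled rest) for class
#' decisions, plus one classifier per *pair* of time points whose
#' Platt-calibrated outputs feed the pairwise-coupling quadratic program that
#' produces the multiclass probability vector. This is the single-model
#' building block; most users want [celltempo()], which wraps it in nested
#' cross-validation.
#'
#' @param x Numeric cells-by-features matrix.
#' @param times Per-cell observed time labels (numeric); at least two
#'   distinct values, each with at least two cells.
#' @param hyper A single candidate from [hyper_grid()] (list with `R`, `C`,
#'   `gamma`); default RBF with `C = 1`.
#' @param probability Fit the pairwise calibration machinery (default
#'   `TRUE`); with `FALSE` only class decisions are available, which is
#'   cheaper inside hyperparameter search.
#' @param probability_mode `"pairwise"` (Platt per class pair followed by
#'   coupling; the default) or `"ovr"` (Platt per one-vs-rest classifier,
#'   renormalized to sum to one).
#' @param platt_cv Folds for cross-validated Platt decision values
#'   (default 3; 0 disables and calibrates in-sample).
#' @param seed Integer seed for the calibration folds.
#' @return An object of class `celltempo_model`.
#' @export
celltempo_fit <- function(x, times, hyper = list(R = 1, C = 1, gamma = "auto"),
                          probability = TRUE,
                          probability_mode = c("pairwise", "ovr"),
                          platt_cv = 3L, seed = 0L) {
  probability_mode <- match.arg(probability_mode)
  x <- as.matrix(x)
  if (nrow(x) != length(times)) stop("one time label per row of 'x' required")
  classes <- sort(unique(times))
  D <- length(classes)
  if (D < 2L) stop("at least two distinct time points are required")
  sizes <- table(factor(times, levels = classes))
  if (any(sizes < 2L)) {
    stop(sprintf("time point %s has fewer than 2 cells",
                 paste(classes[sizes < 2L], collapse = ", ")))
  }
  spec <- kernel_from_hyper(hyper, x)
  K <- compute_kernel(x, x, spec)

  ovr <- vector("list", D)
  for (d in seq_len(D)) {
    y <- ifelse(times == classes[d], 1L, -1L)
    ovr[[d]] <- train_binary_svm(K, y, hyper$C)
  }

  pairs <- NULL
  if (probability && probability_mode == "pairwise") {
    pairs <- list()
    for (i in seq_len(D - 1L)) {
      for (j in seq(i + 1L, D)) {
        idx <- which(times %in% classes[c(i, j)])
        y <- ifelse(times[idx] == classes[i], 1L, -1L)
        cal <- calibrate_pair(K[idx, idx, drop = FALSE], y, hyper$C,
                              platt_cv = platt_cv,
                              seed = seed + 97L * i + j)
        pairs[[paste(i, j, sep = "_")]] <-
          c(cal, list(i = i, j = j, idx = idx))
      }
    }
  }
  ovr_platt <- NULL
  if (probability && probability_mode == "ovr") {
    ovr_platt <- vector("list", D)
    for (d in seq_len(D)) {
      y <- ifelse(times == classes[d], 1L, -1L)
      cal <- calibrate_pair(K, y, hyper$C, platt_cv = platt_cv,
                            seed = seed + 131L * d)
      ovr_platt[[d]] <- cal$platt
      ovr[[d]] <- cal$model
    }
  }

  structure(list(x = x, classes = classes, times = times, kernel = spec,
                 hyper = hyper, ovr = ovr, pairs = pairs,
                 ovr_platt = ovr_platt, probability = probability,
                 probability_mode = probability_mode, seed = seed),
            class = "celltempo_model")
}

#' @export
print.celltempo_model <- function(x, ...) {
  cat(sprintf("Per-time-point SVM ensemble: %d time points, %d cells, %s kernel (C = %g)\n",
              length(x$classes), nrow(x$x), x$kernel$kind, x$hyper$C))
  invisible(x)
}

# One-vs-rest decision values for new rows: N x D matrix.
ovr_decision <- function(model, newx) {
  K_new <- compute_kernel(newx, model$x, model$kernel)
  dec <- vapply(model$ovr, function(m) svm_decision(m, K_new),
                numeric(nrow(K_new)))
  matrix(dec, nrow = nrow(K_new))
}

#' Predict from a fitted classifier ensemble
#'
#' @param object A [celltempo_fit()] model.
#' @param newdata Cells-by-features matrix with the training feature
#'   dimension.
#' @param type `"prob"` for the calibrated N-by-D probability matrix (rows
#'   sum to 1), `"class"` for the predicted time point (one-vs-rest argmax,
#'   ties resolved to the earliest time point), `"pseudotime"` for the
#'   conditional expectation of the collection time, or `"decision"` for the
#'   raw one-vs-rest decision values.
#' @param ... Unused.
#' @return Matrix or vector according to `type`.
#' @export
predict.celltempo_model <- function(object, newdata,
                                    type = c("prob", "class", "pseudotime",
                                             "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) {
    stop(sprintf("newdata has %d features; the model was trained on %d",
                 ncol(newdata), ncol(object$x)))
  }
  if (type == "decision") return(ovr_decision(object, newdata))
  if (type == "class") {
    dec <- ovr_decision(object, newdata)
    return(object$classes[apply(dec, 1, which.max)])  # which.max: first = earliest
  }
  P <- predict_proba(object, newdata)
  if (type == "prob") return(P)
  pseudotime(P, object$classes)
}

#' Calibrated class-membership probabilities
#'
#' In the default pairwise mode, each pair's Platt sigmoid maps that pair's
#' decision values to \eqn{r_{ij} \approx P(T_i \mid T_i \text{ or } T_j)},
#' and [pairwise_coupling()] combines all pairs into one probability vector
#' per cell. In `"ovr"` mode the per-class Platt probabilities are
#' renormalized to sum to one.
#'
#' @param model A [celltempo_fit()] model with `probability = TRUE`.
#' @param newdata Cells-by-features matrix.
#' @return N-by-D probability matrix with columns in ascending time order;
#'   rows sum to 1.
#' @export
predict_proba <- function(model, newdata) {
  if (!isTRUE(model$probability)) {
    stop("the model was fitted with probability = FALSE")
  }
  newdata <- as.matrix(newdata)
  D <- length(model$classes)
  n <- nrow(newdata)
  eps <- 1e-7
  if (model$probability_mode == "pairwise") {
    K_new <- compute_kernel(newdata, model$x, model$kernel)
    r_all <- lapply(model$pairs, function(pr) {
      f <- svm_decision(pr$model, K_new[, pr$idx, drop = FALSE])
      pmin(pmax(platt_predict(pr$platt, f), eps), 1 - eps)
    })
    P <- matrix(0, n, D)
    r <- matrix(0.5, D, D)
    for (c_i in seq_len(n)) {
      for (pr_id in seq_along(model$pairs)) {
        pr <- model$pairs[[pr_id]]
        r[pr$i, pr$j] <- r_all[[pr_id]][c_i]
        r[pr$j, pr$i] <- 1 - r_all[[pr_id]][c_i]
      }
      P[c_i, ] <- pairwise_coupling(r)
    }
  } else {
    dec <- ovr_decision(model, newdata)
    P <- vapply(seq_len(D), function(d) {
      pmin(pmax(platt_predict(model$ovr_platt[[d]], dec[, d]), eps), 1 - eps)
    }, numeric(n))
    P <- matrix(P, n, D)
    P <- P / rowSums(P)
  }
  colnames(P) <- format(model$classes, trim = TRUE)
  rownames(P) <- rownames(newdata)
  P
}

#' Conditional-expectation pseudotime
#'
#' Given the calibrated probability vector \eqn{(p_1, \ldots, p_D)} over the
#' ordered observed time points \eqn{T_1 < \ldots < T_D}, each cell's
#' pseudotime is \eqn{E(Y \mid X = x) = \sum_d p_d T_d} — a convex
#' combination, so it always lies in \eqn{[T_1, T_D]}.
#'
#' @param P N-by-D probability matrix; rows must sum to 1 (tolerance 1e-6).
#' @param times Ascending time points, one per column of `P`.
#' @return Numeric pseudotime vector.
#' @examples
#' pseudotime(matrix(c(.1, .2, .3, .2, .2), 1), c(0, 3, 7, 11, 21))  # 9.1
#' @export
pseudotime <- function(P, times) {
  P <- as.matrix(P)
  if (ncol(P) != length(times)) stop("one column of 'P' per time point")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  bad <- abs(rowSums(P) - 1) > 1e-6
  if (any(bad)) {
    stop(sprintf("%d probability row(s) do not sum to 1", sum(bad)))
  }
  drop(P %*% times)
}
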