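# Evaluation statistics: confusion/accuracy, tie-corrected Kendall rank
# correlation, LOTO adjacency with its analytic uniform-error null, exact
# Fisher and Wilcoxon tests, a ridge baseline, and permutation importance.

#' Confusion matrix and classification accuracy
#'
#' @param true,pred Equal-length vectors of observed and predicted time
#'   labels; classes are the sorted union unless given.
#' @param classes Optional explicit class set (ascending).
#' @return `confusion_matrix()`: a D-by-D integer matrix, rows = true class
#'   (ascending), columns = predicted. `accuracy()`: percent of counts on
#'   the diagonal.
#' @examples
#' accuracy(matrix(c(3809, 255, 0, 0), 2, 2))  # 93.73...
#' @export
confusion_matrix <- function(true, pred, classes = NULL) {
  if (length(true) != length(pred)) stop("'true' and 'pred' lengths differ")
  if (length(true) == 0L) stop("empty input")
  if (is.null(classes)) classes <- sort(unique(c(true, pred)))
  if (!all(c(true, pred) %in% classes)) {
    stop("labels outside the declared class set")
  }
  f <- function(v) factor(v, levels = classes)
  cm <- table(true = f(true), predicted = f(pred))
  matrix(as.integer(cm), nrow = length(classes),
         dimnames = dimnames(cm))
}

#' @rdname confusion_matrix
#' @param cm A square confusion matrix of counts.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("'cm' must be square")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Rank agreement between inferred pseudotime and observed time. Observed
#' times are heavily tied (many cells per collection day), so the
#' tie-corrected tau-b variant is used.
#'
#' @param x,y Equal-length numeric vectors, neither constant.
#' @return tau-b in \[-1, 1\].
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Kendall tau is undefined for a constant vector")
  }
  stats::cor(x, y, method = "kendall")
}

#' Observed and expected adjacency in a leave-one-time-point-out confusion
#'
#' With one time point withheld at training, every held-out cell is
#' predicted into some *other* time point (the confusion diagonal is
#' structurally zero). `adjacency_proportion()` measures how often the
#' prediction lands on a time point immediately adjacent (in time order) to
#' the held-out one. `expected_uniform_adjacency()` is the analytic null
#' under uniformly distributed errors: a held-out class `d` has 1 (endpoint)
#' or 2 (interior) adjacent classes among the remaining `D - 1`, so
#' \deqn{E = \frac{\sum_d n_d \, a_d / (D - 1)}{\sum_d n_d}.}
#' For five balanced classes this is \eqn{(1+2+2+2+1)/(5 \cdot 4) = 0.40}.
#'
#' @param cm LOTO confusion matrix (rows = held-out true class, ascending
#'   time order; zero diagonal).
#' @param times Optional ascending time points (only their order is used).
#' @return Proportion in \[0, 1\].
#' @export
adjacency_proportion <- function(cm, times = NULL) {
  cm <- as.matrix(cm)
  D <- nrow(cm)
  if (ncol(cm) != D || D < 3L) stop("'cm' must be square with D >= 3")
  if (any(diag(cm) != 0)) {
    stop("the diagonal must be structurally zero in a LOTO confusion matrix")
  }
  if (!is.null(times) && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing")
  }
  adj <- 0
  for (d in seq_len(D)) {
    nb <- c(d - 1L, d + 1L)
    nb <- nb[nb >= 1L & nb <= D]
    adj <- adj + sum(cm[d, nb])
  }
  adj / sum(cm)
}

#' @rdname adjacency_proportion
#' @param class_sizes Per-class cell counts in ascending time order.
#' @export
expected_uniform_adjacency <- function(class_sizes) {
  D <- length(class_sizes)
  if (D < 3L) stop("the adjacency null needs D >= 3 classes")
  if (any(class_sizes <= 0)) stop("class sizes must be positive")
  a <- c(1, rep(2, D - 2L), 1)
  sum(class_sizes * a / (D - 1)) / sum(class_sizes)
}

#' Two-sided Fisher's exact test on a 2-by-2 table
#'
#' Exact p by hypergeometric enumeration: the sum of the probabilities of
#' all tables (with the observed margins) no more probable than the observed
#' one. Used to compare two methods' (correct, incorrect) counts.
#'
#' @param tab 2-by-2 matrix of nonnegative integer counts.
#' @return Two-sided p-value; a table with a zero margin carries no
#'   information and returns 1.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("'tab' must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("'tab' must contain nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Exact Wilcoxon signed-rank test
#'
#' Exact p-value of the signed-rank statistic by dynamic programming over
#' the distribution of the positive-rank sum across all \eqn{2^n} sign
#' patterns, which stays exact under tied ranks (where
#' [stats::wilcox.test()] falls back to a normal approximation). Zero
#' differences are dropped with a warning, following the usual convention.
#'
#' @param d Numeric vector of paired differences.
#' @param alternative `"two.sided"`, `"greater"` (positive shift), or
#'   `"less"`.
#' @param exact_max Largest n for which the exact distribution is computed
#'   (default 30); beyond it a normal approximation with tie correction is
#'   used, with a warning.
#' @return The p-value.
#' @examples
#' wilcoxon_signed_rank_exact(c(2, 3, 1, 5, 4), "greater")  # 1/32
#' @export
wilcoxon_signed_rank_exact <- function(d,
                                       alternative = c("two.sided", "greater",
                                                       "less"),
                                       exact_max = 30L) {
  alternative <- match.arg(alternative)
  if (any(d == 0)) {
    warning(sprintf("dropping %d zero difference(s)", sum(d == 0)))
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of W+ over sign patterns; scale ranks to integers
    # (average ranks under ties are multiples of 1/2)
    ri <- as.integer(round(2 * r))
    total <- sum(ri)
    dist <- rep(0, total + 1L)  # dist[w + 1] ~ #patterns with 2*W+ = w
    dist[1L] <- 1
    for (rk in ri) {
      shifted <- c(rep(0, rk), dist[seq_len(total + 1L - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- round(2 * w_pos)
    p_ge <- sum(dist[(w2 + 1L):(total + 1L)])
    p_le <- sum(dist[1L:(w2 + 1L)])
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    warning("n exceeds 'exact_max'; using a normal approximation")
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z_ge <- (w_pos - 0.5 - mu) / sqrt(sig2)
    z_le <- (w_pos + 0.5 - mu) / sqrt(sig2)
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p_le <- stats::pnorm(z_le)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  }
  p
}

#' Ridge regression baseline for pseudotime
#'
#' Penalized least squares of the observed times on the features (intercept
#' unpenalized, coefficients shrunk by `alpha`), the linear baseline the
#' classifier pipeline is compared against. Predictions are unconstrained
#' reals — unlike the conditional-expectation pseudotime they need not fall
#' inside the observed time range.
#'
#' @param x_train,x_test Cells-by-features matrices.
#' @param t_train Training time labels.
#' @param alpha Nonnegative ridge penalty (default 1).
#' @return Predicted times for `x_test`.
#' @export
ridge_baseline <- function(x_train, t_train, x_test, alpha = 1) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (alpha < 0) stop("'alpha' must be nonnegative")
  mu <- colMeans(x_train)
  xc <- sweep(x_train, 2, mu)
  ty <- t_train - mean(t_train)
  A <- crossprod(xc) + diag(alpha, ncol(xc))
  beta <- tryCatch(solve(A, crossprod(xc, ty)), error = function(e) {
    stop("singular system; use alpha > 0")
  })
  drop(sweep(x_test, 2, mu) %*% beta) + mean(t_train)
}

#' Permutation feature importance
#'
#' For each feature, the within-column values are permuted `n_repeats` times
#' and the mean drop in classification accuracy (relative to the unpermuted
#' accuracy) is reported. Features the classifiers ignore score near zero;
#' informative features score positively.
#'
#' @param model A [celltempo_fit()] model.
#' @param x Cells-by-features evaluation matrix.
#' @param times True time labels for `x`.
#' @param n_repeats Permutations per feature (default 5).
#' @param seed Integer seed.
#' @return Named numeric vector of mean accuracy drops (percentage points).
#' @export
permutation_importance <- function(model, x, times, n_repeats = 5L,
                                   seed = 0L) {
  if (n_repeats < 1L) stop("'n_repeats' must be at least 1")
  x <- as.matrix(x)
  base_acc <- 100 * mean(predict(model, x, type = "class") == times)
  drops <- withr::with_seed(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      mean(vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(x)), j]
        base_acc - 100 * mean(predict(model, xp, type = "class") == times)
      }, numeric(1)))
    }, numeric(1))
  })
  names(drops) <- colnames(x)
  drops
}
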