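#' Train a binary soft-margin kernel SVM from a precomputed kernel matrix
#'
#' Maximizes the dual objective
#' \deqn{\sum_i a_i - \frac12 \sum_{i,j} a_i a_j y_i y_j K_{ij}}
#' subject to the box constraints \eqn{0 \le a_i \le C} and the equality
#' constraint \eqn{\sum_i a_i y_i = 0}, by sequential minimal optimization
#' with maximal-violating-pair working-set selection. The bias is recovered
#' from the free support vectors (those with \eqn{0 < a_i < C}), falling back
#' to the midpoint of the KKT bounds when no coefficient is free.
#'
#' @param K Square symmetric positive semi-definite kernel matrix over the
#'   training points.
#' @param y Labels in \{-1, +1\} (numeric or integer), one per row of `K`.
#' @param C Positive soft-margin cost.
#' @param tol KKT violation tolerance for the stopping rule.
#' @param max_iter Cap on working-set iterations.
#' @return An object of class `binary_svm` with elements `alpha` (dual
#'   coefficients), `support` (indices with `alpha > 1e-8`), `bias`,
#'   `objective` (dual objective at the solution), `C`, and `y`.
#' @examples
#' K <- tcrossprod(matrix(c(0, 2), 2, 1))
#' m <- train_binary_svm(K, c(-1, 1), C = 10)
#' m$alpha  # c(0.5, 0.5)
#' @export
train_binary_svm <- function(K, y, C, tol = 1e-3, max_iter = NULL) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("'K' must be square")
  y <- as.integer(round(y))
  if (length(y) != n) stop("'y' length must match nrow(K)")
  if (!all(y %in% c(-1L, 1L))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!is.numeric(C) || C <= 0) stop("'C' must be positive")
  if (max(abs(K - t(K))) > 1e-8 * (1 + max(abs(K)))) {
    stop("'K' must be symmetric")
  }
  # cheap PSD guard for small problems; indefiniteness breaks the dual
  if (n <= 500L) {
    lam <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (lam < -1e-8 * (1 + max(abs(K)))) {
      warning("kernel matrix is not PSD; adding diagonal jitter")
      K <- K + diag(2 * abs(lam), n)
    }
  }
  if (is.null(max_iter)) max_iter <- max(50000L, 200L * n)
  sol <- smo_solve(K, y, C, tol, as.integer(max_iter))
  if (!sol$converged) {
    warning(sprintf("SMO did not reach tolerance %g (gap %g)", tol, sol$gap))
  }
  a <- sol$alpha
  f0 <- drop(K %*% (a * y))           # decision values without bias
  eps <- 1e-8 * max(C, 1)
  free <- which(a > eps & a < C - eps)
  if (length(free) > 0L) {
    bias <- mean(y[free] - f0[free])
  } else {
    yg <- y - f0                      # -y_i * grad_i
    up <- (y == 1L & a < C - eps) | (y == -1L & a > eps)
    lo <- (y == 1L & a > eps) | (y == -1L & a < C - eps)
    bias <- (max(yg[up]) + min(yg[lo])) / 2
  }
  structure(list(alpha = a, support = which(a > eps), bias = bias,
                 objective = sol$objective, iterations = sol$iterations,
                 C = C, y = y),
            class = "binary_svm")
}

#' Decision values of a binary SVM
#'
#' @param model A [train_binary_svm()] fit.
#' @param K_new Kernel matrix between new points (rows) and the training
#'   points (columns, in training order).
#' @return Numeric vector of decision values \eqn{f(x) = \sum_i a_i y_i
#'   K(x_i, x) + b}.
#' @export
svm_decision <- function(model, K_new) {
  K_new <- as.matrix(K_new)
  if (ncol(K_new) != length(model$alpha)) {
    stop("'K_new' must have one column per training point")
  }
  drop(K_new %*% (model$alpha * model$y)) + model$bias
}

#' Platt scaling of decision values
#'
#' Fits the sigmoid \eqn{P(y = +1 \mid f) = 1 / (1 + \exp(A f + B))} to
#' decision values by minimizing the regularized cross-entropy against the
#' smoothed targets \eqn{t_+ = (N_+ + 1)/(N_+ + 2)} and
#' \eqn{t_- = 1/(N_- + 2)}, using the damped Newton iteration of Lin, Lin
#' and Weng (2007). With this parametrization a well-separated classifier
#' yields `A < 0`, so the probability increases with the decision value.
#'
#' @param f Numeric decision values.
#' @param y Labels in \{-1, +1\}.
#' @param max_iter Newton iteration cap.
#' @param tol Gradient infinity-norm convergence threshold.
#' @return An object of class `platt_params` with elements `A` and `B`.
#' @export
fit_platt <- function(f, y, max_iter = 100L, tol = 1e-10) {
  if (any(!is.finite(f))) stop("decision values must be finite")
  y <- as.integer(round(y))
  if (!all(y %in% c(-1L, 1L))) stop("labels must be -1/+1")
  n_pos <- sum(y == 1L); n_neg <- sum(y == -1L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  t_i <- ifelse(y == 1L, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))

  # objective F(A,B) = sum_i t_i*z_i + log(1+exp(-z_i)), z_i = A f_i + B
  fval <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t_i * z + log1p(exp(-z)), (t_i - 1) * z + log1p(exp(z))))
  }
  A <- 0; B <- log((n_neg + 1) / (n_pos + 1))
  Fv <- fval(A, B)
  sigma <- 1e-12
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    q <- 1 - p
    d1 <- t_i - p                     # dF/dz
    gA <- sum(f * d1); gB <- sum(d1)
    if (max(abs(gA), abs(gB)) < tol) break
    w <- p * q
    hAA <- sum(f * f * w) + sigma
    hBB <- sum(w) + sigma
    hAB <- sum(f * w)
    det <- hAA * hBB - hAB^2
    dA <- -(hBB * gA - hAB * gB) / det
    dB <- -(-hAB * gA + hAA * gB) / det
    # backtracking line search
    step <- 1
    repeat {
      A_new <- A + step * dA; B_new <- B + step * dB
      F_new <- fval(A_new, B_new)
      if (F_new < Fv + 1e-4 * step * (gA * dA + gB * dB) || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB
    Fv <- fval(A, B)
  }
  structure(list(A = A, B = B), class = "platt_params")
}

#' Calibrated probability from Platt parameters
#'
#' @param params A [fit_platt()] result.
#' @param f Decision values.
#' @return \eqn{P(y = +1 \mid f)} in (0, 1).
#' @export
platt_predict <- function(params, f) {
  z <- params$A * f + params$B
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' Couple pairwise probabilities into a multiclass probability vector
#'
#' Given the matrix of pairwise estimates \eqn{r_{ij} \approx P(\text{class }
#' i \mid \text{class } i \text{ or } j)}, finds the probability vector `p`
#' minimizing \eqn{\sum_{i<j} (r_{ji} p_i - r_{ij} p_j)^2} subject to
#' \eqn{\sum_d p_d = 1,\ p \ge 0} (the second method of Wu, Lin and Weng,
#' 2004), by their normalized fixed-point iteration.
#'
#' @param r D-by-D matrix with `r[i, j]` in (0, 1) and `r[j, i] = 1 - r[i, j]`
#'   for all pairs; the diagonal is ignored.
#' @param tol Stationarity tolerance.
#' @param max_iter Iteration cap.
#' @return Probability vector of length D summing to 1.
#' @examples
#' r <- matrix(0.5, 3, 3)
#' pairwise_coupling(r)  # uniform
#' @export
pairwise_coupling <- function(r, tol = 1e-10, max_iter = 1000L) {
  r <- as.matrix(r)
  D <- nrow(r)
  if (ncol(r) != D || D < 2L) stop("'r' must be a square matrix, D >= 2")
  off <- row(r) != col(r)
  if (any(!is.finite(r[off])) || any(r[off] <= 0) || any(r[off] >= 1)) {
    stop("off-diagonal entries of 'r' must lie strictly in (0, 1)")
  }
  if (max(abs((r + t(r))[off] - 1)) > 1e-6) {
    stop("'r' must satisfy r[j, i] = 1 - r[i, j]")
  }
  Q <- matrix(0, D, D)
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (i == j) {
        Q[i, i] <- sum(r[-i, i]^2)
      } else {
        Q[i, j] <- -r[j, i] * r[i, j]
      }
    }
  }
  p <- rep(1 / D, D)
  for (it in seq_len(max_iter)) {
    Qp <- drop(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < tol) break
    for (t in seq_len(D)) {
      p[t] <- (-sum(Q[t, -t] * p[-t]) + pQp) / Q[t, t]
      p <- p / sum(p)
      Qp <- drop(Q %*% p)
      pQp <- sum(p * Qp)
    }
  }
  p[p < 0] <- 0
  p / sum(p)
}
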