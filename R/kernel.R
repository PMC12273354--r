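#' Kernel specification
#'
#' Describes the kernel used by the margin classifiers: either the linear
#' kernel \eqn{K(x, z) = x^T z} or the radial basis function (RBF) kernel
#' \eqn{K(x, z) = \exp(-\gamma \|x - z\|^2)}, where `gamma` is the inverse
#' squared kernel width.
#'
#' @param kind `"linear"` or `"rbf"`.
#' @param gamma Positive RBF width inverse, or `"auto"` to resolve it from the
#'   training matrix via [default_gamma()] at fit time. Ignored for the linear
#'   kernel.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("rbf", gamma = 0.5)
#' @export
kernel_spec <- function(kind = c("rbf", "linear"), gamma = "auto") {
  kind <- match.arg(kind)
  if (kind == "rbf" && !identical(gamma, "auto")) {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
        gamma <= 0) {
      stop("'gamma' must be a single positive finite number or \"auto\"")
    }
  }
  structure(list(kind = kind, gamma = gamma), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Kernel:", x$kind)
  if (x$kind == "rbf") cat(" (gamma =", format(x$gamma), ")")
  cat("\n")
  invisible(x)
}

#' Default RBF kernel width
#'
#' Resolves the RBF `gamma` from the data as
#' \eqn{\gamma = 1 / (M \cdot \mathrm{Var}(\mathrm{vec}(X)))}, where `M` is the
#' number of features and the variance is the population variance of the
#' flattened matrix. This scales the kernel width with both dimensionality and
#' the overall spread of the measurements.
#'
#' @param x Numeric cells-by-features matrix.
#' @return A single positive number.
#' @examples
#' default_gamma(matrix(c(0, 2, 0, 2), 2, 2))  # 1 / (2 * 1) = 0.5
#' @export
default_gamma <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0L) stop("'x' is empty")
  v <- mean(x^2) - mean(x)^2  # population variance of vec(X)
  if (!is.finite(v) || v <= 0) {
    stop("cannot resolve gamma: the matrix has zero variance")
  }
  1 / (ncol(x) * v)
}

#' Kernel matrix between two sets of rows
#'
#' @param a,b Numeric matrices with the same number of columns; rows are
#'   observations.
#' @param spec A [kernel_spec()].
#' @return The `nrow(a)` by `nrow(b)` kernel matrix.
#' @examples
#' compute_kernel(diag(2), diag(2), kernel_spec("linear"))
#' @export
compute_kernel <- function(a, b, spec) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) {
    stop(sprintf("feature dimension mismatch: %d vs %d", ncol(a), ncol(b)))
  }
  if (spec$kind == "linear") return(tcrossprod(a, b))
  gamma <- spec$gamma
  if (identical(gamma, "auto")) {
    stop("gamma = \"auto\" must be resolved (via default_gamma) before use")
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # guard against rounding
  exp(-gamma * d2)
}
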