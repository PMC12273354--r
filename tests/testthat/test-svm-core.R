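test_that("default gamma is the inverse of features times flattened variance", {
  expect_equal(default_gamma(matrix(c(0, 2, 0, 2), 2, 2)), 0.5)
  expect_error(default_gamma(matrix(3, 4, 4)), "variance")
  x <- withr::with_seed(1, matrix(rnorm(60), 10))
  expect_equal(default_gamma(3 * x), default_gamma(x) / 9)
})

test_that("kernel matrices match their closed forms", {
  x <- withr::with_seed(2, matrix(rnorm(20), 5))
  K <- compute_kernel(x, x, kernel_spec("rbf", gamma = 1))
  expect_equal(unname(diag(K)), rep(1, 5))
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  expect_equal(compute_kernel(rbind(c(0, 0)), rbind(c(1, 1)),
                              kernel_spec("rbf", gamma = 0.5))[1, 1],
               exp(-1))
  expect_equal(compute_kernel(rbind(c(1, 0)), rbind(c(0, 1)),
                              kernel_spec("linear"))[1, 1], 0)
  expect_error(compute_kernel(matrix(0, 2, 3), matrix(0, 2, 4),
                              kernel_spec("linear")), "mismatch")
})

test_that("the two-point dual has its known analytic solution", {
  x <- matrix(c(0, 2), 2, 1)
  K <- tcrossprod(x)
  m <- train_binary_svm(K, c(-1, 1), C = 10)
  expect_equal(m$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$bias, -1, tolerance = 1e-6)
  # decision boundary at x = 1: f(x) = x - 1
  f <- svm_decision(m, tcrossprod(matrix(c(0, 1, 2), 3, 1), x))
  expect_equal(f, c(-1, 0, 1), tolerance = 1e-6)
})

test_that("dual solutions satisfy the box and equality constraints and KKT", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, {
      x <- matrix(rnorm(40), 20, 2)
      y <- ifelse(x[, 1] + 0.5 * rnorm(20) > 0, 1L, -1L)
      if (length(unique(y)) < 2) y[1] <- -y[1]
      list(x = x, y = y)
    })
    C <- c(0.1, 1, 10)[(seed %% 3) + 1]
    K <- compute_kernel(dat$x, dat$x, kernel_spec("rbf", gamma = 0.5))
    m <- train_binary_svm(K, dat$y, C)
    a <- m$alpha
    expect_true(all(a >= -1e-9 & a <= C + 1e-9))
    expect_lt(abs(sum(a * dat$y)), 1e-6)
    # KKT: free SVs on the margin, bounded ones on the correct side
    f <- svm_decision(m, K)
    free <- a > 1e-6 & a < C - 1e-6
    if (any(free)) expect_lt(max(abs(dat$y[free] * f[free] - 1)), 5e-3)
    expect_true(all(dat$y[a < 1e-6] * f[a < 1e-6] >= 1 - 5e-3))
    expect_true(all(dat$y[a > C - 1e-6] * f[a > C - 1e-6] <= 1 + 5e-3))
  }
  K1 <- diag(2)
  expect_error(train_binary_svm(K1, c(1, 1), 1), "both classes")
})

test_that("small dual solutions match a brute-force grid-search oracle", {
  for (seed in 1:6) {
    dat <- withr::with_seed(seed, {
      x <- matrix(rnorm(8), 4, 2)
      y <- c(1L, 1L, -1L, -1L)
      list(x = x, y = y)
    })
    spec <- if (seed %% 2) kernel_spec("rbf", gamma = 0.7)
            else kernel_spec("linear")
    K <- compute_kernel(dat$x, dat$x, spec)
    C <- if (seed > 3) 1 else 5
    m <- train_binary_svm(K, dat$y, C, tol = 1e-6)
    orc <- oracle_svm_dual(K, dat$y, C)
    expect_equal(m$objective, orc$objective, tolerance = 1e-4)
  }
})

test_that("the dual solver agrees with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  dat <- withr::with_seed(10, {
    x <- matrix(rnorm(80), 40, 2)
    y <- ifelse(rowSums(x) + rnorm(40, sd = 0.5) > 0, 1, -1)
    list(x = x, y = y)
  })
  gamma <- 0.5; C <- 2
  K <- compute_kernel(dat$x, dat$x, kernel_spec("rbf", gamma = gamma))
  mine <- train_binary_svm(K, dat$y, C, tol = 1e-5)
  ref <- e1071::svm(dat$x, factor(dat$y, levels = c(1, -1)), scale = FALSE,
                    kernel = "radial", gamma = gamma, cost = C)
  co <- rep(0, 40); co[ref$index] <- ref$coefs
  ref_obj <- sum(abs(co)) - 0.5 * drop(crossprod(co, K %*% co))
  expect_equal(mine$objective, ref_obj, tolerance = 1e-3)
})

test_that("non-PSD kernel input triggers the jitter path with a warning", {
  K <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3 and -1
  expect_warning(m <- train_binary_svm(K, c(-1, 1), 1), "jitter")
  expect_true(all(is.finite(m$alpha)))
})

test_that("Platt scaling calibrates decision values into probabilities", {
  # symmetric decisions: intercept 0, probability one half at f = 0
  p <- fit_platt(c(-2, -1, 1, 2), c(-1, -1, 1, 1))
  expect_equal(p$B, 0, tolerance = 1e-6)
  expect_equal(platt_predict(p, 0), 0.5, tolerance = 1e-6)
  # perfect separation: probability increases with the decision value
  expect_lt(p$A, 0)
  f_grid <- seq(-3, 3, 0.5)
  expect_true(all(diff(platt_predict(p, f_grid)) > 0))
  expect_error(fit_platt(c(Inf, 1), c(-1, 1)), "finite")
  expect_error(fit_platt(c(1, 2), c(1, 1)), "both classes")
})

test_that("Platt parameters match an independent optimizer on the same loss", {
  for (seed in 1:3) {
    dat <- withr::with_seed(seed, {
      f <- rnorm(50)
      y <- ifelse(f + rnorm(50) > 0, 1L, -1L)
      list(f = f, y = y)
    })
    fit <- fit_platt(dat$f, dat$y)
    n_pos <- sum(dat$y == 1); n_neg <- sum(dat$y == -1)
    t_i <- ifelse(dat$y == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
    nll <- function(ab) {
      z <- ab[1] * dat$f + ab[2]
      sum(ifelse(z >= 0, t_i * z + log1p(exp(-z)),
                 (t_i - 1) * z + log1p(exp(z))))
    }
    ref <- optim(c(0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    expect_equal(c(fit$A, fit$B), ref$par, tolerance = 1e-6)
  }
})

test_that("pairwise coupling recovers consistent probabilities and handles symmetry", {
  # two classes reduce to the single pairwise estimate
  r2 <- matrix(c(0.5, 0.3, 0.7, 0.5), 2, 2)
  expect_equal(pairwise_coupling(r2), c(0.7, 0.3), tolerance = 1e-8)
  # full symmetry gives the uniform vector
  expect_equal(pairwise_coupling(matrix(0.5, 4, 4)), rep(0.25, 4),
               tolerance = 1e-8)
  # consistent pairwise ratios from p = (0.5, 0.3, 0.2) are inverted exactly
  p0 <- c(0.5, 0.3, 0.2)
  r <- diag(3) * 0 + 0.5
  for (i in 1:2) for (j in (i + 1):3) {
    r[i, j] <- p0[i] / (p0[i] + p0[j]); r[j, i] <- 1 - r[i, j]
  }
  expect_equal(pairwise_coupling(r), p0, tolerance = 1e-6)
  expect_error(pairwise_coupling(matrix(c(0.5, 1.2, -0.2, 0.5), 2, 2)),
               "strictly")
})

test_that("coupling matches a brute-force simplex search on random inputs", {
  for (seed in 1:6) {
    D <- if (seed <= 3) 3L else 4L
    r <- withr::with_seed(seed, {
      r <- matrix(0.5, D, D)
      for (i in seq_len(D - 1)) for (j in seq(i + 1, D)) {
        r[i, j] <- runif(1, 0.05, 0.95); r[j, i] <- 1 - r[i, j]
      }
      r
    })
    p <- pairwise_coupling(r)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    orc <- oracle_coupling(r)
    obj <- function(p) {
      s <- 0
      for (i in seq_len(D - 1)) for (j in seq(i + 1, D)) {
        s <- s + (r[j, i] * p[i] - r[i, j] * p[j])^2
      }
      s
    }
    expect_lt(abs(obj(p) - orc$objective), 1e-4)
    expect_equal(p, orc$p, tolerance = 1e-3)
  }
})
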