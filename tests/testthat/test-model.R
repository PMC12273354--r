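test_that("the default hyperparameter grid has six candidates in declared order", {
  g <- hyper_grid()
  expect_length(g, 6L)
  expect_equal(g[[1]], list(R = 0L, C = 0.1, gamma = "auto"))
  expect_equal(vapply(g, `[[`, numeric(1), "R"), c(0, 0, 0, 1, 1, 1))
  expect_equal(vapply(g, `[[`, numeric(1), "C"), c(0.1, 1, 10, 0.1, 1, 10))
  expect_length(hyper_grid(R = 1, C = 1), 1L)
  expect_error(hyper_grid(C = numeric(0)), "nonempty")
})

test_that("a separable toy is classified perfectly in-sample", {
  toy <- toy_two_class()
  m <- celltempo_fit(toy$x, toy$times, list(R = 1, C = 1, gamma = "auto"))
  expect_equal(predict(m, toy$x, type = "class"), toy$times)
  # deep inside a class the calibrated probability dominates
  P <- predict_proba(m, toy$x)
  expect_gt(P[1, "0"], 0.5)
  expect_gt(P[nrow(P), "1"], 0.5)
  # two-class probabilities equal the single pair's Platt output
  pr <- m$pairs[["1_2"]]
  K_new <- compute_kernel(toy$x, m$x, m$kernel)
  f <- svm_decision(pr$model, K_new[, pr$idx, drop = FALSE])
  expect_equal(unname(P[, 1]), unname(platt_predict(pr$platt, f)),
               tolerance = 1e-6)
})

test_that("degenerate fits are rejected with informative errors", {
  expect_error(celltempo_fit(matrix(1, 10, 3), rep(c(0, 1), 5)), "variance")
  x <- matrix(rnorm(12), 6, 2)
  expect_error(celltempo_fit(x, c(0, 0, 0, 0, 0, 7)), "7")
  expect_error(celltempo_fit(x, rep(3, 6)), "two distinct")
})

test_that("noiseless five-class simulation is memorized perfectly in-sample", {
  sim <- simulate_linear(sim_config(n_cells = 50, n_genes = 20,
                                    gaussian_sd = 0, seed = 2))
  expect_equal(sim$true_pseudotime, sim$time_labels)  # sd -> 0 identity
  m <- celltempo_fit(sim$matrix, sim$time_labels,
                     list(R = 1, C = 10, gamma = "auto"))
  expect_equal(predict(m, sim$matrix, type = "class"), sim$time_labels)
})

test_that("probability rows sum to one and pseudotime is the stated expectation", {
  expect_equal(pseudotime(matrix(c(1, 0, 0, 0, 0), 1), c(0, 3, 7, 11, 21)), 0)
  expect_equal(pseudotime(matrix(0.2, 1, 5), c(0, 3, 7, 11, 21)), 8.4)
  expect_equal(pseudotime(matrix(c(.1, .2, .3, .2, .2), 1),
                          c(0, 3, 7, 11, 21)), 9.1)
  expect_error(pseudotime(matrix(c(.5, .2), 1), c(0, 1)), "sum to 1")
  sim <- simulate_linear(sim_config(n_cells = 60, n_genes = 30, seed = 4))
  m <- celltempo_fit(sim$matrix, sim$time_labels,
                     list(R = 1, C = 1, gamma = "auto"))
  P <- predict_proba(m, sim$matrix)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_true(all(P >= 0 & P <= 1))
  pt <- pseudotime(P, sort(unique(sim$time_labels)))
  expect_true(all(pt >= 0 & pt <= 21))
})

test_that("inner selection prefers the RBF kernel on a radially separable layout", {
  # XOR-like layout: classes separable only with a nonlinear boundary
  dat <- withr::with_seed(6, {
    x <- matrix(rnorm(200, sd = 0.3), 100, 2)
    q <- rep(1:4, each = 25)
    x <- x + cbind(c(2, -2, -2, 2)[q], c(2, 2, -2, -2)[q])
    list(x = x, times = ifelse(q %in% c(1, 3), 0, 1))
  })
  sel <- inner_select(dat$x, dat$times, seed = 1)
  expect_equal(sel$R, 1L)
  # a singleton grid needs no selection
  g1 <- hyper_grid(R = 1, C = 10)
  expect_equal(inner_select(dat$x, dat$times, g1), g1[[1]])
  # ties are broken by grid order: on an easy toy all candidates hit 100%
  toy <- toy_two_class(n_per = 12, gap = 8)
  sel2 <- suppressWarnings(inner_select(toy$x, toy$times, seed = 1))
  acc <- attr(sel2, "accuracy")
  expect_equal(sel2[c("R", "C", "gamma")],
               hyper_grid()[[which.max(acc)]][c("R", "C", "gamma")])
  expect_equal(which.max(acc), match(max(acc), acc))
})

test_that("nested cross-validation partitions cells once and never leaks", {
  sim <- simulate_linear(sim_config(n_cells = 80, n_genes = 30, seed = 5))
  res <- suppressWarnings(
    nested_cv_predict(sim$matrix, sim$time_labels, cv = cv_config(seed = 9)))
  n <- 80
  # every cell predicted exactly once
  expect_equal(sort(unique(res$fold)), 1:5)
  expect_false(anyNA(res$pseudotime))
  expect_false(anyNA(res$probabilities))
  # ~20% of cells per test fold (stratified: exactly balanced here)
  expect_true(all(abs(table(res$fold) - n / 5) <= 2))
  # leakage audit: per fold, training indices exclude all test cells
  for (fd in 1:5) {
    expect_length(intersect(res$train_index[[fd]], which(res$fold == fd)), 0)
    expect_setequal(union(res$train_index[[fd]], which(res$fold == fd)), 1:n)
  }
  # determinism under a fixed seed
  res2 <- suppressWarnings(
    nested_cv_predict(sim$matrix, sim$time_labels, cv = cv_config(seed = 9)))
  expect_identical(res$probabilities, res2$probabilities)
  expect_identical(res$fold, res2$fold)
  # pseudotime stays inside the observed time range
  expect_true(all(res$pseudotime >= 0 & res$pseudotime <= 21))
  # recovers the temporal ordering out-of-fold
  expect_gte(kendall_tau_b(res$pseudotime, sim$time_labels), 0.8)
})

test_that("the in-sample variant memorizes a separable toy and is flagged noCV", {
  toy <- toy_two_class(n_per = 15, gap = 6)
  res <- suppressWarnings(fit_full_no_cv(toy$x, toy$times, seed = 3))
  expect_equal(res$predicted_class, toy$times)
  expect_equal(res$mode, "noCV")
  expect_s3_class(res$model, "celltempo_model")
})

test_that("parameter recovery: low-noise simulations are solved out-of-fold", {
  for (seed in 1:5) {
    sim <- simulate_linear(sim_config(gaussian_sd = 0.5, seed = seed))
    fit <- suppressWarnings(
      celltempo(sim$matrix, sim$time_labels, cv = cv_config(seed = seed)))
    s <- summary(fit)
    expect_gte(s$accuracy, 95)
    expect_gte(kendall_tau_b(fit$pseudotime, sim$true_pseudotime), 0.9)
  }
})

test_that("leave-one-time-point-out has structural zeros and temporal adjacency", {
  sim <- simulate_linear(sim_config(n_cells = 100, n_genes = 50,
                                    gaussian_sd = 0.5, seed = 8))
  lt <- suppressWarnings(
    leave_one_timepoint_out(sim$matrix, sim$time_labels, seed = 8))
  cm <- lt$confusion
  expect_equal(unname(diag(cm)), rep(0L, 5))
  expect_equal(unname(rowSums(cm)), as.vector(table(sim$time_labels)))
  expect_gt(adjacency_proportion(cm, lt$classes),
            expected_uniform_adjacency(rowSums(cm)))
  expect_error(leave_one_timepoint_out(sim$matrix[1:40, ],
                                       rep(c(0, 3), each = 20)),
               "3 time points")
})

test_that("LOTO adjacency beats the uniform null across seeded replicates", {
  hy <- list(R = 1, C = 1, gamma = "auto")
  wins <- 0L
  for (seed in 1:20) {
    sim <- simulate_linear(sim_config(n_cells = 60, n_genes = 25,
                                      gaussian_sd = 1, seed = seed))
    lt <- suppressWarnings(
      leave_one_timepoint_out(sim$matrix, sim$time_labels, hyper = hy,
                              seed = seed))
    obs <- adjacency_proportion(lt$confusion, lt$classes)
    if (obs > expected_uniform_adjacency(rowSums(lt$confusion))) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 19L)
})

test_that("the celltempo object supports the standard modelling methods", {
  sim <- simulate_linear(sim_config(n_cells = 60, n_genes = 25, seed = 12))
  fit <- suppressWarnings(
    celltempo(sim$matrix, sim$time_labels, cv = cv_config(seed = 12)))
  expect_s3_class(fit, "celltempo")
  expect_output(print(fit), "out-of-fold")
  s <- summary(fit)
  expect_s3_class(s, "summary.celltempo")
  expect_output(print(s), "Kendall")
  expect_equal(fitted(fit), fit$pseudotime)
  expect_equal(residuals(fit), fit$pseudotime - fit$times)
  expect_equal(predict(fit), fit$pseudotime)
  expect_error(predict(fit, sim$matrix), "refit")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  # a noCV fit can score new cells
  fit2 <- suppressWarnings(
    celltempo(sim$matrix, sim$time_labels, mode = "nocv",
              cv = cv_config(seed = 12)))
  pt_new <- predict(fit2, sim$matrix[1:5, ])
  expect_length(pt_new, 5L)
  expect_true(all(pt_new >= 0 & pt_new <= 21))
})

test_that("permutation importance singles out the informative feature", {
  dat <- withr::with_seed(21, {
    pt <- rep(c(0, 1, 2), each = 12) + rnorm(36, sd = 0.1)
    x <- cbind(signal = pt, matrix(rnorm(36 * 9), 36,
                                   dimnames = list(NULL, paste0("n", 1:9))))
    list(x = x, times = rep(c(0, 1, 2), each = 12))
  })
  m <- celltempo_fit(dat$x, dat$times, list(R = 1, C = 10, gamma = "auto"))
  imp <- permutation_importance(m, dat$x, dat$times, n_repeats = 3, seed = 1)
  expect_equal(names(which.max(imp)), "signal")
  expect_gt(imp["signal"], max(imp[-1]))
  expect_identical(imp, permutation_importance(m, dat$x, dat$times,
                                               n_repeats = 3, seed = 1))
})
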