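# Independent brute-force oracles used to validate the optimization and
# test-statistic code. These deliberately share no code with the package
# internals: plain grid searches and exhaustive enumerations at tiny n.

# Staged grid search for the SVM dual on <= 4 points: parametrize the last
# coefficient through the equality constraint and scan the rest, refining
# the grid around the incumbent.
oracle_svm_dual <- function(K, y, C, stages = 4L, grid_n = 21L) {
  n <- nrow(K)
  stopifnot(n <= 4L)
  obj <- function(a) {
    ay <- a * y
    sum(a) - 0.5 * drop(crossprod(ay, K %*% ay))
  }
  lo <- rep(0, n - 1L); hi <- rep(C, n - 1L)
  best <- NULL; best_obj <- -Inf
  for (s in seq_len(stages)) {
    grids <- lapply(seq_len(n - 1L), function(i) {
      seq(lo[i], hi[i], length.out = grid_n)
    })
    pts <- as.matrix(expand.grid(grids))
    a_last <- -y[n] * drop(pts %*% y[-n])
    ok <- a_last >= 0 & a_last <= C
    if (!any(ok)) stop("no feasible point on the oracle grid")
    pts <- pts[ok, , drop = FALSE]; a_last <- a_last[ok]
    vals <- vapply(seq_len(nrow(pts)), function(r) {
      obj(c(pts[r, ], a_last[r]))
    }, numeric(1))
    r <- which.max(vals)
    if (vals[r] > best_obj) {
      best_obj <- vals[r]; best <- c(pts[r, ], a_last[r])
    }
    step <- (hi - lo) / (grid_n - 1)
    lo <- pmax(0, best[-n] - step); hi <- pmin(C, best[-n] + step)
  }
  list(alpha = unname(best), objective = best_obj)
}

# Staged simplex grid search for the pairwise-coupling objective
# sum_{i<j} (r_ji p_i - r_ij p_j)^2, D <= 4.
oracle_coupling <- function(r, stages = 5L, grid_n = 21L) {
  D <- nrow(r)
  stopifnot(D <= 4L)
  obj <- function(p) {
    s <- 0
    for (i in seq_len(D - 1L)) for (j in seq(i + 1L, D)) {
      s <- s + (r[j, i] * p[i] - r[i, j] * p[j])^2
    }
    s
  }
  lo <- rep(0, D - 1L); hi <- rep(1, D - 1L)
  best <- NULL; best_obj <- Inf
  for (s in seq_len(stages)) {
    grids <- lapply(seq_len(D - 1L), function(i) {
      seq(lo[i], hi[i], length.out = grid_n)
    })
    pts <- as.matrix(expand.grid(grids))
    p_last <- 1 - rowSums(pts)
    ok <- p_last >= 0 & p_last <= 1
    pts <- pts[ok, , drop = FALSE]; p_last <- p_last[ok]
    vals <- vapply(seq_len(nrow(pts)), function(k) obj(c(pts[k, ], p_last[k])),
                   numeric(1))
    k <- which.min(vals)
    if (vals[k] < best_obj) {
      best_obj <- vals[k]; best <- c(pts[k, ], p_last[k])
    }
    step <- (hi - lo) / (grid_n - 1)
    lo <- pmax(0, best[-D] - step); hi <- pmin(1, best[-D] + step)
  }
  list(p = unname(best), objective = best_obj)
}

# Exact two-sided Fisher p by direct hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher <- function(tab) {
  m <- rowSums(tab); k <- colSums(tab)
  if (any(m == 0) || any(k == 0)) return(1)
  xs <- max(0, k[1] - m[2]):min(k[1], m[1])
  probs <- dhyper(xs, m[1], m[2], k[1])
  p_obs <- dhyper(tab[1, 1], m[1], m[2], k[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact signed-rank p by full enumeration of all 2^n sign patterns.
oracle_wilcoxon <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Tie-corrected Kendall tau-b by O(n^2) pair enumeration.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) next
    if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Small separable two-cluster toy shared by several model tests.
toy_two_class <- function(n_per = 10, gap = 4, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
               matrix(rnorm(n_per * 2, mean = gap), ncol = 2))
  })
  list(x = x, times = rep(c(0, 1), each = n_per))
}
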