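#' Simulation configuration
#'
#' Collects the constants of the synthetic differentiation time courses:
#' 200 cells spread over the five collection days \{0, 3, 7, 11, 21\}, a
#' Gaussian pseudotime around each cell's collection day, min-max
#' normalization of the pseudotime onto \[0, 21\], projection onto 500 genes,
#' and (for the bifurcating variant) branch assignment with probability 0.5.
#'
#' @param n_cells Number of cells (default 200).
#' @param time_points Strictly increasing numeric collection times
#'   (default `c(0, 3, 7, 11, 21)`).
#' @param gaussian_sd Standard deviation of the per-cell pseudotime around its
#'   collection day (default 2, comparable to the smallest inter-day gap of 3
#'   so that neighbouring days overlap realistically).
#' @param n_genes Number of projected genes (default 500).
#' @param norm_range Length-2 range the pseudotime is rescaled onto
#'   (default `c(0, 21)`).
#' @param branch_prob Probability of branch A for cells past the trunk in the
#'   bifurcating simulation (default 0.5).
#' @param assignment `"balanced"` gives each collection day `n_cells / D`
#'   cells with any remainder going to the earliest days; `"uniform"` samples
#'   each cell's day uniformly at random.
#' @param seed Integer seed recorded with the dataset and used for all
#'   sampling.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 200L, time_points = c(0, 3, 7, 11, 21),
                       gaussian_sd = 2, n_genes = 500L,
                       norm_range = c(0, 21), branch_prob = 0.5,
                       assignment = c("balanced", "uniform"), seed = 0L) {
  assignment <- match.arg(assignment)
  if (any(diff(time_points) <= 0)) {
    stop("'time_points' must be strictly increasing")
  }
  if (n_cells < length(time_points)) {
    stop("'n_cells' must be at least the number of time points")
  }
  if (gaussian_sd < 0) stop("'gaussian_sd' must be nonnegative")
  if (n_genes < 1L) stop("'n_genes' must be positive")
  if (length(norm_range) != 2L || norm_range[1] >= norm_range[2]) {
    stop("'norm_range' must be c(lo, hi) with lo < hi")
  }
  if (branch_prob < 0 || branch_prob > 1) stop("'branch_prob' must be in [0,1]")
  structure(list(n_cells = as.integer(n_cells), time_points = time_points,
                 gaussian_sd = gaussian_sd, n_genes = as.integer(n_genes),
                 norm_range = norm_range, branch_prob = branch_prob,
                 assignment = assignment, seed = as.integer(seed)),
            class = "sim_config")
}

#' Assign collection days and draw raw pseudotimes
#'
#' Each cell is assigned to an observed collection day and its latent
#' pseudotime is drawn from a Gaussian centred on that day with standard
#' deviation `config$gaussian_sd`.
#'
#' @param config A [sim_config()].
#' @return List with `time_labels` (per-cell observed day) and `raw` (per-cell
#'   unnormalized pseudotime).
#' @export
sample_pseudotimes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$time_points
  D <- length(tp)
  n <- config$n_cells
  withr::with_seed(config$seed, {
    if (config$assignment == "balanced") {
      base <- n %/% D
      extra <- n %% D
      counts <- rep(base, D) + c(rep(1L, extra), rep(0L, D - extra))
      labels <- rep(tp, counts)
    } else {
      labels <- sample(tp, n, replace = TRUE)
    }
    raw <- stats::rnorm(n, mean = labels, sd = config$gaussian_sd)
  })
  list(time_labels = labels, raw = raw)
}

#' Min-max rescale a pseudotime vector onto a target range
#'
#' Affine rescaling so that the minimum maps to `norm_range[1]` and the
#' maximum to `norm_range[2]`; rank order is preserved exactly (ties map to
#' equal values).
#'
#' @param raw Numeric vector with at least two distinct values.
#' @param norm_range Length-2 target range.
#' @return Rescaled vector.
#' @examples
#' normalize_pseudotime(c(1, 2, 3), c(0, 21))  # 0, 10.5, 21
#' @export
normalize_pseudotime <- function(raw, norm_range = c(0, 21)) {
  rng <- range(raw)
  if (!all(is.finite(rng))) stop("'raw' must be finite")
  if (rng[1] == rng[2]) {
    stop("cannot normalize a constant pseudotime vector")
  }
  norm_range[1] + (raw - rng[1]) / (rng[2] - rng[1]) *
    (norm_range[2] - norm_range[1])
}

#' Simulate a linear differentiation trajectory
#'
#' Draws per-cell pseudotimes (see [sample_pseudotimes()]), min-max rescales
#' them onto `norm_range`, and projects the scalar pseudotime onto
#' `n_genes` genes by multiplying with independent standard Gaussian
#' projection weights: `expr[n, g] = pt[n] * w[g]`. Every gene is therefore an
#' exact linear function of the true pseudotime.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_dataset`: list with `matrix` (cells by
#'   genes, dimnames set), `time_labels`, `true_pseudotime`, `config`, and
#'   `mode = "linear"`.
#' @export
simulate_linear <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pts <- sample_pseudotimes(config)
  pt <- normalize_pseudotime(pts$raw, config$norm_range)
  w <- withr::with_seed(config$seed + 1L,
                        stats::rnorm(config$n_genes))
  m <- outer(pt, w)
  dimnames(m) <- list(sprintf("cell_%d", seq_len(config$n_cells)),
                      sprintf("gene_%d", seq_len(config$n_genes)))
  structure(list(matrix = m, time_labels = pts$time_labels,
                 true_pseudotime = pt, branch = NULL,
                 config = config, mode = "linear"),
            class = "sim_dataset")
}

#' Simulate a bifurcating differentiation trajectory
#'
#' As [simulate_linear()], except that cells from the last three collection
#' days are assigned to one of two branches with probability `branch_prob`,
#' each branch carries its own vector of Gaussian projection weights, and the
#' projection is cubed elementwise:
#' `expr[n, g] = (pt[n] * w_branch(n)[g])^3`, giving each gene a nonlinear
#' (but still monotone per branch) relationship with pseudotime. Trunk cells
#' (the first two collection days) are also assigned a random branch, so the
#' two branches coincide near pseudotime zero and diverge later; the per-cell
#' branch is recorded so the choice is auditable.
#'
#' @param config A [sim_config()]; needs at least four time points.
#' @return A `sim_dataset` with a per-cell `branch` factor (`"A"`/`"B"`) and
#'   `mode = "bifurcating"`.
#' @export
simulate_bifurcating <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$time_points) < 4L) {
    stop("the bifurcating simulation needs at least 4 time points")
  }
  pts <- sample_pseudotimes(config)
  pt <- normalize_pseudotime(pts$raw, config$norm_range)
  n <- config$n_cells
  out <- withr::with_seed(config$seed + 1L, {
    wA <- stats::rnorm(config$n_genes)
    wB <- stats::rnorm(config$n_genes)
    branch <- ifelse(stats::runif(n) < config$branch_prob, "A", "B")
    list(wA = wA, wB = wB, branch = branch)
  })
  w <- rbind(A = out$wA, B = out$wB)
  m <- (pt * w[out$branch, , drop = FALSE])^3
  dimnames(m) <- list(sprintf("cell_%d", seq_len(n)),
                      sprintf("gene_%d", seq_len(config$n_genes)))
  structure(list(matrix = m, time_labels = pts$time_labels,
                 true_pseudotime = pt,
                 branch = factor(out$branch, levels = c("A", "B")),
                 config = config, mode = "bifurcating"),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated %s trajectory: %d cells x %d genes\n",
              x$mode, nrow(x$matrix), ncol(x$matrix)))
  cat("Time points:", paste(x$config$time_points, collapse = ", "), "\n")
  cat(sprintf("True pseudotime range: [%.3g, %.3g]\n",
              min(x$true_pseudotime), max(x$true_pseudotime)))
  invisible(x)
}

#' Robustness perturbations for simulated matrices
#'
#' `apply_dropout()` zeroes each entry independently with probability `rate`;
#' `apply_noise()` adds i.i.d. Gaussian noise with standard deviation `sd`;
#' `append_irrelevant_genes()` appends `k` columns of pure standard Gaussian
#' noise carrying no pseudotime signal. These emulate, respectively, dropout,
#' measurement noise, and uninformative features.
#'
#' @param m Numeric matrix.
#' @param rate Dropout probability in \[0, 1\].
#' @param sd Noise standard deviation, nonnegative.
#' @param k Number of noise genes to append, nonnegative.
#' @param seed Integer seed.
#' @return A matrix of the same (or, for `append_irrelevant_genes`, widened)
#'   shape.
#' @export
apply_dropout <- function(m, rate, seed = 0L) {
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]")
  if (rate == 0) return(m)
  mask <- withr::with_seed(seed, stats::runif(length(m)) < rate)
  m[mask] <- 0
  m
}

#' @rdname apply_dropout
#' @export
apply_noise <- function(m, sd, seed = 0L) {
  if (sd < 0) stop("'sd' must be nonnegative")
  if (sd == 0) return(m)
  m + withr::with_seed(seed, matrix(stats::rnorm(length(m), sd = sd), nrow(m)))
}

#' @rdname apply_dropout
#' @export
append_irrelevant_genes <- function(m, k, seed = 0L) {
  if (k < 0) stop("'k' must be nonnegative")
  if (k == 0) return(m)
  noise <- withr::with_seed(seed, matrix(stats::rnorm(nrow(m) * k), nrow(m)))
  colnames(noise) <- sprintf("noise_%d", seq_len(k))
  cbind(m, noise)
}
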