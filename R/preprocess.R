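#' Standard scRNA-seq feature preparation
#'
#' Applies the usual count-matrix recipe: drop low-quality cells (fewer than
#' `min_features` nonzero features or zero total counts), scale each
#' remaining cell to `target_sum` total counts, `log1p`-transform, and keep
#' the `n_hvg` most variable genes (variance of the log-normalized values,
#' ties broken by feature order). When fewer than `n_hvg` genes are present,
#' all genes are kept.
#'
#' @param raw Nonnegative cells-by-genes count matrix (dense or `Matrix`
#'   sparse) with row and column names.
#' @param min_features Minimum number of nonzero features per cell
#'   (default 200).
#' @param target_sum Per-cell total after normalization (default 1e4).
#' @param n_hvg Number of highly variable genes to retain (default 1000).
#' @return Dense log-normalized cells-by-genes matrix restricted to the
#'   selected genes.
#' @export
preprocess_rna <- function(raw, min_features = 200L, target_sum = 1e4,
                           n_hvg = 1000L) {
  m <- as.matrix(raw)
  if (any(m < 0)) stop("counts must be nonnegative")
  nz <- rowSums(m > 0)
  keep <- nz >= min_features & rowSums(m) > 0
  if (!any(keep)) stop("all cells were filtered out")
  m <- m[keep, , drop = FALSE]
  m <- m / rowSums(m) * target_sum
  m <- log1p(m)
  if (ncol(m) > n_hvg) {
    v <- apply(m, 2, stats::var)
    ord <- order(-v, seq_along(v))     # ties by feature order
    m <- m[, sort(ord[seq_len(n_hvg)]), drop = FALSE]
  }
  m
}

#' scATAC-seq feature preparation
#'
#' Binarizes the cell-by-peak matrix, drops zero-variance peaks and keeps the
#' `n_peaks` most variable ones (binarized variance), performs library-size
#' normalization (each cell scaled to `target_sum`) followed by `log1p`, and
#' returns the cell scores on the top `n_components` principal components
#' (columns centred, not scaled; each component's sign fixed so that its
#' largest-magnitude loading is positive).
#'
#' @param raw Nonnegative cells-by-peaks matrix.
#' @param n_components Number of principal components (default 50).
#' @param n_peaks Number of variable peaks to keep before PCA (default all
#'   nonconstant peaks).
#' @param target_sum Per-cell total used in library-size normalization.
#' @return Cells-by-`n_components` PC score matrix.
#' @export
preprocess_atac <- function(raw, n_components = 50L, n_peaks = NULL,
                            target_sum = 1e4) {
  m <- as.matrix(raw)
  if (any(m < 0)) stop("counts must be nonnegative")
  m[m > 0] <- 1
  v <- apply(m, 2, stats::var)
  keep <- which(v > 0)
  if (length(keep) == 0L) stop("no peak varies across cells")
  if (!is.null(n_peaks) && length(keep) > n_peaks) {
    ord <- order(-v[keep], keep)
    keep <- sort(keep[ord[seq_len(n_peaks)]])
  }
  m <- m[, keep, drop = FALSE]
  if (n_components > min(dim(m))) {
    stop(sprintf("n_components (%d) exceeds min(cells, peaks) = %d",
                 n_components, min(dim(m))))
  }
  rs <- rowSums(m)
  if (any(rs == 0)) stop("cells with no accessible peaks cannot be normalized")
  m <- log1p(m / rs * target_sum)
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE,
                       rank. = as.integer(n_components))
  scores <- pca$x
  for (j in seq_len(ncol(scores))) {    # deterministic sign convention
    load <- pca$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Balance classes by random downsampling
#'
#' Randomly subsamples each time-point class without replacement down to the
#' smallest class size, so that every class contributes equally.
#'
#' @param m Cells-by-features matrix.
#' @param labels Per-cell time labels, one per row of `m`.
#' @param seed Integer seed.
#' @return List with the subsetted `matrix` and `labels` (original row order
#'   preserved; cell-label pairing untouched).
#' @examples
#' m <- matrix(rnorm(16), 8, 2)
#' balance_downsample(m, c(0, 0, 0, 0, 0, 3, 3, 3), seed = 1)
#' @export
balance_downsample <- function(m, labels, seed = 0L) {
  m <- as.matrix(m)
  if (nrow(m) != length(labels)) stop("one label per row of 'm' is required")
  sizes <- table(labels)
  if (any(sizes == 0)) stop("every class must be nonempty")
  k <- min(sizes)
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(labels), labels),
                  function(i) if (length(i) == k) i else sample(i, k)),
           use.names = FALSE)
  })
  idx <- sort(idx)
  list(matrix = m[idx, , drop = FALSE], labels = labels[idx])
}
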