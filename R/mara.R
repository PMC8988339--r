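# Motif activity response analysis (MARA): decompose a peak-by-sample
# signal matrix into motif site counts times per-sample motif activities,
# fit by ridge regression with a shared penalty chosen by generalized
# cross-validation.

#' Motif activity response analysis
#'
#' Fits the linear model `x~(p, s) ~ sum_m N~(p, m) * A(m, s)`, where `x~`
#' is the signal matrix after `log2(x + 1)` (optional), peak(row)-centering
#' and sample(column)-centering, and `N~` is the column-centered site-count
#' matrix. Activities `A` are estimated per sample by ridge regression with
#' a single penalty `lambda` shared across samples, selected from
#' `lambda_grid` by leave-one-out generalized cross-validation averaged
#' over samples. Activity rows are centered across samples
#' (identifiability); per-motif variability is the standard deviation of
#' the activity across samples, used to report the most variable motifs.
#'
#' @param peak_signal Peak-by-sample numeric matrix (>= 2 samples).
#' @param site_counts Peak-by-motif numeric matrix; rows must align with
#'   `peak_signal` (matched by rownames when present).
#' @param lambda_grid Candidate ridge penalties (default: log-spaced
#'   `10^-2 ... 10^3`). `lambda = 0` is refused when the site-count matrix
#'   is rank deficient.
#' @param log_transform Apply `log2(x + 1)` before centering (default
#'   `TRUE`); set `FALSE` when the input is already on a linear scale.
#' @return A `mara_result`: list with `activity` (motif-by-sample matrix,
#'   rows centered), `site_counts`, `lambda` (selected penalty),
#'   `variability` (named per-motif sd, descending), and `gcv`
#'   (`data.frame` of `lambda`, `score`).
#' @export
tf_mara <- function(peak_signal, site_counts,
                    lambda_grid = 10^seq(-2, 3, length.out = 21),
                    log_transform = TRUE) {
  X <- as.matrix(peak_signal)
  N <- as.matrix(site_counts)
  if (!is.null(rownames(X)) && !is.null(rownames(N))) {
    miss <- setdiff(rownames(X), rownames(N))
    if (length(miss)) .stopf("peak(s) missing from site_counts: %s", miss[1])
    N <- N[rownames(X), , drop = FALSE]
  } else if (nrow(X) != nrow(N)) {
    .stopf("peak_signal (%d rows) and site_counts (%d rows) do not align",
           nrow(X), nrow(N))
  }
  if (ncol(X) < 2) .stopf("need >= 2 samples")
  if (log_transform) {
    if (any(X < 0))
      .stopf("negative signal values; supply counts or use log_transform = FALSE")
    X <- log2(X + 1)
  }
  X <- X - rowMeans(X)          # peak centering
  X <- sweep(X, 2, colMeans(X)) # sample centering
  Nc <- sweep(N, 2, colMeans(N))
  sv <- svd(Nc)
  tol <- max(dim(Nc)) * max(sv$d) * .Machine$double.eps
  rank_def <- any(sv$d < tol)
  if (rank_def && any(lambda_grid <= 0))
    .stopf("site-count matrix is rank deficient; use lambda > 0")
  d <- sv$d
  Uty <- crossprod(sv$u, X)     # r x S
  n <- nrow(X)
  gcv <- vapply(lambda_grid, function(lam) {
    shr <- d^2 / (d^2 + lam)
    df <- sum(shr)
    # residual sum of squares per sample via the SVD identity
    fit_part <- shr * Uty
    rss <- colSums(Uty^2) - 2 * colSums(Uty * fit_part) + colSums(fit_part^2) +
      (colSums(X^2) - colSums(Uty^2))
    mean(n * rss / (n - df)^2)
  }, numeric(1))
  lam <- lambda_grid[which.min(gcv)]
  A <- sv$v %*% ((d / (d^2 + lam)) * Uty)
  rownames(A) <- colnames(N)
  colnames(A) <- colnames(X)
  A <- A - rowMeans(A)
  variability <- sort(apply(A, 1, sd), decreasing = TRUE)
  structure(list(activity = A, site_counts = N, lambda = lam,
                 variability = variability,
                 gcv = data.frame(lambda = lambda_grid, score = gcv)),
            class = "mara_result")
}

#' @export
print.mara_result <- function(x, ...) {
  cat(sprintf("mara_result: %d motif(s) x %d sample(s), lambda = %g\n",
              nrow(x$activity), ncol(x$activity), x$lambda))
  cat("most variable motifs:",
      paste(head(names(x$variability), 5), collapse = ", "), "\n")
  invisible(x)
}

#' Top variable motifs from a MARA fit
#'
#' @param x `mara_result` object.
#' @param k Number of motifs (default 40).
#' @return Character vector of motif ids, most variable first.
#' @export
top_variable_motifs <- function(x, k = 40) {
  stopifnot(inherits(x, "mara_result"))
  head(names(x$variability), k)
}
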