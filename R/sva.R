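#' Estimate surrogate variables from group-model residuals
#'
#' Residualizes every gene on its group means and takes the top `K` right
#' singular vectors of the residual matrix as orthonormal array-level
#' surrogate variables.  These span the dominant directions of expression
#' variation not explained by the phenotype, e.g. a shared technical array
#' effect, and can then be adjusted for in per-gene regression tests
#' ([sva_test()]).
#'
#' @param m An `"expr_matrix"`.
#' @param K Number of surrogate variables, `0 <= K < n_arrays(m) - 2`.
#' @return An arrays x `K` numeric matrix with orthonormal columns
#'   (rownames = array ids).  `K = 0` gives a zero-column matrix.
#' @export
estimate_surrogates <- function(m, K = 2L) {
  N <- ncol(m$values)
  if (K < 0L || K >= N - 2L)
    stop("K must satisfy 0 <= K < number of arrays - 2", call. = FALSE)
  H <- matrix(numeric(0), nrow = N, ncol = 0L)
  if (K > 0L) {
    resid <- m$values
    for (g in c("A", "B")) {
      cols <- group_cols(m, g)
      resid[, cols] <- resid[, cols] - rowMeans(resid[, cols, drop = FALSE])
    }
    H <- svd(resid, nu = 0L, nv = K)$v
  }
  rownames(H) <- colnames(m$values)
  H
}

#' Nested-model F-test for group effect, adjusting for surrogate variables
#'
#' Per gene, fits by ordinary least squares a null model (intercept +
#' surrogate variables) and a full model (the same plus the group
#' indicator) and reports the nested-model F statistic with its p-value.
#' With `K = 0` surrogate variables this reduces exactly to the two-sided
#' pooled-variance t-test (F = t^2).
#'
#' @param m An `"expr_matrix"`.
#' @param sv Surrogate variable matrix from [estimate_surrogates()]
#'   (arrays x K).
#' @return A [test_result()] data frame; `statistic` is the F value.
#' @export
sva_test <- function(m, sv) {
  N <- ncol(m$values)
  if (nrow(sv) != N)
    stop("surrogate variable rows must match the number of arrays",
         call. = FALSE)
  group <- as.numeric(m$groups == "A")
  X0 <- cbind(1, sv)
  X1 <- cbind(X0, group)
  qr1 <- qr(X1)
  if (qr1$rank < ncol(X1))
    stop("design matrix (intercept + surrogates + group) is rank-deficient",
         call. = FALSE)
  Y <- t(m$values)
  rss0 <- colSums(qr.resid(qr(X0), Y)^2)
  rss1 <- colSums(qr.resid(qr1, Y)^2)
  df1 <- N - ncol(X1)
  f <- (rss0 - rss1) / (rss1 / df1)
  p <- stats::pf(f, 1, df1, lower.tail = FALSE)
  test_result(rownames(m$values), f, p)
}
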