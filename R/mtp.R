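#' Bonferroni adjustment with strict rejection
#'
#' Familywise-error-rate control: `p_adj = min(1, G * p)`.  A gene is
#' rejected when its adjusted p-value is strictly below `alpha`.  The
#' strict inequality is deliberate: it is measure-zero for continuous
#' p-values but matters for permutation p-values, whose support includes
#' exact multiples of `1 / (n_perm + 1)`.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\], or a
#'   [test_result()] data frame (its `p_raw` column is used and gene ids
#'   are carried through).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return A data frame with columns `gene_id` (if available), `p_raw`,
#'   `p_adj`, `rejected`, and attribute `alpha`.
#' @export
adjust_bonferroni <- function(p, alpha = 0.05) {
  .adjust(p, alpha, "bonferroni")
}

#' Benjamini-Hochberg adjustment with strict rejection
#'
#' False-discovery-rate control by the step-up procedure: with ordered
#' p-values `p_(1) <= ... <= p_(G)`, `q_(i) = p_(i) * G / i` made monotone
#' by a cumulative minimum from the largest rank, mapped back to the
#' original order.  Rejection uses the same strict `p_adj < alpha` rule as
#' [adjust_bonferroni()]; for distinct p-values the rejection set equals
#' the classical step-up rule's.
#'
#' @inheritParams adjust_bonferroni
#' @return As for [adjust_bonferroni()].
#' @export
adjust_bh <- function(p, alpha = 0.05) {
  .adjust(p, alpha, "BH")
}

.adjust <- function(p, alpha, method) {
  gene_ids <- NULL
  if (is.data.frame(p)) {
    gene_ids <- p$gene_id
    p <- p$p_raw
  }
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("raw p-values must lie in [0, 1]", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  p_adj <- stats::p.adjust(p, method = method)
  out <- data.frame(p_raw = p, p_adj = p_adj, rejected = p_adj < alpha)
  if (!is.null(gene_ids)) out <- cbind(gene_id = gene_ids, out)
  attr(out, "alpha") <- alpha
  out
}
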