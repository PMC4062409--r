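#' Identity normalization
#'
#' Returns the matrix unchanged; the baseline every other procedure is
#' compared against.
#'
#' @param m An `"expr_matrix"`.
#' @return `m`, untouched.
#' @export
normalize_none <- function(m) m

#' Global (array mean-centering) normalization
#'
#' Subtracts from each value the mean over all genes on its array, so every
#' column mean becomes zero.  This removes any additive per-array effect
#' exactly, but the subtracted mean contains the differentially expressed
#' genes' signal, which biases group differences when up- and
#' down-regulation do not cancel.
#'
#' @param m An `"expr_matrix"`.
#' @return The centered `"expr_matrix"`.
#' @export
normalize_global <- function(m) {
  m$values <- sweep(m$values, 2L, colMeans(m$values))
  m
}

#' Rank normalization
#'
#' Replaces every value by its fractional rank within the array: rank
#' divided by the number of genes, so each tie-free column is a permutation
#' of 1/G, ..., G/G.  Ties get the average fractional rank (midranks).  The
#' output is invariant under any strictly increasing per-column transform
#' of the input.
#'
#' @param m An `"expr_matrix"`.
#' @return The rank-normalized `"expr_matrix"`.
#' @export
normalize_rank <- function(m) {
  G <- nrow(m$values)
  m$values[] <- apply(m$values, 2L, rank, ties.method = "average") / G
  m
}

#' Quantile-normalization reference array
#'
#' The reference is the average across all arrays (both phenotypic groups
#' pooled) of each array's sorted values: entry k is the mean k-th order
#' statistic.
#'
#' @param m An `"expr_matrix"`.
#' @return Numeric nondecreasing vector of length `n_genes(m)`.
#' @export
quantile_reference <- function(m) {
  unname(rowMeans(apply(m$values, 2L, sort, method = "radix")))
}

#' Quantile normalization
#'
#' Each array's values are replaced by the entries of the reference array
#' ([quantile_reference()]) with the same rank, so all columns share
#' identical sorted values and identical means while within-column rank
#' order is preserved.  Ties are broken by original gene index (stable
#' sort), which makes the procedure deterministic and idempotent on
#' tie-free data.
#'
#' @param m An `"expr_matrix"`.
#' @param reference Optional reference vector; defaults to the reference
#'   computed from `m` itself.  Supplying one allows normalizing new arrays
#'   against a frozen reference.
#' @return The quantile-normalized `"expr_matrix"`.
#' @export
normalize_quantile <- function(m, reference = NULL) {
  ref <- if (is.null(reference)) quantile_reference(m) else reference
  if (length(ref) != nrow(m$values))
    stop("reference length must equal the number of genes", call. = FALSE)
  if (is.unsorted(ref))
    stop("reference must be nondecreasing", call. = FALSE)
  m$values[] <- apply(m$values, 2L, function(col) {
    out <- numeric(length(col))
    out[order(col)] <- ref  # order() is stable: ties keep gene-index order
    out
  })
  m
}

#' Delta-sequence pairing of variance-matched genes
#'
#' Sorts genes ascending by their sample variance (ties broken by original
#' gene index) and records the differences between successive genes in
#' this order, twice: offset-0 pairs (1,2), (3,4), ... and offset-1 pairs
#' (2,3), (4,5), ..., (G,1), the last gene paired cyclically with the
#' first.  Each difference series inherits the array/group structure, so
#' any per-gene test can be applied to the pairs.  Pairing genes of
#' similar variance normalizes each gene by a same-noise "reference gene"
#' while cancelling any shared per-array effect exactly.
#'
#' By default the sorting variance is the within-group (group-centered)
#' sample variance, i.e. the pooled noise variance that also feeds the
#' t-test denominator.  Sorting by the total variance over all arrays
#' (`sort_by = "pooled"`) is also provided, but with strong differential
#' signal it inflates the DEGs' variances, sorts them next to each other,
#' and their pair differences cancel the very signal being tested; the
#' noise-variance sort keeps DEGs interspersed among null genes, which is
#' what gives the method its power cap of roughly `1 - gamma` and its
#' stable false-positive count.
#'
#' With an odd number of genes the lowest-variance gene is dropped with a
#' warning (an even count is assumed).
#'
#' @param m An `"expr_matrix"`.
#' @param sort_by `"within_group"` (default) or `"pooled"`: the sample
#'   variance used to order the genes.
#' @return An object of class `"paired_diffs"`: list with
#'   \describe{
#'     \item{order}{gene ids in ascending-variance order (after any drop);}
#'     \item{diffs0, diffs1}{`"expr_matrix"` objects of pair differences
#'       (second member minus first, in sorted order), one row per pair;}
#'     \item{pairs0, pairs1}{two-column character matrices of the member
#'       gene ids of each pair;}
#'     \item{dropped}{id of the dropped gene, or `NULL`.}
#'   }
#' @export
delta_pair <- function(m, sort_by = c("within_group", "pooled")) {
  sort_by <- match.arg(sort_by)
  sort_var <- function(v) {
    if (sort_by == "pooled") return(apply(v, 1L, stats::var))
    ia <- group_cols(m, "A"); ib <- group_cols(m, "B")
    a <- v[, ia, drop = FALSE]; b <- v[, ib, drop = FALSE]
    (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) /
      (length(ia) + length(ib) - 2L)
  }
  v <- m$values
  dropped <- NULL
  if (nrow(v) %% 2L == 1L) {
    vars <- sort_var(v)
    drop_idx <- which.min(vars)  # ties: which.min takes the first index
    dropped <- rownames(v)[drop_idx]
    warning("odd number of genes: dropping lowest-variance gene ", dropped,
            call. = FALSE)
    v <- v[-drop_idx, , drop = FALSE]
  }
  G <- nrow(v)
  vars <- sort_var(v)
  ord <- order(vars)  # stable: equal variances keep original gene order
  vs <- v[ord, , drop = FALSE]
  ids <- rownames(vs)

  first0 <- seq(1L, G, by = 2L)
  second0 <- first0 + 1L
  d0 <- vs[second0, , drop = FALSE] - vs[first0, , drop = FALSE]
  rownames(d0) <- paste0("pair0_", seq_len(G %/% 2L))

  first1 <- seq(2L, G, by = 2L)
  second1 <- c(seq(3L, G, by = 2L), 1L)
  d1 <- vs[second1, , drop = FALSE] - vs[first1, , drop = FALSE]
  rownames(d1) <- paste0("pair1_", seq_len(G %/% 2L))

  structure(list(
    order = ids,
    diffs0 = expression_matrix(d0, m$groups),
    diffs1 = expression_matrix(d1, m$groups),
    pairs0 = cbind(ids[first0], ids[second0]),
    pairs1 = cbind(ids[first1], ids[second1]),
    dropped = dropped
  ), class = "paired_diffs")
}

#' Break delta-sequence pairs into a gene list
#'
#' Given per-pair rejection results for both pairings of [delta_pair()],
#' reports the genes whose offset-0 pair AND offset-1 pair were both
#' rejected (the intersection of the two unpaired gene sets).
#'
#' @param res0,res1 Adjusted results (see [adjust_bonferroni()]) for the
#'   offset-0 and offset-1 pair differences, in pair order.
#' @param pd The `"paired_diffs"` object the results were computed from.
#' @return Character vector of selected gene ids.
#' @export
delta_select <- function(res0, res1, pd) {
  if (nrow(res0) != nrow(pd$pairs0) || nrow(res1) != nrow(pd$pairs1))
    stop("pair counts of results and pairing disagree", call. = FALSE)
  hit0 <- unique(as.vector(pd$pairs0[res0$rejected, , drop = FALSE]))
  hit1 <- unique(as.vector(pd$pairs1[res1$rejected, , drop = FALSE]))
  intersect(hit0, hit1)
}
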