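#' Define a gene-selection strategy
#'
#' A strategy is a normalization procedure, a per-gene test, and a
#' multiple-testing procedure with its significance level, run in that
#' order.  Two combinations get special handling:
#' \itemize{
#'   \item `normalization = "sva"` uses the nested-model F-test
#'     ([sva_test()]) and therefore only combines with `test = "t"` (the
#'     F-test is the regression form of the pooled t);
#'   \item `normalization = "delta"` applies the chosen test and MTP to
#'     both delta-sequence pairings and selects genes whose pairs are
#'     rejected in both ([delta_select()]).
#' }
#'
#' @param normalization One of `"none"`, `"global"`, `"rank"`,
#'   `"quantile"`, `"delta"`, `"sva"`.
#' @param test One of `"t"`, `"modt"`, `"wilcox"`, `"nstat"`.
#' @param mtp `"bonf"` or `"bh"`.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param K Number of surrogate variables when `normalization = "sva"`.
#' @param n_perm Permutation count for `test = "nstat"`.
#' @return A list of class `"strategy"`.
#' @export
strategy <- function(normalization = c("none", "global", "rank",
                                       "quantile", "delta", "sva"),
                     test = c("t", "modt", "wilcox", "nstat"),
                     mtp = c("bonf", "bh"), alpha = 0.05, K = 2L,
                     n_perm = 10000L) {
  normalization <- match.arg(normalization)
  test <- match.arg(test)
  mtp <- match.arg(mtp)
  if (normalization == "sva" && test != "t")
    stop("SVA combines only with the regression F-test (test = \"t\")",
         call. = FALSE)
  structure(list(normalization = normalization, test = test, mtp = mtp,
                 alpha = alpha, K = as.integer(K),
                 n_perm = as.integer(n_perm)),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat("strategy: ", x$normalization, " + ", x$test, " + ", x$mtp,
      " @ alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Count true and false positives of a selection
#'
#' @param selected Character vector of selected gene ids.
#' @param truth A `"truth_set"`.
#' @return List with integer `tp` (selected genes that are truly up or
#'   down) and `fp` (selected null genes).
#' @export
count_tp_fp <- function(selected, truth) {
  cls <- truth$class_of[selected]
  list(tp = sum(cls != "null"), fp = sum(cls == "null"))
}

#' Run one gene-selection strategy on one dataset
#'
#' Normalizes, tests, adjusts, and scores the rejections against the
#' truth.  For the delta-sequence strategy the returned per-gene adjusted
#' p-value is the larger of the gene's two pair-level adjusted p-values,
#' so `rejected == (p_adj < alpha)` still holds gene-wise.
#'
#' @param m An `"expr_matrix"`.
#' @param truth The matching `"truth_set"`.
#' @param s A [strategy()].
#' @param seed Seed for the permutation test (ignored by the other
#'   tests).
#' @return List with `result` (per-gene adjusted data frame), `selected`
#'   (gene ids), `tp` and `fp`.
#' @export
run_strategy <- function(m, truth, s, seed = 1L) {
  stopifnot(inherits(s, "strategy"))
  adjust_fun <- switch(s$mtp, bonf = adjust_bonferroni, bh = adjust_bh)
  run_test <- function(mat) {
    switch(s$test,
           t = row_t_test(mat),
           modt = row_moderated_t(mat),
           wilcox = row_wilcoxon(mat),
           nstat = row_n_test(mat, n_perm = s$n_perm, seed = seed))
  }

  if (s$normalization == "delta") {
    pd <- delta_pair(m)
    res0 <- adjust_fun(run_test(pd$diffs0), s$alpha)
    res1 <- adjust_fun(run_test(pd$diffs1), s$alpha)
    genes <- rownames(m$values)
    if (!is.null(pd$dropped)) genes <- setdiff(genes, pd$dropped)
    pair0_of <- stats::setNames(rep(seq_len(nrow(pd$pairs0)), 2L),
                                as.vector(pd$pairs0))
    pair1_of <- stats::setNames(rep(seq_len(nrow(pd$pairs1)), 2L),
                                as.vector(pd$pairs1))
    p_adj <- pmax(res0$p_adj[pair0_of[genes]], res1$p_adj[pair1_of[genes]])
    result <- data.frame(gene_id = genes, p_adj = p_adj,
                         rejected = p_adj < s$alpha)
    attr(result, "alpha") <- s$alpha
    selected <- result$gene_id[result$rejected]
  } else if (s$normalization == "sva") {
    sv <- estimate_surrogates(m, s$K)
    result <- adjust_fun(sva_test(m, sv), s$alpha)
    selected <- result$gene_id[result$rejected]
  } else {
    norm_fun <- switch(s$normalization, none = normalize_none,
                       global = normalize_global, rank = normalize_rank,
                       quantile = normalize_quantile)
    result <- adjust_fun(run_test(norm_fun(m)), s$alpha)
    selected <- result$gene_id[result$rejected]
  }
  counts <- count_tp_fp(selected, truth)
  list(result = result, selected = selected,
       tp = counts$tp, fp = counts$fp)
}

#' Run strategies over a preset grid of simulated datasets
#'
#' For each tuning value of the chosen preset, simulates `reps` datasets
#' (replicate seeds derived deterministically from `seed`, shared across
#' strategies so they see identical data) and reports the mean and
#' standard deviation of true and false positive counts per strategy.
#'
#' @param preset,structure Passed to [simu_preset()].
#' @param tuning_grid Numeric vector of tuning values (effect sizes for
#'   SIMU1, per-group sample sizes for SIMU2/3).
#' @param strategies List of [strategy()] objects.
#' @param reps Replicates per grid cell (>= 2; default the preset's 20).
#' @param seed Master seed.
#' @return A data frame with one row per (tuning, strategy): columns
#'   `preset`, `structure`, `tuning`, `normalization`, `test`, `mtp`,
#'   `mean_tp`, `sd_tp`, `mean_fp`, `sd_fp`, `reps`.
#' @export
run_grid <- function(preset, structure, tuning_grid, strategies,
                     reps = 20L, seed = 1L) {
  if (reps < 2L) stop("need reps >= 2 to report standard deviations",
                      call. = FALSE)
  rows <- list()
  for (tuning in tuning_grid) {
    cfg <- simu_preset(preset, structure, tuning)
    rep_seeds <- derive_seeds(seed + round(1000 * tuning), reps)
    counts <- array(NA_real_, c(reps, length(strategies), 2L))
    for (r in seq_len(reps)) {
      cfg$seed <- rep_seeds[r]
      sim <- simulate_random_effect(cfg)
      for (si in seq_along(strategies)) {
        out <- run_strategy(sim$matrix, sim$truth, strategies[[si]],
                            seed = rep_seeds[r])
        counts[r, si, ] <- c(out$tp, out$fp)
      }
    }
    for (si in seq_along(strategies)) {
      s <- strategies[[si]]
      rows[[length(rows) + 1L]] <- data.frame(
        preset = preset, structure = structure, tuning = tuning,
        normalization = s$normalization, test = s$test, mtp = s$mtp,
        mean_tp = mean(counts[, si, 1L]), sd_tp = stats::sd(counts[, si, 1L]),
        mean_fp = mean(counts[, si, 2L]), sd_fp = stats::sd(counts[, si, 2L]),
        reps = reps)
    }
  }
  do.call(rbind, rows)
}

#' ROC curve of a raw p-value vector against the truth
#'
#' Sweeps the rejection threshold over the sorted unique raw p-values
#' (most permissive first) and counts true and false positives among
#' genes with `p <= threshold`; all genes tied at a threshold enter
#' together.  Raw p-values are used because monotone MTP adjustments
#' cannot change the induced gene ranking.
#'
#' @param p Named numeric vector of raw p-values (names = gene ids), or a
#'   [test_result()] data frame.
#' @param truth A `"truth_set"`.
#' @return A data frame with columns `threshold` (descending), `tp`,
#'   `fp`.
#' @export
roc_curve <- function(p, truth) {
  if (is.data.frame(p)) p <- stats::setNames(p$p_raw, p$gene_id)
  if (is.null(names(p))) stop("p must be named by gene ids", call. = FALSE)
  if (any(!is.finite(p))) stop("p-values must be finite", call. = FALSE)
  thr <- sort(unique(p), decreasing = TRUE)
  is_deg <- truth$class_of[names(p)] != "null"
  ord <- order(p)
  deg_sorted <- is_deg[ord]
  cum_tp <- cumsum(deg_sorted)
  cum_fp <- cumsum(!deg_sorted)
  # index of the last gene included at each threshold
  last <- vapply(thr, function(t) sum(p <= t), integer(1L))
  data.frame(threshold = thr, tp = cum_tp[last], fp = cum_fp[last])
}
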