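#' Per-gene pooled-variance two-sample t-test
#'
#' Classical equal-variance t-test of group A versus group B for every
#' gene, with two-sided p-values from the t distribution on
#' `n_A + n_B - 2` degrees of freedom.  The pooled form is used (rather
#' than Welch) because the random-effect model underlying the package's
#' simulators and theory assumes a common per-gene variance in both
#' groups.
#'
#' Genes with zero pooled variance are degenerate: they get `p = 1` when
#' the group means are equal and `p = 0` otherwise, and a message reports
#' how many genes were affected.
#'
#' @param m An `"expr_matrix"`.
#' @return A [test_result()] data frame.
#' @export
row_t_test <- function(m) {
  a <- m$values[, group_cols(m, "A"), drop = FALSE]
  b <- m$values[, group_cols(m, "B"), drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  df <- na + nb - 2
  diff <- rowMeans(a) - rowMeans(b)
  s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) / df
  se <- sqrt(s2 * (1 / na + 1 / nb))
  stat <- diff / se
  p <- 2 * stats::pt(-abs(stat), df)
  degen <- se == 0
  if (any(degen)) {
    message(sum(degen), " gene(s) with zero pooled variance: p set to 0/1")
    stat[degen] <- ifelse(diff[degen] == 0, 0, sign(diff[degen]) * Inf)
    p[degen] <- ifelse(diff[degen] == 0, 1, 0)
  }
  test_result(rownames(m$values), stat, p)
}

#' Per-gene empirical-Bayes moderated t-test
#'
#' Shrinks each gene's pooled sample variance toward a prior variance
#' `s0^2` with prior degrees of freedom `d0`, both estimated by moment
#' matching of the log sample variances across genes (the standard
#' moderated-t construction): if `s_g^2` follows a scaled F distribution
#' around `s0^2`, then `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`
#' satisfies `var(e_g) = trigamma(d/2) + trigamma(d0/2)` and
#' `mean(e_g) = log(s0^2) + digamma(d0/2) - log(d0/2)`.  The moderated
#' statistic divides the mean difference by the posterior variance
#' `(d0 s0^2 + d s_g^2) / (d0 + d)` and is referred to a t distribution on
#' `d + d0` degrees of freedom.
#'
#' @param m An `"expr_matrix"` with at least 2 genes (the prior cannot be
#'   estimated from one gene).
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom; `0` forces no shrinkage (ordinary t), `Inf` complete
#'   shrinkage to `s0^2`.
#' @return A [test_result()] data frame, with the fitted prior attached as
#'   attributes `prior_df` and `prior_var`.
#' @export
row_moderated_t <- function(m, prior_df = NULL) {
  if (nrow(m$values) < 2L)
    stop("need at least 2 genes to estimate the variance prior",
         call. = FALSE)
  a <- m$values[, group_cols(m, "A"), drop = FALSE]
  b <- m$values[, group_cols(m, "B"), drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  d <- na + nb - 2
  diff <- rowMeans(a) - rowMeans(b)
  s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) / d
  if (any(s2 <= 0))
    stop("zero sample variance; moderated t needs positive variances",
         call. = FALSE)

  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.null(prior_df)) {
    if (is.na(evar) || evar <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * .trigamma_inverse(evar)
    }
  } else {
    d0 <- prior_df
  }
  # d0 = Inf limit of the prior-variance formula is exp(mean(e)); but when
  # the observed log variances show no spread at all there is no sampling
  # scatter to correct for and the prior variance is the common value itself
  s02 <- if (is.infinite(d0)) {
    if (stats::sd(e) < 1e-10) exp(mean(log(s2))) else exp(mean(e))
  } else if (d0 == 0) {
    NA_real_  # no shrinkage: prior variance unused
  } else {
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + d * s2) / (d0 + d)
  stat <- diff / sqrt(s2_post * (1 / na + 1 / nb))
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(stat), df_total)
  out <- test_result(rownames(m$values), stat, p)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

# Solve trigamma(x) = y for x > 0 (monotone decreasing), on the log scale
# for robustness across the y ranges produced by small and large prior df.
.trigamma_inverse <- function(y) {
  stats::uniroot(function(lx) trigamma(exp(lx)) - y,
                 lower = -30, upper = 30, tol = 1e-12)$root |> exp()
}

#' Per-gene Wilcoxon rank-sum test
#'
#' Exact two-sided p-values by enumeration when the total sample size is
#' at most 12 and the gene has no tied values; otherwise the normal
#' approximation with tie correction and continuity correction.  Both
#' routes are the standard ones provided by [stats::wilcox.test()]; the
#' statistic reported is the Mann-Whitney U of group A over group B.
#'
#' @param m An `"expr_matrix"`.
#' @param exact Logical override of the exact/approximate choice; `NULL`
#'   (default) applies the size-and-ties rule above per gene.
#' @return A [test_result()] data frame.
#' @export
row_wilcoxon <- function(m, exact = NULL) {
  ia <- group_cols(m, "A"); ib <- group_cols(m, "B")
  small <- (length(ia) + length(ib)) <= 12L
  res <- apply(m$values, 1L, function(x) {
    xa <- x[ia]; xb <- x[ib]
    ex <- if (is.null(exact)) small && !anyDuplicated(c(xa, xb)) else exact
    w <- suppressWarnings(
      stats::wilcox.test(xa, xb, exact = ex, correct = TRUE))
    c(w$statistic, w$p.value)
  })
  test_result(rownames(m$values), res[1L, ], res[2L, ])
}

#' N-statistic (energy-type) two-sample distance with Euclidean kernel
#'
#' \deqn{N = \frac{2}{nm}\sum_{i,j}|x_i-y_j|
#'         - \frac{1}{n^2}\sum_{i,i'}|x_i-x_{i'}|
#'         - \frac{1}{m^2}\sum_{j,j'}|y_j-y_{j'}|}
#' with all double sums running over every ordered pair (diagonals
#' included).  For the Euclidean kernel `N >= 0`, with equality when the
#' two samples are identical as multisets; `N` is invariant under a common
#' shift of both samples.
#'
#' @param x,y Non-empty numeric vectors.
#' @return The statistic, a single nonnegative number.
#' @examples
#' n_statistic(c(0, 1), c(2, 3))  # 4 - 0.5 - 0.5 = 3
#' @export
n_statistic <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  cross <- mean(abs(outer(x, y, "-")))
  within_x <- mean(abs(outer(x, x, "-")))
  within_y <- mean(abs(outer(y, y, "-")))
  2 * cross - within_x - within_y
}

#' Per-gene permutation test based on the N-statistic
#'
#' For every gene, the group labels are permuted `n_perm` times (uniform
#' random permutations, shared across genes and fully determined by
#' `seed`) and the permutation p-value uses the add-one convention
#' `p = (1 + #\{N_perm >= N_obs\}) / (1 + n_perm)`, so the smallest
#' attainable p is `1 / (n_perm + 1)` and Bonferroni-adjusted values stay
#' finite.
#'
#' @param m An `"expr_matrix"`.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed controlling the permutations.
#' @return A [test_result()] data frame; `statistic` is the observed N.
#' @export
row_n_test <- function(m, n_perm = 10000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  ia <- group_cols(m, "A"); ib <- group_cols(m, "B")
  n <- length(ia); mm <- length(ib)
  N <- n + mm
  perms <- withr::with_seed(seed,
    replicate(n_perm, sample.int(N), simplify = FALSE))
  v <- m$values[, c(ia, ib), drop = FALSE]
  res <- apply(v, 1L, function(x) {
    D <- abs(outer(x, x, "-"))
    nstat <- function(idx_a) {
      idx_b <- setdiff(seq_len(N), idx_a)
      2 * mean(D[idx_a, idx_b]) - mean(D[idx_a, idx_a]) -
        mean(D[idx_b, idx_b])
    }
    obs <- nstat(seq_len(n))
    # small tolerance so permutations mathematically tied with the observed
    # partition count as exceedances despite summation-order rounding
    eps <- 1e-9 * (abs(obs) + 1)
    exceed <- sum(vapply(perms,
                         function(p) nstat(p[seq_len(n)]) >= obs - eps,
                         logical(1L)))
    c(obs, (1 + exceed) / (1 + n_perm))
  })
  test_result(rownames(m$values), res[1L, ], res[2L, ])
}
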