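#' Configuration of the equicorrelated random-effect simulator
#'
#' Parameters of the generating model
#' \deqn{X_{gjk} = \mu_{gk} + b_{jk} + e_{gjk},}
#' where `b_jk ~ N(0, rho * sigma2)` is a per-array effect shared by all
#' genes on array j of group k and `e_gjk ~ N(0, (1 - rho) * sigma2)` is
#' independent gene-level noise.  This decomposition gives every gene the
#' total variance `sigma2` and every pair of distinct genes the common
#' correlation `rho`.  Group-B means are zero; in group A the first `n_up`
#' genes have mean `mu_up`, the next `n_down` have `mu_down`, and the rest
#' are null.
#'
#' The default `sigma2 = 0.1286` and `rho = 0.894` describe a typical
#' large leukemia microarray cohort: per-gene log2 variance near 0.13 and
#' intergene correlation near 0.9, almost all of it driven by the shared
#' array effect (see the package vignette for how these defaults were
#' fixed).
#'
#' @param G Total number of genes.
#' @param n Arrays per group.
#' @param n_up,n_down Numbers of up-/down-regulated genes,
#'   `n_up + n_down <= G`.
#' @param mu_up,mu_down Log2 effect sizes (`mu_up > 0 >= mu_down` unless a
#'   class is empty).
#' @param sigma2 Total per-gene variance (> 0).
#' @param rho Common intergene correlation in \[0, 1).
#' @param seed Integer seed; the generator is a pure function of the
#'   config including the seed.
#' @param reps Replicate count carried along for grid experiments.
#' @return A list of class `"re_config"`.
#' @export
random_effect_config <- function(G = 1000L, n = 10L, n_up = 50L,
                                 n_down = 50L, mu_up = 1, mu_down = -1,
                                 sigma2 = 0.1286, rho = 0.894, seed = 1L,
                                 reps = 20L) {
  if (n_up + n_down > G) stop("n_up + n_down must not exceed G",
                              call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (n < 2L) stop("need at least 2 arrays per group", call. = FALSE)
  structure(list(G = as.integer(G), n = as.integer(n),
                 n_up = as.integer(n_up), n_down = as.integer(n_down),
                 mu_up = mu_up, mu_down = mu_down, sigma2 = sigma2,
                 rho = rho, seed = as.integer(seed),
                 reps = as.integer(reps)),
            class = "re_config")
}

#' Simulate one dataset from the random-effect model
#'
#' @param cfg A [random_effect_config()].
#' @return List with elements `matrix` (an `"expr_matrix"`, arrays named
#'   `A01..` / `B01..`) and `truth` (the matching `"truth_set"`; genes
#'   `g0001..`, the first `n_up` up-regulated, the next `n_down`
#'   down-regulated).
#' @export
simulate_random_effect <- function(cfg) {
  stopifnot(inherits(cfg, "re_config"))
  G <- cfg$G; n <- cfg$n
  sd_b <- sqrt(cfg$rho * cfg$sigma2)
  sd_e <- sqrt((1 - cfg$rho) * cfg$sigma2)
  mu_a <- c(rep(cfg$mu_up, cfg$n_up), rep(cfg$mu_down, cfg$n_down),
            rep(0, G - cfg$n_up - cfg$n_down))
  vals <- withr::with_seed(cfg$seed, {
    one_group <- function(mu) {
      b <- stats::rnorm(n, 0, sd_b)
      matrix(stats::rnorm(G * n, 0, sd_e), G, n) +
        rep(b, each = G) + mu
    }
    cbind(one_group(mu_a), one_group(0))
  })
  gene_ids <- sprintf("g%04d", seq_len(G))
  array_ids <- c(sprintf("A%02d", seq_len(n)), sprintf("B%02d", seq_len(n)))
  dimnames(vals) <- list(gene_ids, array_ids)
  groups <- stats::setNames(rep(c("A", "B"), each = n), array_ids)
  cls <- stats::setNames(
    rep(c("up", "down", "null"),
        c(cfg$n_up, cfg$n_down, G - cfg$n_up - cfg$n_down)), gene_ids)
  list(matrix = expression_matrix(vals, groups),
       truth = truth_set(cls,
                         mu_up = if (cfg$n_up > 0L) cfg$mu_up else NA_real_,
                         mu_down = if (cfg$n_down > 0L) cfg$mu_down
                                   else NA_real_))
}

#' Preset simulation scenarios
#'
#' Three study designs over the random-effect model, all with `G = 1000`
#' genes, 100 of them differentially expressed (balanced: 50 up / 50 down;
#' unbalanced: 60 up / 40 down), `sigma2 = 0.1286`, `rho = 0.894` and 20
#' replicates:
#' \describe{
#'   \item{SIMU1}{sample size fixed at `n = 10`; `tuning` is the common
#'     effect size magnitude (grid 0.2-1.8 typical).}
#'   \item{SIMU2}{effect size fixed at 1.0 (small); `tuning` is the
#'     per-group sample size.}
#'   \item{SIMU3}{effect size fixed at 1.8 (large); `tuning` is the
#'     per-group sample size.}
#' }
#'
#' @param name `"SIMU1"`, `"SIMU2"` or `"SIMU3"`.
#' @param structure `"balanced"` or `"unbalanced"`.
#' @param tuning The scenario's tuning parameter (effect size for SIMU1,
#'   per-group sample size for SIMU2/3).
#' @param seed Seed stored in the config.
#' @return A [random_effect_config()].
#' @export
simu_preset <- function(name = c("SIMU1", "SIMU2", "SIMU3"),
                        structure = c("balanced", "unbalanced"),
                        tuning, seed = 1L) {
  name <- match.arg(name)
  structure <- match.arg(structure)
  n_up <- if (structure == "balanced") 50L else 60L
  n_down <- 100L - n_up
  if (name == "SIMU1") {
    effect <- tuning
    n <- 10L
  } else {
    effect <- if (name == "SIMU2") 1.0 else 1.8
    n <- as.integer(tuning)
  }
  random_effect_config(G = 1000L, n = n, n_up = n_up, n_down = n_down,
                       mu_up = effect, mu_down = -effect,
                       sigma2 = 0.1286, rho = 0.894, seed = seed,
                       reps = 20L)
}

#' Synthetic biological-style seed matrix
#'
#' A stand-in for a real leukemia expression cohort, used to seed the
#' resampling simulator: gene-specific log2 variances drawn around 0.15,
#' a shared per-array effect giving intergene correlation near 0.9, gene
#' baseline levels around 7 log2 units, plus a mild per-array scale
#' distortion of the within-array deviations.  The distortion is
#' non-additive on the log scale, emulating residual technical noise that
#' mean-centering cannot remove but rank- and quantile-based procedures
#' absorb.  All arrays are exchangeable: the matrix carries no group
#' structure of its own (labels are assigned by [simulate_resample()]).
#'
#' This matrix is synthetic by construction; it reproduces summary
#' statistics of real cohorts (variance scale, correlation), not any real
#' gene's behaviour.
#'
#' @param G Number of genes (>= 2).
#' @param n_arrays Number of arrays (>= 4).
#' @param seed Integer seed.
#' @return An `"expr_matrix"` with arrays split half/half into provisional
#'   groups A and B (required by the container; the resampler relabels).
#' @export
synthetic_seed_matrix <- function(G = 1000L, n_arrays = 160L, seed = 1L) {
  if (G < 2L || n_arrays < 4L)
    stop("need G >= 2 and n_arrays >= 4", call. = FALSE)
  vals <- withr::with_seed(seed, {
    base <- stats::rnorm(G, mean = 7, sd = 1)
    s2 <- 0.15 * stats::rchisq(G, df = 20) / 20  # gene variances ~ 0.15
    s <- sqrt(s2)
    rho <- 0.9
    z <- stats::rnorm(n_arrays)                  # shared array effect
    eps <- matrix(stats::rnorm(G * n_arrays), G, n_arrays)
    x <- base + s * (sqrt(rho) * rep(z, each = G) +
                     sqrt(1 - rho) * eps)
    scale_j <- 1 + stats::rnorm(n_arrays, 0, 0.05)  # per-array distortion
    centers <- colMeans(x)
    sweep(sweep(x, 2L, centers), 2L, scale_j, "*") +
      rep(centers, each = G)
  })
  gene_ids <- sprintf("g%04d", seq_len(G))
  array_ids <- sprintf("s%03d", seq_len(n_arrays))
  dimnames(vals) <- list(gene_ids, array_ids)
  half <- n_arrays %/% 2L
  groups <- stats::setNames(
    rep(c("A", "B"), c(half, n_arrays - half)), array_ids)
  expression_matrix(vals, groups)
}

#' Configuration of the resampling simulator
#'
#' @param seed_matrix An `"expr_matrix"` whose arrays are resampled
#'   (e.g. [synthetic_seed_matrix()]).
#' @param n Per-group sample size; `2 * n` must not exceed the number of
#'   seed arrays.
#' @param deg_effects Named numeric vector: log2 effect sizes to spike
#'   into group A, named by gene id (subset of the seed matrix's genes).
#'   May be empty (pure permutation null).
#' @param seed Integer seed for the array permutation.
#' @return A list of class `"resample_config"`.
#' @export
resample_config <- function(seed_matrix, n, deg_effects = numeric(0),
                            seed = 1L) {
  if (2L * n > ncol(seed_matrix$values))
    stop("2n exceeds the number of seed arrays", call. = FALSE)
  if (length(deg_effects) &&
      !all(names(deg_effects) %in% rownames(seed_matrix$values)))
    stop("deg_effects names must be seed-matrix gene ids", call. = FALSE)
  structure(list(seed_matrix = seed_matrix, n = as.integer(n),
                 deg_effects = deg_effects, seed = as.integer(seed)),
            class = "resample_config")
}

#' Simulate a two-group dataset by resampling a seed matrix
#'
#' Permutes the seed arrays uniformly at random, takes the first `n` as
#' group A and the next `n` as group B (two exchangeable pseudo-groups
#' with no true differential expression), then adds the configured effect
#' sizes to the group-A values of the spiked genes.  The truth set labels
#' spiked genes up or down by the sign of their effect.
#'
#' @param cfg A [resample_config()].
#' @return List with `matrix` (an `"expr_matrix"`) and `truth` (a
#'   `"truth_set"`; `mu_up`/`mu_down` are the mean spiked effects per
#'   direction, the per-gene effects being heterogeneous here).
#' @export
simulate_resample <- function(cfg) {
  stopifnot(inherits(cfg, "resample_config"))
  sm <- cfg$seed_matrix
  perm <- withr::with_seed(cfg$seed, sample.int(ncol(sm$values)))
  take <- perm[seq_len(2L * cfg$n)]
  vals <- sm$values[, take, drop = FALSE]
  groups <- stats::setNames(rep(c("A", "B"), each = cfg$n), colnames(vals))
  if (length(cfg$deg_effects)) {
    idx <- match(names(cfg$deg_effects), rownames(vals))
    vals[idx, seq_len(cfg$n)] <-
      vals[idx, seq_len(cfg$n)] + cfg$deg_effects
  }
  cls <- stats::setNames(rep("null", nrow(vals)), rownames(vals))
  eff <- cfg$deg_effects
  cls[names(eff)[eff > 0]] <- "up"
  cls[names(eff)[eff < 0]] <- "down"
  list(matrix = expression_matrix(vals, groups),
       truth = truth_set(cls,
                         mu_up = if (any(eff > 0)) mean(eff[eff > 0])
                                 else NA_real_,
                         mu_down = if (any(eff < 0)) mean(eff[eff < 0])
                                   else NA_real_))
}

#' Average within-group per-gene sample variance
#'
#' The variance summary used throughout the package to quantify the
#' variance-reduction side of normalization: each gene's sample variance
#' is computed separately within each phenotypic group, then averaged over
#' genes and both groups.  (Pooling the groups instead would inflate the
#' summary by the differentially expressed genes' mean shifts.)
#'
#' @param m An `"expr_matrix"`.
#' @return A single number.
#' @export
avg_within_group_variance <- function(m) {
  per_group <- function(g) {
    v <- m$values[, group_cols(m, g), drop = FALSE]
    rowSums((v - rowMeans(v))^2) / (ncol(v) - 1)
  }
  mean(c(per_group("A"), per_group("B")))
}

#' Per-gene group mean difference (A minus B)
#'
#' @param m An `"expr_matrix"`.
#' @return Named numeric vector: `mean(group A) - mean(group B)` per gene.
#' @export
group_mean_difference <- function(m) {
  rowMeans(m$values[, group_cols(m, "A"), drop = FALSE]) -
    rowMeans(m$values[, group_cols(m, "B"), drop = FALSE])
}
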