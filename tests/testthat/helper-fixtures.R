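# Small in-code fixtures shared across test files.

# genes x arrays matrix with groups A/B split half-half
make_em <- function(values, n_a = ncol(values) %/% 2L) {
  G <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", seq_len(G))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("a%02d", seq_len(ncol(values)))
  groups <- stats::setNames(
    rep(c("A", "B"), c(n_a, ncol(values) - n_a)), colnames(values))
  expression_matrix(values, groups)
}

# iid Gaussian fixture, no differential signal
random_em <- function(G, n_a, n_b, seed = 1L, sd = 1) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(G * (n_a + n_b), sd = sd), G, n_a + n_b)
    make_em(v, n_a)
  })
}

# truth set with the first n_up genes up, next n_down down
simple_truth <- function(gene_ids, n_up, n_down, mu_up = 1, mu_down = -1) {
  cls <- rep("null", length(gene_ids))
  cls[seq_len(n_up)] <- "up"
  if (n_down > 0) cls[n_up + seq_len(n_down)] <- "down"
  truth_set(stats::setNames(cls, gene_ids),
            mu_up = if (n_up > 0) mu_up else NA_real_,
            mu_down = if (n_down > 0) mu_down else NA_real_)
}
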