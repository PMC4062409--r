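# Deterministic per-replicate seeds from a single master seed.  Drawing a
# seed table (rather than seed + rep offsets) keeps replicate streams
# independent of how many replicates neighbouring experiments use.
#' Derive independent replicate seeds from a master seed
#'
#' @param master Integer master seed.
#' @param k Number of seeds needed.
#' @return Integer vector of length `k`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(master, k) {
  withr::with_seed(as.integer(master),
                   sample.int(.Machine$integer.max, k))
}
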