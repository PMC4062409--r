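#' Construct a two-group log2 expression matrix
#'
#' The basic container of the package: a genes x arrays matrix of
#' log2-scale expression values together with a two-level group assignment
#' (`"A"` = phenotype of interest, `"B"` = reference/normal phenotype).
#' Values are assumed to be log2-transformed already; no transformation is
#' applied anywhere in the package.
#'
#' @param values Numeric matrix, genes in rows and arrays in columns, with
#'   unique rownames (gene ids) and colnames (array ids).  All entries must
#'   be finite.
#' @param groups Named character vector mapping every array id to `"A"` or
#'   `"B"`.  Each group needs at least two arrays.
#' @return An object of class `"expr_matrix"`: a list with elements
#'   `values` (the matrix) and `groups` (the map, reordered to match the
#'   matrix columns).
#' @examples
#' v <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("a", 1:4)))
#' m <- expression_matrix(v, c(a1 = "A", a2 = "A", a3 = "B", a4 = "B"))
#' @export
expression_matrix <- function(values, groups) {
  m <- structure(list(values = values, groups = groups),
                 class = "expr_matrix")
  validate_expression_matrix(m)
}

#' Validate an expression matrix
#'
#' Checks every container invariant: finite numeric values, at least two
#' genes, unique gene and array ids, a complete array-to-group map, and at
#' least two arrays per group.  Called by all constructors and the TSV
#' reader; error messages name the offending row, column, or array.
#'
#' @param m An `"expr_matrix"` object (or a bare list with `values` and
#'   `groups`).
#' @return `m`, invisibly classed, if all invariants hold.
#' @export
validate_expression_matrix <- function(m) {
  v <- m$values
  if (!is.matrix(v) || !is.numeric(v))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(v) < 2L)
    stop("need at least 2 genes, got ", nrow(v), call. = FALSE)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    stop("`values` must have gene ids as rownames and array ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(v)))
    stop("duplicate gene id: ",
         rownames(v)[duplicated(rownames(v))][1L], call. = FALSE)
  if (anyDuplicated(colnames(v)))
    stop("duplicate array id: ",
         colnames(v)[duplicated(colnames(v))][1L], call. = FALSE)
  bad <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite value at gene ", rownames(v)[bad[1L, 1L]],
         ", array ", colnames(v)[bad[1L, 2L]], call. = FALSE)
  g <- m$groups
  if (is.null(names(g)))
    stop("`groups` must be a named vector (array id -> group)", call. = FALSE)
  missing <- setdiff(colnames(v), names(g))
  if (length(missing) > 0L)
    stop("array missing from group labels: ", missing[1L], call. = FALSE)
  g <- g[colnames(v)]
  if (!all(g %in% c("A", "B")))
    stop("group labels must be \"A\" or \"B\"; offending array: ",
         names(g)[which(!g %in% c("A", "B"))[1L]], call. = FALSE)
  tab <- table(factor(g, levels = c("A", "B")))
  if (any(tab < 2L))
    stop("each group needs at least 2 arrays; group ",
         names(tab)[which(tab < 2L)[1L]], " has ", min(tab), call. = FALSE)
  m$groups <- g
  class(m) <- "expr_matrix"
  m
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat("expr_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " arrays (A: ", tab[["A"]], ", B: ", tab[["B"]], ")\n", sep = "")
  invisible(x)
}

#' Number of genes / arrays in an expression matrix
#' @param m An `"expr_matrix"`.
#' @return Integer count.
#' @export
n_genes <- function(m) nrow(m$values)

#' @rdname n_genes
#' @export
n_arrays <- function(m) ncol(m$values)

#' Column indices of one phenotypic group
#'
#' @param m An `"expr_matrix"`.
#' @param group `"A"` or `"B"`.
#' @return Integer vector of column indices.
#' @export
group_cols <- function(m, group) which(m$groups == group)

#' Read an expression matrix and its group labels from TSV files
#'
#' The matrix file is tab-separated with a header row of array ids and a
#' first column of gene ids under the header token `gene_id`; decimal
#' separator is `"."` and no quoting is used.  The labels file has two
#' tab-separated columns, `array_id` and `group`, with no header
#' requirement beyond those names.
#'
#' @param path Path to the matrix TSV.
#' @param labels_path Path to the two-column label TSV.
#' @return A validated `"expr_matrix"`.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, labels_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L || names(raw)[1L] != "gene_id")
    stop("matrix TSV must start with a `gene_id` column", call. = FALSE)
  gene_ids <- raw[[1L]]
  num <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(num), nrow = nrow(num)))
  bad <- which(is.na(storage) & num != "NA", arr.ind = TRUE)
  bad <- rbind(bad, which(num == "NA", arr.ind = TRUE))
  if (nrow(bad) > 0L)
    stop("non-numeric cell at gene ", gene_ids[bad[1L, 1L]], ", array ",
         colnames(num)[bad[1L, 2L]], ": \"",
         num[bad[1L, 1L], bad[1L, 2L]], "\"", call. = FALSE)
  dimnames(storage) <- list(gene_ids, colnames(num))
  lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                           quote = "", colClasses = "character")
  if (!all(c("array_id", "group") %in% names(lab)))
    stop("labels TSV needs columns `array_id` and `group`", call. = FALSE)
  groups <- stats::setNames(lab$group, lab$array_id)
  expression_matrix(storage, groups)
}

#' Write an expression matrix and its group labels to TSV files
#'
#' Values are written with full double precision (17 significant digits) so
#' that a read/write round trip is the identity.
#'
#' @param m A validated `"expr_matrix"`.
#' @param path Output path for the matrix TSV.
#' @param labels_path Output path for the label TSV.
#' @return Invisibly, `m`.
#' @export
write_expression_matrix <- function(m, path, labels_path) {
  m <- validate_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m$values),
                   format(m$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(array_id = colnames(m$values), group = unname(m$groups))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}

#' Construct a truth set of gene classes and effect sizes
#'
#' Records which genes are truly up-regulated, down-regulated, or null
#' (non-differentially expressed) in group A relative to group B, together
#' with the common log2 effect sizes of the up and down classes.
#'
#' @param class_of Named character vector mapping gene id to one of
#'   `"null"`, `"up"`, `"down"`.
#' @param mu_up Positive log2 effect size shared by up-regulated genes
#'   (may be `NA` when there are none).
#' @param mu_down Negative log2 effect size shared by down-regulated genes
#'   (may be `NA` when there are none).
#' @return An object of class `"truth_set"`.
#' @export
truth_set <- function(class_of, mu_up = NA_real_, mu_down = NA_real_) {
  if (is.null(names(class_of)) || anyDuplicated(names(class_of)))
    stop("`class_of` must be named by unique gene ids", call. = FALSE)
  if (!all(class_of %in% c("null", "up", "down")))
    stop("gene classes must be \"null\", \"up\" or \"down\"", call. = FALSE)
  if (any(class_of == "up") && !(is.finite(mu_up) && mu_up > 0))
    stop("`mu_up` must be > 0 when up-regulated genes are present",
         call. = FALSE)
  if (any(class_of == "down") && !(is.finite(mu_down) && mu_down < 0))
    stop("`mu_down` must be < 0 when down-regulated genes are present",
         call. = FALSE)
  structure(list(class_of = class_of, mu_up = mu_up, mu_down = mu_down),
            class = "truth_set")
}

#' Gene-set sizes and DEG fractions of a truth set
#'
#' @param t A `"truth_set"`.
#' @return List with counts `n0`, `n_up`, `n_down`, total `G`, and the
#'   fractions `gamma_up = n_up / G`, `gamma_down = n_down / G`.
#' @export
truth_counts <- function(t) {
  G <- length(t$class_of)
  n_up <- sum(t$class_of == "up")
  n_down <- sum(t$class_of == "down")
  list(G = G, n0 = G - n_up - n_down, n_up = n_up, n_down = n_down,
       gamma_up = n_up / G, gamma_down = n_down / G)
}

#' @export
print.truth_set <- function(x, ...) {
  ct <- truth_counts(x)
  cat("truth_set: ", ct$G, " genes (", ct$n_up, " up @ ", x$mu_up, ", ",
      ct$n_down, " down @ ", x$mu_down, ", ", ct$n0, " null)\n", sep = "")
  invisible(x)
}

#' Read / write a truth set as TSV
#'
#' Three tab-separated columns: `gene_id`, `class` (null/up/down) and
#' `effect` (the gene's log2 effect size; 0 for null genes).
#'
#' @param path TSV path.
#' @return `read_truth_set` returns a `"truth_set"`.
#' @export
read_truth_set <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  cls <- stats::setNames(df$class, df$gene_id)
  up <- df$effect[df$class == "up"]
  dn <- df$effect[df$class == "down"]
  truth_set(cls,
            mu_up = if (length(up)) up[1L] else NA_real_,
            mu_down = if (length(dn)) dn[1L] else NA_real_)
}

#' @rdname read_truth_set
#' @param t A `"truth_set"` to write.
#' @export
write_truth_set <- function(t, path) {
  eff <- ifelse(t$class_of == "up", t$mu_up,
                ifelse(t$class_of == "down", t$mu_down, 0))
  df <- data.frame(gene_id = names(t$class_of), class = unname(t$class_of),
                   effect = unname(eff))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(t)
}

#' Per-gene test result container
#'
#' A thin data frame wrapper shared by all four tests: one row per gene with
#' the test statistic and the raw two-sided p-value.
#'
#' @param gene_ids Character vector of gene ids.
#' @param statistic Numeric vector of per-gene statistics.
#' @param p_raw Numeric vector of raw p-values in \[0, 1\].
#' @return A `data.frame` with columns `gene_id`, `statistic`, `p_raw`.
#' @export
test_result <- function(gene_ids, statistic, p_raw) {
  stopifnot(length(gene_ids) == length(statistic),
            length(gene_ids) == length(p_raw))
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop("raw p-values must lie in [0, 1]", call. = FALSE)
  data.frame(gene_id = gene_ids, statistic = statistic, p_raw = p_raw,
             stringsAsFactors = FALSE)
}
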