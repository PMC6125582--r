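#' Single-sample gene set enrichment score (ssGSEA)
#'
#' Ranks the sample's genes by expression (descending; ties broken by stable
#' gene-id order) and walks down the list comparing the weighted empirical
#' cumulative distribution of rank weights inside the set against the
#' unweighted ECDF outside it. With rank-from-bottom weights
#' `r = N - position + 1`,
#' `ES = sum_i [ P_in(i) - P_out(i) ]` where
#' `P_in(i) = sum_{j <= i, g_j in S} r_j^alpha / sum_{g in S} r_g^alpha` and
#' `P_out(i) = |{j <= i : g_j not in S}| / (N - |S|)`.
#'
#' @param expression named numeric vector of one sample's expression over the
#'   gene universe.
#' @param gene_set character vector of gene ids, a strict non-empty subset of
#'   the universe.
#' @param alpha rank-weight exponent (default 0.25).
#' @return the enrichment score (a single number).
#' @export
ssgsea_sample_score <- function(expression, gene_set, alpha = 0.25) {
  genes <- names(expression)
  if (is.null(genes)) stop("expression vector must be named by gene id")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% genes))
    stop("gene_set contains genes absent from the expression universe")
  n <- length(expression)
  ns <- length(gene_set)
  if (ns == 0L || ns == n)
    stop("gene_set must be a non-empty strict subset of the universe")
  ord <- order(-expression, genes)
  in_set <- genes[ord] %in% gene_set
  r <- seq.int(n, 1L)
  w <- r^alpha * in_set
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (n - ns)
  sum(p_in - p_out)
}

#' Sample x module ssGSEA score matrix
#'
#' Applies [ssgsea_sample_score()] to every sample and module. Module gene
#' sets are intersected with the expression matrix's gene universe first (the
#' replication use case); a module with no genes present yields an `NA`
#' column with a warning. If `normalize` is set, all raw scores are divided
#' by the global range (max - min) of the raw score matrix.
#'
#' @param expr numeric matrix, samples x genes, with dimnames.
#' @param modules either a named integer label vector (0 = unassigned), as
#'   returned by [dynamic_tree_cut()], or a named list of gene-id sets.
#' @param alpha rank-weight exponent.
#' @param normalize divide by the global raw-score range.
#' @return numeric matrix, samples x modules, with a `normalization`
#'   attribute of "range-normalized" or "raw".
#' @export
score_matrix <- function(expr, modules, alpha = 0.25, normalize = TRUE) {
  expr <- as.matrix(expr)
  sets <- .as_gene_sets(modules)
  if (length(sets) == 0L) stop("no nonzero modules to score")
  universe <- colnames(expr)
  sets <- lapply(sets, intersect, universe)
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty))
    warning("module(s) with no genes in the expression universe: ",
            paste(names(sets)[empty], collapse = ", "))

  scores <- matrix(NA_real_, nrow(expr), length(sets),
                   dimnames = list(rownames(expr), names(sets)))
  n <- ncol(expr)
  for (s in seq_len(nrow(expr))) {
    x <- expr[s, ]
    ord <- order(-x, universe)
    ordered_genes <- universe[ord]
    rw <- seq.int(n, 1L)^alpha
    for (m in seq_along(sets)) {
      if (empty[m] || length(sets[[m]]) == n) next
      in_set <- ordered_genes %in% sets[[m]]
      w <- rw * in_set
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!in_set) / (n - length(sets[[m]]))
      scores[s, m] <- sum(p_in - p_out)
    }
  }
  normalization <- "raw"
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
    normalization <- "range-normalized"
  }
  attr(scores, "normalization") <- normalization
  scores
}

# accept a label vector or a list of gene sets
.as_gene_sets <- function(modules) {
  if (is.list(modules)) {
    if (is.null(names(modules)))
      names(modules) <- paste0("M", seq_along(modules))
    return(modules)
  }
  if (is.null(names(modules)))
    stop("module label vector must be named by gene id")
  labs <- sort(unique(modules[modules > 0L]))
  stats::setNames(lapply(labs, function(l) names(modules)[modules == l]),
                  paste0("M", labs))
}
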