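#' Eigenvector centrality of a weighted network
#'
#' Entrywise non-negative principal eigenvector of the adjacency matrix,
#' computed by power iteration on the largest connected component and
#' normalized to unit Euclidean norm; genes outside that component get
#' centrality 0 (with a warning listing component sizes).
#'
#' @param adj symmetric non-negative adjacency with zero diagonal.
#' @param tol relative convergence tolerance of the power iteration.
#' @param max_iter maximum number of iterations.
#' @return named non-negative vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(adj, tol = 1e-10, max_iter = 1e4) {
  a <- unclass(adj)
  n <- nrow(a)
  if (!any(a > 0)) stop("network has no edges")
  comp <- .components(a > 0)
  sizes <- tabulate(comp)
  main <- which.max(sizes)
  if (length(unique(comp)) > 1L)
    warning("network is disconnected; centrality computed on the largest ",
            "component (component sizes: ",
            paste(sort(sizes, decreasing = TRUE), collapse = ", "), ")")
  idx <- which(comp == main)
  m <- a[idx, idx, drop = FALSE]
  # positive diagonal shift: identical eigenvectors, but makes the principal
  # eigenvalue strictly dominant (bipartite graphs have a -lambda_max pair)
  shift <- 0.1 * max(rowSums(m))
  diag(m) <- diag(m) + shift
  v <- rep(1 / sqrt(length(idx)), length(idx))
  for (it in seq_len(max_iter)) {
    w <- as.vector(m %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("power iteration collapsed to the zero vector")
    w <- w / nw
    if (max(abs(w - v)) <= tol * max(abs(v))) {
      out <- numeric(n)
      out[idx] <- abs(w)               # Perron vector is sign-consistent
      out <- out / sqrt(sum(out^2))
      names(out) <- rownames(a)
      return(out)
    }
    v <- w
  }
  stop("power iteration did not converge in ", max_iter, " iterations")
}

# connected components of an undirected graph given a logical adjacency
.components <- function(edges) {
  n <- nrow(edges)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(edges[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Univariate gene importance for a binary phenotype
#'
#' Logistic regression of diagnosis on each gene separately (Wald two-sided
#' p-value on the slope), BH adjustment across genes, and the importance
#' `s = -log(adjusted p)` (natural log). Genes with perfect separation fall
#' back to a likelihood-ratio test and are flagged.
#'
#' @param expr numeric matrix, samples x genes.
#' @param diagnosis binary vector (factor, logical, or 2-level character).
#' @return data.frame per gene: p, p_adj, s, separation flag.
#' @export
univariate_importance <- function(expr, diagnosis) {
  expr <- as.matrix(expr)
  if (is.null(colnames(expr)))
    colnames(expr) <- sprintf("G%05d", seq_len(ncol(expr)))
  y <- as.integer(as.factor(diagnosis)) - 1L
  if (length(unique(y)) != 2L) stop("both diagnosis classes must be present")
  if (length(y) != nrow(expr)) stop("diagnosis length mismatch")
  one <- function(g) {
    if (stats::var(g) == 0) return(c(p = 1, sep = 0))  # uninformative gene
    fit <- suppressWarnings(
      stats::glm(y ~ g, family = stats::binomial())
    )
    sep <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
    if (sep) {
      null <- stats::glm(y ~ 1, family = stats::binomial())
      p <- stats::pchisq(null$deviance - fit$deviance, df = 1,
                         lower.tail = FALSE)
    } else {
      p <- summary(fit)$coefficients[2, 4]
    }
    c(p = p, sep = as.numeric(sep))
  }
  res <- t(apply(expr, 2, one))
  p_adj <- bh_adjust(res[, "p"])
  data.frame(
    gene = colnames(expr), p = res[, "p"], p_adj = p_adj,
    s = -log(p_adj), separation = res[, "sep"] > 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-module correlation of gene importance with network centrality
#'
#' Within each module, regresses importance `s` on eigenvector centrality by
#' ordinary least squares and reports the coefficient of determination R^2.
#' Modules smaller than 3 genes, or with zero-variance centrality, are
#' reported as `NA`.
#'
#' @param importance named numeric vector of gene importances `s` (or the
#'   data.frame from [univariate_importance()]).
#' @param centrality named numeric vector from [eigenvector_centrality()].
#' @param modules named integer label vector (0 = unassigned).
#' @return data.frame per nonzero module: label, size, r_squared.
#' @export
module_centrality_correlation <- function(importance, centrality, modules) {
  if (is.data.frame(importance))
    importance <- stats::setNames(importance$s, importance$gene)
  labs <- sort(unique(modules[modules > 0L]))
  rows <- lapply(labs, function(l) {
    genes <- names(modules)[modules == l]
    genes <- intersect(genes, intersect(names(importance), names(centrality)))
    r2 <- NA_real_
    if (length(genes) >= 3L && stats::var(centrality[genes]) > 0) {
      fit <- stats::lm(importance[genes] ~ centrality[genes])
      r2 <- summary(fit)$r.squared
    }
    data.frame(module = paste0("M", l), size = length(genes), r_squared = r2)
  })
  do.call(rbind, rows)
}

#' Hypergeometric enrichment of modules among top-ranked genes
#'
#' Ranks genes by p-value (ascending, ties broken by gene id); for module i
#' of size K in a universe of N genes with x of its genes among the top k,
#' reports the inclusive upper-tail probability `P(X >= x)`,
#' X ~ Hypergeometric(N, K, k).
#'
#' @param modules named integer label vector (0 = unassigned).
#' @param gene_p named numeric vector of per-gene p-values over the universe.
#' @param top_k size of the top list (default 100).
#' @return data.frame per nonzero module: label, size, x (overlap with the
#'   top list), p_hyper.
#' @export
top_gene_enrichment <- function(modules, gene_p, top_k = 100) {
  if (top_k <= 0) stop("top_k must be positive")
  genes <- names(gene_p)
  if (is.null(genes)) stop("gene_p must be named")
  if (top_k > length(genes)) stop("top_k exceeds the gene universe")
  top <- genes[order(gene_p, genes)][seq_len(top_k)]
  n_univ <- length(genes)
  labs <- sort(unique(modules[modules > 0L]))
  rows <- lapply(labs, function(l) {
    mod_genes <- intersect(names(modules)[modules == l], genes)
    k_i <- length(mod_genes)
    x <- length(intersect(mod_genes, top))
    p <- stats::phyper(x - 1, k_i, n_univ - k_i, top_k, lower.tail = FALSE)
    data.frame(module = paste0("M", l), size = k_i, x = x, p_hyper = p)
  })
  do.call(rbind, rows)
}
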