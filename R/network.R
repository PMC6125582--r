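#' Unsigned correlation adjacency
#'
#' Builds the unsigned co-expression adjacency `a_ij = |cor(x_i, x_j)|`
#' (Pearson) with an exactly zero diagonal.
#'
#' @param expr numeric matrix, samples x genes; at least 3 samples.
#' @return symmetric genes x genes matrix in [0,1], diagonal 0, with a
#'   `tau` attribute of 0 (no thresholding applied yet).
#' @export
correlation_adjacency <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3L) stop("need at least 3 samples")
  v <- apply(expr, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(expr)[v == 0]
    stop("zero-variance gene(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  a <- abs(stats::cor(expr))
  a[a > 1] <- 1
  diag(a) <- 0
  attr(a, "tau") <- 0
  a
}

#' Hard-threshold an adjacency matrix
#'
#' Entries below `tau` are set to zero. By default surviving entries keep
#' their weights ("weighted" network); `binarize = TRUE` sets them to 1.
#'
#' @param adj adjacency matrix in [0,1], zero diagonal.
#' @param tau threshold in [0,1].
#' @param binarize replace surviving entries by 1.
#' @return thresholded adjacency with a `tau` attribute.
#' @export
hard_threshold <- function(adj, tau, binarize = FALSE) {
  if (!is.finite(tau) || tau < 0 || tau > 1) stop("tau must lie in [0,1]")
  a <- unclass(adj)
  a[a < tau] <- 0
  if (binarize) a[a > 0] <- 1
  diag(a) <- 0
  attr(a, "tau") <- tau
  a
}

#' Topological overlap dissimilarity
#'
#' For an adjacency `a` with connectivities `k_i = sum_u a_iu` and shared
#' neighbourhoods `l_ij = sum_u a_iu a_uj`, the topological overlap is
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` (i != j, TOM_ii = 1)
#' and the returned dissimilarity is `1 - TOM`. Pairs with a non-positive
#' denominator (isolated gene pairs) are assigned TOM 0, i.e. maximal
#' dissimilarity, with a warning.
#'
#' @param adj symmetric adjacency in [0,1] with zero diagonal.
#' @return symmetric dissimilarity matrix in [0,1] with zero diagonal.
#' @export
tom_dissimilarity <- function(adj) {
  a <- unclass(adj)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  k <- rowSums(a)
  l <- a %*% a                      # zero diagonal excludes u = i, j terms
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  bad <- denom <= 0
  diag(bad) <- FALSE
  if (any(bad)) {
    warning(sum(bad) / 2, " gene pair(s) with degenerate TOM denominator; ",
            "set to maximal dissimilarity")
    tom[bad] <- 0
  }
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  diag(tom) <- 1
  d <- 1 - tom
  d <- (d + t(d)) / 2               # enforce exact symmetry
  dimnames(d) <- dimnames(a)
  d
}

#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return an [stats::hclust] object.
#' @export
average_linkage <- function(d) {
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Adaptive (dynamic) tree cut
#'
#' Identifies modules from a dendrogram by branch shape rather than a single
#' fixed height: (1) a static cut at `cut_height_quantile` of the maximum
#' merge height yields initial branches; (2) each branch is recursively split
#' where the contrast between the mean between-branch dissimilarity (the
#' merge height, under average linkage) and the larger mean within-branch
#' dissimilarity exceeds `split_gap` (relative to the remaining height range)
#' and both resulting branches satisfy the size floor; (3)
#' branches smaller than `min_module_size` are merged into the nearest branch
#' by average inter-branch dissimilarity when that distance lies within the
#' cut height, and are otherwise left unassigned (label 0). Labels are
#' renumbered by decreasing module size.
#'
#' @param dend [stats::hclust] object from [average_linkage()] on `d`.
#' @param d the dissimilarity matrix the dendrogram was built from.
#' @param min_module_size smallest allowed module.
#' @param cut_height_quantile static cut height as a fraction of the maximum
#'   merge height.
#' @param split_gap between/within dissimilarity contrast required to split a branch.
#' @return named integer vector of module labels per gene (0 = unassigned)
#'   with a `module_sizes` attribute (table of nonzero labels).
#' @export
dynamic_tree_cut <- function(dend, d, min_module_size = 30,
                             cut_height_quantile = 0.99, split_gap = 0.3) {
  n <- length(dend$order)
  if (min_module_size > n)
    stop("min_module_size exceeds number of genes")
  d <- as.matrix(d)
  gene_ids <- dend$labels
  if (is.null(gene_ids)) gene_ids <- rownames(d)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(n))

  h_max <- max(dend$height)
  if (h_max <= 0) {                      # all genes identical: one module
    lab <- rep(1L, n)
    names(lab) <- gene_ids
    attr(lab, "module_sizes") <- table(lab)
    return(lab)
  }
  h_cut <- cut_height_quantile * h_max
  static <- stats::cutree(dend, h = h_cut)

  ## subtree bookkeeping: children and heights per internal node
  merge <- dend$merge
  node_height <- dend$height
  leaves_of <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    lv <- integer(0)
    for (ch in merge[i, ]) {
      lv <- c(lv, if (ch < 0) -ch else leaves_of[[ch]])
    }
    leaves_of[[i]] <- lv
  }

  ## Bottom-up split decision per node (children precede parents in `merge`,
  ## so ascending index order is a valid post-order traversal).  Under
  ## average linkage the merge height of a node equals the mean
  ## dissimilarity between its two branches, and the mean within-branch
  ## dissimilarity is maintained incrementally; a node splits when the
  ## between/within contrast
  ##   (h - max(w1, w2)) / (h_max - max(w1, w2))
  ## exceeds `split_gap` and both branches meet the size floor.  Splits found
  ## deeper in a branch propagate upward through chained or equal-height
  ## merges, with an undersized side branch carried along as its own
  ## (to-be-merged) piece.
  res_of <- vector("list", n - 1L)       # list of leaf-index clusters
  has_split <- logical(n - 1L)
  sum_within <- numeric(n - 1L)          # sum of pairwise d inside the node
  child_info <- function(ch) {
    if (ch < 0)
      list(leaves = -ch, size = 1L, within = 0, s = 0,
           res = list(-ch), split = FALSE)
    else {
      sz <- length(leaves_of[[ch]])
      list(leaves = leaves_of[[ch]], size = sz,
           within = sum_within[ch] / (sz * (sz - 1) / 2),
           s = sum_within[ch], res = res_of[[ch]], split = has_split[ch])
    }
  }
  for (i in seq_len(n - 1L)) {
    c1 <- child_info(merge[i, 1])
    c2 <- child_info(merge[i, 2])
    lv <- leaves_of[[i]]
    h <- node_height[i]
    sum_within[i] <- c1$s + c2$s + h * c1$size * c2$size
    if (length(lv) < 2L * min_module_size) {
      res_of[[i]] <- list(lv)
      next
    }
    w <- max(c1$within, c2$within)
    gap <- if (h_max > w) (h - w) / (h_max - w) else 0
    small <- min(c1$size, c2$size)
    if (gap >= split_gap && small >= min_module_size) {
      res_of[[i]] <- c(c1$res, c2$res)
      has_split[i] <- TRUE
    } else if (small >= min_module_size) {
      # both branches sizeable but no clear contrast here: keep deeper splits
      if (c1$split || c2$split) {
        res_of[[i]] <- c(c1$res, c2$res)
        has_split[i] <- TRUE
      } else {
        res_of[[i]] <- list(lv)
      }
    } else {
      # chained merge: descend the big branch, carry the small one
      big <- if (c1$size >= c2$size) c1 else c2
      sml <- if (c1$size >= c2$size) c2 else c1
      if (big$split) {
        res_of[[i]] <- c(big$res, list(sml$leaves))
        has_split[i] <- TRUE
      } else {
        res_of[[i]] <- list(lv)
      }
    }
  }

  ## top node of each static branch (highest node fully inside the branch)
  node_cl <- rep(NA_integer_, n - 1L)
  cl_of <- function(ch) if (ch < 0) static[-ch] else node_cl[ch]
  for (i in seq_len(n - 1L)) {
    c1 <- cl_of(merge[i, 1]); c2 <- cl_of(merge[i, 2])
    if (!is.na(c1) && !is.na(c2) && c1 == c2) node_cl[i] <- c1
  }
  clusters <- list()
  for (cl in sort(unique(static))) {
    members <- which(static == cl)
    if (length(members) == 1L) {
      clusters <- c(clusters, list(members))
      next
    }
    tops <- which(node_cl == cl)
    top <- tops[which.max(vapply(tops, function(i)
      length(leaves_of[[i]]), integer(1)))]
    clusters <- c(clusters, res_of[[top]])
  }

  ## merge or drop undersized branches
  unassigned <- integer(0)
  repeat {
    sizes <- vapply(clusters, length, integer(1))
    small <- which(sizes < min_module_size)
    if (length(small) == 0L || length(clusters) == 1L) break
    i <- small[which.min(sizes[small])]
    others <- setdiff(seq_along(clusters), i)
    avg_d <- vapply(others, function(j)
      mean(d[clusters[[i]], clusters[[j]], drop = FALSE]), numeric(1))
    j <- others[which.min(avg_d)]
    if (min(avg_d) <= h_cut) {
      clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    } else {
      unassigned <- c(unassigned, clusters[[i]])
    }
    clusters[[i]] <- NULL
  }
  sizes <- vapply(clusters, length, integer(1))
  if (length(clusters) == 1L && sizes[1] < min_module_size) {
    unassigned <- c(unassigned, clusters[[1]])
    clusters <- list()
    sizes <- integer(0)
  }

  labels <- rep(0L, n)
  for (rank in seq_along(clusters)) {
    labels[clusters[[order(-sizes)[rank]]]] <- rank
  }
  names(labels) <- gene_ids
  attr(labels, "module_sizes") <- table(labels[labels > 0L])
  labels
}

#' Tune the hard threshold toward a target mean module size
#'
#' Runs the full module-detection stage (threshold, TOM dissimilarity,
#' average linkage, adaptive tree cut) for each candidate threshold and picks
#' the one whose mean nonzero-module size is closest to `target_mean_size`;
#' ties go to the smaller threshold. Grid points yielding zero modules are
#' skipped with a warning.
#'
#' @param expr numeric matrix, samples x genes.
#' @param grid candidate thresholds in [0,1].
#' @param target_mean_size desired mean module size (default 200).
#' @param min_module_size,cut_height_quantile,split_gap passed to
#'   [dynamic_tree_cut()].
#' @param binarize passed to [hard_threshold()].
#' @return list with `tau` (chosen threshold), `modules` (its module
#'   assignment), `adjacency` (thresholded adjacency at `tau`), and `report`
#'   (data.frame of tau, n_modules, mean/min/max module size per grid point).
#' @export
tune_hard_threshold <- function(expr, grid = seq(0.1, 0.5, by = 0.05),
                                target_mean_size = 200,
                                min_module_size = 30,
                                cut_height_quantile = 0.99,
                                split_gap = 0.3, binarize = FALSE) {
  if (length(grid) == 0L) stop("empty threshold grid")
  adj0 <- correlation_adjacency(expr)
  rows <- list()
  assignments <- list()
  for (tau in sort(grid)) {
    a <- hard_threshold(adj0, tau, binarize)
    dd <- suppressWarnings(tom_dissimilarity(a))
    hc <- average_linkage(dd)
    mods <- dynamic_tree_cut(hc, dd, min_module_size, cut_height_quantile,
                             split_gap)
    sz <- as.integer(attr(mods, "module_sizes"))
    if (length(sz) == 0L) {
      warning("threshold ", tau, " yields zero modules; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      tau = tau, n_modules = length(sz), mean_size = mean(sz),
      min_size = min(sz), max_size = max(sz)
    )
    assignments[[as.character(tau)]] <- mods
  }
  if (length(rows) == 0L) stop("all grid points yielded zero modules")
  report <- do.call(rbind, rows)
  obj <- abs(report$mean_size - target_mean_size)
  best <- which(obj == min(obj))[1]          # grid sorted: tie -> smaller tau
  tau <- report$tau[best]
  list(tau = tau,
       modules = assignments[[as.character(tau)]],
       adjacency = hard_threshold(adj0, tau, binarize),
       report = report)
}
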