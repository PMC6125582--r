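# Independent reference implementations used as oracles. Each is written as
# a literal transcription of the defining formula (loops, no vectorized
# shortcuts shared with the package code).

# topological overlap dissimilarity by triple loop
oracle_tom_dissimilarity <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      den <- min(k[i], k[j]) + 1 - a[i, j]
      tom <- if (den <= 0) 0 else (l + a[i, j]) / den
      d[i, j] <- 1 - min(max(tom, 0), 1)
    }
  }
  d
}

# BH adjustment by literal sort / scan / cumulative-minimum
oracle_bh <- function(p, m = length(p)) {
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(length(p))
  running <- 1
  for (k in rev(seq_along(ranked))) {
    running <- min(running, ranked[k] * m / k)
    adj[k] <- running
  }
  out <- numeric(length(p))
  out[o] <- pmin(adj, 1)
  out
}

# ABOF by literal double loop over unordered pairs (population variance);
# x must already be on the scale the implementation uses internally
oracle_abof <- function(x) {
  n <- nrow(x)
  out <- numeric(n)
  for (p in seq_len(n)) {
    vals <- c()
    others <- setdiff(seq_len(n), p)
    for (ii in seq_along(others)) {
      for (jj in seq_along(others)) {
        if (jj <= ii) next
        u <- x[p, ] - x[others[ii], ]
        v <- x[p, ] - x[others[jj], ]
        nu <- sum(u^2); nv <- sum(v^2)
        if (nu == 0 || nv == 0) next
        vals <- c(vals, sum(u * v) / (nu * nv))
      }
    }
    out[p] <- if (length(vals) < 2) 0 else mean((vals - mean(vals))^2)
  }
  out
}

# ssGSEA enrichment score by literal position-by-position accumulation
oracle_ssgsea <- function(x, gene_set, alpha) {
  genes <- names(x)
  n <- length(x)
  pos <- order(-x, genes)
  num_den <- 0
  for (g in gene_set) {
    rank_from_bottom <- n - which(genes[pos] == g) + 1
    num_den <- num_den + rank_from_bottom^alpha
  }
  es <- 0
  pin <- 0
  pout <- 0
  for (i in seq_len(n)) {
    g <- genes[pos[i]]
    if (g %in% gene_set) {
      pin <- pin + (n - i + 1)^alpha / num_den
    } else {
      pout <- pout + 1 / (n - length(gene_set))
    }
    es <- es + (pin - pout)
  }
  es
}

# block-structured dissimilarity with jittered entries, for tree-cut tests
make_block_d <- function(sizes, within, between, seed = 1, jitter = 0.02) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  for (b in seq_along(sizes)) {
    idx <- which(lab == b)
    d[idx, idx] <- within[min(b, length(within))]
  }
  noise <- matrix(stats::runif(n * n, -jitter, jitter), n, n)
  noise <- (noise + t(noise)) / 2
  d <- pmin(pmax(d + noise, 0), 1)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(sprintf("G%03d", 1:n), sprintf("G%03d", 1:n))
  list(d = d, labels = stats::setNames(lab, rownames(d)))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small synthetic cohort shortcut for tests
quick_cohort <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_samples = 100L, n_genes = 600L, module_sizes = rep(80L, 4),
         n_trait_modules = 1, trait_effect = 5, frac_low_count = 0.15,
         frac_high_cov = 0.05, n_outliers = 1, seed = seed),
    list(...))
  generate_cohort(do.call(sim_config, args))
}
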