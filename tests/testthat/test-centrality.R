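test_that("eigenvector centrality matches closed forms and is scale free", {
  # complete graph on 5 nodes: uniform 1/sqrt(5)
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(unname(eigenvector_centrality(k5)), rep(1 / sqrt(5), 5),
               tolerance = 1e-9)

  # 3-node path: (1, sqrt(2), 1) / 2, principal eigenvalue sqrt(2)
  p3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(unname(eigenvector_centrality(p3)),
               c(1, sqrt(2), 1) / 2, tolerance = 1e-9)

  # scaling the adjacency leaves the eigenvector unchanged
  set.seed(1)
  a <- matrix(runif(64), 8, 8); a <- (a + t(a)) / 2; diag(a) <- 0
  expect_equal(eigenvector_centrality(a), eigenvector_centrality(10 * a),
               tolerance = 1e-9)

  # disconnected graph: zeros off the main component, unit norm overall
  b <- matrix(0, 5, 5)
  b[1, 2] <- b[2, 1] <- 1
  b[3, 4] <- b[4, 3] <- b[4, 5] <- b[5, 4] <- b[3, 5] <- b[5, 3] <- 1
  expect_warning(ec <- eigenvector_centrality(b), "disconnected")
  expect_equal(ec[1:2], c(0, 0), ignore_attr = TRUE)
  expect_equal(sum(ec^2), 1, tolerance = 1e-9)

  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "no edges")
})

test_that("power iteration agrees with full eigendecomposition", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(runif(50 * 50), 50, 50) * (matrix(runif(2500), 50) < 0.15)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    if (!any(a > 0)) next
    got <- suppressWarnings(eigenvector_centrality(a))
    keep <- got > 0
    ev <- eigen(a[keep, keep], symmetric = TRUE)
    ref <- abs(ev$vectors[, 1])
    expect_equal(unname(got[keep]), ref, tolerance = 1e-8)
  }
})

test_that("univariate importance detects discriminative genes", {
  set.seed(2)
  n <- 500
  liability <- rnorm(n)
  dx <- ifelse(liability > 0, "MDD", "HC")
  expr <- cbind(signal = liability + rnorm(n, sd = 0.3),
                flat = rep(1.5, n),
                noise = rnorm(n))
  imp <- univariate_importance(expr, dx)
  expect_lt(imp$p_adj[imp$gene == "signal"], 1e-6)
  expect_equal(imp$p[imp$gene == "flat"], 1)
  expect_equal(imp$s[imp$gene == "flat"], 0)
  expect_equal(imp$s, -log(imp$p_adj))
  expect_true(all(imp$s >= 0))

  # permuted labels give roughly uniform p-values
  set.seed(3)
  e0 <- matrix(rnorm(120 * 200), 120, 200)
  imp0 <- univariate_importance(e0, sample(rep(0:1, 60)))
  expect_gt(stats::ks.test(imp0$p, "punif")$p.value, 0.01)

  # perfect separation falls back to the likelihood-ratio test
  sep <- cbind(perfect = c(rep(0, 10), rep(10, 10)))
  imp_sep <- univariate_importance(sep, rep(c("HC", "MDD"), each = 10))
  expect_true(imp_sep$separation[1])
  expect_lt(imp_sep$p[1], 0.01)

  expect_error(univariate_importance(expr, rep("MDD", n)), "classes")
})

test_that("per-module importance-centrality R2 behaves at the extremes", {
  genes <- sprintf("g%02d", 1:30)
  cent <- stats::setNames(seq(0.1, 1, length.out = 30), genes)
  mods <- stats::setNames(rep(1L, 30), genes)

  exact <- suppressWarnings(            # perfect fit is the point here
    module_centrality_correlation(2 * cent + 1, cent, mods))
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  # independent importance: E[R2] = 1 / (size - 1) under the null
  set.seed(4)
  r2 <- replicate(300, {
    module_centrality_correlation(
      stats::setNames(rnorm(30), genes), cent, mods)$r_squared
  })
  expect_lt(abs(mean(r2) - 1 / 29), 0.012)

  tiny <- stats::setNames(c(1L, 1L), genes[1:2])
  expect_true(is.na(
    module_centrality_correlation(2 * cent + 1, cent, tiny)$r_squared))
})

test_that("hub genes of a diagnosis-coupled module carry more importance", {
  hits <- sapply(1:20, function(seed) {
    set.seed(seed)
    n <- 200; g <- 40
    f <- rnorm(n)
    load <- seq(0.9, 0.2, length.out = g)        # decreasing factor loading
    expr <- sapply(load, function(l) l * f + sqrt(1 - l^2) * rnorm(n))
    colnames(expr) <- sprintf("g%02d", 1:g)
    dx <- ifelse(f + rnorm(n, sd = 0.7) > 0, "MDD", "HC")
    imp <- univariate_importance(expr, dx)
    mean(imp$s[1:10]) > mean(imp$s[31:40])       # top vs bottom loading
  })
  expect_gte(mean(hits), 0.9)
})

test_that("hypergeometric top-gene enrichment matches the pmf tail", {
  genes <- sprintf("g%04d", 1:500)
  mods <- stats::setNames(c(rep(1L, 50), rep(0L, 450)), genes)

  # module absent from the top list: p = 1
  p_far <- stats::setNames(c(rep(0.9, 50), sort(runif(450, 0, 0.5))), genes)
  out <- top_gene_enrichment(mods, p_far, top_k = 100)
  expect_equal(out$x, 0)
  expect_equal(out$p_hyper, 1)

  # K = k extreme: all top genes from the module
  mods_k <- stats::setNames(c(rep(1L, 20), rep(0L, 480)), genes)
  p_top <- stats::setNames(c(seq(1e-6, 1e-4, length.out = 20),
                             runif(480, 0.2, 1)), genes)
  out_k <- top_gene_enrichment(mods_k, p_top, top_k = 20)
  expect_equal(out_k$x, 20)
  expect_equal(out_k$p_hyper, 1 / choose(500, 20), tolerance = 1e-10)

  # pmf-summation oracle at the reference scale
  n_univ <- 5912; k_mod <- 291; k_top <- 100; x <- 10
  tail_sum <- sum(stats::dhyper(x:min(k_mod, k_top), k_mod,
                                n_univ - k_mod, k_top))
  expect_equal(stats::phyper(x - 1, k_mod, n_univ - k_mod, k_top,
                             lower.tail = FALSE), tail_sum, tolerance = 1e-12)

  # super-uniformity under random rankings
  set.seed(5)
  pv <- replicate(500, {
    top_gene_enrichment(mods, stats::setNames(runif(500), genes),
                        top_k = 50)$p_hyper
  })
  for (q in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(pv <= q), q + 3 * sqrt(q * (1 - q) / 500))

  expect_error(top_gene_enrichment(mods, p_far, top_k = 0), "positive")
  expect_error(top_gene_enrichment(mods, p_far, top_k = 1000), "exceeds")
})
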