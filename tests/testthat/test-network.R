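test_that("correlation adjacency is unsigned with zero diagonal", {
  set.seed(1)
  x <- matrix(rnorm(50), 10, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  x[, 2] <- -x[, 1]
  a <- correlation_adjacency(x)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(diag(a), rep(0, 5), ignore_attr = TRUE)
  expect_equal(a, t(a))

  # hand-computed 3-gene example over 5 samples
  h <- cbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 4, 6, 8, 10),
             g3 = c(5, 3, 4, 1, 2))
  ah <- correlation_adjacency(h)
  expect_equal(ah["g1", "g2"], 1)
  expect_equal(ah["g1", "g3"], abs(cor(h[, 1], h[, 3])))

  # null mean |r| is about sqrt(2 / (pi n))
  set.seed(2)
  z <- matrix(rnorm(1000 * 40), 1000, 40)
  an <- correlation_adjacency(z)
  expect_equal(mean(an[upper.tri(an)]), sqrt(2 / (pi * 1000)),
               tolerance = 0.15)

  x[, 3] <- 1
  expect_error(correlation_adjacency(x), "zero-variance")
})

test_that("hard threshold zeroes sub-threshold entries and keeps weights", {
  m <- matrix(c(0, 0.1, 0.19, 0.2,
                0.1, 0, 0.6, 0.3,
                0.19, 0.6, 0, 0.05,
                0.2, 0.3, 0.05, 0), 4, 4)
  t0 <- hard_threshold(m, 0)
  expect_equal(unname(t0), m, ignore_attr = TRUE)
  t1 <- hard_threshold(m, 1)
  expect_true(all(t1 == 0))
  t02 <- hard_threshold(m, 0.2)
  expect_equal(sort(unique(as.vector(t02))), c(0, 0.2, 0.3, 0.6))
  tb <- hard_threshold(m, 0.2, binarize = TRUE)
  expect_setequal(unique(as.vector(tb)), c(0, 1))
  expect_error(hard_threshold(m, 1.5), "tau")
})

test_that("TOM dissimilarity matches its definition and the brute force", {
  # two genes connected only to each other with weight 1
  a2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(tom_dissimilarity(a2)[1, 2], 0)

  # disconnected pair with no shared neighbours
  a0 <- matrix(0, 3, 3)
  a0[1, 3] <- a0[3, 1] <- 0  # fully empty adjacency is degenerate everywhere
  a0[2, 3] <- a0[3, 2] <- 0.5
  d0 <- suppressWarnings(tom_dissimilarity(a0))
  expect_equal(d0[1, 2], 1)

  # weighted 5-node toy graph vs triple-loop brute force
  set.seed(3)
  a5 <- matrix(runif(25), 5, 5)
  a5 <- (a5 + t(a5)) / 2
  diag(a5) <- 0
  expect_equal(unname(tom_dissimilarity(a5)), oracle_tom_dissimilarity(a5),
               tolerance = 1e-12)

  # bounds and symmetry on random adjacencies
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(runif(100), 10, 10) * rbinom(100, 1, 0.5)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    d <- suppressWarnings(tom_dissimilarity(a))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
  }
})

test_that("edge connectivity is monotone non-increasing in the threshold", {
  set.seed(4)
  x <- matrix(rnorm(30 * 40), 30, 40)
  a <- correlation_adjacency(x)
  taus <- c(0, 0.1, 0.2, 0.4, 0.8)
  k_prev <- NULL
  for (tau in taus) {
    k <- rowSums(hard_threshold(a, tau))
    if (!is.null(k_prev)) expect_true(all(k <= k_prev + 1e-12))
    k_prev <- k
  }
})

test_that("average linkage reproduces hand agglomeration", {
  # identical genes merge first at height 0
  d0 <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5, 0), 3, 3)
  hc0 <- average_linkage(d0)
  expect_equal(hc0$height[1], 0)

  # 4-leaf hand-computed UPGMA: AB at 0.1, CD at 0.2,
  # then mean(0.8, 0.9, 0.7, 0.85) = 0.8125
  d4 <- matrix(c(0, 0.1, 0.8, 0.9,
                 0.1, 0, 0.7, 0.85,
                 0.8, 0.7, 0, 0.2,
                 0.9, 0.85, 0.2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  hc4 <- average_linkage(d4)
  expect_equal(hc4$height, c(0.1, 0.2, 0.8125))
  expect_equal(stats::cutree(hc4, 2), c(A = 1, B = 1, C = 2, D = 2))

  # permuting leaves preserves the multiset of merge heights
  perm <- c(3, 1, 4, 2)
  hcp <- average_linkage(d4[perm, perm])
  expect_equal(sort(hcp$height), sort(hc4$height))
})

test_that("adaptive tree cut recovers planted blocks and enforces the floor", {
  blocks <- make_block_d(c(50, 60), within = 0.1, between = 0.9, seed = 1)
  hc <- average_linkage(blocks$d)
  mods <- dynamic_tree_cut(hc, blocks$d, min_module_size = 30)
  expect_equal(length(attr(mods, "module_sizes")), 2L)
  expect_equal(adjusted_rand(mods, blocks$labels), 1)

  # a 10-gene block is below the floor: absorbed or unassigned
  small <- make_block_d(c(50, 10), within = 0.1, between = 0.9, seed = 2)
  hc2 <- average_linkage(small$d)
  mods2 <- dynamic_tree_cut(hc2, small$d, min_module_size = 30)
  expect_equal(length(attr(mods2, "module_sizes")), 1L)
  expect_true(all(mods2[names(small$labels)[small$labels == 1]] == 1L))

  # nested hierarchy: three blocks, two of them closer to each other
  aris <- sapply(1:10, function(seed) {
    n1 <- 60; n2 <- 70; n3 <- 80
    d <- make_block_d(c(n1, n2, n3), within = 0.05, between = 0.9,
                      seed = seed)$d
    idx2 <- (n1 + 1):(n1 + n2)
    d[1:n1, idx2] <- d[1:n1, idx2] * 0 + 0.5
    d[idx2, 1:n1] <- 0.5
    lab <- rep(1:3, c(n1, n2, n3))
    hc3 <- average_linkage(d)
    adjusted_rand(dynamic_tree_cut(hc3, d, min_module_size = 30), lab)
  })
  expect_gte(mean(aris >= 0.9), 0.9)

  expect_error(dynamic_tree_cut(hc, blocks$d, min_module_size = 1000),
               "min_module_size")
})

test_that("tree-cut output is a partition respecting the size floor", {
  for (seed in 1:5) {
    co <- quick_cohort(seed = seed, n_genes = 400L,
                       module_sizes = rep(60L, 3))
    expr <- logcpm(filter_low_counts(co$counts)$counts)
    a <- hard_threshold(correlation_adjacency(expr), 0.2)
    d <- suppressWarnings(tom_dissimilarity(a))
    mods <- dynamic_tree_cut(average_linkage(d), d, min_module_size = 30)
    expect_length(mods, ncol(expr))
    sizes <- table(mods[mods > 0])
    if (length(sizes)) expect_true(all(sizes >= 30))
  }
})

test_that("threshold tuning targets the mean module size with tie to smaller tau", {
  co <- quick_cohort(seed = 9, n_samples = 120L, n_genes = 700L,
                     module_sizes = rep(100L, 4), frac_low_count = 0)
  pre <- preprocess_counts(co$counts, co$phenotypes)

  single <- tune_hard_threshold(pre$expr, grid = 0.25, target_mean_size = 100)
  expect_equal(single$tau, 0.25)

  tuned <- tune_hard_threshold(pre$expr, grid = c(0.15, 0.2, 0.25),
                               target_mean_size = 100)
  expect_true(tuned$tau %in% c(0.15, 0.2, 0.25))
  best <- abs(tuned$report$mean_size - 100)
  expect_equal(tuned$tau, tuned$report$tau[which.min(best)])
  expect_true(all(c("tau", "n_modules", "mean_size", "min_size",
                    "max_size") %in% names(tuned$report)))

  expect_error(tune_hard_threshold(pre$expr, grid = numeric(0)), "empty")
})
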