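#' Configuration for a synthetic RNA-Seq cohort
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' generator emulates a bulk RNA-Seq case/control depression cohort: negative
#' binomial counts over genes x samples, block-correlated gene modules induced
#' by per-module latent factors (Gaussian copula on the log-mean), a MADRS-like
#' quantitative severity trait linearly coupled to a subset of module factors,
#' batch offsets, covariates (sex, age, BMI, smoking), deliberately low-count
#' genes, high-variability genes, and a few geometric outlier samples.
#'
#' @param n_samples number of samples.
#' @param n_genes total number of genes; genes not covered by `module_sizes`
#'   are uncorrelated background.
#' @param module_sizes integer vector of planted module sizes;
#'   `sum(module_sizes) <= n_genes`.
#' @param within_module_correlation latent-factor share `rho` in (0,1) of the
#'   per-gene log-scale variance; controls within-module expression correlation.
#' @param n_trait_modules number of modules whose latent factor is linearly
#'   coupled to the trait; at most `length(module_sizes)`.
#' @param trait_effect slope of the trait on the summed trait-module factors,
#'   in trait-score units per factor standard deviation.
#' @param n_batches number of sequencing batches.
#' @param batch_sd standard deviation (natural-log scale) of per-batch gene
#'   expression offsets.
#' @param nb_dispersion negative binomial dispersion (`size = 1/dispersion`).
#' @param frac_low_count fraction of genes given a log-mean low enough to fail
#'   the low-count filter, in [0,1).
#' @param frac_high_cov fraction of genes given inflated per-sample variance so
#'   that their coefficient of variation exceeds typical filter thresholds.
#' @param n_outliers number of samples shifted away from the data cloud.
#' @param outlier_shift size of the outlier shift in multiples of each shifted
#'   gene's log-scale standard deviation.
#' @param seed integer seed; the whole cohort is deterministic given the seed.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 157,
                       n_genes = 6000,
                       module_sizes = rep(200L, 12),
                       within_module_correlation = 0.6,
                       n_trait_modules = 2,
                       trait_effect = 5,
                       n_batches = 2,
                       batch_sd = 0.1,
                       nb_dispersion = 0.15,
                       frac_low_count = 0.3,
                       frac_high_cov = 0.05,
                       n_outliers = 2,
                       outlier_shift = 4,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    within_module_correlation = within_module_correlation,
    n_trait_modules = as.integer(n_trait_modules),
    trait_effect = trait_effect,
    n_batches = as.integer(n_batches), batch_sd = batch_sd,
    nb_dispersion = nb_dispersion,
    frac_low_count = frac_low_count, frac_high_cov = frac_high_cov,
    n_outliers = as.integer(n_outliers), outlier_shift = outlier_shift,
    seed = as.integer(seed)
  )
  if (cfg$n_samples < 1L)
    stop("invalid sim_config: n_samples must be >= 1")
  if (cfg$n_genes < 1L)
    stop("invalid sim_config: n_genes must be >= 1")
  if (length(cfg$module_sizes) == 0L || any(cfg$module_sizes < 1L))
    stop("invalid sim_config: module_sizes must be positive")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("invalid sim_config: sum(module_sizes) exceeds n_genes")
  rho <- cfg$within_module_correlation
  if (!is.finite(rho) || rho <= 0 || rho >= 1)
    stop("invalid sim_config: within_module_correlation must lie in (0,1)")
  if (cfg$n_trait_modules < 0L || cfg$n_trait_modules > length(cfg$module_sizes))
    stop("invalid sim_config: n_trait_modules exceeds number of modules")
  if (cfg$n_batches < 1L)
    stop("invalid sim_config: n_batches must be >= 1")
  if (cfg$nb_dispersion <= 0)
    stop("invalid sim_config: nb_dispersion must be > 0")
  for (f in c("frac_low_count", "frac_high_cov")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1)
      stop("invalid sim_config: ", f, " must lie in [0,1)")
  }
  if (cfg$n_outliers < 0L || cfg$n_outliers > cfg$n_samples)
    stop("invalid sim_config: n_outliers exceeds n_samples")
  structure(cfg, class = "sim_config")
}

# Deterministic child seeds so sub-stages can be re-drawn independently.
.child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic cohort with planted co-expression modules
#'
#' Draws a cohort under the generative model described in
#' [sim_config()]. Genes in planted module m share a per-sample standard
#' normal latent factor f_m; the log-mean of gene g in sample s is
#' `b_g + sigma_g * (sqrt(rho) * f_m[s] + sqrt(1-rho) * eps_gs)` plus a batch
#' offset and a log library-size factor, and counts are negative binomial
#' around `exp(log-mean)`. The MADRS-like trait is
#' `intercept + trait_effect * sum(trait-module factors) + covariate terms +
#' Gaussian noise`, truncated at 0 and rounded to integers. Diagnosis is
#' assigned by thresholding a liability score built from the trait so that
#' diagnosis and trait are correlated as in a clinical case/control sample.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_cohort`: a list with
#'   \item{counts}{integer matrix, genes x samples, with dimnames;}
#'   \item{phenotypes}{data.frame with sample_id, diagnosis ("MDD"/"HC"),
#'     madrs, sex, age, bmi, batch, smoking;}
#'   \item{truth}{list with `module_labels` (named integer vector over genes,
#'     0 = background), `trait_modules` (labels of trait-coupled modules),
#'     `outliers` (sample ids of planted outliers).}
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_samples
  g <- config$n_genes
  sizes <- config$module_sizes
  m <- length(sizes)
  rho <- config$within_module_correlation
  seeds <- .child_seeds(config$seed, 6L)

  ## --- covariates and trait ------------------------------------------------
  set.seed(seeds[1])
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  age <- pmin(55L, pmax(18L, as.integer(round(stats::rnorm(n, 32, 10)))))
  bmi <- round(pmin(45, pmax(16, stats::rnorm(n, 28, 6))), 1)
  batch <- sample(rep_len(seq_len(config$n_batches), n))
  smoking <- sample(c("smoker", "non-smoker"), n, replace = TRUE,
                    prob = c(0.1, 0.9))

  set.seed(seeds[2])
  factors <- matrix(stats::rnorm(n * m), n, m)
  trait_modules <- if (config$n_trait_modules > 0L)
    seq_len(config$n_trait_modules) else integer(0)
  f_trait <- if (length(trait_modules))
    rowSums(factors[, trait_modules, drop = FALSE]) else numeric(n)
  madrs_raw <- 10 + config$trait_effect * f_trait +
    0.05 * (age - 32) + 0.15 * (bmi - 28) + stats::rnorm(n, 0, 6)
  madrs <- pmax(0, round(madrs_raw))
  liability <- scale(madrs_raw)[, 1] + stats::rnorm(n, 0, 0.5)
  diagnosis <- ifelse(rank(liability, ties.method = "first") > n / 2,
                      "MDD", "HC")

  ## --- gene parameters -----------------------------------------------------
  set.seed(seeds[3])
  module_of <- integer(g)                      # 0 = background
  module_of[seq_len(sum(sizes))] <- rep(seq_len(m), sizes)
  module_of <- sample(module_of)               # scatter module genes
  b <- stats::rnorm(g, log(100), 1)            # baseline log-mean (counts)
  sigma <- stats::runif(g, 0.3, 0.5)           # per-gene log-scale SD
  background <- which(module_of == 0L)
  pick <- function(pool, k) pool[seq_len(min(k, length(pool)))]
  low_idx <- pick(sample(background), round(config$frac_low_count * g))
  b[low_idx] <- log(0.1)                       # fails any read-count filter
  remaining <- setdiff(background, low_idx)
  hicov_idx <- pick(sample(remaining), round(config$frac_high_cov * g))
  sigma[hicov_idx] <- stats::runif(length(hicov_idx), 1.1, 1.5)

  ## --- log-scale expression ------------------------------------------------
  set.seed(seeds[4])
  eps <- matrix(stats::rnorm(n * g), n, g)
  x <- eps * rep(sigma * sqrt(1 - rho), each = n)
  in_mod <- module_of > 0L
  x[, in_mod] <- x[, in_mod] +
    factors[, module_of[in_mod], drop = FALSE] *
      rep(sigma[in_mod] * sqrt(rho), each = n)

  set.seed(seeds[5])
  batch_off <- matrix(stats::rnorm(config$n_batches * g, 0, config$batch_sd),
                      config$n_batches, g)
  x <- x + batch_off[batch, , drop = FALSE]

  outliers <- integer(0)
  if (config$n_outliers > 0L) {
    outliers <- sample(n, config$n_outliers)
    for (s in outliers) {
      shifted <- sample(g, round(0.5 * g))
      x[s, shifted] <- x[s, shifted] +
        config$outlier_shift * sigma[shifted] * sample(c(-1, 1), 1)
    }
  }

  lib_factor <- stats::rlnorm(n, 0, 0.294)     # CV ~ 0.3 library sizes

  ## --- counts --------------------------------------------------------------
  set.seed(seeds[6])
  mu <- exp(sweep(x, 2, b, "+")) * lib_factor  # n x g
  counts <- matrix(stats::rnbinom(n * g, mu = mu, size = 1 / config$nb_dispersion),
                   n, g)
  counts <- t(counts)                          # genes x samples
  gene_ids <- sprintf("G%05d", seq_len(g))
  sample_ids <- sprintf("S%03d", seq_len(n))
  dimnames(counts) <- list(gene_ids, sample_ids)

  phenotypes <- data.frame(
    sample_id = sample_ids, diagnosis = diagnosis, madrs = madrs,
    sex = sex, age = age, bmi = bmi, batch = factor(batch),
    smoking = smoking, stringsAsFactors = FALSE
  )
  truth <- list(
    module_labels = stats::setNames(module_of, gene_ids),
    trait_modules = trait_modules,
    outliers = sample_ids[sort(outliers)]
  )
  structure(list(counts = counts, phenotypes = phenotypes, truth = truth),
            class = "synthetic_cohort")
}

#' Generate an independent replication cohort over a reduced gene universe
#'
#' Builds a second cohort that shares only a fraction of each discovery
#' module's genes (the rest are absent from the replication gene universe,
#' emulating differing low-abundance filters between studies). Diagnosis is
#' coupled to the trait-module latent factors through a logistic liability
#' with log-odds `config$trait_effect` per summed-factor standard deviation.
#'
#' @param config a [sim_config()]; `n_samples`, correlation, dispersion and
#'   batch settings are reused for the new cohort.
#' @param modules named integer vector of discovery module labels per gene
#'   (0 = unassigned), as in `synthetic_cohort$truth$module_labels` or
#'   [dynamic_tree_cut()].
#' @param overlap_fraction fraction in (0,1] of each module's genes retained
#'   in the replication universe (rounded to the nearest integer count).
#' @param trait_modules labels of the modules coupled to diagnosis; defaults
#'   to the first `config$n_trait_modules` labels in sorted order.
#' @return a `synthetic_cohort`; its phenotype table has no MADRS trait
#'   (diagnosis-only replication design).
#' @export
generate_replication_cohort <- function(config, modules, overlap_fraction,
                                        trait_modules = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  labels <- modules[modules > 0L]
  if (length(labels) == 0L)
    stop("modules must contain at least one assigned gene")
  if (!is.finite(overlap_fraction) || overlap_fraction <= 0 ||
      overlap_fraction > 1)
    stop("overlap_fraction must lie in (0, 1]")

  seeds <- .child_seeds(config$seed + 1L, 3L)
  set.seed(seeds[1])
  keep <- character(0)
  labs <- sort(unique(labels))
  kept_label <- integer(0)
  for (l in labs) {
    genes <- names(labels)[labels == l]
    k <- max(1L, round(overlap_fraction * length(genes)))
    chosen <- if (k >= length(genes)) genes else sample(genes, k)
    keep <- c(keep, chosen)
    kept_label <- c(kept_label, rep(l, length(chosen)))
  }
  if (is.null(trait_modules))
    trait_modules <- labs[seq_len(min(config$n_trait_modules, length(labs)))]

  n <- config$n_samples
  rho <- config$within_module_correlation
  g_mod <- length(keep)
  n_bg <- max(0L, config$n_genes - length(labels))   # background universe
  g <- g_mod + n_bg

  set.seed(seeds[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- pmin(70L, pmax(18L, as.integer(round(stats::rnorm(n, 40, 12)))))
  bmi <- round(pmin(45, pmax(16, stats::rnorm(n, 27, 5))), 1)
  factors <- matrix(stats::rnorm(n * length(labs)), n, length(labs),
                    dimnames = list(NULL, paste0("M", labs)))
  f_trait <- rowSums(factors[, paste0("M", trait_modules), drop = FALSE])
  p_mdd <- stats::plogis(config$trait_effect * scale(f_trait)[, 1])
  diagnosis <- ifelse(stats::runif(n) < p_mdd, "MDD", "HC")

  set.seed(seeds[3])
  module_of <- c(kept_label, rep(0L, n_bg))
  b <- stats::rnorm(g, log(100), 1)
  sigma <- stats::runif(g, 0.3, 0.5)
  eps <- matrix(stats::rnorm(n * g), n, g)
  x <- eps * rep(sigma * sqrt(1 - rho), each = n)
  in_mod <- module_of > 0L
  x[, in_mod] <- x[, in_mod] +
    factors[, paste0("M", module_of[in_mod]), drop = FALSE] *
      rep(sigma[in_mod] * sqrt(rho), each = n)
  lib_factor <- stats::rlnorm(n, 0, 0.294)
  mu <- exp(sweep(x, 2, b, "+")) * lib_factor
  counts <- t(matrix(stats::rnbinom(n * g, mu = mu,
                                    size = 1 / config$nb_dispersion), n, g))
  gene_ids <- c(keep, sprintf("BG%05d", seq_len(n_bg)))
  sample_ids <- sprintf("R%03d", seq_len(n))
  dimnames(counts) <- list(gene_ids, sample_ids)

  phenotypes <- data.frame(
    sample_id = sample_ids, diagnosis = diagnosis,
    sex = sex, age = age, bmi = bmi, stringsAsFactors = FALSE
  )
  truth <- list(
    module_labels = stats::setNames(module_of, gene_ids),
    trait_modules = trait_modules,
    outliers = character(0)
  )
  structure(list(counts = counts, phenotypes = phenotypes, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  nz <- x$truth$module_labels[x$truth$module_labels > 0]
  cat("  planted modules:", length(unique(nz)),
      "(", length(nz), "genes ), trait-coupled:",
      paste(x$truth$trait_modules, collapse = ", "), "\n")
  cat("  planted outliers:", if (length(x$truth$outliers))
    paste(x$truth$outliers, collapse = ", ") else "none", "\n")
  invisible(x)
}
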