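#' Filter genes with low read counts
#'
#' Retains genes supported by at least `min_samples` samples whose read count
#' meets a per-sample threshold that depends on the sample's library size:
#' the threshold interpolates linearly over library-size rank from
#' `min_reads_range[1]` (smallest library) to `min_reads_range[2]` (largest
#' library), rounded to the nearest integer. With the defaults this
#' operationalizes the rule "at least 15 individuals with at least 2-7 reads,
#' depending on the library size".
#'
#' @param counts integer matrix, genes x samples (non-negative).
#' @param min_samples minimum number of samples meeting their threshold.
#' @param min_reads_range length-2 numeric, read thresholds for the smallest
#'   and largest library.
#' @return list with `counts` (the retained rows), `removed` (character vector
#'   of removed gene ids), `thresholds` (per-sample integer read thresholds).
#' @export
filter_low_counts <- function(counts, min_samples = 15,
                              min_reads_range = c(2, 7)) {
  counts <- .check_counts(counts)
  n <- ncol(counts)
  if (min_samples > n)
    stop("min_samples (", min_samples, ") exceeds number of samples (", n, ")")
  lib <- colSums(counts)
  r <- rank(lib, ties.method = "first")
  t_j <- if (n == 1L) round(min_reads_range[1]) else
    round(min_reads_range[1] +
            (min_reads_range[2] - min_reads_range[1]) * (r - 1) / (n - 1))
  ok <- rowSums(sweep(counts, 2, t_j, ">=")) >= min_samples
  list(counts = counts[ok, , drop = FALSE],
       removed = rownames(counts)[!ok],
       thresholds = stats::setNames(as.integer(t_j), colnames(counts)))
}

.check_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  counts
}

#' log2 counts per million
#'
#' `logcpm(counts)[s, g] = log2((counts[g, s] + prior) /
#' (library_size[s] + 2 * prior) * 1e6)`. Library sizes are the column sums of
#' the full matrix unless supplied.
#'
#' @param counts integer matrix, genes x samples.
#' @param prior prior count added to the numerator (half of it, doubled, to
#'   the library size), keeping zeros finite.
#' @param lib_sizes optional per-sample library sizes; defaults to column sums.
#' @return numeric matrix, samples x genes (analysis orientation).
#' @export
logcpm <- function(counts, prior = 0.5, lib_sizes = NULL) {
  counts <- .check_counts(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) {
    bad <- colnames(counts)[lib_sizes <= 0]
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  cpm <- sweep(counts + prior, 2, lib_sizes + 2 * prior, "/") * 1e6
  t(log2(cpm))
}

# unlogged CPM on the same prior convention, samples x genes
.cpm_linear <- function(counts, prior = 0.5, lib_sizes = NULL) {
  counts <- .check_counts(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  t(sweep(counts + prior, 2, lib_sizes + 2 * prior, "/") * 1e6)
}

#' Angle-based outlier factors (ABOF)
#'
#' For each sample p (a point in gene space), the ABOF is the variance over
#' all unordered pairs (x, y) of the other samples of
#' `<p-x, p-y> / (|p-x|^2 * |p-y|^2)`. Samples that sit far outside the data
#' cloud see all other points under a narrow range of angles and get a small
#' ABOF. Expression is standardized per gene (zero mean, unit variance)
#' before the computation so that all genes contribute on the same scale.
#'
#' @param expr numeric matrix, samples x genes.
#' @param threshold samples with ABOF strictly below this are flagged for
#'   removal (default 0.001).
#' @param standardize standardize each gene before computing angles.
#' @return list with `abof` (named per-sample factor), `threshold`, and
#'   `removed` (sample ids with `abof < threshold`).
#' @export
abof_scores <- function(expr, threshold = 0.001, standardize = TRUE) {
  expr <- as.matrix(expr)
  n <- nrow(expr)
  if (n < 3L) stop("ABOF needs at least 3 samples")
  # per-gene standardization plus a 1/sqrt(n_genes) rescale keeps the ABOF
  # magnitude independent of the gene-universe size, so one absolute
  # threshold is meaningful across data sets
  x <- if (standardize) .standardize_genes(expr) / sqrt(ncol(expr)) else expr
  # Gram trick: <p-a, p-b> = K[a,b] - K[p,a] - K[p,b] + K[p,p]
  k <- tcrossprod(x)
  abof <- numeric(n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    ip <- k[others, others] - outer(k[p, others], rep(1, n - 1L)) -
      outer(rep(1, n - 1L), k[p, others]) + k[p, p]
    sq <- diag(ip)                       # |p - a|^2
    denom <- outer(sq, sq)
    vals <- ip / denom
    ut <- upper.tri(vals)
    good <- ut & is.finite(vals)         # skip pairs with coincident points
    v <- vals[good]
    if (length(v) < 2L) {
      if (all(!is.finite(vals[ut])))
        stop("all sample pairs degenerate for sample ", rownames(expr)[p])
      abof[p] <- 0
    } else {
      abof[p] <- stats::var(v) * (length(v) - 1) / length(v)  # population var
    }
  }
  names(abof) <- rownames(expr)
  list(abof = abof, threshold = threshold,
       removed = rownames(expr)[abof < threshold])
}

.standardize_genes <- function(expr) {
  mu <- colMeans(expr)
  sd <- apply(expr, 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(expr, 2, mu), 2, sd, "/")
}

#' Remove batch effects by per-gene linear regression
#'
#' Fits, per gene, an ordinary least squares model of expression on an
#' intercept, optional covariates to be preserved, and batch indicator
#' contrasts, then subtracts only the fitted batch component. Gene-wise grand
#' means and covariate effects are preserved.
#'
#' @param expr numeric matrix, samples x genes.
#' @param batch factor (or coercible) of batch membership per sample.
#' @param keep_covariates optional numeric design matrix (samples x columns)
#'   of effects that must be preserved, without intercept.
#' @return corrected matrix, samples x genes.
#' @export
remove_batch_effect <- function(expr, batch, keep_covariates = NULL) {
  expr <- as.matrix(expr)
  batch <- droplevels(as.factor(batch))
  if (length(batch) != nrow(expr))
    stop("batch length does not match number of samples")
  if (any(table(batch) < 2L))
    stop("every batch level needs at least 2 samples")
  if (nlevels(batch) < 2L) return(expr)
  bmat <- stats::model.matrix(~batch)[, -1, drop = FALSE]  # treatment contrasts
  base <- cbind(Intercept = rep(1, nrow(expr)),
                if (!is.null(keep_covariates)) as.matrix(keep_covariates))
  design <- cbind(base, bmat)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("singular design: batch confounded with kept covariates (",
         paste(dropped, collapse = ", "), ")")
  }
  beta <- qr.coef(qr_d, expr)                     # coefficients x genes
  batch_cols <- seq.int(ncol(base) + 1L, ncol(design))
  comp <- bmat %*% beta[batch_cols, , drop = FALSE]
  # centering the batch component preserves each gene's grand mean exactly
  expr - sweep(comp, 2, colMeans(comp))
}

#' Filter genes by coefficient of variation
#'
#' The coefficient of variation (COV) is computed per gene on the unlogged CPM
#' scale (sample standard deviation over mean); genes with COV above the
#' threshold are removed as technically over-variable. Survivors are returned
#' together with the removal record.
#'
#' @param cpm numeric matrix, samples x genes, unlogged CPM.
#' @param threshold maximum allowed COV (default 0.8).
#' @return list with `keep` (logical per gene), `cov` (named per-gene COV),
#'   `removed` (gene ids) and `reasons` (rule per removed gene).
#' @export
cov_filter <- function(cpm, threshold = 0.8) {
  cpm <- as.matrix(cpm)
  if (any(cpm < 0)) stop("CPM values must be non-negative")
  mu <- colMeans(cpm)
  sd <- apply(cpm, 2, stats::sd)
  cov <- ifelse(mu > 0, sd / mu, Inf)
  names(cov) <- colnames(cpm)
  keep <- is.finite(cov) & cov <= threshold
  reasons <- ifelse(mu[!keep] > 0, sprintf("COV > %g", threshold), "zero-mean")
  list(keep = keep, cov = cov,
       removed = colnames(cpm)[!keep],
       reasons = stats::setNames(reasons, colnames(cpm)[!keep]))
}

#' TMM-style normalization-factor diagnostic
#'
#' Trimmed mean of M-values factors relative to the sample with library size
#' closest to the mean, reported as a diagnostic only (the pipeline's logCPM
#' uses raw library sizes). Extreme factors typically coincide with outlier
#' samples.
#'
#' @param counts integer matrix, genes x samples.
#' @param trim_m,trim_a trim fractions for log-ratios and average intensities.
#' @return named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  counts <- .check_counts(counts)
  lib <- colSums(counts)
  ref <- which.min(abs(lib - mean(lib)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    ok <- counts[, j] > 0 & counts[, ref] > 0
    if (!any(ok)) return(NA_real_)
    m <- log2((counts[ok, j] / lib[j]) / (counts[ok, ref] / lib[ref]))
    a <- 0.5 * log2((counts[ok, j] / lib[j]) * (counts[ok, ref] / lib[ref]))
    qm <- stats::quantile(m, c(trim_m, 1 - trim_m))
    qa <- stats::quantile(a, c(trim_a, 1 - trim_a))
    use <- m >= qm[1] & m <= qm[2] & a >= qa[1] & a <= qa[2]
    if (!any(use)) return(NA_real_)
    2^mean(m[use])
  }, numeric(1))
  stats::setNames(f, colnames(counts))
}

#' Preprocess a raw count matrix end to end
#'
#' Applies, in order: low-count filtering, logCPM normalization, angle-based
#' outlier-sample removal, batch-effect removal, and coefficient-of-variation
#' gene filtering. Returns the final logCPM matrix (samples x genes) plus a
#' provenance record listing every removed gene and sample with the rule that
#' removed it, so that `genes in - removed(low count) - removed(COV) =
#' genes out` is checkable on any run.
#'
#' @param counts integer matrix, genes x samples.
#' @param phenotypes data.frame with a `sample_id` column matching the count
#'   columns, and a `batch` column if batch correction is wanted.
#' @param min_samples,min_reads_range see [filter_low_counts()].
#' @param abof_threshold see [abof_scores()]; set to `NA` to skip.
#' @param cov_threshold see [cov_filter()]; set to `NA` to skip.
#' @param prior logCPM prior count.
#' @param keep_covariates optional columns of `phenotypes` preserved during
#'   batch correction (numeric or 2-level factors).
#' @return list with `expr` (samples x genes logCPM, batch-corrected),
#'   `phenotypes` (rows for retained samples), `provenance` (filter
#'   thresholds, removed ids and counts at each stage), `abof` (the outlier
#'   report) and `tmm` (diagnostic normalization factors).
#' @export
preprocess_counts <- function(counts, phenotypes = NULL,
                              min_samples = 15, min_reads_range = c(2, 7),
                              abof_threshold = 0.001, cov_threshold = 0.8,
                              prior = 0.5, keep_covariates = NULL) {
  counts <- .check_counts(counts)
  n_in <- nrow(counts)
  lc <- filter_low_counts(counts, min_samples, min_reads_range)
  counts <- lc$counts
  tmm <- tmm_factors(counts)

  expr <- logcpm(counts, prior)
  removed_samples <- character(0)
  abof <- NULL
  if (!is.na(abof_threshold)) {
    abof <- abof_scores(expr, abof_threshold)
    removed_samples <- abof$removed
    if (length(removed_samples)) {
      keep_s <- setdiff(rownames(expr), removed_samples)
      counts <- counts[, keep_s, drop = FALSE]
      # re-derive logCPM on the retained samples' own library sizes
      expr <- logcpm(counts, prior)
    }
  }
  if (!is.null(phenotypes)) {
    phenotypes <- phenotypes[match(rownames(expr), phenotypes$sample_id), ,
                             drop = FALSE]
    if (anyNA(phenotypes$sample_id))
      stop("phenotype table is missing retained samples")
  }

  if (!is.null(phenotypes) && "batch" %in% names(phenotypes) &&
      nlevels(droplevels(as.factor(phenotypes$batch))) > 1L) {
    kc <- NULL
    if (!is.null(keep_covariates)) {
      kc <- stats::model.matrix(
        stats::reformulate(keep_covariates), data = phenotypes)[, -1,
                                                                drop = FALSE]
    }
    expr <- remove_batch_effect(expr, phenotypes$batch, kc)
  }

  removed_cov <- character(0)
  cov_report <- NULL
  if (!is.na(cov_threshold)) {
    cpm_lin <- .cpm_linear(counts, prior)
    cov_report <- cov_filter(cpm_lin, cov_threshold)
    removed_cov <- cov_report$removed
    expr <- expr[, setdiff(colnames(expr), removed_cov), drop = FALSE]
  }

  provenance <- list(
    n_genes_in = n_in,
    removed_low_count = lc$removed,
    n_removed_low_count = length(lc$removed),
    removed_samples_abof = removed_samples,
    removed_high_cov = removed_cov,
    n_removed_high_cov = length(removed_cov),
    n_genes_out = ncol(expr),
    rules = list(low_count = list(min_samples = min_samples,
                                  min_reads_range = min_reads_range),
                 abof = list(threshold = abof_threshold),
                 cov = list(threshold = cov_threshold))
  )
  list(expr = expr, phenotypes = phenotypes, provenance = provenance,
       abof = abof, tmm = tmm)
}
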