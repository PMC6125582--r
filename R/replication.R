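#' Restrict discovered modules to an external gene universe
#'
#' Intersects each module's gene set with the genes measured in an external
#' cohort and reports the per-module overlap; modules falling below the size
#' floor are flagged (they are kept in the output so the caller can decide).
#'
#' @param modules named integer label vector (0 = unassigned) or a named list
#'   of gene sets.
#' @param external_universe character vector of gene ids available in the
#'   external cohort.
#' @param floor minimum retained size below which a module is flagged.
#' @return list with `sets` (named list of restricted gene sets) and
#'   `overlap` (data.frame: module, n_original, n_retained, fraction,
#'   below_floor).
#' @export
restrict_modules <- function(modules, external_universe, floor = 10) {
  sets <- .as_gene_sets(modules)
  restricted <- lapply(sets, intersect, external_universe)
  n0 <- vapply(sets, length, integer(1))
  n1 <- vapply(restricted, length, integer(1))
  if (all(n1 == 0L))
    stop("no module gene overlaps the external universe")
  overlap <- data.frame(
    module = names(sets), n_original = n0, n_retained = n1,
    fraction = n1 / n0, below_floor = n1 < floor,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(sets = restricted, overlap = overlap)
}

#' Test modules against diagnosis in an independent cohort
#'
#' Computes ssGSEA scores of the restricted modules on the external
#' expression matrix (rank-based, self-contained: no reference to the
#' discovery cohort) and runs, per module, a logistic regression of diagnosis
#' on the module score plus covariates. Reports the Wald two-sided p-value
#' without multiplicity adjustment (the replication family is small by
#' construction).
#'
#' @param external_expr numeric matrix, samples x genes (post-filter logCPM
#'   of the external cohort).
#' @param modules restricted module gene sets (a named list, e.g.
#'   `restrict_modules(...)$sets`) or a label vector.
#' @param diagnosis binary vector per external sample.
#' @param covariates optional data.frame (e.g. sex, age, BMI).
#' @param alpha ssGSEA exponent.
#' @return data.frame per module: log-odds beta, se, z, p, n.
#' @export
replicate_modules <- function(external_expr, modules, diagnosis,
                              covariates = NULL, alpha = 0.25) {
  external_expr <- as.matrix(external_expr)
  y <- as.integer(as.factor(diagnosis)) - 1L
  if (length(unique(y)) != 2L) stop("both diagnosis classes must be present")
  scores <- score_matrix(external_expr, modules, alpha = alpha)
  cov_mat <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_mat <- stats::model.matrix(~., data = covariates)[, -1, drop = FALSE]
  }
  rows <- lapply(colnames(scores), function(m) {
    sc <- scores[, m]
    if (all(is.na(sc)))
      return(data.frame(module = m, beta = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_, n = NA_integer_))
    x <- cbind(score = sc, cov_mat)
    if (qr(cbind(1, x))$rank < ncol(x) + 1L)
      stop("singular design in replication model for module ", m)
    fit <- stats::glm(y ~ x, family = stats::binomial())
    cf <- summary(fit)$coefficients[2, ]   # score is the first design column
    data.frame(module = m, beta = cf[1], se = cf[2], z = cf[3], p = cf[4],
               n = length(y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
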