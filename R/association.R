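#' z-score a quantitative trait
#'
#' @param x numeric vector (e.g. MADRS scores).
#' @return `(x - mean(x)) / sd(x)` (sample standard deviation).
#' @export
scale_trait <- function(x) {
  if (length(x) == 0L || any(!is.finite(x))) stop("trait must be finite")
  s <- stats::sd(x)
  if (s == 0) stop("trait has zero variance")
  (x - mean(x)) / s
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_(k) = min_{j >= k} min(1, p_(j) * m / j)`
#' mapped back to input order.
#'
#' @param p numeric vector of p-values in [0,1].
#' @param m family size (defaults to `length(p)`).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Covariate-adjusted linear association of module scores with a trait
#'
#' Per module, fits ordinary least squares `trait ~ score + covariates` and
#' reports the score coefficient, its standard error, t statistic, two-sided
#' p-value, and the BH-adjusted p-value across the module family. Rows with
#' missing values in the trait or covariates are dropped listwise before
#' fitting.
#'
#' @param scores numeric matrix, samples x modules (see [score_matrix()]).
#' @param trait numeric vector per sample (typically [scale_trait()] output).
#' @param covariates optional data.frame of covariates per sample (factors
#'   enter as indicator contrasts).
#' @return data.frame of class `association_table`: one row per module with
#'   beta, se, t, p, p_adj, n, bic; the fitted covariate names are in the
#'   `covariates` attribute.
#' @export
fit_module_models <- function(scores, trait, covariates = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(trait))
    stop("scores and trait have different numbers of samples")
  keep <- is.finite(trait)
  cov_mat <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(trait))
      stop("covariates and trait have different numbers of samples")
    keep <- keep & stats::complete.cases(covariates)
  }
  scores <- scores[keep, , drop = FALSE]
  trait <- trait[keep]
  if (!is.null(covariates)) {
    covariates <- droplevels(covariates[keep, , drop = FALSE])
    cov_mat <- stats::model.matrix(~., data = covariates)[, -1, drop = FALSE]
  }
  n <- length(trait)
  p_cols <- 2L + if (is.null(cov_mat)) 0L else ncol(cov_mat)
  if (n <= p_cols) stop("fewer samples than model parameters")

  fit_one <- function(score) {
    x <- cbind(score = score, cov_mat)
    qr_x <- qr(cbind(1, x))
    if (qr_x$rank < ncol(x) + 1L) {
      piv <- qr_x$pivot[(qr_x$rank + 1L):(ncol(x) + 1L)]
      stop("singular design; collinear column(s): ",
           paste(c("(Intercept)", colnames(x))[piv], collapse = ", "))
    }
    fit <- stats::lm(trait ~ x)
    cf <- summary(fit)$coefficients[2, ]   # score is the first design column
    c(beta = cf[1], se = cf[2], t = cf[3], p = cf[4],
      bic = stats::BIC(fit))
  }
  res <- t(apply(scores, 2, fit_one))
  out <- data.frame(
    module = colnames(scores),
    beta = res[, 1], se = res[, 2], t = res[, 3], p = res[, 4],
    p_adj = bh_adjust(res[, 4]),
    n = n, bic = res[, 5],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "covariates") <- colnames(cov_mat)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Compare two fitted models by BIC
#'
#' `BIC = -2 logLik + k log(n)`. Returns the model with the smaller BIC;
#' exact ties keep the first model.
#'
#' @param model_a,model_b fitted model objects (e.g. [stats::lm()]) on the
#'   same response and sample size.
#' @return list with `choice` ("a" or "b"), `bic_a`, `bic_b`, `tie`.
#' @export
compare_bic <- function(model_a, model_b) {
  na <- stats::nobs(model_a)
  nb <- stats::nobs(model_b)
  if (na != nb) stop("models were fitted on different sample sizes")
  ba <- stats::BIC(model_a)
  bb <- stats::BIC(model_b)
  list(choice = if (bb < ba) "b" else "a", bic_a = ba, bic_b = bb,
       tie = isTRUE(all.equal(ba, bb)))
}

#' Sensitivity re-fit on a sample subset
#'
#' Re-runs [fit_module_models()] on a subset of samples (e.g. a single
#' self-reported-ancestry stratum).
#'
#' @param scores,trait,covariates as in [fit_module_models()].
#' @param mask logical or integer index selecting the samples to keep.
#' @return an `association_table` for the subset.
#' @export
subset_sensitivity <- function(scores, trait, covariates = NULL, mask) {
  scores <- as.matrix(scores)
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0L) stop("empty sample subset")
  fit_module_models(scores[idx, , drop = FALSE], trait[idx],
                    if (!is.null(covariates))
                      as.data.frame(covariates)[idx, , drop = FALSE])
}
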