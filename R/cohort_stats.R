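#' Pearson chi-square test on a contingency table
#'
#' `chi2 = sum (O - E)^2 / E` with expected counts from the margins; no
#' continuity correction. Rows or columns with zero margin are dropped with a
#' warning before computing; df = (r - 1)(c - 1) on the remaining table.
#'
#' @param tab non-negative integer matrix (r x c contingency table).
#' @return list with `statistic`, `df`, `p`.
#' @export
pearson_chi_square <- function(tab) {
  tab <- .check_table(tab)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Yates continuity-corrected chi-square test on a 2x2 table
#'
#' `chi2 = n (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped at 0 when
#' `|ad - bc| < n/2`.
#'
#' @param tab a 2x2 non-negative integer matrix.
#' @return list with `statistic`, `df` (always 1), `p`.
#' @export
yates_chi_square <- function(tab) {
  tab <- .check_table(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("Yates correction applies to 2x2 tables only")
  res <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(res$statistic), df = 1L, p = unname(res$p.value))
}

.check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("contingency counts must be non-negative")
  rz <- rowSums(tab) == 0
  cz <- colSums(tab) == 0
  if (any(rz) || any(cz)) {
    warning("dropping ", sum(rz), " zero-margin row(s) and ", sum(cz),
            " zero-margin column(s)")
    tab <- tab[!rz, !cz, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table needs at least 2 rows and 2 columns with positive margins")
  tab
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `statistic` (t), `df` (`n1 + n2 - 2`), `p` (two-sided).
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Table-1 style group comparison of a phenotype table
#'
#' For each requested variable, compares the two diagnosis groups: numeric
#' variables by pooled two-sample t-test, categorical variables by Pearson
#' chi-square; for 2x2 tables both the uncorrected and the Yates-corrected
#' statistics are reported. Missing values are dropped per variable
#' (available-data analysis).
#'
#' @param phenotypes data.frame with one row per sample.
#' @param group name of the 2-level grouping column (default "diagnosis").
#' @param variables columns to compare; defaults to all except `group` and
#'   `sample_id`.
#' @return data.frame: variable, type, statistic, df, p, plus
#'   `statistic_yates`/`p_yates` for 2x2 tables.
#' @export
table_one <- function(phenotypes, group = "diagnosis", variables = NULL) {
  g <- droplevels(as.factor(phenotypes[[group]]))
  if (nlevels(g) != 2L) stop("grouping column must have exactly 2 levels")
  if (is.null(variables))
    variables <- setdiff(names(phenotypes), c(group, "sample_id"))
  rows <- lapply(variables, function(v) {
    x <- phenotypes[[v]]
    ok <- !is.na(x)
    if (is.numeric(x)) {
      s <- vapply(levels(g), function(l)
        c(mean(x[ok & g == l]), stats::sd(x[ok & g == l]),
          sum(ok & g == l)), numeric(3))
      tt <- pooled_t_test(s[1, 1], s[2, 1], s[3, 1], s[1, 2], s[2, 2], s[3, 2])
      data.frame(variable = v, type = "numeric",
                 statistic = tt$statistic, df = tt$df, p = tt$p,
                 statistic_yates = NA_real_, p_yates = NA_real_)
    } else {
      tab <- table(droplevels(as.factor(x[ok])), g[ok])
      ct <- pearson_chi_square(tab)
      y <- if (all(dim(tab) == c(2L, 2L))) yates_chi_square(tab) else NULL
      data.frame(variable = v, type = "categorical",
                 statistic = ct$statistic, df = ct$df, p = ct$p,
                 statistic_yates = if (is.null(y)) NA_real_ else y$statistic,
                 p_yates = if (is.null(y)) NA_real_ else y$p)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
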