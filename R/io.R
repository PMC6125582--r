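#' Read / write gene x sample count matrices as TSV
#'
#' The TSV layout is one gene per row, first column `gene_id`, one column per
#' sample.
#'
#' @param counts integer matrix, genes x samples.
#' @param path file path.
#' @return `read_counts_tsv` returns the matrix with dimnames.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write an expression matrix (samples x genes) as TSV
#'
#' Stored transposed (genes in rows) to match the count-matrix layout; the
#' first column is `gene_id`.
#'
#' @param expr numeric matrix, samples x genes.
#' @param path file path.
#' @export
write_expr_tsv <- function(expr, path) {
  write_counts_tsv(t(expr), path)
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(path) {
  t(read_counts_tsv(path))
}

#' Read / write gene sets in GMT format
#'
#' One line per set: name, description, then gene ids, tab-separated.
#'
#' @param sets named list of character vectors, or a named module label
#'   vector (0 = unassigned).
#' @param path file path.
#' @param descriptions optional per-set description strings.
#' @return `read_gmt` returns a named list of gene-id vectors with a
#'   `descriptions` attribute.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  sets <- .as_gene_sets(sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Write a synthetic cohort to disk
#'
#' Counts as TSV, phenotypes as CSV, planted modules as GMT, plus a JSON
#' sidecar with trait-coupled module labels and planted outlier sample ids.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    truth_gmt = file.path(dir, "truth_modules.gmt"),
    truth_json = file.path(dir, "truth.json")
  )
  write_counts_tsv(cohort$counts, paths$counts)
  utils::write.csv(cohort$phenotypes, paths$phenotypes, row.names = FALSE)
  write_gmt(cohort$truth$module_labels, paths$truth_gmt)
  jsonlite::write_json(
    list(trait_modules = cohort$truth$trait_modules,
         outliers = cohort$truth$outliers),
    paths$truth_json, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(paths)
}
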