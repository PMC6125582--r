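#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis with their default
#' values: COV threshold 0.8, ABOF threshold 0.001, hard-threshold grid
#' around 0.2, target mean module size 200, ssGSEA exponent 0.25, minimum
#' module size 30, FDR threshold 0.05.
#'
#' @param simulation list of [sim_config()] arguments (used when no counts
#'   are supplied).
#' @param counts,phenotypes paths to a counts TSV and phenotype CSV (override
#'   simulation).
#' @param trait name of the quantitative trait column (default "madrs").
#' @param covariates covariate column names for the association models.
#' @param sensitivity_covariate extra covariate for the sensitivity model
#'   (default "smoking"; set NULL to skip).
#' @param min_samples,min_reads_range,abof_threshold,cov_threshold,prior
#'   preprocessing parameters, see [preprocess_counts()].
#' @param tau_grid hard-threshold grid; a single value pins the threshold.
#' @param target_mean_size,min_module_size,cut_height_quantile,split_gap
#'   module-detection parameters, see [tune_hard_threshold()].
#' @param alpha ssGSEA exponent.
#' @param fdr module discovery threshold on BH-adjusted p-values.
#' @param replication NULL, or a list with either `counts`/`phenotypes` paths
#'   of an external cohort or `overlap_fraction` (simulate one).
#' @param run_centrality compute the centrality/importance stage (the most
#'   expensive one).
#' @return a config list.
#' @export
pipeline_config <- function(simulation = list(),
                            counts = NULL, phenotypes = NULL,
                            trait = "madrs",
                            covariates = c("sex", "age", "bmi", "batch"),
                            sensitivity_covariate = "smoking",
                            min_samples = 15, min_reads_range = c(2, 7),
                            abof_threshold = 0.001, cov_threshold = 0.8,
                            prior = 0.5,
                            tau_grid = 0.2, target_mean_size = 200,
                            min_module_size = 30,
                            cut_height_quantile = 0.99, split_gap = 0.3,
                            alpha = 0.25, fdr = 0.05,
                            replication = NULL, run_centrality = TRUE) {
  as.list(environment())
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full module-discovery pipeline
#'
#' Executes preprocessing, network/module detection, ssGSEA scoring,
#' covariate-adjusted trait association with FDR control, the
#' centrality/importance analysis, and (optionally) replication on an
#' independent cohort. Writes every intermediate plus a JSON run manifest
#' when `out_dir` is given.
#'
#' @param config a [pipeline_config()] list, or a path to a YAML/JSON file
#'   with the same fields.
#' @param out_dir optional output directory for artifacts.
#' @return list with elements `cohort`, `preprocess`, `network`, `scores`,
#'   `association`, `sensitivity`, `centrality`, `replication`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- .read_config(config)
  defaults <- pipeline_config()
  config <- utils::modifyList(defaults, config)

  ## ---- input ---------------------------------------------------------------
  cohort <- .stage("input", {
    if (!is.null(config$counts)) {
      if (is.null(config$phenotypes))
        stop("counts supplied without a phenotype table")
      list(counts = read_counts_tsv(config$counts),
           phenotypes = utils::read.csv(config$phenotypes,
                                        stringsAsFactors = FALSE),
           truth = NULL)
    } else {
      generate_cohort(do.call(sim_config, config$simulation))
    }
  })

  ## ---- preprocess ----------------------------------------------------------
  pre <- .stage("preprocess", preprocess_counts(
    cohort$counts, cohort$phenotypes,
    min_samples = config$min_samples,
    min_reads_range = config$min_reads_range,
    abof_threshold = config$abof_threshold,
    cov_threshold = config$cov_threshold,
    prior = config$prior
  ))

  ## ---- network + modules ---------------------------------------------------
  net <- .stage("network_modules", tune_hard_threshold(
    pre$expr, grid = config$tau_grid,
    target_mean_size = config$target_mean_size,
    min_module_size = config$min_module_size,
    cut_height_quantile = config$cut_height_quantile,
    split_gap = config$split_gap
  ))

  ## ---- module scores -------------------------------------------------------
  scores <- .stage("module_scores",
                   score_matrix(pre$expr, net$modules, alpha = config$alpha))

  ## ---- association ---------------------------------------------------------
  ph <- pre$phenotypes
  assoc <- sens <- NULL
  if (!is.null(ph) && config$trait %in% names(ph)) {
    assoc <- .stage("association", {
      trait <- scale_trait(ph[[config$trait]])
      covs <- ph[, intersect(config$covariates, names(ph)), drop = FALSE]
      fit_module_models(scores, trait, if (ncol(covs)) covs else NULL)
    })
    sc <- config$sensitivity_covariate
    if (!is.null(sc) && sc %in% names(ph)) {
      sens <- .stage("sensitivity", {
        trait <- scale_trait(ph[[config$trait]])
        covs2 <- ph[, intersect(c(config$covariates, sc), names(ph)),
                    drop = FALSE]
        fit_module_models(scores, trait, covs2)
      })
    }
  }

  ## ---- centrality ----------------------------------------------------------
  centr <- NULL
  if (isTRUE(config$run_centrality) && !is.null(ph) &&
      "diagnosis" %in% names(ph)) {
    centr <- .stage("centrality", {
      ec <- suppressWarnings(eigenvector_centrality(net$adjacency))
      imp <- univariate_importance(pre$expr, ph$diagnosis)
      list(
        centrality = ec, importance = imp,
        module_r2 = module_centrality_correlation(imp, ec, net$modules),
        enrichment = top_gene_enrichment(
          net$modules, stats::setNames(imp$p, imp$gene),
          top_k = min(100, ncol(pre$expr)))
      )
    })
  }

  ## ---- replication ---------------------------------------------------------
  repl <- NULL
  if (!is.null(config$replication)) {
    repl <- .stage("replication", {
      rc <- config$replication
      if (!is.null(rc$counts)) {
        ext_counts <- read_counts_tsv(rc$counts)
        ext_ph <- utils::read.csv(rc$phenotypes, stringsAsFactors = FALSE)
      } else {
        # couple the simulated external cohort's diagnosis to the modules
        # found trait-associated in discovery (the replication hypothesis)
        sig <- if (!is.null(assoc))
          as.integer(sub("^M", "", assoc$module[assoc$p_adj < config$fdr]))
        else integer(0)
        ext <- generate_replication_cohort(
          do.call(sim_config, config$simulation), net$modules,
          overlap_fraction = rc$overlap_fraction %||% 0.8,
          trait_modules = if (length(sig)) sig else NULL)
        ext_counts <- ext$counts
        ext_ph <- ext$phenotypes
      }
      ext_pre <- preprocess_counts(ext_counts, ext_ph,
                                   min_samples = config$min_samples,
                                   abof_threshold = NA,
                                   cov_threshold = config$cov_threshold,
                                   prior = config$prior)
      restr <- restrict_modules(net$modules, colnames(ext_pre$expr))
      covs <- ext_pre$phenotypes[, intersect(c("sex", "age", "bmi"),
                                             names(ext_pre$phenotypes)),
                                 drop = FALSE]
      res <- replicate_modules(ext_pre$expr, restr$sets,
                               ext_pre$phenotypes$diagnosis,
                               if (ncol(covs)) covs else NULL,
                               alpha = config$alpha)
      list(overlap = restr$overlap, association = res)
    })
  }

  manifest <- list(
    parameters = config[setdiff(names(config), "replication")],
    gene_chain = list(
      n_genes_in = pre$provenance$n_genes_in,
      removed_low_count = pre$provenance$n_removed_low_count,
      removed_high_cov = pre$provenance$n_removed_high_cov,
      n_genes_out = pre$provenance$n_genes_out
    ),
    n_samples = nrow(pre$expr),
    removed_samples = pre$provenance$removed_samples_abof,
    tau = net$tau,
    n_modules = length(attr(net$modules, "module_sizes")),
    module_sizes = as.integer(attr(net$modules, "module_sizes")),
    significant_modules = if (!is.null(assoc))
      assoc$module[assoc$p_adj < config$fdr] else character(0),
    versions = list(coexmod = as.character(utils::packageVersion("coexmod")),
                    R = R.version.string)
  )

  result <- list(cohort = cohort, preprocess = pre, network = net,
                 scores = scores, association = assoc, sensitivity = sens,
                 centrality = centr, replication = repl, manifest = manifest)
  if (!is.null(out_dir)) .write_artifacts(result, out_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_config <- function(path) {
  if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_expr_tsv(result$preprocess$expr, p("expression_filtered.tsv"))
  utils::write.table(result$network$report, p("tau_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(result$network$modules, p("modules.gmt"))
  utils::write.table(
    data.frame(gene_id = names(result$network$modules),
               module = as.integer(result$network$modules)),
    p("gene_modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_expr_tsv(t(result$scores), p("module_scores.tsv"))
  if (!is.null(result$association))
    utils::write.table(result$association, p("association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$centrality)) {
    utils::write.table(
      data.frame(gene = result$centrality$importance$gene,
                 centrality =
                   result$centrality$centrality[
                     result$centrality$importance$gene],
                 result$centrality$importance[, -1]),
      p("centrality_genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      merge(result$centrality$module_r2, result$centrality$enrichment,
            by = c("module", "size")),
      p("centrality_modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(result$replication)) {
    utils::write.table(
      merge(result$replication$overlap, result$replication$association,
            by = "module", all.x = TRUE),
      p("replication.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
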