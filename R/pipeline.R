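#' Assemble a pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: either a [sim_config()] (the
#' data are generated) or file paths to a genotype panel, phenotype CSV and
#' summary-statistics TSV; the QC thresholds; the selection and model grids;
#' and the CV plan parameters.
#'
#' @param outdir Output directory (created if absent).
#' @param simulate A [sim_config()], or NULL when file inputs are given.
#' @param genotypes,phenotypes,sumstats Input paths (dosage TSV or PLINK
#'   prefix; CSV; TSV). Ignored when `simulate` is set.
#' @param qc A [qc_thresholds()].
#' @param factors Fixed-effect factor columns to correct for.
#' @param selections List of [selection_spec()] (and/or NULL for the
#'   no-preselection baseline).
#' @param models List of [model_spec()].
#' @param k_folds,repeats CV plan parameters.
#' @param weight_fn Kernel weight function.
#' @param seed Integer seed for the CV fold assignments.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, simulate = NULL, genotypes = NULL,
                       phenotypes = NULL, sumstats = NULL,
                       qc = qc_thresholds(),
                       factors = c("year", "season", "sex", "farm"),
                       selections = list(NULL),
                       models = list(model_spec("GBLUP")),
                       k_folds = 10, repeats = 5,
                       weight_fn = "squared", seed = 1L) {
  if (is.null(simulate) &&
      (is.null(genotypes) || is.null(phenotypes))) {
    stop2("provide either `simulate` or genotype + phenotype inputs")
  }
  if (!length(models)) stop2("empty model grid")
  if (!length(selections)) stop2("empty selection grid")
  structure(list(outdir = outdir, simulate = simulate, genotypes = genotypes,
                 phenotypes = phenotypes, sumstats = sumstats, qc = qc,
                 factors = factors, selections = selections, models = models,
                 k_folds = k_folds, repeats = repeats,
                 weight_fn = weight_fn, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full prediction pipeline
#'
#' QC -> phenotype correction -> preselection grid -> kernels -> repeated CV,
#' writing `qc_report.tsv`, `cv_results.tsv`, `cv_summary.tsv`,
#' `model_comparison.tsv` and a `manifest.json` (configuration, seed,
#' package version and a configuration hash) into `outdir`. Reruns with the
#' same configuration and seed are bit-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`genotypes`,
#'   `qc_report`, `corrected`, `cv`, `summary`, `comparison`, `outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    g <- simulate_genotypes(config$simulate)
    tr <- simulate_trait(g, config$simulate)
    pheno <- tr$pheno
    stats <- if (config$simulate$n_cohorts > 0) {
      simulate_meta_gwas(config$simulate, tr$truth)
    }
  } else {
    g <- if (file.exists(paste0(config$genotypes, ".bed"))) {
      read_plink(config$genotypes)
    } else {
      read_dosage_tsv(config$genotypes)
    }
    pheno <- read_phenotypes_csv(config$phenotypes, factors = config$factors)
    stats <- if (!is.null(config$sumstats)) {
      read_summary_stats_tsv(config$sumstats)
    }
  }

  qc <- run_qc(g, config$qc)
  corrected <- correct_phenotypes(pheno, config$factors)
  plan <- cv_plan(n_individuals(qc$genotypes), config$k_folds,
                  config$repeats, config$seed)
  cvres <- run_cv(qc$genotypes, corrected, config$models, plan,
                  selections = config$selections, sumstats = stats,
                  weight_fn = config$weight_fn)
  summ <- summarize_cv(cvres)
  comp <- compare_models(cvres)

  wt <- function(x, f) {
    utils::write.table(x, file.path(config$outdir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(qc$report, "qc_report.tsv")
  wt(cvres, "cv_results.tsv")
  wt(summ, "cv_summary.tsv")
  if (!is.null(comp)) wt(comp, "model_comparison.tsv")

  manifest <- list(
    package = "preselblup",
    version = as.character(utils::packageVersion("preselblup")),
    seed = config$seed,
    config = serialize_config(config),
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(genotypes = qc$genotypes, qc_report = qc$report,
                 corrected = corrected, cv = cvres, summary = summ,
                 comparison = comp, outdir = config$outdir))
}

# flatten the config into plain JSON-serializable values
serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), strip)
    } else if (is.function(x)) {
      NULL
    } else {
      unclass(x)
    }
  }
  strip(config)
}

#' Hash of a run configuration
#'
#' FNV-1a over the JSON serialization of the configuration; stamped into the
#' manifest so outputs from different configurations cannot be mixed
#' silently.
#'
#' @param config A `run_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(serialize_config(config), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
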