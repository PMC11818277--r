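# End-to-end pipeline: catalog -> QV -> burden -> association -> phenotype
# -> regression, driven by a single YAML config, with a reproducibility
# manifest.

required_config_keys <- c("inputs", "qv", "association")

validate_pipeline_config <- function(config) {
  missing_keys <- setdiff(required_config_keys, names(config))
  if (length(missing_keys) > 0L) {
    stop("pipeline config is missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  inputs <- config$inputs
  for (key in c("variants", "gene_sets", "phenotype")) {
    if (is.null(inputs[[key]])) {
      stop("pipeline config inputs is missing key: ", key, call. = FALSE)
    }
    if (!file.exists(inputs[[key]])) {
      stop("pipeline input file not found: ", inputs[[key]], call. = FALSE)
    }
  }
  if (is.null(config$association$group)) {
    stop("pipeline config association is missing key: group", call. = FALSE)
  }
  invisible(config)
}

#' Run the full QV burden pipeline
#'
#' Executes, in dependency order: variant ingestion and spectrum summary,
#' qualifying-variant selection, gene-set burden profiling, gene-set CMH
#' association, RBC endpoint extraction with group comparison (when a
#' panel is supplied), and the regression grid (endpoints x gene sets)
#' with FDR screening. All stage outputs are written as TSV/JSON to
#' `out_dir` together with a reproducibility manifest (config and input
#' checksums, seed, versions, per-stage row counts). The pipeline itself
#' is deterministic; re-running on identical inputs reproduces identical
#' outputs.
#'
#' @param config_path YAML config path. Keys: `seed`; `inputs` (`variants`,
#'   `gene_sets`, `phenotype`, optional `panel`); `qv` (`af_max`,
#'   `include_missing_af`, `target_maf`, optional `cap`); `association`
#'   (`group` column name, `mode`, `stratify_by`, `fdr`); optional
#'   `regression` (`timepoints`, `fdr`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config_path, out_dir) {
  config <- yaml::read_yaml(config_path)
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  vt <- read_variant_table(config$inputs$variants)
  counts$variants <- nrow(vt$catalog)
  spectrum <- summarize_spectrum(vt$catalog, vt$genotypes)

  qv_cfg <- qv_config(
    af_max = config$qv$af_max %||% 0.001,
    include_missing_af = config$qv$include_missing_af %||% TRUE,
    max_cohort_alt_alleles = config$qv$cap,
    target_maf = config$qv$target_maf %||% 0.03)
  qvset <- qualify_variants(vt$catalog, vt$genotypes, qv_cfg)
  counts$qualifying_variants <- sum(qvset$qualified)

  collection <- read_gmt(config$inputs$gene_sets)
  counts$gene_sets <- length(collection)
  burden <- burden_profile(qvset, vt$genotypes, vt$catalog, collection)

  phenotype <- utils::read.delim(config$inputs$phenotype,
                                 stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(phenotype)) {
    stop("phenotype table lacks sample_id column", call. = FALSE)
  }
  group_col <- config$association$group
  if (!group_col %in% names(phenotype)) {
    stop("phenotype table lacks group column: ", group_col, call. = FALSE)
  }
  groups <- stats::setNames(phenotype[[group_col]], phenotype$sample_id)
  groups <- groups[rownames(vt$genotypes)]
  assoc <- geneset_burden_test(
    qvset, vt$genotypes, vt$catalog, collection, groups,
    mode = config$association$mode %||% "exact",
    stratify_by = config$association$stratify_by %||% "gene",
    fdr_threshold = config$association$fdr %||% 0.05)
  counts$associations <- nrow(assoc)

  endpoints <- NULL; comparison <- NULL; screen <- NULL
  if (!is.null(config$inputs$panel)) {
    panel <- utils::read.delim(config$inputs$panel, stringsAsFactors = FALSE)
    endpoints <- extract_endpoints(panel)
    counts$endpoints <- nrow(endpoints)
    comparison <- group_compare(endpoints, groups)
    screen <- pipeline_regression(endpoints, phenotype, burden, config)
  }

  files <- write_pipeline_outputs(out_dir, spectrum, qvset, burden, assoc,
                                  endpoints, comparison, screen)
  manifest <- build_manifest(config_path, config, counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(spectrum = spectrum, qvset = qvset, burden = burden,
                 association = assoc, endpoints = endpoints,
                 comparison = comparison, regression = screen,
                 manifest = manifest, files = files))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# regression grid: every (parameter, timepoint) endpoint x every gene set,
# with sex/status dummies and age + per-set QV count as covariates
pipeline_regression <- function(endpoints, phenotype, burden, config) {
  timepoints <- config$regression$timepoints %||% c("first", "final", "minmax")
  fdr <- config$regression$fdr %||% 0.1
  need <- c("sex", "age", "status")
  if (!all(need %in% names(phenotype))) return(NULL)
  pheno <- phenotype
  if (is.character(pheno$sex)) {
    pheno$sex <- ifelse(tolower(pheno$sex) == "male", 1L, 2L)
  }
  fits <- list()
  for (set_name in unique(burden$set_name)) {
    qv <- burden[burden$set_name == set_name, c("sample_id", "qv_count")]
    for (param in unique(endpoints$parameter)) {
      ep <- endpoints[endpoints$parameter == param, , drop = FALSE]
      for (tp in timepoints) {
        df <- data.frame(sample_id = ep$sample_id, y = ep[[tp]],
                         stringsAsFactors = FALSE)
        df <- merge(df, pheno[c("sample_id", "sex", "age", "status")],
                    by = "sample_id")
        df <- merge(df, qv, by = "sample_id")
        df <- stats::na.omit(df)
        if (nrow(df) < 10L || stats::sd(df$y) == 0 ||
            stats::sd(df$qv_count) == 0) next
        fit <- tryCatch(
          fit_mlr(df, "y", covariates = c("age", "qv_count"),
                  dummy_covariates = c("sex", "status"),
                  family_id = "pipeline",
                  label = paste(param, tp, set_name, sep = ".")),
          error = function(e) NULL)
        if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
      }
    }
  }
  if (length(fits) == 0L) return(NULL)
  model_screen(fits, r2_fdr = fdr, beta_fdr = fdr)
}

write_pipeline_outputs <- function(out_dir, spectrum, qvset, burden, assoc,
                                   endpoints, comparison, screen) {
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- list(
    spectrum = file.path(out_dir, "spectrum.json"),
    qv = tsv(as.data.frame(qvset), "qv.tsv"),
    burden = tsv(burden, "burden.tsv"),
    association = tsv(assoc, "association.tsv"))
  jsonlite::write_json(
    list(n_variants = spectrum$n_variants, n_sites = spectrum$n_sites,
         impact_counts = as.list(spectrum$impact_counts),
         impact_pct = as.list(spectrum$impact_pct),
         af_bin_counts = as.list(spectrum$af_bin_counts)),
    files$spectrum, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(endpoints)) files$endpoints <- tsv(endpoints, "endpoints.tsv")
  if (!is.null(comparison)) {
    files$comparison <- tsv(comparison, "group_compare.tsv")
  }
  if (!is.null(screen)) {
    files$regression_models <- tsv(screen$models, "regression_models.tsv")
    files$regression_coefficients <-
      tsv(screen$coefficients, "regression_coefficients.tsv")
  }
  files
}

build_manifest <- function(config_path, config, counts) {
  input_paths <- unlist(config$inputs)
  list(
    config_md5 = unname(tools::md5sum(config_path)),
    input_md5 = as.list(tools::md5sum(input_paths)),
    seed = config$seed %||% NA,
    package_version = as.character(utils::packageVersion("qvburden")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    row_counts = counts)
}

#' Write a human-readable run report
#'
#' Summarises a pipeline output directory: stage row counts from the
#' manifest, top associations and diagnostics flags. Every number is read
#' back from the stage output files, and regeneration is deterministic.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param path report destination (default `report.txt` inside `out_dir`).
#' @return invisibly, the report lines.
#' @export
write_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  lines <- c("qvburden pipeline report", "=======================",
             sprintf("seed: %s", manifest$seed),
             sprintf("config md5: %s", manifest$config_md5), "",
             "stage row counts:")
  for (nm in names(manifest$row_counts)) {
    lines <- c(lines, sprintf("  %s: %s", nm, manifest$row_counts[[nm]]))
  }
  assoc_path <- file.path(out_dir, "association.tsv")
  if (file.exists(assoc_path)) {
    assoc <- utils::read.delim(assoc_path, stringsAsFactors = FALSE)
    testable <- assoc[assoc$testable, , drop = FALSE]
    lines <- c(lines, "", "gene-set associations:")
    if (nrow(testable) == 0L) {
      lines <- c(lines, "  no testable sets")
    } else {
      testable <- testable[order(testable$p), , drop = FALSE]
      for (i in seq_len(nrow(testable))) {
        lines <- c(lines, sprintf(
          "  %s: OR = %.3g (%.3g-%.3g), p = %.3g, q = %.3g%s",
          testable$set[i], testable$or[i], testable$ci_low[i],
          testable$ci_high[i], testable$p[i], testable$q[i],
          if (isTRUE(testable$significant[i])) " *" else ""))
      }
    }
  }
  writeLines(lines, path)
  invisible(lines)
}
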