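# Synthetic cohort generator with known ground truth: exome-like variant
# catalogs, gene sets with planted carrier odds ratios, binary phenotypes
# and longitudinal RBC panels with planted genetic effects.

# population means / SDs used for simulated RBC parameters (adult ranges)
.rbc_param_mu <- c(RBC = 4.5, HGB = 120, HCT = 0.38, MCV = 90, MCH = 30,
                   MCHC = 330, RDW = 13.5)
.rbc_param_sd <- c(RBC = 0.5, HGB = 15, HCT = 0.04, MCV = 5, MCH = 2,
                   MCHC = 10, RDW = 1.2)

#' Simulation configuration
#'
#' Defaults emulate a small critically-ill exome cohort: 50 diploid
#' samples, an exome-like consequence mixture with ~2% high-impact
#' variants, a rare-skewed AF spectrum with a configurable fraction of
#' variants absent from the population AF database (simulated as
#' ultra-rare, true AF <= 1/(4 n)), one causal gene set with a planted
#' set-carrier odds ratio on a binary phenotype, and longitudinal RBC
#' panels with a linear effect of the causal-set QV count on chosen
#' parameters.
#'
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @param n_samples diploid cohort size.
#' @param n_genes number of simulated genes.
#' @param mean_variants_per_gene Poisson mean (plus 1) of variants per gene.
#' @param impact_mix named proportions over HI / MISSENSE / SYNONYMOUS /
#'   OTHER; must sum to 1.
#' @param af_masses point masses of the known-AF spectrum.
#' @param af_weights sampling weights of `af_masses`.
#' @param missing_af_frac fraction of variants with no database AF.
#' @param indel_frac fraction of variants simulated as indels.
#' @param n_set_genes genes per planted set.
#' @param planted_or set-carrier odds ratio of the causal set on the
#'   binary phenotype (1 = null).
#' @param baseline_case_rate phenotype rate among non-carriers.
#' @param genetic_betas named standardized effects of the causal-set QV
#'   count on RBC parameters (default: -0.4 on MCHC only).
#' @param n_timepoints measurements per sample (>= 2).
#' @param series_noise_sd within-person measurement noise, in SD units of
#'   each parameter.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, n_samples = 50L, n_genes = 100L,
                       mean_variants_per_gene = 3,
                       impact_mix = c(HI = 0.02, MISSENSE = 0.365,
                                      SYNONYMOUS = 0.305, OTHER = 0.31),
                       af_masses = c(5e-4, 5e-3, 0.05),
                       af_weights = c(0.5, 0.3, 0.2),
                       missing_af_frac = 0.3,
                       indel_frac = 0.1,
                       n_set_genes = 15L,
                       planted_or = 2.5,
                       baseline_case_rate = 0.3,
                       genetic_betas = c(MCHC = -0.4),
                       n_timepoints = 3L,
                       series_noise_sd = 0.15) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (abs(sum(impact_mix) - 1) > 1e-8) {
    stop("impact_mix must sum to 1", call. = FALSE)
  }
  if (planted_or <= 0) stop("planted_or must be positive", call. = FALSE)
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

.hi_pool <- c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
              "splice_donor_variant", "stop_lost", "start_lost")

#' Simulate a full synthetic cohort
#'
#' Draws genotypes per variant as Binomial(2, true AF), plants a causal
#' gene set whose carrier status (>= 1 alternate allele at a rare HI site
#' of a set gene) raises the odds of the binary phenotype by the
#' configured odds ratio, and generates longitudinal RBC panels with a
#' linear effect of the causal-set QV count. A matching null gene set is
#' included. Identical seeds give identical outputs; when `out_dir` is
#' supplied, VCF, GMT, phenotype/panel TSVs and a ground-truth JSON are
#' written there.
#'
#' @param config [sim_config()].
#' @param out_dir optional output directory.
#' @return list of class `sim_cohort`: `catalog`, `genotypes`,
#'   `collection`, `phenotype` (per-sample data.frame: `sample_id`, `sex`,
#'   `age`, `status`, `group`, `qv_count`), `panel` (long RBC series),
#'   `truth` (ground-truth list), `files` (paths when written).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  n_var_per_gene <- stats::rpois(config$n_genes, config$mean_variants_per_gene) + 1L
  gene_of <- rep(genes, n_var_per_gene)
  m <- length(gene_of)

  impact <- sample(names(config$impact_mix), m, replace = TRUE,
                   prob = config$impact_mix)
  consequence <- ifelse(
    impact == "HI", sample(.hi_pool, m, replace = TRUE),
    ifelse(impact == "MISSENSE", "missense_variant",
           ifelse(impact == "SYNONYMOUS", "synonymous_variant",
                  "intron_variant")))
  af_missing <- stats::runif(m) < config$missing_af_frac
  true_af <- ifelse(
    af_missing,
    stats::runif(m, 0, 1 / (4 * n)),
    sample(config$af_masses, m, replace = TRUE, prob = config$af_weights))
  pop_af <- ifelse(af_missing, NA_real_, true_af)

  is_indel <- stats::runif(m) < config$indel_frac
  ins <- is_indel & stats::runif(m) < 0.5
  ref <- ifelse(is_indel & !ins, "AT", "A")
  alt <- ifelse(ins, "AT", ifelse(is_indel, "A", "G"))
  catalog <- variant_catalog(data.frame(
    chrom = "1", pos = seq_len(m) * 100L, ref = ref, alt = alt,
    gene = gene_of, consequence = consequence, pop_af = pop_af,
    stringsAsFactors = FALSE))

  genotypes <- matrix(stats::rbinom(n * m, 2L, rep(true_af, each = n)),
                      nrow = n, ncol = m, dimnames = list(samples, catalog$variant_id))

  # planted sets: causal genes first, a disjoint null set after
  causal_genes <- genes[seq_len(config$n_set_genes)]
  null_genes <- genes[config$n_set_genes + seq_len(config$n_set_genes)]
  collection <- gene_set_collection(
    list(SET_CAUSAL = causal_genes, SET_NULL = null_genes),
    descriptions = c("planted causal set", "planted null set"))

  # set carrier status from rare HI sites in set genes (generator truth)
  rare_hi <- impact == "HI" & (af_missing | true_af < 0.001)
  carrier_of <- function(set_genes) {
    idx <- which(rare_hi & gene_of %in% set_genes)
    if (length(idx) == 0L) rep(FALSE, n) else
      rowSums(genotypes[, idx, drop = FALSE] >= 1L) > 0L
  }
  qv_count_of <- function(set_genes) {
    idx <- which(rare_hi & gene_of %in% set_genes)
    if (length(idx) == 0L) rep(0L, n) else
      as.integer(rowSums(genotypes[, idx, drop = FALSE] >= 1L))
  }
  carrier <- carrier_of(causal_genes)
  qv_count <- qv_count_of(causal_genes)
  if (!any(carrier)) {
    warning("no carriers of the causal set realized; achieved carrier rate 0")
  }

  eta <- stats::qlogis(config$baseline_case_rate) + log(config$planted_or) * carrier
  case <- stats::rbinom(n, 1L, stats::plogis(eta))
  phenotype <- data.frame(
    sample_id = samples,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(stats::rnorm(n, 55, 12)),
    status = stats::rbinom(n, 1L, 0.5),
    group = factor(ifelse(case == 1L, "case", "control"),
                   levels = c("case", "control")),
    qv_count = qv_count, stringsAsFactors = FALSE)

  panel <- simulate_rbc_series(config, qv_count, samples)

  truth <- list(
    seed = config$seed, n_samples = n,
    variant_id = catalog$variant_id, true_af = true_af,
    impact = impact, af_missing = af_missing,
    causal_set = "SET_CAUSAL", causal_genes = causal_genes,
    planted_or = config$planted_or,
    genetic_betas = as.list(config$genetic_betas),
    carrier = as.list(stats::setNames(carrier, samples)),
    case = as.list(stats::setNames(case, samples)))

  out <- list(catalog = catalog, genotypes = genotypes,
              collection = collection, phenotype = phenotype,
              panel = panel, truth = truth, files = NULL)
  class(out) <- "sim_cohort"
  if (!is.null(out_dir)) out$files <- write_sim_cohort(out, out_dir)
  out
}

#' Simulate longitudinal RBC panels
#'
#' Per sample and parameter, a person-level value is drawn as
#' `mu + sd * (beta * z(qv_count) + e)` with `e ~ N(0, sqrt(1 - beta^2))`,
#' then observed at each timepoint with independent measurement noise, so
#' the planted `beta` is the standardized effect of the QV count on the
#' person-level parameter.
#'
#' @param config [sim_config()].
#' @param qv_count per-sample QV burden in the causal set.
#' @param samples sample ids.
#' @return long data.frame: `sample_id`, `timestamp`, seven RBC columns.
#' @export
simulate_rbc_series <- function(config, qv_count, samples = NULL) {
  n <- length(qv_count)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(n))
  z <- if (stats::sd(qv_count) > 0) {
    (qv_count - mean(qv_count)) / stats::sd(qv_count)
  } else rep(0, n)
  tt <- config$n_timepoints
  out <- data.frame(sample_id = rep(samples, each = tt),
                    timestamp = rep(seq_len(tt), n))
  for (param in rbc_parameters) {
    beta <- if (param %in% names(config$genetic_betas)) {
      config$genetic_betas[[param]]
    } else 0
    e <- stats::rnorm(n, 0, sqrt(max(0, 1 - beta^2)))
    base <- .rbc_param_mu[[param]] + .rbc_param_sd[[param]] * (beta * z + e)
    noise <- stats::rnorm(n * tt, 0, config$series_noise_sd * .rbc_param_sd[[param]])
    out[[param]] <- rep(base, each = tt) + noise
  }
  out
}

#' Simulate a case-control stratified carrier design
#'
#' Retrospective sampling for stratified 2x2 association: for each of
#' `n_strata` strata (genes), control carrier probabilities are drawn
#' uniformly in `p0_range` and case carrier odds are `or` times the
#' control odds, so every stratum shares the common odds ratio `or`.
#'
#' @param n_cases,n_controls group sizes.
#' @param n_strata number of strata (genes).
#' @param or common carrier odds ratio (truth).
#' @param p0_range range of control carrier probabilities.
#' @return `qv_strata` array (see [build_strata()]).
#' @export
simulate_stratified_cohort <- function(n_cases, n_controls, n_strata = 4L,
                                       or = 2.5, p0_range = c(0.05, 0.2)) {
  tabs <- vector("list", n_strata)
  for (j in seq_len(n_strata)) {
    p0 <- stats::runif(1, p0_range[1], p0_range[2])
    p1 <- stats::plogis(stats::qlogis(p0) + log(or))
    a <- stats::rbinom(1, n_cases, p1)
    c <- stats::rbinom(1, n_controls, p0)
    tabs[[j]] <- c(a, n_cases - a, c, n_controls - c)
  }
  strata_from_counts(tabs, labels = sprintf("G%03d", seq_len(n_strata)))
}

#' Simulate a regression cohort with one planted genetic effect
#'
#' Generates per-sample covariates (z-scored age, sex dummy 1/2, clinical
#' status dummy 0/1, Poisson QV count) and all seven RBC endpoints, with
#' the planted standardized genetic effect on `target` only. As in the
#' longitudinal generator, the clinical covariates carry no effect on the
#' simulated parameters unless `nuisance` is set; effects and residual
#' variance are scaled so each endpoint has unit population variance
#' before parameter scaling, making `beta_genetic` the standardized
#' coefficient the fit should recover.
#'
#' @param n sample size.
#' @param beta_genetic standardized effect of the QV count on `target`.
#' @param target parameter receiving the genetic effect.
#' @param lambda Poisson mean of the QV count.
#' @param nuisance named standardized effects of `age`, `sex`, `status`
#'   applied to every endpoint (default all zero).
#' @return data.frame: `sex`, `age`, `status`, `qv_count`, plus one column
#'   per RBC parameter.
#' @export
simulate_regression_cohort <- function(n, beta_genetic = -0.4,
                                       target = "MCHC", lambda = 0.8,
                                       nuisance = c(age = 0, sex = 0,
                                                    status = 0)) {
  age <- stats::rnorm(n)
  sex <- sample(1:2, n, replace = TRUE)
  status <- stats::rbinom(n, 1L, 0.5)
  qv_count <- stats::rpois(n, lambda)
  z_sex <- (sex - 1.5) / 0.5
  z_status <- (status - 0.5) / 0.5
  z_qv <- (qv_count - lambda) / sqrt(lambda)
  b_age <- nuisance[["age"]]; b_sex <- nuisance[["sex"]]
  b_status <- nuisance[["status"]]
  out <- data.frame(sex = sex, age = age, status = status,
                    qv_count = qv_count)
  for (param in rbc_parameters) {
    bg <- if (param == target) beta_genetic else 0
    sigma2 <- 1 - b_age^2 - b_sex^2 - b_status^2 - bg^2
    if (sigma2 <= 0) stop("planted effects exceed unit variance", call. = FALSE)
    y <- b_age * age + b_sex * z_sex + b_status * z_status + bg * z_qv +
      stats::rnorm(n, 0, sqrt(sigma2))
    out[[param]] <- .rbc_param_mu[[param]] + .rbc_param_sd[[param]] * y
  }
  out
}

# ---- file output -----------------------------------------------------------

write_sim_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    vcf = file.path(out_dir, "cohort.vcf"),
    gmt = file.path(out_dir, "sets.gmt"),
    phenotype = file.path(out_dir, "phenotype.tsv"),
    panel = file.path(out_dir, "panel.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_cohort_vcf(cohort$catalog, cohort$genotypes, files$vcf)
  write_gmt(cohort$collection, files$gmt)
  utils::write.table(cohort$phenotype, files$phenotype, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$panel, files$panel, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, files$truth, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files
}

#' Write a catalog + genotypes as a VCF v4.2 file
#'
#' Annotations go to INFO keys `GENE`, `CSQ` and `AF` (omitted when the
#' population AF is missing); genotypes are unphased biallelic GT calls.
#'
#' @param catalog variant catalog (biallelic rows).
#' @param genotypes dosage matrix (samples x variants).
#' @param path output path.
#' @export
write_cohort_vcf <- function(catalog, genotypes, path) {
  samples <- rownames(genotypes)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence term\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(catalog)), function(i) {
    info <- paste0("GENE=", catalog$gene[i], ";CSQ=", catalog$consequence[i])
    if (!is.na(catalog$pop_af[i])) {
      info <- paste0(info, ";AF=", format(catalog$pop_af[i], scientific = FALSE))
    }
    gts <- ifelse(is.na(genotypes[, i]), "./.", gt_code[genotypes[, i] + 1L])
    paste(c(catalog$chrom[i], catalog$pos[i], catalog$variant_id[i],
            catalog$ref[i], catalog$alt[i], ".", "PASS", info, "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
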