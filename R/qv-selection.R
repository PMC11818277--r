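# Qualifying-variant (QV) selection: rare high-impact variants passing
# population-AF and cohort allele-count filters.

#' Cohort allele-count cap implied by an observed minor-AF ceiling
#'
#' In a diploid cohort of `n_samples`, restricting the observed minor allele
#' frequency to at most `target_maf` allows at most
#' `floor(2 * n_samples * target_maf)` alternate alleles (never less than 1).
#' With the default 3% ceiling this gives a cap of 3 alleles at n = 50 and
#' 4 alleles at n = 77.
#'
#' @param n_samples number of diploid samples (>= 1).
#' @param target_maf observed minor-AF ceiling, in (0, 0.5).
#' @return integer allele-count cap.
#' @export
max_alleles_for_maf <- function(n_samples, target_maf = 0.03) {
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("n_samples must be >= 1", call. = FALSE)
  }
  if (!is.numeric(target_maf) || target_maf <= 0 || target_maf >= 0.5) {
    stop("target_maf must be in (0, 0.5)", call. = FALSE)
  }
  max(1L, as.integer(floor(2 * n_samples * target_maf)))
}

#' Qualifying-variant filter configuration
#'
#' @param af_max population-AF threshold; qualification requires
#'   `pop_af < af_max` (strict).
#' @param include_missing_af treat variants absent from the reference AF
#'   database as rare.
#' @param max_cohort_alt_alleles cohort alternate-allele count cap (`<=`,
#'   inclusive); if `NULL`, derived from `target_maf` and the cohort size at
#'   filter time.
#' @param target_maf observed minor-AF ceiling used to derive the cap.
#' @return list of class `qv_config`.
#' @export
qv_config <- function(af_max = 0.001, include_missing_af = TRUE,
                      max_cohort_alt_alleles = NULL, target_maf = 0.03) {
  if (af_max <= 0 || af_max >= 1) stop("af_max must be in (0, 1)", call. = FALSE)
  if (!is.null(max_cohort_alt_alleles) && max_cohort_alt_alleles < 1) {
    stop("allele-count cap must be >= 1", call. = FALSE)
  }
  structure(list(af_max = af_max, include_missing_af = include_missing_af,
                 max_cohort_alt_alleles = max_cohort_alt_alleles,
                 target_maf = target_maf),
            class = "qv_config")
}

#' Select qualifying variants
#'
#' A variant qualifies iff (i) its consequence class is high impact, (ii) its
#' population AF is below `af_max` or missing (when missing AFs are
#' included), and (iii) its cohort alternate-allele count — the sum of
#' non-missing dosages in the analysis cohort — does not exceed the cap.
#' Each excluded variant carries exactly one machine-readable reason, the
#' first failing rule in the order impact, AF, allele-count cap.
#'
#' @param catalog variant catalog.
#' @param genotypes dosage matrix (samples x variants) aligned to the
#'   catalog.
#' @param config [qv_config()].
#' @return data.frame of class `qv_set` with one row per catalog variant:
#'   `variant_id`, `gene`, `impact`, `pop_af`, `cohort_ac`, `qualified`,
#'   `reason` (`NA` for qualifying variants). The cap actually applied is in
#'   `attr(, "cap")`.
#' @export
qualify_variants <- function(catalog, genotypes, config = qv_config()) {
  stopifnot(inherits(config, "qv_config"),
            ncol(genotypes) == nrow(catalog))
  cap <- config$max_cohort_alt_alleles
  if (is.null(cap)) cap <- max_alleles_for_maf(nrow(genotypes), config$target_maf)
  if (cap < 1) stop("allele-count cap must be >= 1", call. = FALSE)
  impact <- classify_impact(catalog$consequence)
  cohort_ac <- as.integer(colSums(genotypes, na.rm = TRUE))
  af_ok <- ifelse(is.na(catalog$pop_af), config$include_missing_af,
                  catalog$pop_af < config$af_max)
  cap_ok <- cohort_ac <= cap
  qualified <- impact == "HI" & af_ok & cap_ok
  reason <- rep(NA_character_, nrow(catalog))
  reason[impact != "HI"] <- "impact_class"
  reason[impact == "HI" & !af_ok] <- "af_too_high"
  reason[impact == "HI" & af_ok & !cap_ok] <- "allele_count_cap"
  out <- data.frame(variant_id = catalog$variant_id, gene = catalog$gene,
                    impact = as.character(impact), pop_af = catalog$pop_af,
                    cohort_ac = cohort_ac, qualified = qualified,
                    reason = reason, stringsAsFactors = FALSE)
  attr(out, "cap") <- cap
  attr(out, "config") <- config
  class(out) <- c("qv_set", "data.frame")
  out
}

#' Qualifying variant ids
#' @param qvset result of [qualify_variants()].
#' @return character vector of qualifying `variant_id`s.
#' @export
qv_ids <- function(qvset) qvset$variant_id[qvset$qualified]

#' Genes harbouring at least one qualifying variant
#' @param qvset result of [qualify_variants()].
#' @return character vector of gene symbols.
#' @export
qv_genes <- function(qvset) unique(qvset$gene[qvset$qualified])
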