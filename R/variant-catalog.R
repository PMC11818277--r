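# Variant catalog: ingest annotated variant tables, classify variants and
# summarise the cohort variant spectrum.

#' Construct a validated variant catalog
#'
#' A variant catalog is a plain `data.frame` with one row per decomposed
#' alternate allele and columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`, `pop_af` and a canonical `variant_id`
#' (`chrom:pos:ref:alt`). `pop_af` is the population alternate-allele
#' frequency and may be `NA` for variants absent from the reference
#' frequency database.
#'
#' @param df data.frame with at least `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`; `pop_af` defaults to `NA` when absent.
#' @return data.frame of class `qv_catalog`.
#' @export
variant_catalog <- function(df) {
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"pop_af" %in% names(df)) df$pop_af <- NA_real_
  df$pos <- as.integer(df$pos)
  df$pop_af <- as.numeric(df$pop_af)
  if (any(df$pos < 1L)) stop("variant positions must be >= 1", call. = FALSE)
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ", call. = FALSE)
  bad_af <- !is.na(df$pop_af) & (df$pop_af < 0 | df$pop_af > 1)
  if (any(bad_af)) stop("pop_af outside [0, 1]", call. = FALSE)
  df$variant_id <- variant_id(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(df$variant_id)) {
    dup <- unique(df$variant_id[duplicated(df$variant_id)])
    stop("duplicate variant_id in catalog: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("qv_catalog", "data.frame")
  df
}

#' Canonical variant identifier
#'
#' @param chrom,pos,ref,alt vectors describing one decomposed allele each.
#' @return character vector `chrom:pos:ref:alt`.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read an annotated variant table with genotypes
#'
#' Reads either a VCF (via \pkg{vcfR}) or a flat TSV and returns the
#' decomposed variant catalog together with the samples-by-variants
#' alternate-allele dosage matrix. Multi-allelic VCF records are decomposed
#' into one catalog row per alternate allele; per-allele dosage is the count
#' of that allele in the genotype call. Missing genotypes become `NA`.
#'
#' For VCF input the gene, consequence and population-AF annotations are
#' taken from INFO fields (defaults `GENE`, `CSQ`, `AF`); for multi-allelic
#' records comma-separated per-allele INFO values are split positionally and
#' a single value is recycled. The TSV dialect has columns `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `consequence`, `pop_af` followed by one dosage
#' column per sample.
#'
#' @param path file path.
#' @param format `"vcf"`, `"tsv"` or `"auto"` (by file extension).
#' @param gene_field,consequence_field,af_field INFO keys for VCF input.
#' @return list with elements `catalog` (see [variant_catalog()]) and
#'   `genotypes` (integer matrix, samples x variants, dimnames set).
#' @export
read_variant_table <- function(path, format = c("auto", "vcf", "tsv"),
                               gene_field = "GENE",
                               consequence_field = "CSQ",
                               af_field = "AF") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    read_variant_vcf(path, gene_field, consequence_field, af_field)
  } else {
    read_variant_tsv(path)
  }
}

read_variant_vcf <- function(path, gene_field, consequence_field, af_field) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  info_get <- function(key) vcfR::extract.info(vcf, element = key)
  gene <- info_get(gene_field)
  csq <- info_get(consequence_field)
  af <- info_get(af_field)
  if (all(is.na(gene))) {
    stop("VCF INFO field not found: ", gene_field, call. = FALSE)
  }
  if (all(is.na(csq))) {
    stop("VCF INFO field not found: ", consequence_field, call. = FALSE)
  }
  rows <- list()
  dosages <- list()
  pick <- function(values, k) {
    # positional per-allele value; recycle a single value across alleles
    if (length(values) == 1L) values else values[k]
  }
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gene_i <- strsplit(if (is.na(gene[i])) NA_character_ else gene[i], ",")[[1]]
    csq_i <- strsplit(if (is.na(csq[i])) NA_character_ else csq[i], ",")[[1]]
    af_i <- if (is.na(af[i])) NA_character_ else strsplit(af[i], ",")[[1]]
    for (k in seq_along(alts)) {
      af_k <- if (length(af_i) == 1L && is.na(af_i[1])) NA_character_ else pick(af_i, k)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        gene = pick(gene_i, k), consequence = pick(csq_i, k),
        pop_af = if (is.na(af_k) || af_k == ".") NA_real_ else as.numeric(af_k),
        stringsAsFactors = FALSE)
      dosages[[length(dosages) + 1L]] <- allele_dosage(gt[i, ], k)
    }
  }
  catalog <- variant_catalog(do.call(rbind, rows))
  geno <- do.call(cbind, dosages)
  dimnames(geno) <- list(samples, catalog$variant_id)
  list(catalog = catalog, genotypes = geno)
}

# dosage of allele index k (1-based among ALT alleles) in GT strings
allele_dosage <- function(gt_strings, k) {
  out <- rep(NA_integer_, length(gt_strings))
  for (j in seq_along(gt_strings)) {
    g <- gt_strings[j]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) next
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) next
    out[j] <- sum(alleles == as.character(k))
  }
  out
}

read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "pop_af")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(df), required)
  catalog <- variant_catalog(df[required])
  geno <- t(as.matrix(df[sample_cols]))
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(sample_cols, catalog$variant_id)
  list(catalog = catalog, genotypes = geno)
}

#' Write a catalog + genotypes to the flat TSV dialect
#'
#' Inverse of the TSV branch of [read_variant_table()]; round-trips exactly.
#'
#' @param catalog variant catalog.
#' @param genotypes dosage matrix (samples x variants).
#' @param path output path.
#' @export
write_variant_table <- function(catalog, genotypes, path) {
  stopifnot(ncol(genotypes) == nrow(catalog))
  df <- catalog[c("chrom", "pos", "ref", "alt", "gene", "consequence", "pop_af")]
  df <- cbind(df, as.data.frame(t(genotypes), optional = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- consequence classification -------------------------------------------

# severe consequence terms (Ensembl vocabulary) counted as high impact
.hi_terms <- c("splice_acceptor_variant", "splice_donor_variant",
               "stop_gained", "frameshift_variant", "stop_lost", "start_lost")
.missense_terms <- c("missense_variant")
.synonymous_terms <- c("synonymous_variant")

.default_synonyms <- c(
  "acceptor splice" = "splice_acceptor_variant",
  "splice acceptor" = "splice_acceptor_variant",
  "donor splice" = "splice_donor_variant",
  "splice donor" = "splice_donor_variant",
  "stop gained" = "stop_gained",
  "stop-loss" = "stop_lost",
  "stop loss" = "stop_lost",
  "stoploss" = "stop_lost",
  "start-loss" = "start_lost",
  "start loss" = "start_lost",
  "startloss" = "start_lost",
  "frameshift" = "frameshift_variant",
  "missense" = "missense_variant",
  "missense variant" = "missense_variant",
  "synonymous" = "synonymous_variant",
  "synonymous variant" = "synonymous_variant")

#' Classify consequence terms into impact classes
#'
#' High-impact (HI) covers the severe protein-truncating consequences:
#' splice acceptor, splice donor, stop gained, frameshift, stop loss and
#' start loss. Everything not recognised as HI, missense or synonymous maps
#' to `OTHER` — unknown severe-looking terms are never promoted to HI.
#' Spaced and underscored spellings are both accepted via a synonym table.
#'
#' @param consequence character vector of consequence terms.
#' @param synonyms named character vector mapping alternate spellings to the
#'   canonical underscored vocabulary.
#' @return factor with levels `HI`, `MISSENSE`, `SYNONYMOUS`, `OTHER`.
#' @export
classify_impact <- function(consequence, synonyms = .default_synonyms) {
  if (length(consequence) == 0L) {
    return(factor(character(0), levels = c("HI", "MISSENSE", "SYNONYMOUS", "OTHER")))
  }
  if (any(is.na(consequence) | !nzchar(trimws(consequence)))) {
    stop("empty consequence term", call. = FALSE)
  }
  term <- trimws(tolower(consequence))
  hit <- match(term, names(synonyms))
  term[!is.na(hit)] <- synonyms[hit[!is.na(hit)]]
  cls <- rep("OTHER", length(term))
  cls[term %in% .hi_terms] <- "HI"
  cls[term %in% .missense_terms] <- "MISSENSE"
  cls[term %in% .synonymous_terms] <- "SYNONYMOUS"
  factor(cls, levels = c("HI", "MISSENSE", "SYNONYMOUS", "OTHER"))
}

#' Classify a variant as SNV, insertion or deletion
#'
#' Equal multi-base allele lengths (MNVs) are classified `OTHER` with a
#' warning; they fall outside the three reported types.
#'
#' @param ref,alt allele strings (vectorised).
#' @return factor with levels `SNV`, `insertion`, `deletion`, `OTHER`.
#' @export
classify_variant_type <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("empty allele string", call. = FALSE)
  }
  lr <- nchar(ref); la <- nchar(alt)
  type <- rep("OTHER", length(ref))
  type[lr == 1L & la == 1L] <- "SNV"
  type[la > lr] <- "insertion"
  type[la < lr] <- "deletion"
  if (any(type == "OTHER")) {
    warning(sum(type == "OTHER"),
            " MNV record(s) (equal multi-base allele lengths) classified OTHER")
  }
  factor(type, levels = c("SNV", "insertion", "deletion", "OTHER"))
}

#' Bin population allele frequencies
#'
#' Bins: `no-AF` (missing), `rare` (AF < 0.001), `low-frequency`
#' (0.001 <= AF < 0.01) and `common` (AF >= 0.01). The bins partition all
#' possible values; an AF of exactly 0 falls in `rare`.
#'
#' @param pop_af numeric vector in `[0, 1]`, `NA` for missing.
#' @param breaks two interior cut points (defaults 0.001 and 0.01).
#' @return factor with levels `no-AF`, `rare`, `low-frequency`, `common`.
#' @export
af_bin <- function(pop_af, breaks = c(0.001, 0.01)) {
  stopifnot(length(breaks) == 2L, breaks[1] < breaks[2])
  ok <- is.na(pop_af) | (pop_af >= 0 & pop_af <= 1)
  if (!all(ok)) stop("pop_af outside [0, 1]", call. = FALSE)
  bin <- rep("no-AF", length(pop_af))
  bin[!is.na(pop_af) & pop_af < breaks[1]] <- "rare"
  bin[!is.na(pop_af) & pop_af >= breaks[1] & pop_af < breaks[2]] <- "low-frequency"
  bin[!is.na(pop_af) & pop_af >= breaks[2]] <- "common"
  factor(bin, levels = c("no-AF", "rare", "low-frequency", "common"))
}

# round half up to `digits` decimals (base round() is half-even)
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarise the variant spectrum of a cohort catalog
#'
#' Counts unique variants per impact class (with percentages of the total,
#' rounded half-up to two decimals), per AF bin, singletons (cohort
#' alternate-allele count exactly 1) per AF bin, and SNV/insertion/deletion
#' types per AF bin.
#'
#' @param catalog variant catalog.
#' @param genotypes dosage matrix aligned to the catalog, or `NULL` to skip
#'   the genotype-based (singleton) sections.
#' @return list of class `spectrum_summary`: `n_variants` (post-decomposition
#'   unique variants), `n_sites` (unique chrom:pos sites), `impact_counts`,
#'   `impact_pct`, `af_bin_counts`, `singleton_counts`, `type_counts`.
#' @export
summarize_spectrum <- function(catalog, genotypes = NULL) {
  n <- nrow(catalog)
  impact <- classify_impact(catalog$consequence)
  bins <- af_bin(catalog$pop_af)
  impact_counts <- table(impact)
  impact_pct <- if (n > 0) round_half_up(100 * as.numeric(impact_counts) / n, 2L) else
    rep(NA_real_, length(impact_counts))
  names(impact_pct) <- names(impact_counts)
  out <- list(
    n_variants = n,
    n_sites = length(unique(paste(catalog$chrom, catalog$pos))),
    impact_counts = impact_counts,
    impact_pct = impact_pct,
    af_bin_counts = table(bins),
    type_counts = suppressWarnings(
      table(type = classify_variant_type(catalog$ref, catalog$alt), af_bin = bins)),
    singleton_counts = NULL)
  if (!is.null(genotypes)) {
    stopifnot(ncol(genotypes) == n)
    ac <- colSums(genotypes, na.rm = TRUE)
    out$singleton_counts <- table(bins[ac == 1L])
  }
  if (n == 0L) out$percentages_defined <- FALSE else out$percentages_defined <- TRUE
  class(out) <- "spectrum_summary"
  out
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Variant spectrum:", x$n_variants, "unique variants (",
      x$n_sites, "sites )\n")
  for (cl in names(x$impact_counts)) {
    cat(sprintf("  %-10s %8d  (%.2f%%)\n", cl, x$impact_counts[[cl]],
                x$impact_pct[[cl]]))
  }
  cat("AF bins:\n"); print(x$af_bin_counts)
  invisible(x)
}

#' Overlap of two cohort catalogs
#'
#' Counts unique keys (variant ids or gene symbols) private to each cohort
#' and shared between them.
#'
#' @param catalog_a,catalog_b variant catalogs (or data.frames with the key
#'   column).
#' @param key `"variant_id"` or `"gene"`.
#' @return named integer vector `a_only`, `shared`, `b_only`.
#' @export
cohort_overlap <- function(catalog_a, catalog_b, key = c("variant_id", "gene")) {
  key <- match.arg(key)
  a <- unique(catalog_a[[key]])
  b <- unique(catalog_b[[key]])
  shared <- length(intersect(a, b))
  c(a_only = length(a) - shared, shared = shared, b_only = length(b) - shared)
}
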