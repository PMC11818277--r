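test_that("VCF genotypes decode to alternate-allele dosage and round-trip", {
  toy <- make_toy_cohort(n_samples = 3L)
  # plant the canonical 0/0, 0/1, 1/1 pattern on the first variant
  toy$genotypes[, 1] <- c(0L, 1L, 2L)
  toy$genotypes[1, 2] <- NA_integer_
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(toy$catalog, toy$genotypes, vcf_path)
  got <- read_variant_table(vcf_path, format = "vcf")
  expect_equal(unname(got$genotypes[, 1]), c(0L, 1L, 2L))
  expect_true(is.na(got$genotypes[1, 2]))
  expect_equal(got$catalog$variant_id, toy$catalog$variant_id)
  expect_equal(got$catalog$pop_af, toy$catalog$pop_af)
  expect_equal(got$catalog$consequence, toy$catalog$consequence)
})

test_that("multi-allelic records decompose into one variant per alt allele", {
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"c\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "500", ".", "A", "G,T", ".", "PASS",
          "GENE=GX;CSQ=stop_gained,missense_variant;AF=0.0001,0.002",
          "GT", "1/2", "0/1", "2/2", sep = "\t")), vcf_path)
  got <- read_variant_table(vcf_path, format = "vcf")
  expect_equal(nrow(got$catalog), 2L)
  expect_equal(got$catalog$chrom, c("1", "1"))
  expect_equal(got$catalog$pos, c(500L, 500L))
  expect_equal(got$catalog$ref, c("A", "A"))
  expect_equal(got$catalog$alt, c("G", "T"))
  expect_equal(got$catalog$pop_af, c(1e-4, 2e-3))
  # per-allele dosage: S1 = 1/2 carries one of each; S3 = 2/2 is hom for T
  expect_equal(unname(got$genotypes[, 1]), c(1L, 1L, 0L))
  expect_equal(unname(got$genotypes[, 2]), c(1L, 0L, 2L))
})

test_that("a written catalog re-reads identically (TSV round trip)", {
  cohort <- simulate_cohort(sim_config(seed = 7L, n_genes = 30L))
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(cohort$catalog, cohort$genotypes, tsv_path)
  got <- read_variant_table(tsv_path, format = "tsv")
  expect_equal(got$catalog$variant_id, cohort$catalog$variant_id)
  expect_equal(got$catalog$pop_af, cohort$catalog$pop_af)
  expect_equal(unname(got$genotypes), unname(cohort$genotypes))
})

test_that("missing mandatory columns and duplicate ids are rejected", {
  expect_error(variant_catalog(data.frame(chrom = "1", pos = 1)),
               "missing mandatory column")
  df <- data.frame(chrom = "1", pos = c(1L, 1L), ref = "A", alt = "G",
                   gene = "X", consequence = "stop_gained")
  expect_error(variant_catalog(df), "duplicate variant_id")
})

test_that("consequence terms map to impact classes conservatively", {
  expect_equal(as.character(classify_impact("stop_gained")), "HI")
  expect_equal(as.character(classify_impact("stop gained")), "HI")
  expect_equal(as.character(classify_impact("acceptor splice")), "HI")
  expect_equal(as.character(classify_impact("missense_variant")), "MISSENSE")
  expect_equal(as.character(classify_impact("intron_variant")), "OTHER")
  # severe-looking but unrecognized terms never silently become HI
  expect_equal(as.character(classify_impact("transcript_ablation")), "OTHER")
  expect_error(classify_impact(""), "empty consequence")
  hi_terms <- c("splice_acceptor_variant", "splice_donor_variant",
                "stop_gained", "frameshift_variant", "stop_lost",
                "start_lost")
  expect_true(all(classify_impact(hi_terms) == "HI"))
})

test_that("variant types follow allele-length rules, MNVs flagged", {
  expect_equal(as.character(classify_variant_type("A", "G")), "SNV")
  expect_equal(as.character(classify_variant_type("A", "ATT")), "insertion")
  expect_equal(as.character(classify_variant_type("ACG", "A")), "deletion")
  expect_warning(type <- classify_variant_type("AC", "GT"), "MNV")
  expect_equal(as.character(type), "OTHER")
  expect_error(classify_variant_type("", "G"), "empty allele")
})

test_that("AF bins partition all possible values", {
  expect_equal(as.character(af_bin(NA_real_)), "no-AF")
  expect_equal(as.character(af_bin(0.0005)), "rare")
  expect_equal(as.character(af_bin(0.001)), "low-frequency")
  expect_equal(as.character(af_bin(0.05)), "common")
  expect_error(af_bin(1.5), "outside")
  set.seed(11)
  afs <- c(NA, 0, 1, runif(500))
  bins <- af_bin(afs)
  expect_false(anyNA(bins))
  expect_equal(sum(table(bins)), length(afs))
})

test_that("spectrum summary reproduces a planted composition and conserves counts", {
  catalog <- variant_catalog(data.frame(
    chrom = "1", pos = seq_len(100) * 10L, ref = "A", alt = "G",
    gene = "X",
    consequence = c(rep("stop_gained", 10), rep("missense_variant", 40),
                    rep("synonymous_variant", 50)),
    pop_af = rep(c(NA, 5e-4, 5e-3, 0.5), 25), stringsAsFactors = FALSE))
  s <- summarize_spectrum(catalog)
  expect_equal(unname(s$impact_pct[c("HI", "MISSENSE", "SYNONYMOUS")]),
               c(10, 40, 50))
  expect_equal(sum(s$impact_counts), s$n_variants)
  expect_equal(sum(s$af_bin_counts), s$n_variants)
})

test_that("singletons are counted from cohort allele counts, order-invariant", {
  toy <- make_toy_cohort(n_samples = 8L, seed = 3L)
  toy$genotypes[] <- 0L
  toy$genotypes[1, 1] <- 1L           # singleton
  toy$genotypes[2, 2] <- 2L           # AC = 2, not a singleton
  s <- summarize_spectrum(toy$catalog, toy$genotypes)
  expect_equal(sum(s$singleton_counts), 1L)
  shuffled <- toy$genotypes[sample(nrow(toy$genotypes)), , drop = FALSE]
  s2 <- summarize_spectrum(toy$catalog, shuffled)
  expect_equal(s$singleton_counts, s2$singleton_counts)
})

test_that("cohort overlap counts unique shared keys", {
  a <- make_toy_cohort(seed = 1L)$catalog
  expect_equal(unname(cohort_overlap(a, a)), c(0L, nrow(a), 0L))
  b <- a
  b$variant_id <- paste0(b$variant_id, "_b")
  expect_equal(cohort_overlap(a, b)[["shared"]], 0L)
  # plant exactly 15 shared variant ids between two synthetic catalogs
  big <- simulate_cohort(sim_config(seed = 5L, n_genes = 40L))$catalog
  other <- big
  keep <- seq_len(15L)
  other$variant_id <- paste0(other$variant_id, "_x")
  other$variant_id[keep] <- big$variant_id[keep]
  expect_equal(cohort_overlap(big, other)[["shared"]], 15L)
})
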