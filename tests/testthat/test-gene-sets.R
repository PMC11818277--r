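test_that("GMT parsing handles the Broad dialect", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("hsa04330\tNotch\tLFNG\tATXN1\tDTX3L\tNCOR2", gmt)
  col <- read_gmt(gmt)
  expect_equal(length(col), 1L)
  expect_equal(col$hsa04330, c("LFNG", "ATXN1", "DTX3L", "NCOR2"))
  expect_equal(unname(attr(col, "descriptions")["hsa04330"]), "Notch")
})

test_that("GMT parsing deduplicates, rejects empties, reports bad lines", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG1", "setB\tdesc\tG3"), gmt)
  expect_warning(col <- read_gmt(gmt), "duplicate genes")
  expect_equal(col$setA, c("G1", "G2"))
  writeLines("loneset", gmt)
  expect_error(read_gmt(gmt), "malformed GMT line 1")
  expect_error(gene_set_collection(list(empty = character(0))), "empty")
})

test_that("GMT write/read round-trips a collection", {
  col <- gene_set_collection(list(A = c("G1", "G2"), B = c("G2", "G3", "G4")),
                             descriptions = c("first", "second"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, gmt)
  got <- read_gmt(gmt)
  expect_equal(unclass(got)[names(got)], unclass(col)[names(col)],
               ignore_attr = TRUE)
  expect_equal(attr(got, "descriptions"), attr(col, "descriptions"))
})

test_that("overlap regions decompose the union", {
  col <- gene_set_collection(list(A = c("G1", "G2", "G3"),
                                  B = c("G1", "G2", "G3")))
  ov <- collection_overlap(col)
  expect_equal(unname(ov["A&B"]), 3L)
  expect_equal(sum(ov), 3L)
  col2 <- gene_set_collection(list(A = c("G1", "G2"), B = c("G3", "G4")))
  ov2 <- collection_overlap(col2)
  expect_false("A&B" %in% names(ov2))
  # planted three-set structure: pairwise and triple regions known exactly
  col3 <- gene_set_collection(list(
    A = c("u1", "ab", "abc"), B = c("u2", "u3", "ab", "bc", "abc"),
    C = c("u4", "bc", "abc")))
  ov3 <- collection_overlap(col3)
  expect_equal(unname(ov3[c("A", "B", "C", "A&B", "B&C", "A&B&C")]),
               c(1L, 2L, 1L, 1L, 1L, 1L))
  expect_equal(sum(ov3), length(unique(unlist(col3))))
  expect_error(collection_overlap(col3, c("A", "nope")), "unknown set")
})

test_that("restriction keeps only QV genes and is idempotent", {
  fx <- simulate_cohort(sim_config(
    seed = 31L, n_genes = 60L, n_samples = 40L, mean_variants_per_gene = 10,
    impact_mix = c(HI = 0.2, MISSENSE = 0.3, SYNONYMOUS = 0.3, OTHER = 0.2)))
  qv <- qualify_variants(fx$catalog, fx$genotypes, qv_config())
  # a set whose genes are exactly 6 QV genes plus noise restricts to size 6
  qg <- qv_genes(qv)
  expect_gte(length(qg), 6L)
  col <- gene_set_collection(list(
    planted = c(qg[1:6], "NOT_A_GENE_1", "NOT_A_GENE_2"),
    barren = c("NOT_A_GENE_3")))
  r1 <- restrict_to_qv_genes(col, qv)
  expect_equal(length(r1$planted), 6L)
  expect_equal(attr(r1, "empty_sets"), "barren")
  r2 <- restrict_to_qv_genes(r1, qv)
  expect_equal(unclass(r2)[names(r2)], unclass(r1)[names(r1)],
               ignore_attr = TRUE)
})

test_that("burden counts distinct carrier sites under the dominant model", {
  catalog <- variant_catalog(data.frame(
    chrom = "1", pos = c(10L, 20L, 30L), ref = "A", alt = "G",
    gene = c("G1", "G2", "G3"), consequence = "stop_gained",
    pop_af = NA_real_, stringsAsFactors = FALSE))
  genotypes <- matrix(c(1L, 1L, 0L,   # S1: het at two set genes
                        2L, 0L, 0L,   # S2: hom at one site counts once
                        0L, 0L, 0L),  # S3: non-carrier
                      nrow = 3L, byrow = TRUE,
                      dimnames = list(c("S1", "S2", "S3"),
                                      catalog$variant_id))
  qv <- qualify_variants(catalog, genotypes, qv_config(max_cohort_alt_alleles = 4L))
  col <- gene_set_collection(list(SET = c("G1", "G2")))
  bp <- burden_profile(qv, genotypes, catalog, col)
  expect_equal(bp$qv_count, c(2L, 1L, 0L))
  expect_equal(bp$carrier, c(TRUE, TRUE, FALSE))
  # dosage-sum sensitivity mode counts the homozygote twice
  bp2 <- burden_profile(qv, genotypes, catalog, col, mode = "dosage_sum")
  expect_equal(bp2$qv_count, c(2L, 2L, 0L))
})

test_that("burden equals an exhaustive recount and ignores input order", {
  fx <- simulate_cohort(sim_config(seed = 33L, n_genes = 50L, n_samples = 30L))
  qv <- qualify_variants(fx$catalog, fx$genotypes, qv_config())
  bp <- burden_profile(qv, fx$genotypes, fx$catalog, fx$collection)
  # brute-force recount straight off the genotype matrix
  ids <- qv_ids(qv)
  for (set_name in names(fx$collection)) {
    genes <- fx$collection[[set_name]]
    for (s in rownames(fx$genotypes)) {
      expected <- 0L
      for (j in seq_len(ncol(fx$genotypes))) {
        if (fx$catalog$variant_id[j] %in% ids &&
            fx$catalog$gene[j] %in% genes &&
            !is.na(fx$genotypes[s, j]) && fx$genotypes[s, j] >= 1L) {
          expected <- expected + 1L
        }
      }
      got <- bp$qv_count[bp$sample_id == s & bp$set_name == set_name]
      expect_equal(got, expected)
    }
  }
  # permutation of variant and sample order changes nothing (up to relabel)
  perm_v <- sample(ncol(fx$genotypes))
  perm_s <- sample(nrow(fx$genotypes))
  cat2 <- fx$catalog[perm_v, ]
  class(cat2) <- class(fx$catalog)
  bp2 <- burden_profile(qv, fx$genotypes[perm_s, perm_v], cat2, fx$collection)
  key <- function(x) x[order(x$sample_id, x$set_name), c("qv_count", "carrier")]
  expect_equal(key(bp2), key(bp), ignore_attr = TRUE)
})

test_that("per-gene carrier flags respect missing genotypes", {
  catalog <- variant_catalog(data.frame(
    chrom = "1", pos = c(10L, 20L), ref = "A", alt = "G",
    gene = c("G1", "G1"), consequence = "stop_gained",
    pop_af = NA_real_, stringsAsFactors = FALSE))
  genotypes <- matrix(c(NA_integer_, NA_integer_,
                        0L, 1L),
                      nrow = 2L, byrow = TRUE,
                      dimnames = list(c("S1", "S2"), catalog$variant_id))
  qv <- qualify_variants(catalog, genotypes, qv_config(max_cohort_alt_alleles = 4L))
  cm <- carrier_by_gene(qv, genotypes, catalog)
  expect_true(is.na(cm["S1", "G1"]))
  expect_true(cm["S2", "G1"])
})
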