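# printed per-gene carrier counts for the four Notch genes, anemic (25)
# vs non-anemic (25) patients: 10/25 vs 5/25, 7/25 vs 2/25, 1/25 vs 0/25,
# 12/25 vs 7/25
notch_strata <- function() {
  strata_from_counts(list(c(10, 15, 5, 20), c(7, 18, 2, 23),
                          c(1, 24, 0, 25), c(12, 13, 7, 18)),
                     labels = c("LFNG", "ATXN1", "DTX3L", "NCOR2"))
}

test_that("strata cross-tabulate carriers by group and drop empty strata", {
  carrier <- cbind(g1 = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   g2 = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  groups <- rep(c("case", "control"), each = 3)
  st <- suppressWarnings(build_strata(carrier, groups))
  expect_equal(dim(st)[3], 1L)
  expect_equal(attr(st, "dropped"), "g2")
  expect_equal(as.vector(st[, , 1]), c(2L, 0L, 1L, 3L))
  # permuting samples leaves the tables unchanged
  perm <- sample(6)
  st2 <- build_strata(carrier[perm, , drop = FALSE], groups[perm])
  expect_equal(unclass(st2), unclass(st), ignore_attr = TRUE)
  expect_error(build_strata(carrier, rep("one", 6)), "binary")
})

test_that("MH odds ratio reproduces the hand value on the Notch strata", {
  res <- cmh_test(notch_strata(), mode = "exact")
  expect_equal(res$mh_or, (4 + 3.22 + 0.5 + 4.32) / (1.5 + 0.72 + 0 + 1.82),
               tolerance = 1e-3)
  expect_equal(res$strata_used, 4L)  # 1/25 vs 0/25 still has a free a-cell
  expect_lt(res$p_value, 0.05)
})

test_that("a single 2x2 reduces to ad/bc and the doubled Fisher tail", {
  tab <- c(10, 15, 5, 20)
  res <- cmh_test(strata_from_counts(list(tab)), mode = "exact")
  expect_equal(res$mh_or, 10 * 20 / (15 * 5))
  # tail-doubling on the central hypergeometric a-cell distribution
  p_le <- phyper(10, 15, 35, 25)
  p_ge <- 1 - phyper(9, 15, 35, 25)
  expect_equal(res$p_value, min(1, 2 * min(p_le, p_ge)), tolerance = 1e-12)
})

test_that("identical balanced strata are exactly null", {
  st <- strata_from_counts(list(c(1, 1, 1, 1), c(1, 1, 1, 1)))
  res <- cmh_test(st, mode = "exact")
  expect_equal(res$mh_or, 1)
  expect_equal(res$p_value, 1)
})

test_that("exact CMH equals exhaustive enumeration and mantelhaen.test", {
  set.seed(201)
  for (i in 1:150) {
    k <- sample(2:3, 1)
    st <- strata_from_counts(replicate(k, random_table2x2(12L),
                                       simplify = FALSE))
    mine <- cmh_test(st, mode = "exact")
    expect_equal(mine$p_value, cmh_enum_oracle(st), tolerance = 1e-10)
    # one-sided exact tails are convention-free: compare to mantelhaen.test
    lo <- tryCatch(mantelhaen.test(unclass(st), exact = TRUE,
                                   alternative = "less"),
                   error = function(e) NULL)
    hi <- tryCatch(mantelhaen.test(unclass(st), exact = TRUE,
                                   alternative = "greater"),
                   error = function(e) NULL)
    if (!is.null(lo)) expect_equal(mine$p_lower, lo$p.value, tolerance = 1e-9)
    if (!is.null(hi)) expect_equal(mine$p_upper, hi$p.value, tolerance = 1e-9)
  }
})

test_that("asymptotic CMH matches the continuity-corrected reference", {
  set.seed(202)
  for (i in 1:50) {
    st <- strata_from_counts(replicate(3, random_table2x2(40L),
                                       simplify = FALSE))
    mine <- cmh_test(st, mode = "asymptotic")
    ref <- tryCatch(mantelhaen.test(unclass(st), correct = TRUE),
                    error = function(e) NULL)
    if (is.null(ref)) next
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$mh_or, unname(ref$estimate), tolerance = 1e-9)
  }
})

test_that("exact and asymptotic p agree for balanced, well-filled strata", {
  set.seed(203)
  for (i in 1:20) {
    tabs <- replicate(3, 10L + matrix(rpois(4, 15), 2), simplify = FALSE)
    st <- strata_from_counts(lapply(tabs, as.vector))
    pe <- cmh_test(st, "exact")$p_value
    pa <- cmh_test(st, "asymptotic")$p_value
    expect_equal(pe, pa, tolerance = 0.1 * max(pe, pa))
  }
})

test_that("gene-set burden test flags untestable sets and duplicates agree", {
  fx <- simulate_cohort(sim_config(seed = 205L, n_genes = 60L,
                                   n_samples = 50L, planted_or = 4))
  qv <- qualify_variants(fx$catalog, fx$genotypes, qv_config())
  col <- gene_set_collection(list(
    causal = fx$collection$SET_CAUSAL,
    causal_copy = fx$collection$SET_CAUSAL,
    barren = "NOT_A_GENE"))
  groups <- setNames(fx$phenotype$group, fx$phenotype$sample_id)
  res <- geneset_burden_test(qv, fx$genotypes, fx$catalog, col,
                             groups[rownames(fx$genotypes)])
  expect_false(res$testable[res$set == "barren"])
  expect_equal(res[res$set == "causal", c("or", "p", "strata_used")],
               res[res$set == "causal_copy", c("or", "p", "strata_used")],
               ignore_attr = TRUE)
})

test_that("exome-wide scan computes Bonferroni, QQ coordinates and lambda", {
  set.seed(206)
  n <- 200L; m <- 400L
  af <- runif(m, 0.2, 0.5)  # common variants so carrier tables are dense
  geno <- matrix(rbinom(n * m, 2L, rep(af, each = n)), n, m)
  catalog <- variant_catalog(data.frame(
    chrom = "1", pos = seq_len(m) * 10L, ref = "A", alt = "G", gene = "X",
    consequence = "missense_variant", pop_af = af, stringsAsFactors = FALSE))
  dimnames(geno) <- list(sprintf("S%03d", 1:n), catalog$variant_id)
  groups <- rep(c("case", "control"), each = n / 2)  # null labels
  scan <- exome_wide_scan(catalog, geno, groups)
  expect_equal(scan$n_tested + scan$n_skipped, m)
  expect_equal(scan$bonferroni, 0.05 / scan$n_tested)
  expect_equal(scan$qq$expected,
               -log10((seq_len(scan$n_tested) - 0.5) / scan$n_tested))
  expect_false(is.unsorted(rev(scan$qq$observed)))
  # exact-test discreteness deflates the observed quantiles, so lambda
  # sits at or below 1 under the null (the QQ deflation the scan reports)
  expect_gt(scan$lambda, 0.5)
  expect_lt(scan$lambda, 1.05)
  expect_lt(median(scan$qq$observed - scan$qq$expected), 0.1)
  # a variant nobody carries is skipped, not tested
  geno0 <- cbind(geno, 0L)
  cat0 <- variant_catalog(data.frame(
    chrom = "1", pos = c(seq_len(m) * 10L, 99999L), ref = "A", alt = "G",
    gene = "X", consequence = "missense_variant",
    pop_af = c(af, 0.001), stringsAsFactors = FALSE))
  colnames(geno0) <- cat0$variant_id
  scan0 <- exome_wide_scan(cat0, geno0, groups)
  expect_equal(scan0$n_skipped, 1L)
})
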