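# Gene-set burden association via the stratified Cochran-Mantel-Haenszel
# framework, and the exome-wide single-variant scan.

as_binary_groups <- function(groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) {
    stop("groups must be binary (exactly two levels), got ",
         nlevels(g), call. = FALSE)
  }
  g
}

#' Build stratified 2x2 carrier tables
#'
#' Cross-tabulates carrier status against a binary phenotype within each
#' stratum (one stratum per gene or per variant). Cell layout per stratum:
#' rows = phenotype groups (first factor level first), columns = carrier /
#' non-carrier, so `a` counts carriers in the first group. Samples with
#' missing carrier status are excluded from that stratum; strata with zero
#' carriers in both groups are dropped (counted in `attr(, "dropped")`).
#'
#' @param carrier logical matrix, samples x strata (e.g. from
#'   [carrier_by_gene()]).
#' @param groups binary phenotype, one label per sample.
#' @return 2x2xK array of class `qv_strata` with stratum dimnames.
#' @export
build_strata <- function(carrier, groups) {
  g <- as_binary_groups(groups)
  if (length(g) != nrow(carrier)) {
    stop("groups length must match carrier rows", call. = FALSE)
  }
  k <- ncol(carrier)
  labels <- colnames(carrier)
  if (is.null(labels)) labels <- paste0("stratum", seq_len(k))
  tabs <- array(0L, dim = c(2L, 2L, k),
                dimnames = list(group = levels(g),
                                trait = c("carrier", "non-carrier"),
                                stratum = labels))
  keep <- rep(TRUE, k)
  for (j in seq_len(k)) {
    cj <- carrier[, j]
    ok <- !is.na(cj) & !is.na(g)
    tabs[1, 1, j] <- sum(cj[ok] & g[ok] == levels(g)[1])
    tabs[1, 2, j] <- sum(!cj[ok] & g[ok] == levels(g)[1])
    tabs[2, 1, j] <- sum(cj[ok] & g[ok] == levels(g)[2])
    tabs[2, 2, j] <- sum(!cj[ok] & g[ok] == levels(g)[2])
    if (tabs[1, 1, j] + tabs[2, 1, j] == 0L) keep[j] <- FALSE
  }
  dropped <- labels[!keep]
  out <- tabs[, , keep, drop = FALSE]
  attr(out, "dropped") <- dropped
  class(out) <- "qv_strata"
  out
}

#' Assemble strata directly from printed 2x2 counts
#'
#' @param tables list of length-4 vectors `c(a, b, c, d)` (a = carriers in
#'   the index group) or 2x2 matrices.
#' @param labels optional stratum labels.
#' @return `qv_strata` array.
#' @export
strata_from_counts <- function(tables, labels = NULL) {
  k <- length(tables)
  if (is.null(labels)) labels <- paste0("stratum", seq_len(k))
  out <- array(0L, dim = c(2L, 2L, k),
               dimnames = list(group = c("group1", "group2"),
                               trait = c("carrier", "non-carrier"),
                               stratum = labels))
  for (j in seq_len(k)) {
    x <- as_table2x2(tables[[j]])
    out[, , j] <- matrix(x, 2L, 2L, byrow = TRUE)
  }
  class(out) <- "qv_strata"
  out
}

# central hypergeometric pmf of the a-cell of one 2x2 given its margins
a_cell_pmf <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  list(support = support,
       pmf = stats::dhyper(support, c1, n - c1, r1))
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' The common odds ratio is the Mantel-Haenszel estimator
#' `sum(a d / n) / sum(b c / n)` with a 95% confidence interval from the
#' Robins-Breslow-Greenland variance of its logarithm. Exact p-values come
#' from the exact conditional null: the per-stratum a-cells follow central
#' hypergeometric distributions given the margins, their sum's distribution
#' is obtained by convolution, and the two-sided p is twice the smaller
#' tail probability of the observed sum, capped at 1. Asymptotic p-values
#' use the continuity-corrected CMH chi-square statistic with 1 df.
#'
#' @param strata `qv_strata` array (see [build_strata()]), a 2x2xK array,
#'   or a single 2x2 matrix.
#' @param mode `"exact"` or `"asymptotic"`.
#' @param conf_level confidence level for the odds-ratio interval.
#' @return list of class `cmh_result`: `mh_or`, `ci95`, `p_value`,
#'   `p_lower`/`p_upper` (one-sided exact tails, exact mode only),
#'   `statistic` (observed a-cell sum or chi-square), `mode`,
#'   `strata_used` (informative strata, those with non-degenerate margins),
#'   `flags`.
#' @export
cmh_test <- function(strata, mode = c("exact", "asymptotic"),
                     conf_level = 0.95) {
  mode <- match.arg(mode)
  if (is.matrix(strata)) strata <- array(strata, dim = c(2L, 2L, 1L))
  stopifnot(length(dim(strata)) == 3L, all(dim(strata)[1:2] == 2L))
  a <- strata[1, 1, ]; b <- strata[1, 2, ]
  c <- strata[2, 1, ]; d <- strata[2, 2, ]
  n <- a + b + c + d
  flags <- character(0)
  pos <- n > 0
  a <- a[pos]; b <- b[pos]; c <- c[pos]; d <- d[pos]; n <- n[pos]
  if (length(n) == 0L) {
    return(structure(list(mh_or = NA_real_, ci95 = c(NA_real_, NA_real_),
                          p_value = NA_real_, statistic = NA_real_,
                          mode = mode, strata_used = 0L,
                          flags = "no informative strata"),
                     class = "cmh_result"))
  }
  # informative strata: a-cell not fixed by its margins
  e_a <- (a + b) * (a + c) / n
  v_a <- (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * pmax(n - 1, 1))
  informative <- v_a > 0
  strata_used <- sum(informative)
  if (strata_used == 0L) {
    return(structure(list(mh_or = NA_real_, ci95 = c(NA_real_, NA_real_),
                          p_value = NA_real_, statistic = NA_real_,
                          mode = mode, strata_used = 0L,
                          flags = "all strata degenerate"),
                     class = "cmh_result"))
  }
  sum_r <- sum(a * d / n)   # numerator terms of the MH estimator
  sum_s <- sum(b * c / n)
  mh_or <- if (sum_s == 0) {
    flags <- c(flags, "odds ratio infinite")
    Inf
  } else sum_r / sum_s
  ci <- c(NA_real_, NA_real_)
  if (is.finite(mh_or) && mh_or > 0 && sum_r > 0) {
    p_term <- (a + d) / n
    q_term <- (b + c) / n
    r_term <- a * d / n
    s_term <- b * c / n
    var_log <- sum(p_term * r_term) / (2 * sum_r^2) +
      sum(p_term * s_term + q_term * r_term) / (2 * sum_r * sum_s) +
      sum(q_term * s_term) / (2 * sum_s^2)
    zc <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(mh_or) + c(-1, 1) * zc * sqrt(var_log))
  } else {
    flags <- c(flags, "RBG interval undefined")
  }
  p_lower <- p_upper <- NA_real_
  if (mode == "exact") {
    pmf <- 1; offset <- 0
    for (j in seq_along(n)) {
      dist <- a_cell_pmf(a[j], b[j], c[j], d[j])
      pmf <- if (length(dist$pmf) == 1L) pmf * dist$pmf else
        convolve_pmf(pmf, dist$pmf)
      offset <- offset + dist$support[1]
    }
    s_obs <- sum(a)
    support <- offset + seq_along(pmf) - 1L
    p_lower <- sum(pmf[support <= s_obs])
    p_upper <- sum(pmf[support >= s_obs])
    p <- min(1, 2 * min(p_lower, p_upper))
    stat <- s_obs
  } else {
    delta <- sum(a - e_a)
    # continuity correction only when it does not overshoot zero
    yates <- if (abs(delta) >= 0.5) 0.5 else 0
    stat <- (abs(delta) - yates)^2 / sum(v_a)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(mh_or = mh_or, ci95 = ci, p_value = p,
                 p_lower = p_lower, p_upper = p_upper, statistic = stat,
                 mode = mode, strata_used = strata_used, flags = flags),
            class = "cmh_result")
}

# open (full) discrete convolution of two pmf vectors
convolve_pmf <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1L)
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

#' @export
print.cmh_result <- function(x, ...) {
  cat("CMH test (", x$mode, "), strata used: ", x$strata_used, "\n", sep = "")
  cat("  MH OR =", format(x$mh_or), " 95% CI [",
      format(x$ci95[1]), ",", format(x$ci95[2]), "]  p =",
      format(x$p_value), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Gene-set QV burden association
#'
#' For each gene set, restricts it to genes with qualifying variants,
#' builds per-gene (or per-variant) carrier strata against the binary
#' phenotype and runs the CMH test. BH q-values are computed across the
#' testable sets of the analysis family.
#'
#' @param qvset result of [qualify_variants()].
#' @param genotypes dosage matrix (samples x variants).
#' @param catalog variant catalog.
#' @param collection [gene_set_collection()].
#' @param groups binary phenotype per sample.
#' @param mode `"exact"` or `"asymptotic"` CMH p-values.
#' @param stratify_by `"gene"` (default) or `"variant"`.
#' @param fdr_threshold FDR level for the significance flag.
#' @return data.frame: `set`, `or`, `ci_low`, `ci_high`, `p`, `q`,
#'   `strata_used`, `mode`, `testable`, `significant`.
#' @export
geneset_burden_test <- function(qvset, genotypes, catalog, collection, groups,
                                mode = c("exact", "asymptotic"),
                                stratify_by = c("gene", "variant"),
                                fdr_threshold = 0.05) {
  mode <- match.arg(mode)
  stratify_by <- match.arg(stratify_by)
  g <- as_binary_groups(groups)
  if (length(g) != nrow(genotypes)) {
    stop("groups length must match genotype rows", call. = FALSE)
  }
  qv_gene_pool <- qv_genes(qvset)
  rows <- lapply(names(collection), function(set_name) {
    genes <- intersect(collection[[set_name]], qv_gene_pool)
    if (length(genes) == 0L) {
      return(data.frame(set = set_name, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        strata_used = 0L, mode = mode, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    if (stratify_by == "gene") {
      carrier <- carrier_by_gene(qvset, genotypes, catalog, genes)
    } else {
      idx <- which(catalog$variant_id %in% qv_ids(qvset) &
                     catalog$gene %in% genes)
      carrier <- genotypes[, idx, drop = FALSE] >= 1L
      colnames(carrier) <- catalog$variant_id[idx]
    }
    strata <- build_strata(carrier, g)
    res <- cmh_test(strata, mode = mode)
    data.frame(set = set_name, or = res$mh_or, ci_low = res$ci95[1],
               ci_high = res$ci95[2], p = res$p_value,
               strata_used = res$strata_used, mode = mode,
               testable = !is.na(res$p_value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, fdr_threshold)
  out$q <- fdr$q
  out$significant <- fdr$reject
  out[c("set", "or", "ci_low", "ci_high", "p", "q", "strata_used",
        "mode", "testable", "significant")]
}

#' Bonferroni family-wise threshold
#' @param m number of tests.
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1)
  alpha / m
}

#' Exome-wide single-variant carrier scan
#'
#' Per variant, tests carrier status (dosage >= 1) against the binary
#' phenotype with Fisher's exact test. Variants without carriers are
#' skipped and counted. The result carries the QQ-plot coordinates
#' (expected `-log10((i - 0.5) / m)` against sorted observed), the
#' Bonferroni threshold `alpha / m`, and the genomic inflation factor
#' lambda (median observed 1-df chi-square over its null median).
#'
#' @param catalog variant catalog.
#' @param genotypes dosage matrix (samples x variants).
#' @param groups binary phenotype per sample.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @return list of class `scan_result`: `tests` (data.frame `variant_id`,
#'   `p`), `n_tested`, `n_skipped`, `bonferroni`, `lambda`, `qq`
#'   (data.frame `expected`, `observed`, -log10 scale).
#' @export
exome_wide_scan <- function(catalog, genotypes, groups, alpha = 0.05) {
  g <- as_binary_groups(groups)
  carrier_mat <- genotypes >= 1L
  p <- rep(NA_real_, nrow(catalog))
  for (j in seq_len(nrow(catalog))) {
    cj <- carrier_mat[, j]
    ok <- !is.na(cj)
    if (!any(cj[ok])) next
    a <- sum(cj[ok] & g[ok] == levels(g)[1])
    b <- sum(!cj[ok] & g[ok] == levels(g)[1])
    c <- sum(cj[ok] & g[ok] == levels(g)[2])
    d <- sum(!cj[ok] & g[ok] == levels(g)[2])
    p[j] <- fisher_exact(c(a, b, c, d))$p_value
  }
  tested <- !is.na(p)
  m <- sum(tested)
  obs <- sort(p[tested])
  chi <- stats::qchisq(p[tested], df = 1, lower.tail = FALSE)
  lambda <- stats::median(chi) / stats::qchisq(0.5, df = 1)
  structure(list(
    tests = data.frame(variant_id = catalog$variant_id, p = p,
                       stringsAsFactors = FALSE),
    n_tested = m, n_skipped = sum(!tested),
    bonferroni = bonferroni_threshold(m, alpha),
    lambda = lambda,
    qq = data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                    observed = -log10(obs))),
    class = "scan_result")
}
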