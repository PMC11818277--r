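# Elementary statistics used throughout the pipeline, as pure functions
# with fixed, documented conventions.

qv_test_result <- function(statistic, p_value, method, estimate = NA_real_,
                           ci = c(NA_real_, NA_real_), sided = "two-sided",
                           flags = character(0)) {
  structure(list(statistic = statistic, p_value = p_value,
                 estimate = estimate, ci = ci, method = method,
                 sided = sided, flags = flags),
            class = "qv_test")
}

#' @export
print.qv_test <- function(x, ...) {
  cat(x$method, " (", x$sided, ")\n", sep = "")
  cat("  statistic =", format(x$statistic), " p =", format(x$p_value), "\n")
  if (!is.na(x$estimate)) {
    cat("  estimate =", format(x$estimate),
        " 95% CI [", format(x$ci[1]), ",", format(x$ci[2]), "]\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

as_table2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2L, 2L)))
    x <- as.vector(t(table))
  } else {
    stopifnot(length(table) == 4L)
    x <- as.numeric(table)
  }
  if (any(x < 0) || any(x != floor(x))) {
    stop("2x2 cells must be non-negative integers", call. = FALSE)
  }
  x  # a, b, c, d: rows = group, cols = trait present/absent
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood convention: the sum of
#' central-hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table.
#' The estimate is the sample odds ratio `ad/bc`. A zero margin yields a
#' degenerate result with p = 1 and a flag.
#'
#' @param table 2x2 matrix (rows = group, cols = trait present/absent) or a
#'   length-4 vector `c(a, b, c, d)`.
#' @return `qv_test` result.
#' @export
fisher_exact <- function(table) {
  x <- as_table2x2(table)
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  r1 <- a + b; c1 <- a + c; n <- sum(x)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    return(qv_test_result(NA_real_, 1, "Fisher exact", flags = "zero margin"))
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  qv_test_result(statistic = a, p_value = p, method = "Fisher exact",
                 estimate = or)
}

#' Chi-square test for a 2x2 table with Yates' continuity correction
#'
#' Statistic `n (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped at 0
#' when `|ad - bc| <= n/2`; p from the chi-square distribution with 1 df.
#'
#' @inheritParams fisher_exact
#' @return `qv_test` result.
#' @export
yates_chi2 <- function(table) {
  x <- as_table2x2(table)
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  n <- sum(x)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) {
    return(qv_test_result(NA_real_, 1, "Yates chi-square", flags = "zero margin"))
  }
  delta <- abs(a * d - b * c)
  stat <- if (delta <= n / 2) 0 else n * (delta - n / 2)^2 / denom
  qv_test_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 "Yates chi-square", estimate = (a * d) / (b * c))
}

#' Likelihood-ratio (G) test of independence for an r x c table
#'
#' `G = 2 * sum(O * log(O / E))` over cells with positive observed counts;
#' df = (r-1)(c-1). All-zero rows or columns are dropped with a warning and
#' the df adjusted.
#'
#' @param table non-negative integer matrix.
#' @return `qv_test` result.
#' @export
g_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  keep_r <- rowSums(table) > 0; keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero row(s)/column(s); df adjusted")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  n <- sum(table)
  if (n == 0) stop("table total must be positive", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / n
  obs <- table[table > 0]
  g <- 2 * sum(obs * log(obs / expected[table > 0]))
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  p <- if (df == 0L) 1 else stats::pchisq(g, df = df, lower.tail = FALSE)
  qv_test_result(g, p, sprintf("G-test (df = %d)", df))
}

# U statistic for sample x against y (count of pairs x < y plus half-ties)
mwu_u <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Exact mode enumerates every assignment of the pooled values to the two
#' groups (handles ties; feasible for small samples) and reports the
#' two-sided p as the probability of a U at least as far from its null mean
#' as observed. Normal mode uses the tie-corrected normal approximation
#' with a 0.5 continuity correction.
#'
#' @param x,y numeric samples.
#' @param mode `"exact"` or `"normal"`.
#' @param max_exact_n refuse exact enumeration above this pooled size.
#' @return `qv_test` result (statistic is U for the first sample).
#' @export
mann_whitney_u <- function(x, y, mode = c("normal", "exact"),
                           max_exact_n = 20L) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u_obs <- mwu_u(x, y)
  if (length(unique(pooled)) == 1L) {
    return(qv_test_result(u_obs, 1, "Mann-Whitney U", flags = "all values identical"))
  }
  mu <- n1 * n2 / 2
  if (mode == "exact") {
    if (n > max_exact_n) {
      stop("exact mode limited to pooled n <= ", max_exact_n, call. = FALSE)
    }
    combos <- utils::combn(n, n1)
    r <- rank(pooled)
    us <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    return(qv_test_result(u_obs, p, "Mann-Whitney U (exact)"))
  }
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(qv_test_result(u_obs, 1, "Mann-Whitney U", flags = "degenerate variance"))
  }
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  qv_test_result(u_obs, min(1, 2 * stats::pnorm(-z)),
                 "Mann-Whitney U (normal approximation)")
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of mid-ranks; the p-value uses the
#' t-approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return `qv_test` result (estimate is rho).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(qv_test_result(NA_real_, NA_real_, "Spearman correlation",
                          flags = "constant input"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  qv_test_result(rho, p, "Spearman correlation", estimate = rho)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] (Royston's algorithm) with
#' the pipeline's result container and explicit sample-size validation.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return `qv_test` result (statistic is W).
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  qv_test_result(unname(sw$statistic), sw$p.value, "Shapiro-Wilk")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values (via [stats::p.adjust()]) and rejection flags at a
#' threshold. Significance is `q < threshold`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param threshold FDR level (default 0.05).
#' @return list with `q` (adjusted values) and `reject` (logical).
#' @export
bh_fdr <- function(p_values, threshold = 0.05) {
  if (length(p_values) == 0L) {
    return(list(q = numeric(0), reject = logical(0)))
  }
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, reject = !is.na(q) & q < threshold)
}
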