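# Shared fixtures and independent oracles, built in code.

# small annotated catalog + genotype matrix with known composition
make_toy_cohort <- function(n_samples = 6L, n_hi = 3L, n_mis = 2L,
                            n_syn = 2L, seed = 1L) {
  set.seed(seed)
  m <- n_hi + n_mis + n_syn
  consequence <- c(rep("stop_gained", n_hi), rep("missense_variant", n_mis),
                   rep("synonymous_variant", n_syn))
  catalog <- variant_catalog(data.frame(
    chrom = "1", pos = seq_len(m) * 10L, ref = "A", alt = "G",
    gene = paste0("GENE", seq_len(m)), consequence = consequence,
    pop_af = c(rep(NA_real_, n_hi), rep(0.005, n_mis), rep(0.2, n_syn)),
    stringsAsFactors = FALSE))
  genotypes <- matrix(rbinom(n_samples * m, 2L, 0.15), n_samples, m,
                      dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                      catalog$variant_id))
  list(catalog = catalog, genotypes = genotypes)
}

# independent Fisher two-sided oracle: full enumeration over tables with
# the observed margins, probabilities from log-binomial coefficients
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent exact CMH oracle: exhaustive enumeration of all a-cell
# vectors compatible with the per-stratum margins
cmh_enum_oracle <- function(strata) {
  k <- dim(strata)[3]
  supports <- list(); pmfs <- list()
  for (j in seq_len(k)) {
    a <- strata[1, 1, j]; b <- strata[1, 2, j]
    c <- strata[2, 1, j]; d <- strata[2, 2, j]
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    supp <- max(0, r1 + c1 - n):min(r1, c1)
    supports[[j]] <- supp
    pmfs[[j]] <- dhyper(supp, c1, n - c1, r1)
  }
  grid <- expand.grid(lapply(supports, seq_along))
  s_obs <- sum(strata[1, 1, ])
  total <- apply(grid, 1L, function(ix) {
    sum(vapply(seq_len(k), function(j) supports[[j]][ix[j]], numeric(1)))
  })
  prob <- apply(grid, 1L, function(ix) {
    prod(vapply(seq_len(k), function(j) pmfs[[j]][ix[j]], numeric(1)))
  })
  p_le <- sum(prob[total <= s_obs])
  p_ge <- sum(prob[total >= s_obs])
  min(1, 2 * min(p_le, p_ge))
}

# random 2x2 with all margins positive and total <= n_max
random_table2x2 <- function(n_max = 30L) {
  repeat {
    n <- sample(4:n_max, 1L)
    x <- as.vector(rmultinom(1L, n, prob = runif(4, 0.05, 1)))
    if (all(x[1] + x[2] > 0, x[3] + x[4] > 0, x[1] + x[3] > 0,
            x[2] + x[4] > 0)) {
      return(x)
    }
  }
}

expect_file_md5_equal <- function(path_a, path_b) {
  expect_identical(unname(tools::md5sum(path_a)), unname(tools::md5sum(path_b)))
}
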