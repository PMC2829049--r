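# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: multinomial probabilities come from
# stats::dmultinom, maximization is a dense grid search, pairwise diversity
# is literal pair enumeration, and smoothing is the O(sites x windows)
# double loop.

nuc_order <- c("A", "C", "G", "T")

# multinomial log-likelihood of a genotype via stats::dmultinom
oracle_loglik <- function(counts, alleles, eps) {
  probs <- rep(eps / 4, 4)
  if (alleles[1] == alleles[2]) {
    probs[alleles[1]] <- 1 - 3 * eps / 4
  } else {
    probs[alleles] <- 1 / 2 - eps / 4
  }
  stats::dmultinom(counts, prob = probs, log = TRUE)
}

# grid-search profile of the error rate for one hypothesis
oracle_grid_mle <- function(counts, alleles, step = 1e-4, eps_max = 1) {
  grid <- seq(0, eps_max, by = step)
  n <- sum(counts)
  if (alleles[1] == alleles[2]) {
    ni <- counts[alleles[1]]
    ll <- ni * log(1 - 3 * grid / 4) + (n - ni) * ifelse(grid == 0, ifelse(n - ni == 0, 0, -Inf), log(grid / 4))
    if (n - ni == 0) ll <- ni * log(1 - 3 * grid / 4)
  } else {
    nij <- counts[alleles[1]] + counts[alleles[2]]
    rest <- n - nij
    ll <- nij * log(1 / 2 - grid / 4) +
      rest * ifelse(grid == 0, ifelse(rest == 0, 0, -Inf), log(grid / 4))
    if (rest == 0) ll <- nij * log(1 / 2 - grid / 4)
  }
  i <- which.max(ll)
  list(eps = grid[i], loglik = ll[i] + lgamma(n + 1) - sum(lgamma(counts + 1)))
}

# nucleotide diversity by literal enumeration of all allele pairs
oracle_pi <- function(counts) {
  alleles <- rep(seq_along(counts), counts)
  if (length(alleles) < 2) return(NA_real_)
  pairs <- utils::combn(alleles, 2)
  mean(pairs[1, ] != pairs[2, ])
}

# O(sites x windows) kernel smoothing with no windowing shortcuts
oracle_smooth <- function(pos, value, n_k, centers, sigma, truncation, step_fun) {
  vapply(centers, function(cc) {
    d <- abs(pos - cc)
    k <- ifelse(d <= truncation * sigma, exp(-(pos - cc)^2 / (2 * sigma^2)), 0) *
      step_fun(n_k)
    if (sum(k) == 0) return(NA_real_)
    sum(k * value) / sum(k)
  }, numeric(1))
}

# exhaustive bootstrap null: every pool assignment of a <=3-site window
oracle_exhaustive_p <- function(obs, kern, pool_v, pool_w) {
  m <- length(kern)
  idx <- as.matrix(expand.grid(rep(list(seq_along(pool_v)), m)))
  vals <- apply(idx, 1, function(ii) {
    kw <- kern * pool_w[ii]
    sum(kw * pool_v[ii]) / sum(kw)
  })
  c(p_elev = mean(vals >= obs), p_red = mean(vals <= obs))
}

# Weir & Cockerham variance-partitioning theta for one biallelic SNP
# (haploid/allele-count form): p_j = allele frequencies, m_j = allele counts
oracle_wc_theta <- function(p_j, m_j) {
  r <- length(p_j)
  nbar <- mean(m_j)
  nc <- (sum(m_j) - sum(m_j^2) / sum(m_j)) / (r - 1)
  pbar <- sum(m_j * p_j) / sum(m_j)
  s2 <- sum(m_j * (p_j - pbar)^2) / ((r - 1) * nbar)
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- (nbar / nc) * (s2 - inner / (nbar - 1))
  b <- (nbar / (nbar - 1)) * inner
  if (a + b == 0) return(NA_real_)
  a / (a + b)
}

# quick counts-table builder: one individual per row of `reads`
make_counts <- function(reads, chrom = "chrI", pos = 1L) {
  tibble::tibble(
    chrom = chrom, pos = pos,
    individual = sprintf("ind_%02d", seq_len(nrow(reads))),
    nA = reads[, 1], nC = reads[, 2], nG = reads[, 3], nT = reads[, 4]
  )
}

# a small two-population call set built directly from genotype strings
make_calls <- function(genos_by_pop, chrom = "chrI", pos = 1L) {
  pops <- names(genos_by_pop)
  rows <- purrr::imap(genos_by_pop, function(g, p) {
    tibble::tibble(
      chrom = chrom, pos = pos,
      individual = sprintf("%s_%02d", p, seq_along(g)),
      n = 10L,
      status = ifelse(is.na(g), "unassigned", "assigned"),
      genotype = g,
      allele1 = substr(g, 1, 1),
      allele2 = substr(g, 3, 3),
      lrt = 10, epsilon = 0, log_lik = -1
    )
  })
  calls <- dplyr::bind_rows(rows)
  popmap <- dplyr::distinct(
    tibble::tibble(individual = calls$individual,
                   pop = sub("_[0-9]+$", "", calls$individual))
  )
  list(calls = calls, popmap = popmap)
}
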