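small_genome <- tibble::tibble(chrom = "chrI", length = 4e5)

two_pop_cfg <- function(...) {
  sim_config(
    genome = small_genome,
    populations = tibble::tibble(pop = c("P1", "P2"), type = c("oceanic", "oceanic"),
                                 n_ind = 20L, f = c(0.1, 0.1)),
    scenarios = list(),
    ...
  )
}

test_that("drifted frequencies have Balding-Nichols moments", {
  set.seed(61)
  p <- draw_population_frequencies(rep(0.5, 1e5), f = 0.1)
  expect_equal(mean(p), 0.5, tolerance = 0.01)
  expect_equal(var(p), 0.1 * 0.25, tolerance = 0.05)
  # tiny drift returns nearly the ancestral frequency
  p2 <- draw_population_frequencies(rep(0.3, 1e4), f = 1e-6)
  expect_lt(max(abs(p2 - 0.3)), 0.05)
  # boundaries pass through untouched
  expect_equal(draw_population_frequencies(c(0, 1), f = 0.2), c(0, 1))
  expect_error(draw_population_frequencies(0.5, f = 0), "f > 0")
})

test_that("the weighted FST of two drifted populations matches its analytic expectation", {
  # with plug-in diversities, E[1 - pi_W/pi_T] at large samples is
  # (F/2) / (1 - F/2) for two populations at the same drift F,
  # not F itself: the pooled-pair diversity only doubles the between-pop
  # pair fraction. Monte-Carlo against that closed form.
  set.seed(62)
  f <- 0.1
  fst_vals <- replicate(4000, {
    p0 <- runif(1, 0.2, 0.8)
    p <- draw_population_frequencies(rep(p0, 2), f)
    m <- 1e4  # large allele sample: estimator noise ~ 0
    c1 <- round(p[1] * m)
    c2 <- round(p[2] * m)
    fst(rbind(c(c1, m - c1), c(c2, m - c2)))
  })
  expected <- (f / 2) / (1 - f / 2)
  expect_equal(mean(fst_vals, na.rm = TRUE), expected, tolerance = 0.15)
})

test_that("scenarios modify frequencies only inside their footprint", {
  pops <- tibble::tibble(pop = c("O1", "F1", "F2"),
                         type = c("oceanic", "freshwater", "freshwater"),
                         n_ind = 10L, f = c(0.01, 0.1, 0.1))
  sites <- tibble::tibble(chrom = "chrI",
                          pos = c(5e4, 2.3e5, 2.0e5, 2.1e5, 3.5e5),
                          p0 = c(0.1, 0.2, 0.1, 0, 0.3))
  freq <- matrix(rep(sites$p0, 3), ncol = 3,
                 dimnames = list(NULL, pops$pop))

  expect_identical(apply_scenarios(freq, sites, list(), pops), freq)

  sw <- scenario_sweep("chrI", 2e5, 4e4, pops = c("F1", "F2"), taper = 2e4)
  out <- apply_scenarios(freq, sites, list(sw), pops)
  # inside the core, targets reach the final frequency; oceanic untouched
  expect_equal(unname(out[3, "F1"]), 0.95)
  expect_equal(unname(out[3, "F2"]), 0.95)
  expect_equal(unname(out[3, "O1"]), 0.1)
  # monomorphic site inside the core stays monomorphic
  expect_equal(unname(out[4, "F1"]), 0)
  # sites beyond core + taper are untouched
  expect_equal(out[c(1, 5), ], freq[c(1, 5), ])
  # taper midpoint: site at 2.3e5 is 1e4 beyond the core edge (2.2e5),
  # halfway through the 2e4 taper
  expect_equal(unname(out[2, "F1"]), 0.5 * 0.95 + 0.5 * 0.2)

  bal <- scenario_balancing("chrI", 2e5, 4e4, freq = 0.5, taper = 2e4)
  outb <- apply_scenarios(freq, sites, list(bal), pops)
  expect_equal(unname(outb[3, ]), rep(0.5, 3))

  expect_error(apply_scenarios(freq, sites, list(sw, bal), pops), "overlapping")
})

test_that("parallel sweeps push one shared allele; non-parallel sweeps differ between targets", {
  set.seed(63)
  pops <- tibble::tibble(pop = c("F1", "F2", "F3"), type = "freshwater",
                         n_ind = 10L, f = 0.1)
  n <- 400
  sites <- tibble::tibble(chrom = "chrI", pos = seq_len(n) * 100,
                          p0 = runif(n, 0.02, 0.3))
  freq <- matrix(rep(sites$p0, 3), ncol = 3, dimnames = list(NULL, pops$pop))
  core <- scenario_sweep("chrI", 2e4, 2e4, pops = pops$pop, taper = 0)
  inside <- abs(sites$pos - 2e4) <= 1e4

  par_out <- apply_scenarios(freq, sites, list(core), pops)
  expect_true(all(par_out[inside, ] == 0.95))

  core$parallel <- FALSE
  np_out <- apply_scenarios(freq, sites, list(core), pops)
  # each target swept to 0.95 of *some* allele: derived freq near 0.95 or 0.05
  swept_high <- np_out[inside, ] > 0.9
  swept_low <- np_out[inside, ] < 0.1
  expect_true(all(swept_high | swept_low))
  # and the choices disagree between populations at a substantial share of sites
  expect_gt(mean(rowSums(swept_high[, 1:3]) %in% 1:2), 0.2)
})

test_that("read emission reflects the generative model exactly in easy regimes", {
  # error-free, deep, no dropout: every polymorphic site recovered perfectly
  cfg <- two_pop_cfg(coverage = 30, error = 0, dropout_freq = 0)
  sim <- simulate_radseq(cfg, seed = 3)
  calls <- call_genotypes(sim$counts)
  ok <- calls$status == "assigned"
  expect_gt(mean(ok), 0.99)
  expect_equal(mean(calls$genotype[ok] == sim$truth$calls$genotype[ok]), 1)

  # universal dropout: no reads at all
  cfg2 <- two_pop_cfg(dropout_freq = 0.999999)
  sim2 <- simulate_radseq(cfg2, seed = 4)
  expect_true(all(sim2$counts[c("nA", "nC", "nG", "nT")] == 0))

  # homozygous-dropout individuals yield zero reads across the whole tag
  cfg3 <- two_pop_cfg(coverage = 30, error = 0, dropout_freq = 0.3)
  sim3 <- simulate_radseq(cfg3, seed = 5)
  depth <- rowSums(sim3$counts[c("nA", "nC", "nG", "nT")])
  expect_true(all(depth[sim3$truth$calls$dropout == 2L] == 0))

  # heterozygous-dropout true heterozygotes show reads for only one allele
  het <- sim3$truth$calls$dropout == 1L &
    substr(sim3$truth$calls$genotype, 1, 1) != substr(sim3$truth$calls$genotype, 3, 3) &
    depth > 0
  reads <- sim3$counts[het, c("nA", "nC", "nG", "nT")]
  expect_true(all(rowSums(reads > 0) == 1))
})

test_that("restriction-site dropout biases diversity downward, never upward", {
  # mechanism, exactly: a heterozygous-dropout heterozygote contributes two
  # copies of one random haplotype instead of one copy of each. Averaging
  # over the two retention outcomes always lowers pi (the duplicated pair is
  # forcibly identical), for every allele configuration
  set.seed(64)
  for (i in 1:50) {
    base <- as.vector(stats::rmultinom(1, sample(10:60, 1), runif(4)))
    alleles <- which(base > 0)
    if (length(alleles) < 2) next
    het <- sample(alleles, 2)
    counts <- base
    counts[het] <- counts[het] + 1           # add the het individual
    keep1 <- keep2 <- counts
    keep1[het[2]] <- keep1[het[2]] - 1; keep1[het[1]] <- keep1[het[1]] + 1
    keep2[het[1]] <- keep2[het[1]] - 1; keep2[het[2]] <- keep2[het[2]] + 1
    expected_after <- mean(c(nucleotide_diversity(keep1),
                             nucleotide_diversity(keep2)))
    expect_lt(expected_after, nucleotide_diversity(counts))
  }

  # and in aggregate on reads: with every site polymorphic at intermediate
  # frequency the many small substitutions dominate their sampling noise
  for (seed in 1:2) {
    sim <- simulate_radseq(two_pop_cfg(coverage = 30, error = 0,
                                       dropout_freq = 0.2, poly_rate = 1,
                                       freq_grid = 0.5), seed = seed)
    calls <- call_genotypes(sim$counts)
    asn <- calls$status == "assigned"
    truth_sub <- dplyr::mutate(
      sim$truth$calls[asn, ],
      status = "assigned",
      allele1 = substr(genotype, 1, 1), allele2 = substr(genotype, 3, 3),
      n = 1L, lrt = 99, epsilon = 0, log_lik = 0
    )
    pi_est <- mean(site_stats(allele_counts(calls[asn, ], sim$popmap))$pi,
                   na.rm = TRUE)
    pi_tru <- mean(site_stats(allele_counts(truth_sub, sim$popmap))$pi,
                   na.rm = TRUE)
    expect_lt(pi_est, pi_tru)
  }
})

test_that("simulation is reproducible from the master seed", {
  s1 <- simulate_radseq(two_pop_cfg(), seed = 11)
  s2 <- simulate_radseq(two_pop_cfg(), seed = 11)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$frequencies, s2$truth$frequencies)
  s3 <- simulate_radseq(two_pop_cfg(), seed = 12)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("the pipeline recovers the simulated differentiation level", {
  # genome-wide mean per-SNP FST from noisy reads should track the value
  # computed from the true genotypes (the sequencing-free oracle) within 20%
  sim <- simulate_radseq(two_pop_cfg(coverage = 20, error = 0.01), seed = 21)
  pools <- list(P1 = "P1", P2 = "P2")
  est <- site_stats(allele_counts(call_genotypes(sim$counts), sim$popmap), pools)

  truth_calls <- dplyr::mutate(
    sim$truth$calls,
    status = "assigned",
    allele1 = substr(genotype, 1, 1),
    allele2 = substr(genotype, 3, 3),
    n = 1L, lrt = 99, epsilon = 0, log_lik = 0
  )
  tru <- site_stats(allele_counts(truth_calls, sim$popmap), pools)
  m_est <- mean(est$fst, na.rm = TRUE)
  m_tru <- mean(tru$fst, na.rm = TRUE)
  expect_lt(abs(m_est - m_tru) / m_tru, 0.2)
})
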