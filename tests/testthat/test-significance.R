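genome1 <- tibble::tibble(chrom = "chrI", length = 1e6)

small_plan <- bootstrap_plan("fst", initial = 1000, cap = 1e5, trigger = 10)

test_that("degenerate windows get the exact degenerate p-values", {
  # homogeneous pool: every replicate equals the observed value
  # 0.25 is exact in binary, so observed and resampled window averages tie
  stats <- tibble::tibble(chrom = "chrI", pos = seq(1e4, 9.9e5, by = 1e4),
                          n_k = 20, fst = 0.25)
  tr <- smooth_track(stats, genome1, "fst", sigma = 5e4, step = 1e5)
  bt <- bootstrap_track(tr, stats, "fst", plan = small_plan, seed = 5,
                        sigma = 5e4)
  expect_true(all(bt$p_elevated == 1))
  expect_true(all(bt$p_reduced == 1))

  # observed above every pool value: zero tail at the cap, flagged
  stats2 <- stats
  stats2$fst <- runif(nrow(stats2), 0, 0.2)
  tr2 <- smooth_track(stats2, genome1, "fst", sigma = 5e4, step = 1e5)
  tr2$value[3] <- 0.9
  bt2 <- bootstrap_track(tr2, stats2, "fst", plan = small_plan, seed = 5,
                         sigma = 5e4)
  expect_equal(bt2$p_elevated[3], 0)
  expect_equal(bt2$p_reduced[3], 1)
  expect_equal(bt2$replicates[3], small_plan$cap)
  expect_equal(bt2$flag[3], "<1/R")
})

test_that("bootstrap p-values match exhaustive enumeration on tiny windows", {
  set.seed(51)
  cases <- list(
    list(kern = c(1, 0.6, 0.2), pool_v = c(0.1, 0.5, 0.9, 0.3, 0.7),
         pool_w = c(10, 20, 5, 40, 15), obs = 0.55),
    list(kern = c(1, 0.3), pool_v = c(0.2, 0.8, 0.5), pool_w = c(1, 1, 1),
         obs = 0.5),
    list(kern = c(0.9, 0.9, 0.1), pool_v = c(0, 1, 0.25, 0.75, 0.5),
         pool_w = c(2, 2, 2, 2, 2), obs = 0.8)
  )
  for (cs in cases) {
    exact <- oracle_exhaustive_p(cs$obs, cs$kern, cs$pool_v, cs$pool_w)
    got <- radscan:::window_bootstrap(
      cs$obs, cs$kern, cs$pool_v, cs$pool_w,
      bootstrap_plan("fst", initial = 1e6, cap = 1e6), seeds = 987654321
    )
    expect_equal(got[1], exact[["p_elev"]], tolerance = 5e-3)
    expect_equal(got[2], exact[["p_red"]], tolerance = 5e-3)
  }
})

test_that("p_elevated is monotone non-increasing in the observed value", {
  kern <- c(1, 0.8, 0.5, 0.2)
  pool_v <- runif(30)
  pool_w <- rep(1, 30)
  p <- vapply(seq(0.1, 0.9, by = 0.1), function(obs) {
    radscan:::window_bootstrap(obs, kern, pool_v, pool_w,
                               bootstrap_plan("fst", initial = 1e5, cap = 1e5),
                               seeds = 42L)[1]
  }, numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("the significance stage is reproducible from one master seed", {
  set.seed(52)
  stats <- tibble::tibble(chrom = "chrI", pos = sort(sample(1e6, 200)),
                          n_k = sample(10:40, 200, replace = TRUE),
                          fst = rbeta(200, 1, 8))
  tr <- smooth_track(stats, genome1, "fst", sigma = 5e4, step = 1e5)
  plan <- bootstrap_plan("fst", initial = 500, cap = 5000)
  b1 <- bootstrap_track(tr, stats, "fst", plan = plan, seed = 9, sigma = 5e4)
  b2 <- bootstrap_track(tr, stats, "fst", plan = plan, seed = 9, sigma = 5e4)
  expect_identical(b1, b2)
  b3 <- bootstrap_track(tr, stats, "fst", plan = plan, seed = 10, sigma = 5e4)
  expect_false(identical(b1$p_elevated, b3$p_elevated))
})

test_that("escalation runs more replicates only where the tail demands it", {
  set.seed(53)
  stats <- tibble::tibble(chrom = "chrI", pos = sort(sample(1e6, 300)),
                          n_k = 20, fst = rbeta(300, 2, 8))
  tr <- smooth_track(stats, genome1, "fst", sigma = 5e4, step = 1e5)
  tr$value[5] <- quantile(stats$fst, 0.999)  # extreme but below max
  plan <- bootstrap_plan("fst", initial = 200, cap = 2e4, trigger = 10)
  bt <- bootstrap_track(tr, stats, "fst", plan = plan, seed = 3, sigma = 5e4)
  expect_gt(bt$replicates[5], 200)
  expect_true(any(bt$replicates == 200))
})

test_that("Tajima bootstrap handles undefined replicates and direction", {
  set.seed(54)
  stats <- tibble::tibble(chrom = "chrI", pos = sort(sample(1e6, 400)),
                          n_k = sample(10:40, 400, replace = TRUE),
                          pi = rbeta(400, 0.5, 4),
                          is_snp = runif(400) < 0.5)
  tr <- tajima_track(stats, genome1, sigma = 5e4, step = 1e5)
  bt <- bootstrap_tajima(tr, stats, plan = bootstrap_plan("d", initial = 500, cap = 5000),
                         seed = 4, sigma = 5e4)
  ok <- !is.na(bt$p_elevated)
  expect_true(any(ok))
  expect_true(all(bt$p_elevated[ok] >= 0 & bt$p_elevated[ok] <= 1))
  expect_true(all(bt$p_elevated[ok] + bt$p_reduced[ok] <= 2))
})

test_that("bootstrap p-values are approximately uniform on a neutral genome", {
  set.seed(55)
  # disjoint windows (truncation radius below half the step), homogeneous null
  stats <- tibble::tibble(chrom = "chrI",
                          pos = sort(sample(2e7, 6000)),
                          n_k = sample(10:40, 6000, replace = TRUE),
                          fst = rbeta(6000, 1.5, 10))
  genome <- tibble::tibble(chrom = "chrI", length = 2e7)
  tr <- smooth_track(stats, genome, "fst", sigma = 15000, step = 1e5)
  bt <- bootstrap_track(tr, stats, "fst",
                        plan = bootstrap_plan("fst", initial = 2000, cap = 2e4),
                        seed = 6, sigma = 15000)
  p <- bt$p_elevated[!is.na(bt$p_elevated)]
  expect_gt(length(p), 150)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.001)
})

test_that("Benjamini-Hochberg step-up matches hand-worked cases", {
  r <- bh_correct(c(0.01, 0.02, 0.9, 1.0), alpha = 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$n_reject, 2L)
  expect_equal(r$threshold, 2 * 0.05 / 4)
  expect_equal(bh_correct(rep(1, 10), 0.05)$n_reject, 0L)
  expect_equal(bh_correct(numeric(0), 0.05)$n_reject, 0L)
  expect_error(bh_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  # order-independence
  p <- c(0.04, 0.001, 0.9, 0.012, 0.2)
  expect_equal(sum(bh_correct(p, 0.05)$reject),
               sum(bh_correct(rev(p), 0.05)$reject))
})

test_that("regions require significance in every track, grow margins and merge", {
  mk_track <- function(p) {
    tibble::tibble(chrom = "chrI", center = seq(5e4, 9.5e5, by = 1e5),
                   value = 0.1 + as.numeric(p < 1e-5), p_elevated = p)
  }
  base <- rep(0.5, 10)
  p1 <- base; p1[4] <- 1e-7
  r <- delineate_regions(mk_track(p1), threshold = 1e-5, genome = genome1,
                         sigma = 5e4)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(3.5e5 - 1e5, 3.5e5 + 1e5))
  expect_equal(r$peak_center, 3.5e5)

  # two adjacent significant windows merge into one region
  p2 <- base; p2[4:5] <- 0
  r2 <- delineate_regions(mk_track(p2), threshold = 1e-5, genome = genome1,
                          sigma = 5e4)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(2.5e5, 5.5e5))

  # a window failing in one of the required tracks vetoes the region
  p3 <- base; p3[4] <- 1e-3
  r3 <- delineate_regions(list(mk_track(p1), mk_track(p3)), threshold = 1e-5,
                          genome = genome1, sigma = 5e4)
  expect_equal(nrow(r3), 0)

  # margins clip at chromosome bounds
  p4 <- base; p4[1] <- 0; p4[10] <- 0
  r4 <- delineate_regions(mk_track(p4), threshold = 1e-5, genome = genome1,
                          sigma = 5e4)
  expect_equal(r4$start[1], 1)
  expect_equal(r4$end[2], 1e6)

  # nearby runs merge once 2-sigma margins overlap
  p5 <- base; p5[4] <- 0; p5[6] <- 0
  r5 <- delineate_regions(mk_track(p5), threshold = 1e-5, genome = genome1,
                          sigma = 5e4)
  expect_equal(nrow(r5), 1)

  # mismatched grids are an error
  t_bad <- mk_track(p1); t_bad$center <- t_bad$center + 1
  expect_error(delineate_regions(list(mk_track(p1), t_bad)), "grid")
})
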