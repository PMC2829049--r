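#' Truncated Gaussian kernel weight
#'
#' Weight of a site at position `p` contributing to a window centred at `c`:
#' `exp(-(p - c)^2 / (2 * sigma^2))` when `|p - c| <= truncation * sigma`,
#' and 0 beyond the truncation radius.
#'
#' @param pos,center Genomic positions in bp (vectorised).
#' @param sigma Kernel bandwidth in bp (default 150000).
#' @param truncation Truncation radius as a multiple of `sigma` (default 3;
#'   sites beyond it have relative weight below about 0.011).
#' @return Numeric weights in `[0, 1]`.
#' @examples
#' kernel_weight(0, 0)                 # 1
#' kernel_weight(150000, 0)            # exp(-1/2)
#' kernel_weight(450001, 0)            # 0, beyond 3 sigma
#' @export
kernel_weight <- function(pos, center, sigma = 150000, truncation = 3) {
  stopifnot(sigma > 0, truncation >= 1)
  d <- pos - center
  ifelse(abs(d) <= truncation * sigma, exp(-d^2 / (2 * sigma^2)), 0)
}

site_weight <- function(n_k, mode = c("npairs", "n", "nm1")) {
  mode <- match.arg(mode)
  switch(mode,
    npairs = n_k * (n_k - 1),
    n = n_k,
    nm1 = n_k - 1
  )
}

window_centers <- function(genome, step) {
  stopifnot(step > 0)
  purrr::map2(genome$chrom, genome$length, function(ch, len) {
    tibble::tibble(chrom = ch, center = seq(step / 2, len, by = step))
  }) %>% dplyr::bind_rows()
}

#' Kernel-smoothed genome-wide track of a per-site statistic
#'
#' Produces a weighted moving average of a per-site statistic along each
#' chromosome. The window value at centre `c` is
#' `sum_k x_k * K(p_k, c) * w(n_k) / sum_k K(p_k, c) * w(n_k)`, where `K` is
#' the truncated Gaussian [kernel_weight()] and `w(n_k)` weights each site by
#' its allele sample size (default `n_k * (n_k - 1)`, the number of allele
#' pairs behind a pairwise diversity estimate). Centres are placed on an
#' arithmetic grid at `step/2, 3*step/2, ...` along each chromosome. Sites
#' with `NA` statistic values are dropped, so SNP-undefined statistics (FST,
#' rho) are smoothed over SNPs only while `pi`/`h` use every sequenced site.
#' Windows with no contributing site are kept with `value = NA`.
#'
#' @param stats Per-site statistics from [site_stats()] (columns `chrom`,
#'   `pos`, `n_k` plus the statistic).
#' @param genome Tibble with columns `chrom`, `length` (bp).
#' @param value Name of the statistic column to smooth (string), e.g.
#'   `"fst"`.
#' @param sigma,truncation Kernel parameters, see [kernel_weight()].
#' @param step Spacing of window centres in bp (default 100000).
#' @param weight Site-weight mode: `"npairs"` (`n_k * (n_k - 1)`, default),
#'   `"n"`, or `"nm1"`.
#' @return A tibble with columns `chrom`, `center`, `value`, `n_sites`
#'   (contributing sites) and `sum_weight`.
#' @examples
#' stats <- tibble::tibble(chrom = "chrI", pos = c(1e5, 3e5), n_k = 40,
#'                         fst = c(0.1, 0.3))
#' genome <- tibble::tibble(chrom = "chrI", length = 5e5)
#' smooth_track(stats, genome, "fst", sigma = 1e5, step = 1e5)
#' @export
smooth_track <- function(stats, genome, value, sigma = 150000,
                         truncation = 3, step = 100000,
                         weight = c("npairs", "n", "nm1")) {
  weight <- match.arg(weight)
  if (!value %in% names(stats)) {
    stop("no column '", value, "' in stats", call. = FALSE)
  }
  if (!all(stats$chrom %in% genome$chrom)) {
    stop("stats contain chromosomes absent from the genome table", call. = FALSE)
  }
  keep <- !is.na(stats[[value]])
  stats <- stats[keep, ]
  grid <- window_centers(genome, step)
  radius <- truncation * sigma

  out <- vector("list", nrow(genome))
  for (g in seq_len(nrow(genome))) {
    ch <- genome$chrom[g]
    centers <- grid$center[grid$chrom == ch]
    sub <- stats[stats$chrom == ch, ]
    if (nrow(sub) == 0) {
      warning("no sites on chromosome ", ch, call. = FALSE)
      out[[g]] <- tibble::tibble(chrom = ch, center = centers,
                                 value = NA_real_, n_sites = 0L,
                                 sum_weight = 0)
      next
    }
    ord <- order(sub$pos)
    p <- sub$pos[ord]
    x <- sub[[value]][ord]
    sw <- site_weight(sub$n_k[ord], weight)
    val <- n_sites <- wsum <- numeric(length(centers))
    lo <- findInterval(centers - radius, p) + 1L
    hi <- findInterval(centers + radius, p)
    for (i in seq_along(centers)) {
      if (hi[i] < lo[i]) {
        val[i] <- NA_real_
        next
      }
      sel <- lo[i]:hi[i]
      k <- exp(-(p[sel] - centers[i])^2 / (2 * sigma^2)) * sw[sel]
      wsum[i] <- sum(k)
      n_sites[i] <- length(sel)
      val[i] <- if (wsum[i] > 0) sum(k * x[sel]) / wsum[i] else NA_real_
    }
    out[[g]] <- tibble::tibble(chrom = ch, center = centers, value = val,
                               n_sites = as.integer(n_sites),
                               sum_weight = wsum)
  }
  dplyr::bind_rows(out)
}

#' Tajima's D from window summaries
#'
#' The standard statistic contrasting the mean number of pairwise
#' differences (`pi_sum`, the per-site diversities summed over a window)
#' with the segregating-sites estimator `S / a1`:
#' `D = (pi_sum - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with the usual constants
#' evaluated at sample size `n`. Negative values indicate an excess of rare
#' variants (sweeps, expansion); positive values an excess of
#' intermediate-frequency variants (balancing selection).
#'
#' @param S Number of segregating sites (SNPs) in the window (vectorised).
#' @param pi_sum Summed per-site nucleotide diversity over the window.
#' @param n Allele sample size (rounded to an integer internally).
#' @return Tajima's D; `NA` where `S < 2`, `n < 3` or the variance term is 0.
#' @examples
#' tajimas_d(S = 5, pi_sum = 2.0, n = 10)
#' @export
tajimas_d <- function(S, pi_sum, n) {
  n <- round(n)
  len <- max(length(S), length(pi_sum), length(n))
  S <- rep_len(S, len); pi_sum <- rep_len(pi_sum, len); n <- rep_len(n, len)
  D <- rep(NA_real_, len)
  ok <- !is.na(S) & !is.na(n) & !is.na(pi_sum) & S >= 2 & n >= 3
  if (!any(ok)) return(D)
  a1 <- vapply(n[ok], function(m) sum(1 / seq_len(m - 1)), numeric(1))
  a2 <- vapply(n[ok], function(m) sum(1 / seq_len(m - 1)^2), numeric(1))
  nn <- n[ok]
  b1 <- (nn + 1) / (3 * (nn - 1))
  b2 <- 2 * (nn^2 + nn + 3) / (9 * nn * (nn - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (nn + 2) / (a1 * nn) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S[ok] + e2 * S[ok] * (S[ok] - 1)
  d <- ifelse(v > 0, (pi_sum[ok] - S[ok] / a1) / sqrt(v), NA_real_)
  D[ok] <- d
  D
}

#' Windowed Tajima's D along the genome
#'
#' For each window centre (grid as in [smooth_track()]), collects all sites
#' within `sigma` bp of the centre, counts the SNPs among them (`S`), sums
#' their per-site diversity (`pi_sum`), averages the allele sample size
#' (`n_bar`) and evaluates [tajimas_d()]. Intended for populations near
#' equilibrium (in the original oceanic/freshwater design, the combined
#' oceanic pool).
#'
#' @inheritParams smooth_track
#' @param stats Per-site statistics from [site_stats()] for the chosen pool
#'   (needs columns `pi`, `is_snp`, `n_k`).
#' @return A tibble with columns `chrom`, `center`, `S`, `pi_sum`, `n_bar`
#'   and `value` (the D statistic; `NA` where undefined).
#' @export
tajima_track <- function(stats, genome, sigma = 150000, step = 100000) {
  grid <- window_centers(genome, step)
  out <- vector("list", nrow(genome))
  for (g in seq_len(nrow(genome))) {
    ch <- genome$chrom[g]
    centers <- grid$center[grid$chrom == ch]
    sub <- stats[stats$chrom == ch & !is.na(stats$pi), ]
    ord <- order(sub$pos)
    p <- sub$pos[ord]
    pi <- sub$pi[ord]
    snp <- as.numeric(sub$is_snp[ord])
    nk <- sub$n_k[ord]
    lo <- findInterval(centers - sigma, p) + 1L
    hi <- findInterval(centers + sigma, p)
    S <- pi_sum <- n_bar <- numeric(length(centers))
    for (i in seq_along(centers)) {
      if (hi[i] < lo[i]) {
        S[i] <- 0; pi_sum[i] <- NA_real_; n_bar[i] <- NA_real_
        next
      }
      sel <- lo[i]:hi[i]
      S[i] <- sum(snp[sel])
      pi_sum[i] <- sum(pi[sel])
      n_bar[i] <- mean(nk[sel])
    }
    out[[g]] <- tibble::tibble(
      chrom = ch, center = centers, S = S, pi_sum = pi_sum, n_bar = n_bar,
      value = tajimas_d(S, pi_sum, n_bar)
    )
  }
  dplyr::bind_rows(out)
}
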