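#' Nucleotide diversity from allele counts
#'
#' Unbiased pairwise-difference estimator of per-site nucleotide diversity
#' (equivalent to expected heterozygosity):
#' `pi = 1 - sum_i n_i * (n_i - 1) / (n * (n - 1))`, the probability that two
#' allele copies drawn without replacement differ. The biased plug-in form
#' `1 - sum_i p_i^2` is available via `unbiased = FALSE`.
#'
#' @param counts Numeric vector of per-allele copy counts at one site, or a
#'   matrix with one site per row.
#' @param unbiased Use the without-replacement (unbiased) form? Default TRUE.
#' @return Diversity in `[0, 1]`; `NA` where fewer than 2 copies were sampled.
#' @examples
#' nucleotide_diversity(c(2, 2))        # 2/3: 4 of the 6 pairs differ
#' nucleotide_diversity(c(8, 0))        # 0, monomorphic
#' @export
nucleotide_diversity <- function(counts, unbiased = TRUE) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (any(counts < 0, na.rm = TRUE)) stop("allele counts must be non-negative", call. = FALSE)
  n <- rowSums(counts)
  pi <- if (unbiased) {
    1 - rowSums(counts * (counts - 1)) / (n * (n - 1))
  } else {
    1 - rowSums((counts / n)^2)
  }
  pi[n < 2] <- NA_real_
  if (length(pi) == 1L) pi[[1]] else pi
}

#' Observed heterozygosity from diploid genotypes
#'
#' The proportion of assigned diploid genotypes that are heterozygous.
#'
#' @param genotypes Character vector of genotypes such as `"A/A"` or
#'   `"G/T"`; `NA` entries (unassigned individuals) are dropped.
#' @return Proportion in `[0, 1]`, `NA` if no genotype is assigned.
#' @examples
#' observed_heterozygosity(c("A/A", "A/A", "A/C", "C/C"))  # 0.25
#' @export
observed_heterozygosity <- function(genotypes) {
  genotypes <- genotypes[!is.na(genotypes)]
  if (length(genotypes) == 0L) return(NA_real_)
  parts <- strsplit(genotypes, "/", fixed = TRUE)
  mean(vapply(parts, function(x) x[1] != x[2], logical(1)))
}

#' Multi-population FST weighted for unequal sample sizes
#'
#' `FST = 1 - sum_j w_j * pi_j / pi_T`, where `pi_j` is the nucleotide
#' diversity within population j, `pi_T` the diversity of the pooled sample,
#' and the weights `w_j` are proportional to the number of within-population
#' allele pairs `n_j * (n_j - 1)` (set `weights = "n"` for weights
#' proportional to sample size). Negative values (within-diversity exceeding
#' pooled diversity) are reported as-is, not clamped.
#'
#' @param counts_by_pop Matrix of allele counts, one population per row,
#'   one allele per column.
#' @param weights `"npairs"` (default) or `"n"`.
#' @param pi_form Diversity form used inside the ratio. The default
#'   `"plugin"` (`1 - sum p_i^2`) uses the same denominator within and
#'   across populations, so identical populations give exactly 0;
#'   `"unbiased"` substitutes the without-replacement estimator.
#' @return FST (`<= 1`); `NA` if the pooled sample is monomorphic or fewer
#'   than two populations contribute at least 2 allele copies.
#' @examples
#' fst(rbind(c(5, 5), c(5, 5)))     # 0
#' fst(rbind(c(10, 0), c(0, 10)))   # 1
#' @export
fst <- function(counts_by_pop, weights = c("npairs", "n"),
                pi_form = c("plugin", "unbiased")) {
  weights <- match.arg(weights)
  pi_form <- match.arg(pi_form)
  counts_by_pop <- as.matrix(counts_by_pop)
  if (nrow(counts_by_pop) < 2L) {
    stop("fst requires allele counts from at least two populations", call. = FALSE)
  }
  unb <- pi_form == "unbiased"
  n_j <- rowSums(counts_by_pop)
  pi_j <- nucleotide_diversity(counts_by_pop, unbiased = unb)
  pi_t <- nucleotide_diversity(colSums(counts_by_pop), unbiased = unb)
  w <- if (weights == "npairs") n_j * (n_j - 1) else n_j
  ok <- n_j >= 2
  if (sum(ok) < 2L || is.na(pi_t) || pi_t == 0) return(NA_real_)
  1 - sum(w[ok] * pi_j[ok]) / sum(w[ok]) / pi_t
}

#' Private-allele indicators
#'
#' For each population j of a comparison, `rho_j = 1` if some allele occurs
#' in population j and in no other population of the comparison, provided at
#' least one individual was genotyped at the site in every population;
#' otherwise `rho_j = 0`.
#'
#' @inheritParams fst
#' @param genotyped Logical vector: does each population have at least one
#'   assigned genotype at this site? Defaults to `rowSums(counts_by_pop) > 0`.
#' @return Integer 0/1 vector, one element per population.
#' @examples
#' private_alleles(rbind(c(9, 1), c(10, 0)))  # c(1, 0)
#' @export
private_alleles <- function(counts_by_pop, genotyped = NULL) {
  counts_by_pop <- as.matrix(counts_by_pop)
  if (is.null(genotyped)) genotyped <- rowSums(counts_by_pop) > 0
  if (!all(genotyped)) return(rep(0L, nrow(counts_by_pop)))
  total <- colSums(counts_by_pop)
  vapply(seq_len(nrow(counts_by_pop)), function(j) {
    as.integer(any(counts_by_pop[j, ] > 0 & total - counts_by_pop[j, ] == 0))
  }, integer(1))
}

#' Goodness-of-fit G-test on an allele-by-population table
#'
#' `G = 2 * sum O * log(O / E)` with expectations from the row and column
#' marginals; empty cells contribute 0 and all-zero rows/columns are dropped
#' before computing the degrees of freedom
#' `(alleles - 1) * (populations - 1)`. No Williams or continuity correction
#' is applied. Used to attach per-SNP significance to FST.
#'
#' @param tab Matrix of allele counts (populations by alleles).
#' @return A tibble with columns `statistic`, `df`, `p.value`; all `NA` for
#'   degenerate tables (fewer than two non-empty rows or columns).
#' @examples
#' g_test(rbind(c(10, 0), c(0, 10)))  # G = 40 * log(2)
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_, p.value = NA_real_))
  }
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  g <- 2 * sum(xlogy(tab, tab / e))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  tibble::tibble(
    statistic = g, df = df,
    p.value = stats::pchisq(g, df, lower.tail = FALSE)
  )
}

#' Tally allele copies per site and population from genotype calls
#'
#' Counts the A/C/G/T allele copies among assigned diploid genotypes for
#' every combination of genomic site and population, along with the number
#' of assigned individuals and heterozygotes. The returned grid is complete:
#' a population with no assigned genotype at a site appears with zero counts.
#'
#' @param calls Genotype calls from [call_genotypes()].
#' @param popmap Tibble mapping `individual` to `pop`. Individuals in the
#'   popmap absent from `calls` are ignored with a warning; individuals in
#'   `calls` absent from the popmap are an error.
#' @return A tibble with columns `chrom`, `pos`, `pop`, `A`, `C`, `G`, `T`
#'   (allele copies), `n` (total copies), `n_ind` (assigned individuals) and
#'   `n_het` (heterozygous individuals).
#' @export
allele_counts <- function(calls, popmap) {
  if (!all(c("individual", "pop") %in% names(popmap))) {
    stop("popmap needs columns 'individual' and 'pop'", call. = FALSE)
  }
  extra <- setdiff(popmap$individual, calls$individual)
  if (length(extra) > 0) {
    warning(length(extra), " popmap individual(s) absent from calls; ignored",
            call. = FALSE)
  }
  unknown <- setdiff(unique(calls$individual), popmap$individual)
  if (length(unknown) > 0) {
    stop("individuals missing from popmap: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  sites <- dplyr::distinct(calls, .data$chrom, .data$pos) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  skey <- paste(sites$chrom, sites$pos)
  pops <- sort(unique(popmap$pop[popmap$individual %in% calls$individual]))
  S <- nrow(sites)
  P <- length(pops)

  asn <- calls$status == "assigned"
  sid <- match(paste(calls$chrom[asn], calls$pos[asn]), skey)
  pid <- match(popmap$pop[match(calls$individual[asn], popmap$individual)], pops)
  a1 <- match(calls$allele1[asn], NUCS)
  a2 <- match(calls$allele2[asn], NUCS)

  base <- (sid - 1L) * (P * 4L) + (pid - 1L) * 4L
  cnt <- tabulate(base + a1, nbins = S * P * 4L) +
    tabulate(base + a2, nbins = S * P * 4L)
  M <- matrix(cnt, ncol = 4L, byrow = TRUE)  # rows: pop within site

  sp <- (sid - 1L) * P + pid
  n_ind <- tabulate(sp, nbins = S * P)
  n_het <- tabulate(sp[a1 != a2], nbins = S * P)

  tibble::tibble(
    chrom = rep(sites$chrom, each = P),
    pos = rep(sites$pos, each = P),
    pop = rep(pops, times = S),
    A = M[, 1], C = M[, 2], G = M[, 3], T = M[, 4],
    n = as.integer(rowSums(M)),
    n_ind = n_ind,
    n_het = n_het
  )
}

# collapse an allele_counts tibble to per-pool arrays for one comparison.
# Returns list(sites, counts = S x 4 x P array, n_ind, n_het = S x P).
pool_arrays <- function(ac, pools) {
  sites <- dplyr::distinct(ac, .data$chrom, .data$pos) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  skey <- paste(sites$chrom, sites$pos)
  S <- nrow(sites)
  P <- length(pools)
  cn <- array(0, dim = c(S, 4L, P))
  n_ind <- matrix(0L, S, P)
  n_het <- matrix(0L, S, P)
  M <- cbind(ac$A, ac$C, ac$G, ac$T)
  rid <- match(paste(ac$chrom, ac$pos), skey)
  for (j in seq_len(P)) {
    members <- pools[[j]]
    missing_pops <- setdiff(members, unique(ac$pop))
    if (length(missing_pops) > 0) {
      stop("comparison references unknown population(s): ",
           paste(missing_pops, collapse = ", "), call. = FALSE)
    }
    sel <- ac$pop %in% members
    g <- rid[sel]
    for (a in 1:4) {
      cn[, a, j] <- unname(tapply2(M[sel, a], g, S))
    }
    n_ind[, j] <- tapply2(ac$n_ind[sel], g, S)
    n_het[, j] <- tapply2(ac$n_het[sel], g, S)
  }
  list(sites = sites, counts = cn, n_ind = n_ind, n_het = n_het)
}

# S x 4 slice of a S x 4 x P array that never drops dimensions
pool_slice <- function(a, j) matrix(a[, , j], nrow = dim(a)[1])

# fast grouped sum onto 1..S (groups without rows get 0)
tapply2 <- function(x, g, S) {
  out <- numeric(S)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Per-site population-genetic statistics for a comparison
#'
#' Computes, for every genomic site, nucleotide diversity `pi` and observed
#' heterozygosity `h` of the pooled sample, and — when the comparison has at
#' least two pools — the sample-size-weighted `fst`, per-pool private-allele
#' indicators `rho_<pool>`, and a per-SNP G-test. A site is a SNP within the
#' comparison when at least two alleles segregate among assigned genotypes
#' in the pooled sample. Monomorphic sites keep `pi = 0`, `h = 0` but have
#' `fst`, `rho` and G undefined (`NA`); they enter diversity tracks and are
#' excluded from SNP-based tracks.
#'
#' @param ac Allele counts from [allele_counts()].
#' @param pools Named list defining the comparison: each element is a
#'   character vector of population labels pooled into one unit, e.g.
#'   `list(oceanic = c("RS", "RB"), freshwater = c("BP", "BL", "ML"))`.
#'   `NULL` (default) pools every population into a single unit (diversity
#'   statistics only).
#' @param g_test Compute per-SNP G-tests? (Skipping them saves time when
#'   only FST tracks are needed.)
#' @param weights Passed to [fst()].
#' @return A tibble with one row per site: `chrom`, `pos`, `n_k` (allele
#'   copies sampled across the comparison), `n_ind`, `is_snp`, `pi`, `h`,
#'   and for multi-pool comparisons `fst`, `g`, `g_df`, `g_p` and one
#'   `rho_<pool>` column per pool.
#' @export
site_stats <- function(ac, pools = NULL, g_test = TRUE,
                       weights = c("npairs", "n")) {
  weights <- match.arg(weights)
  if (is.null(pools)) pools <- list(all = unique(ac$pop))
  if (is.null(names(pools)) || any(names(pools) == "")) {
    stop("pools must be a named list", call. = FALSE)
  }
  arr <- pool_arrays(ac, pools)
  S <- nrow(arr$sites)
  P <- length(pools)

  total <- rowSums(arr$counts, dims = 2)         # S x 4 pooled counts
  n_k <- rowSums(total)
  n_ind_tot <- rowSums(arr$n_ind)
  is_snp <- rowSums(total > 0) >= 2
  pi <- nucleotide_diversity(total)
  h <- ifelse(n_ind_tot > 0, rowSums(arr$n_het) / n_ind_tot, NA_real_)

  out <- tibble::tibble(
    chrom = arr$sites$chrom, pos = arr$sites$pos,
    n_k = as.integer(n_k), n_ind = as.integer(n_ind_tot),
    is_snp = is_snp, pi = pi, h = h
  )
  if (P < 2L) return(out)

  n_j <- matrix(0, S, P)                          # S x P copies per pool
  pairs_sq <- matrix(0, S, P)
  for (j in seq_len(P)) {
    cj <- pool_slice(arr$counts, j)
    n_j[, j] <- rowSums(cj)
    pairs_sq[, j] <- rowSums(cj^2)
  }
  w <- if (weights == "npairs") n_j * (n_j - 1) else n_j * (n_j >= 2)
  # plug-in diversities inside the FST ratio (identical pools give 0 exactly);
  # zero weight where n_j < 2
  pi_j <- ifelse(n_j >= 2, 1 - pairs_sq / n_j^2, 0)
  pi_t <- 1 - rowSums((total / n_k)^2)
  wsum <- rowSums(w)
  pi_w <- rowSums(w * pi_j) / wsum
  valid <- rowSums(n_j >= 2) >= 2 & !is.na(pi) & pi > 0
  out$fst <- ifelse(valid, 1 - pi_w / pi_t, NA_real_)

  # private alleles: allele present in exactly one pool, all pools genotyped
  all_genotyped <- rowSums(arr$n_ind > 0) == P
  for (j in seq_len(P)) {
    cj <- pool_slice(arr$counts, j)
    priv <- rowSums(cj > 0 & (total - cj) == 0) > 0
    rho <- as.integer(priv & all_genotyped)
    rho[!is_snp] <- NA_integer_
    out[[paste0("rho_", names(pools)[j])]] <- rho
  }

  out$g <- NA_real_
  out$g_df <- NA_integer_
  out$g_p <- NA_real_
  if (g_test) {
    idx <- which(is_snp & rowSums(n_j > 0) >= 2)
    if (length(idx) > 0) {
      O <- arr$counts[idx, , , drop = FALSE]
      Rm <- total[idx, , drop = FALSE]              # allele marginals
      Cm <- n_j[idx, , drop = FALSE]                # pool marginals
      nn <- n_k[idx]
      E <- array(0, dim = dim(O))
      for (j in seq_len(P)) E[, , j] <- Rm * (Cm[, j] / nn)
      terms <- array(0, dim = dim(O))
      nz <- O > 0
      terms[nz] <- O[nz] * log(O[nz] / E[nz])
      g <- 2 * rowSums(terms, dims = 1)
      df <- (rowSums(Rm > 0) - 1L) * (rowSums(Cm > 0) - 1L)
      ok <- df > 0
      out$g[idx[ok]] <- g[ok]
      out$g_df[idx[ok]] <- as.integer(df[ok])
      out$g_p[idx[ok]] <- stats::pchisq(g[ok], df[ok], lower.tail = FALSE)
    }
  }
  out
}
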