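#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data :=
#' @importFrom dplyr %>%
#' @importFrom Rcpp sourceCpp
#' @useDynLib radscan, .registration = TRUE
NULL

NUCS <- c("A", "C", "G", "T")

# the ten diploid hypotheses in fixed tie-break order:
# four homozygotes (A<C<G<T), then the six heterozygotes in lexicographic order
HYPOTHESES <- rbind(
  cbind(1:4, 1:4),
  t(utils::combn(4L, 2L))
)
HYP_LABELS <- paste(NUCS[HYPOTHESES[, 1]], NUCS[HYPOTHESES[, 2]], sep = "/")

# x * log(y) with the 0 * log(0) = 0 convention
xlogy <- function(x, y) {
  out <- numeric(length(x))
  nz <- x != 0
  out[nz] <- x[nz] * log(y[nz])
  out
}

parse_genotype <- function(genotype) {
  alleles <- strsplit(toupper(genotype), "/", fixed = TRUE)[[1]]
  if (length(alleles) == 1L) alleles <- rep(alleles, 2L)
  idx <- match(alleles, NUCS)
  if (length(idx) != 2L || anyNA(idx)) {
    stop("genotype must be two nucleotides like 'A/A' or 'G/T'", call. = FALSE)
  }
  sort(idx)
}

#' Multinomial log-likelihood of a diploid genotype from read counts
#'
#' Computes the log probability of an observed vector of per-nucleotide read
#' counts at one site in one individual, given a diploid genotype hypothesis
#' and a sequencing error rate. Reads are modelled as a multinomial sample:
#' for a homozygote i/i each read shows nucleotide i with probability
#' `1 - 3*epsilon/4` and each of the other three nucleotides with probability
#' `epsilon/4`; for a heterozygote i/j each of the two alleles is read with
#' probability `1/2 - epsilon/4` and each other nucleotide with `epsilon/4`.
#' The multinomial coefficient is included, so likelihoods are interpretable
#' as probabilities (it cancels in likelihood-ratio statistics).
#'
#' @param counts Integer vector of length 4: reads showing A, C, G, T.
#' @param genotype Diploid genotype as a string such as `"A/A"` or `"G/T"`.
#' @param epsilon Sequencing error rate. Must keep all category
#'   probabilities in `[0, 1]`: at most 4/3 for a homozygote and 2 for a
#'   heterozygote.
#' @return The log-likelihood (a single number, `<= 0`).
#' @examples
#' genotype_log_likelihood(c(12, 0, 0, 0), "A/A", 0)     # log(1) = 0
#' genotype_log_likelihood(c(6, 6, 0, 0), "A/C", 0)      # log(924) + 12*log(1/2)
#' @seealso [mle_error_rate()], [call_genotypes()]
#' @export
genotype_log_likelihood <- function(counts, genotype, epsilon) {
  counts <- as.numeric(counts)
  if (length(counts) != 4L || any(counts < 0) || anyNA(counts)) {
    stop("counts must be four non-negative read counts (A, C, G, T)", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("no reads at this site (n = 0)", call. = FALSE)
  al <- parse_genotype(genotype)
  eps_lim <- if (al[1] == al[2]) 4 / 3 else 2
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0 || epsilon > eps_lim) {
    stop(sprintf("epsilon must lie in [0, %.4g] for this hypothesis", eps_lim),
         call. = FALSE)
  }
  probs <- rep(epsilon / 4, 4L)
  if (al[1] == al[2]) {
    probs[al[1]] <- 1 - 3 * epsilon / 4
  } else {
    probs[al] <- 1 / 2 - epsilon / 4
  }
  lcoef <- lgamma(n + 1) - sum(lgamma(counts + 1))
  lcoef + sum(xlogy(counts, probs))
}

#' Maximum-likelihood sequencing error rate for one genotype hypothesis
#'
#' Profiles the per-site sequencing error rate for a given diploid genotype
#' hypothesis by maximum likelihood. Closed forms: for a homozygote i/i,
#' `eps_hat = 4 * (n - n_i) / (3 * n)`; for a heterozygote i/j,
#' `eps_hat = 2 * (n - n_i - n_j) / n`; in both cases clamped to
#' `[0, eps_max]`.
#'
#' @inheritParams genotype_log_likelihood
#' @param eps_max Upper bound of the admissible error-rate range
#'   (default 1; rates above 1 are non-physical even where the category
#'   probabilities would remain valid).
#' @return The profiled error rate.
#' @examples
#' mle_error_rate(c(10, 0, 0, 0), "A/A")   # 0
#' mle_error_rate(c(6, 6, 0, 0), "A/A")    # 2/3
#' mle_error_rate(c(5, 5, 2, 0), "A/C")    # 1/3
#' @export
mle_error_rate <- function(counts, genotype, eps_max = 1) {
  counts <- as.numeric(counts)
  if (length(counts) != 4L || any(counts < 0) || anyNA(counts)) {
    stop("counts must be four non-negative read counts (A, C, G, T)", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("no reads at this site (n = 0)", call. = FALSE)
  al <- parse_genotype(genotype)
  raw <- if (al[1] == al[2]) {
    4 * (n - counts[al[1]]) / (3 * n)
  } else {
    2 * (n - counts[al[1]] - counts[al[2]]) / n
  }
  min(max(raw, 0), eps_max)
}

# vectorised core: profiled log-likelihoods of all 10 hypotheses
# (compiled; see src/kernels.cpp). N is an M x 4 count matrix; returns
# list(loglik = M x 10, epsilon = M x 10). Rows with n = 0 come back as NA.
hypothesis_logliks <- function(N, eps_max = 1) {
  cpp_hyp_logliks(N, eps_max)
}

#' Call diploid genotypes from per-site nucleotide read counts
#'
#' For every row of `counts` (one individual at one genomic site), the ten
#' possible diploid genotypes (four homozygous, six heterozygous) are ranked
#' by their multinomial log-likelihood, each maximised over its own per-site
#' sequencing error rate. A genotype is assigned when a likelihood-ratio test
#' between the two most likely hypotheses (one degree of freedom) is
#' significant at level `alpha`; otherwise the site is left unassigned, which
#' removes low-coverage sites without imposing a fixed depth cutoff. Sites
#' with no reads are flagged `no_data`.
#'
#' Exact likelihood ties between the top two hypotheses give a
#' likelihood-ratio statistic of 0 and hence an unassigned call; ties further
#' down the ranking are broken by the fixed nucleotide order A < C < G < T.
#'
#' @param counts Tibble with columns `chrom`, `pos`, `individual`, `nA`,
#'   `nC`, `nG`, `nT` (one row per individual per site; ambiguous reads are
#'   assumed to have been excluded upstream).
#' @param alpha Significance level of the assignment test (default 0.05).
#' @param eps_max Upper bound for the profiled error rate (default 1).
#' @return A tibble with one row per input row: `chrom`, `pos`,
#'   `individual`, `n` (total reads), `status` (`"assigned"`, `"unassigned"`
#'   or `"no_data"`), `genotype` (e.g. `"A/C"`, `NA` unless assigned),
#'   `allele1`, `allele2`, `lrt` (likelihood-ratio statistic), `epsilon`
#'   (error-rate estimate of the best hypothesis) and `log_lik`.
#' @examples
#' counts <- tibble::tibble(
#'   chrom = "chrI", pos = 1:3, individual = "fish_01",
#'   nA = c(12L, 1L, 0L), nC = c(0L, 0L, 0L), nG = 0L, nT = 0L
#' )
#' call_genotypes(counts)
#' @export
call_genotypes <- function(counts, alpha = 0.05, eps_max = 1) {
  required <- c("chrom", "pos", "individual", "nA", "nC", "nG", "nT")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    stop("counts is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (vctrs::vec_duplicate_any(counts[c("chrom", "pos", "individual")])) {
    stop("duplicate (chrom, pos, individual) rows in counts", call. = FALSE)
  }
  N <- cbind(as.double(counts$nA), as.double(counts$nC),
             as.double(counts$nG), as.double(counts$nT))
  if (any(N < 0) || anyNA(N)) stop("read counts must be non-negative", call. = FALSE)

  core <- cpp_call_core(N, eps_max)
  n <- rowSums(N)
  lrt <- pmax(2 * (core$l1 - core$l2), 0)

  crit <- stats::qchisq(1 - alpha, df = 1)
  status <- rep("unassigned", nrow(N))
  assigned <- !is.na(lrt) & lrt > crit
  status[assigned] <- "assigned"
  status[n == 0] <- "no_data"

  genotype <- allele1 <- allele2 <- rep(NA_character_, nrow(N))
  genotype[assigned] <- HYP_LABELS[core$best[assigned]]
  allele1[assigned] <- NUCS[HYPOTHESES[core$best[assigned], 1]]
  allele2[assigned] <- NUCS[HYPOTHESES[core$best[assigned], 2]]

  tibble::tibble(
    chrom = counts$chrom,
    pos = counts$pos,
    individual = counts$individual,
    n = as.integer(n),
    status = status,
    genotype = genotype,
    allele1 = allele1,
    allele2 = allele2,
    lrt = lrt,
    epsilon = core$eps1,
    log_lik = core$l1
  )
}
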