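# genotype label lookup: row = allele 1 (A..T), col = allele 2
GT_LOOKUP <- outer(NUCS, NUCS, function(a, b) paste(a, b, sep = "/"))
# the three nucleotides other than i (rows of this matrix)
OTHERS3 <- t(vapply(1:4, function(i) setdiff(1:4, i), integer(3)))

#' Selective-sweep scenario for the simulator
#'
#' Describes a genomic interval in which a designated ancestrally rare
#' allele has been driven to high frequency in the target populations. In a
#' *parallel* sweep the same allele is swept in every target population
#' (the classic signature: a shared peak in the overall oceanic-freshwater
#' differentiation with little differentiation among the freshwater
#' populations); in a *non-parallel* sweep each target population sweeps
#' its own allele, producing differentiation among the targets themselves.
#' Allele frequencies taper linearly from the swept value inside the
#' interval back to the background over `taper` bp beyond each edge.
#'
#' @param chrom Chromosome name.
#' @param center Interval centre (bp).
#' @param width Interval width (bp).
#' @param pops Character vector of target population labels.
#' @param final Frequency the swept allele reaches inside the interval
#'   (default 0.95).
#' @param taper Width of the linear taper beyond each edge (bp).
#' @param parallel Same allele in all targets (`TRUE`, default) or an
#'   independently chosen allele per target (`FALSE`).
#' @return A scenario object for [sim_config()].
#' @export
scenario_sweep <- function(chrom, center, width, pops, final = 0.95,
                           taper = 150000, parallel = TRUE) {
  stopifnot(width > 0, final > 0, final < 1, taper >= 0)
  structure(list(type = "sweep", chrom = chrom, center = center,
                 width = width, pops = pops, final = final, taper = taper,
                 parallel = parallel),
            class = "rad_scenario")
}

#' Balancing-selection scenario for the simulator
#'
#' An interval where balancing selection holds allele frequencies near an
#' intermediate value in *every* population, producing elevated diversity
#' with reduced differentiation.
#'
#' @inheritParams scenario_sweep
#' @param freq Frequency toward which all populations are pulled
#'   (default 0.5).
#' @export
scenario_balancing <- function(chrom, center, width, freq = 0.5,
                               taper = 150000) {
  stopifnot(width > 0, freq > 0, freq < 1, taper >= 0)
  structure(list(type = "balancing", chrom = chrom, center = center,
                 width = width, pops = NULL, freq = freq, taper = taper),
            class = "rad_scenario")
}

#' The default three-scenario layout
#'
#' One parallel hard sweep, one non-parallel sweep and one
#' balancing-selection interval, each 600 kb wide and centred on its own
#' 5-Mb chromosome, targeting the three freshwater populations of the
#' default design.
#'
#' @param pops Target populations for the sweeps.
#' @export
study_scenarios <- function(pops = c("BP", "BL", "ML")) {
  list(
    scenario_sweep("chrI", 2.5e6, 6e5, pops = pops, parallel = TRUE),
    scenario_sweep("chrII", 2.5e6, 6e5, pops = pops, parallel = FALSE),
    scenario_balancing("chrIII", 2.5e6, 6e5)
  )
}

#' Simulation configuration for a replicate oceanic/freshwater design
#'
#' Describes a RAD-seq study of five populations — two near-panmictic
#' oceanic populations and three independently founded freshwater
#' populations — at desk scale. Population allele frequencies follow the
#' Balding-Nichols model around an ancestral frequency drawn from a
#' neutral-like spectrum (density proportional to 1/p on a grid), with a
#' per-population drift parameter `f` (small for oceanic populations, an
#' order of magnitude larger for the founded freshwater populations).
#' Sequencing is emulated as Poisson read depth over the true HWE genotype
#' with a multinomial error model, plus restriction-site dropout alleles
#' that silence one or both haplotypes of a RAD tag.
#'
#' @param genome Tibble `chrom`, `length`; default three 5-Mb chromosomes.
#' @param rad_spacing Mean distance between RAD tag starts in bp
#'   (default 20000, echoing ~22,830 restriction sites over a ~460-Mb
#'   genome).
#' @param sites_per_tag Sequenced nucleotide sites per tag (default 30).
#' @param populations Tibble `pop`, `type` (`"oceanic"`/`"freshwater"`),
#'   `n_ind` (diploids, default 20) and drift parameter `f`.
#' @param poly_rate Probability that a site is ancestrally polymorphic
#'   (default 0.05).
#' @param freq_grid Grid of ancestral derived-allele frequencies; sampled
#'   with probability proportional to `1/p`.
#' @param coverage Mean per-site read depth per individual (Poisson mean,
#'   default 7).
#' @param error True sequencing error rate (default 0.01).
#' @param dropout_freq Frequency of the restriction-site dropout (null)
#'   allele per RAD tag (default 0.02).
#' @param scenarios List of [scenario_sweep()] / [scenario_balancing()]
#'   objects; default [study_scenarios()]. Use `list()` for a neutral
#'   genome.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(genome = tibble::tibble(chrom = c("chrI", "chrII", "chrIII"),
                                               length = rep(5e6, 3)),
                       rad_spacing = 20000,
                       sites_per_tag = 30,
                       populations = tibble::tibble(
                         pop = c("RS", "RB", "BP", "BL", "ML"),
                         type = c("oceanic", "oceanic",
                                  "freshwater", "freshwater", "freshwater"),
                         n_ind = 20L,
                         f = c(0.005, 0.005, 0.15, 0.10, 0.12)
                       ),
                       poly_rate = 0.05,
                       freq_grid = seq(0.025, 0.975, by = 0.025),
                       coverage = 7,
                       error = 0.01,
                       dropout_freq = 0.02,
                       scenarios = study_scenarios()) {
  stopifnot(all(genome$length > 0), rad_spacing > 0, sites_per_tag >= 1,
            all(populations$n_ind >= 1),
            all(populations$f > 0 & populations$f < 1),
            poly_rate >= 0, poly_rate <= 1,
            all(freq_grid > 0 & freq_grid < 1),
            coverage > 0, error >= 0, error < 1,
            dropout_freq >= 0, dropout_freq < 1)
  for (sc in scenarios) {
    if (!inherits(sc, "rad_scenario")) stop("scenarios must be scenario objects", call. = FALSE)
    if (!sc$chrom %in% genome$chrom) stop("scenario on unknown chromosome ", sc$chrom, call. = FALSE)
    len <- genome$length[match(sc$chrom, genome$chrom)]
    if (sc$width >= len) stop("scenario wider than its chromosome", call. = FALSE)
    if (!is.null(sc$pops) && !all(sc$pops %in% populations$pop)) {
      stop("scenario targets unknown population(s)", call. = FALSE)
    }
  }
  structure(list(genome = genome, rad_spacing = rad_spacing,
                 sites_per_tag = sites_per_tag, populations = populations,
                 poly_rate = poly_rate, freq_grid = freq_grid,
                 coverage = coverage, error = error,
                 dropout_freq = dropout_freq, scenarios = scenarios),
            class = "sim_config")
}

#' Post-founding population allele frequency under Balding-Nichols drift
#'
#' Draws a population allele frequency around the ancestral frequency `p0`
#' from `Beta(p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)`, so that
#' `E[p] = p0` and `Var[p] = f * p0 * (1 - p0)`. Boundary frequencies (0
#' or 1) are returned unchanged.
#'
#' @param p0 Ancestral frequencies (vectorised).
#' @param f Drift parameter in (0, 1).
#' @return Drifted frequencies, one draw per element of `p0`.
#' @export
draw_population_frequencies <- function(p0, f) {
  stopifnot(f > 0, f < 1, all(p0 >= 0 & p0 <= 1))
  out <- p0
  inner <- p0 > 0 & p0 < 1
  k <- (1 - f) / f
  out[inner] <- stats::rbeta(sum(inner), p0[inner] * k, (1 - p0[inner]) * k)
  out
}

# linear taper factor: 1 inside the interval, falling to 0 over `taper` bp
taper_factor <- function(pos, center, width, taper) {
  excess <- abs(pos - center) - width / 2
  pmin(1, pmax(0, 1 - excess / max(taper, 1e-9)))
}

#' Overlay selection scenarios on population allele frequencies
#'
#' Modifies the per-population derived-allele frequency matrix inside each
#' scenario's interval (including tapers). Sweeps push the ancestrally rare
#' allele (the derived allele where `p0 <= 0.5`, the ancestral one
#' otherwise) toward the scenario's final frequency in the target
#' populations — the same allele everywhere for a parallel sweep, an
#' independently chosen allele per target for a non-parallel sweep.
#' Balancing intervals pull every population toward the balanced frequency.
#' Monomorphic sites are untouched. Overlapping scenario footprints are an
#' error.
#'
#' @param freq Site-by-population matrix of derived-allele frequencies.
#' @param sites Site table with `chrom`, `pos`, `p0` (ancestral derived
#'   frequency; 0 marks monomorphic sites).
#' @param scenarios List of scenario objects.
#' @param populations The configuration's population tibble.
#' @return The modified frequency matrix. Uses the current RNG state for
#'   non-parallel allele choices.
#' @export
apply_scenarios <- function(freq, sites, scenarios, populations) {
  if (length(scenarios) == 0) return(freq)
  touched <- rep(FALSE, nrow(sites))
  for (sc in scenarios) {
    half <- sc$width / 2 + sc$taper
    hit <- sites$chrom == sc$chrom & abs(sites$pos - sc$center) <= half
    if (any(hit & touched)) stop("overlapping scenarios", call. = FALSE)
    touched <- touched | hit
    idx <- which(hit & sites$p0 > 0)
    if (length(idx) == 0) next
    t <- taper_factor(sites$pos[idx], sc$center, sc$width, sc$taper)
    if (sc$type == "balancing") {
      for (j in seq_len(ncol(freq))) {
        freq[idx, j] <- t * sc$freq + (1 - t) * freq[idx, j]
      }
    } else {
      targets <- match(sc$pops, populations$pop)
      # swept allele is the ancestrally rare one at each site
      rare_is_derived <- sites$p0[idx] <= 0.5
      for (j in targets) {
        push_derived <- if (sc$parallel) {
          rare_is_derived
        } else {
          stats::runif(length(idx)) < 0.5
        }
        bg <- freq[idx, j]
        swept <- ifelse(push_derived,
                        t * sc$final + (1 - t) * bg,
                        1 - (t * sc$final + (1 - t) * (1 - bg)))
        freq[idx, j] <- swept
      }
    }
  }
  freq
}

#' Emit per-individual read counts from population allele frequencies
#'
#' The generative counterpart of the genotype-calling model. For each
#' individual, two allele copies per site are drawn from its population's
#' frequency (Hardy-Weinberg). Each RAD tag independently carries dropout
#' alleles at frequency `dropout_freq`: an individual homozygous for
#' dropout yields no reads across the tag; a heterozygous-dropout
#' individual retains one haplotype, halving its expected depth and making
#' true heterozygotes read as homozygotes (the downward diversity bias of
#' restriction-site polymorphism). Depth is Poisson(`coverage`), scaled by
#' retained haplotypes, and reads are multinomial with the error-model
#' category probabilities.
#'
#' @param freq Site-by-population derived-allele frequency matrix.
#' @param sites Site table with `chrom`, `pos`, `tag`, `anc`, `der`
#'   (nucleotide indices 1-4).
#' @param populations Population tibble (`pop`, `n_ind`).
#' @param coverage,error,dropout_freq See [sim_config()].
#' @return A list: `counts` (read-count tibble in [call_genotypes()]
#'   format), `popmap`, and `truth` — a tibble aligned row-for-row with
#'   `counts` carrying the true genotype, plus the dropout state. Uses the
#'   current RNG state.
#' @export
emit_read_counts <- function(freq, sites, populations, coverage = 7,
                             error = 0.01, dropout_freq = 0.02) {
  S <- nrow(sites)
  pops <- populations$pop
  n_ind <- populations$n_ind
  N <- sum(n_ind)
  ind <- tibble::tibble(
    individual = unlist(purrr::map2(pops, n_ind, function(p, k) sprintf("%s_%02d", p, seq_len(k)))),
    pop = rep(pops, times = n_ind)
  )
  pidx <- rep(seq_along(pops), times = n_ind)

  Fm <- freq[, pidx, drop = FALSE]                   # S x N
  c1 <- matrix(stats::runif(S * N) < Fm, S, N)       # TRUE = derived copy
  c2 <- matrix(stats::runif(S * N) < Fm, S, N)

  tags <- unique(sites$tag)
  Tn <- length(tags)
  tid <- match(sites$tag, tags)
  d1 <- matrix(stats::runif(Tn * N) < dropout_freq, Tn, N)
  d2 <- matrix(stats::runif(Tn * N) < dropout_freq, Tn, N)
  dcount <- d1 + d2                                  # dropout copies per tag
  keep1 <- matrix(stats::runif(Tn * N) < 0.5, Tn, N) # retained haplotype if het-dropout
  dsite <- dcount[tid, , drop = FALSE]               # S x N
  ksite <- keep1[tid, , drop = FALSE]

  # effective allele copies after dropout
  e1 <- c1; e2 <- c2
  het_drop <- dsite == 1L
  e1[het_drop & !ksite] <- c2[het_drop & !ksite]
  e2[het_drop & ksite] <- c1[het_drop & ksite]

  lambda <- coverage * ifelse(dsite == 0L, 1, ifelse(dsite == 1L, 0.5, 0))
  n <- matrix(stats::rpois(S * N, lambda), S, N)

  A1 <- matrix(ifelse(e1, sites$der, sites$anc), S, N)
  A2 <- matrix(ifelse(e2, sites$der, sites$anc), S, N)

  M <- S * N
  nv <- as.vector(n)
  x <- as.vector(A1)
  y <- as.vector(A2)
  CM <- matrix(0L, M, 4L)
  rows <- seq_len(M)

  hom <- x == y & nv > 0
  if (any(hom)) {
    nh <- nv[hom]
    nerr <- stats::rbinom(sum(hom), nh, 3 * error / 4)
    o <- OTHERS3[x[hom], , drop = FALSE]
    eA <- stats::rbinom(sum(hom), nerr, 1 / 3)
    eB <- stats::rbinom(sum(hom), nerr - eA, 1 / 2)
    eC <- nerr - eA - eB
    r <- rows[hom]
    CM[cbind(r, x[hom])] <- nh - nerr
    CM[cbind(r, o[, 1])] <- eA
    CM[cbind(r, o[, 2])] <- eB
    CM[cbind(r, o[, 3])] <- eC
  }
  het <- x != y & nv > 0
  if (any(het)) {
    nh <- nv[het]
    xh <- x[het]; yh <- y[het]
    nerr <- stats::rbinom(sum(het), nh, error / 2)
    # the two non-allele nucleotides at each het site
    lo <- pmin(xh, yh); hi <- pmax(xh, yh)
    oth <- cbind(
      vapply(seq_along(lo), function(i) setdiff(1:4, c(lo[i], hi[i]))[1], integer(1)),
      vapply(seq_along(lo), function(i) setdiff(1:4, c(lo[i], hi[i]))[2], integer(1))
    )
    eA <- stats::rbinom(sum(het), nerr, 1 / 2)
    good <- nh - nerr
    gx <- stats::rbinom(sum(het), good, 1 / 2)
    r <- rows[het]
    CM[cbind(r, xh)] <- gx
    CM[cbind(r, yh)] <- good - gx
    CM[cbind(r, oth[, 1])] <- eA
    CM[cbind(r, oth[, 2])] <- nerr - eA
  }

  t1 <- matrix(ifelse(c1, sites$der, sites$anc), S, N)
  t2 <- matrix(ifelse(c2, sites$der, sites$anc), S, N)
  g1 <- pmin(t1, t2); g2 <- pmax(t1, t2)
  truth_geno <- GT_LOOKUP[cbind(as.vector(g1), as.vector(g2))]

  counts <- tibble::tibble(
    chrom = rep(sites$chrom, times = N),
    pos = rep(sites$pos, times = N),
    individual = rep(ind$individual, each = S),
    nA = CM[, 1], nC = CM[, 2], nG = CM[, 3], nT = CM[, 4]
  )
  truth <- tibble::tibble(
    chrom = counts$chrom, pos = counts$pos, individual = counts$individual,
    genotype = truth_geno,
    dropout = as.integer(as.vector(dsite))
  )
  list(counts = counts, popmap = ind, truth = truth)
}

#' Simulate a RAD-seq study with known truth
#'
#' Runs the full generative model of [sim_config()]: lays out RAD tags
#' along the genome (exponential inter-tag spacing), draws ancestral
#' polymorphism and per-population drifted frequencies, overlays the
#' selection scenarios, and emits per-individual read counts. All
#' randomness flows from `seed` through fixed named substreams (layout,
#' frequencies, scenarios, reads), so a run is fully reproducible.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return A list with `counts`, `popmap` and `genome` (the inputs the
#'   analysis pipeline consumes), plus `truth` (per-call true genotypes and
#'   dropout states, the site table with ancestral and per-population
#'   frequencies, and the scenario intervals) and the `config`.
#' @examples
#' cfg <- sim_config(genome = tibble::tibble(chrom = "chrI", length = 2e5),
#'                   scenarios = list())
#' sim <- simulate_radseq(cfg, seed = 1)
#' dplyr::glimpse(sim$counts)
#' @export
simulate_radseq <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 1L, 4)

  # RAD tag layout
  set.seed(ss[1])
  site_list <- list()
  tag0 <- 0L
  for (g in seq_len(nrow(config$genome))) {
    len <- config$genome$length[g]
    n_guess <- ceiling(len / config$rad_spacing * 2) + 10
    # minimum gap of one tag length keeps tags non-overlapping while
    # preserving the mean inter-tag spacing
    mean_gap <- max(config$rad_spacing - config$sites_per_tag, 1)
    gaps <- config$sites_per_tag + stats::rexp(n_guess, 1 / mean_gap)
    starts <- cumsum(gaps) + 1
    starts <- floor(starts[starts + config$sites_per_tag - 1 <= len])
    nt <- length(starts)
    site_list[[g]] <- tibble::tibble(
      chrom = config$genome$chrom[g],
      tag = tag0 + rep(seq_len(nt), each = config$sites_per_tag),
      pos = rep(starts, each = config$sites_per_tag) +
        rep(seq_len(config$sites_per_tag) - 1L, times = nt)
    )
    tag0 <- tag0 + nt
  }
  sites <- dplyr::bind_rows(site_list)
  S <- nrow(sites)

  # ancestral state
  set.seed(ss[2])
  poly <- stats::runif(S) < config$poly_rate
  p0 <- numeric(S)
  p0[poly] <- sample(config$freq_grid, sum(poly), replace = TRUE,
                     prob = 1 / config$freq_grid)
  anc <- sample.int(4L, S, replace = TRUE)
  shift <- sample.int(3L, S, replace = TRUE)
  der <- ((anc - 1L + shift) %% 4L) + 1L
  sites$anc <- anc
  sites$der <- der
  sites$p0 <- p0

  freq <- matrix(0, S, nrow(config$populations))
  colnames(freq) <- config$populations$pop
  for (j in seq_len(nrow(config$populations))) {
    freq[poly, j] <- draw_population_frequencies(p0[poly],
                                                 config$populations$f[j])
  }

  set.seed(ss[3])
  freq <- apply_scenarios(freq, sites, config$scenarios, config$populations)

  set.seed(ss[4])
  emitted <- emit_read_counts(freq, sites, config$populations,
                              coverage = config$coverage,
                              error = config$error,
                              dropout_freq = config$dropout_freq)

  scen_tbl <- if (length(config$scenarios) > 0) {
    dplyr::bind_rows(lapply(config$scenarios, function(sc) tibble::tibble(
      type = sc$type, chrom = sc$chrom,
      start = sc$center - sc$width / 2, end = sc$center + sc$width / 2,
      center = sc$center,
      parallel = if (sc$type == "sweep") sc$parallel else NA
    )))
  } else {
    tibble::tibble(type = character(), chrom = character(),
                   start = numeric(), end = numeric(), center = numeric(),
                   parallel = logical())
  }

  list(
    counts = emitted$counts,
    popmap = emitted$popmap,
    genome = config$genome,
    truth = list(
      calls = emitted$truth,
      sites = sites,
      frequencies = freq,
      scenarios = scen_tbl
    ),
    config = config
  )
}
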