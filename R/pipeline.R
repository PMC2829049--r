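#' Standard comparison set for an oceanic/freshwater design
#'
#' Builds the named comparison list the scan revolves around: the overall
#' oceanic-versus-freshwater comparison (both groups pooled), every
#' pairwise freshwater-oceanic comparison, the comparison among freshwater
#' populations, and the oceanic pair.
#'
#' @param oceanic,freshwater Character vectors of population labels.
#' @return Named list of comparisons; each comparison is a named list of
#'   pools suitable for [site_stats()].
#' @examples
#' standard_comparisons(c("RS", "RB"), c("BP", "BL", "ML"))
#' @export
standard_comparisons <- function(oceanic, freshwater) {
  comps <- list(overall = list(oceanic = oceanic, freshwater = freshwater))
  for (fw in freshwater) {
    for (oc in oceanic) {
      comps[[paste0(fw, "_vs_", oc)]] <-
        stats::setNames(list(fw, oc), c(fw, oc))
    }
  }
  comps$among_freshwater <- stats::setNames(as.list(freshwater), freshwater)
  if (length(oceanic) >= 2) {
    comps$oceanic_pair <- stats::setNames(as.list(oceanic), oceanic)
  }
  comps
}

#' Run the full genome-scan pipeline
#'
#' Calls genotypes from read counts, computes per-site statistics for the
#' standard oceanic/freshwater comparisons, smooths FST along the genome,
#' assigns bootstrap significance to every window, and delineates candidate
#' regions of parallel divergent selection: windows with
#' `p_elevated < p_threshold` in the overall comparison *and* in all
#' pairwise freshwater-oceanic comparisons, extended by `2 * sigma`
#' margins. Per-site diversity (`pi`, `h`) of the full sample is smoothed
#' alongside.
#'
#' @param counts Read-count tibble (see [call_genotypes()]).
#' @param popmap Tibble `individual`, `pop`.
#' @param genome Tibble `chrom`, `length`.
#' @param oceanic,freshwater Population labels of the two habitat groups.
#' @param alpha Genotype-assignment significance level.
#' @param sigma,truncation,step,weight Smoothing parameters, see
#'   [smooth_track()].
#' @param plan [bootstrap_plan()] for the FST tracks.
#' @param p_threshold Window significance threshold for region delineation.
#' @param seed Master seed for the bootstrap stage.
#' @param bootstrap Assign bootstrap p-values and delineate regions?
#' @param g_tests Run per-SNP G-tests (overall comparison)?
#' @param keep_calls Keep the full per-individual call table in the result?
#' @return An object of class `radscan_result` with elements `stats` (per
#'   comparison), `tracks` (smoothed FST per comparison, plus `pi` and `h`),
#'   `regions`, `comparisons`, `params` and summary counts. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
run_radscan <- function(counts, popmap, genome,
                        oceanic = c("RS", "RB"),
                        freshwater = c("BP", "BL", "ML"),
                        alpha = 0.05, sigma = 150000, truncation = 3,
                        step = 100000, weight = "npairs",
                        plan = bootstrap_plan("fst"),
                        p_threshold = 1e-5, seed = 1,
                        bootstrap = TRUE, g_tests = FALSE,
                        keep_calls = FALSE) {
  pops <- unique(popmap$pop)
  missing_pops <- setdiff(c(oceanic, freshwater), pops)
  if (length(missing_pops) > 0) {
    stop("populations not in popmap: ", paste(missing_pops, collapse = ", "),
         call. = FALSE)
  }
  calls <- call_genotypes(counts, alpha = alpha)
  ac <- allele_counts(calls, popmap)
  comps <- standard_comparisons(oceanic, freshwater)
  pairwise <- setdiff(names(comps), c("overall", "among_freshwater", "oceanic_pair"))

  stats_list <- purrr::imap(comps, function(pools, nm) {
    site_stats(ac, pools, g_test = g_tests && nm == "overall")
  })
  tracks <- purrr::map(stats_list, function(s) {
    smooth_track(s, genome, "fst", sigma = sigma, truncation = truncation,
                 step = step, weight = weight)
  })

  all_stats <- site_stats(ac, NULL, g_test = FALSE)
  tracks$pi <- smooth_track(all_stats, genome, "pi", sigma = sigma,
                            truncation = truncation, step = step,
                            weight = weight)
  tracks$h <- smooth_track(all_stats, genome, "h", sigma = sigma,
                           truncation = truncation, step = step,
                           weight = weight)

  regions <- NULL
  if (bootstrap) {
    region_comps <- c("overall", pairwise)
    for (i in seq_along(region_comps)) {
      nm <- region_comps[i]
      tracks[[nm]] <- bootstrap_track(tracks[[nm]], stats_list[[nm]], "fst",
                                      plan = plan, seed = seed + i,
                                      sigma = sigma, truncation = truncation,
                                      weight = weight)
    }
    regions <- delineate_regions(tracks[region_comps],
                                 threshold = p_threshold, genome = genome,
                                 sigma = sigma)
  }

  assigned <- calls$status == "assigned"
  structure(list(
    stats = stats_list,
    diversity = all_stats,
    tracks = tracks,
    regions = regions,
    comparisons = comps,
    calls = if (keep_calls) calls else NULL,
    summary = tibble::tibble(
      n_sites = dplyr::n_distinct(all_stats$chrom, all_stats$pos),
      n_individuals = dplyr::n_distinct(counts$individual),
      prop_assigned = mean(assigned),
      n_snps_overall = sum(stats_list$overall$is_snp),
      mean_pi = mean(all_stats$pi, na.rm = TRUE),
      mean_fst_overall = mean(stats_list$overall$fst, na.rm = TRUE),
      n_regions = if (is.null(regions)) NA_integer_ else nrow(regions)
    ),
    params = list(alpha = alpha, sigma = sigma, truncation = truncation,
                  step = step, weight = weight, p_threshold = p_threshold,
                  seed = seed)
  ), class = "radscan_result")
}

#' @export
print.radscan_result <- function(x, ...) {
  s <- x$summary
  cat("<radscan_result>\n")
  cat(sprintf("  %d sites, %d individuals, %.1f%% of calls assigned\n",
              s$n_sites, s$n_individuals, 100 * s$prop_assigned))
  cat(sprintf("  %d SNPs (overall comparison); mean pi = %.4g, mean FST = %.4g\n",
              s$n_snps_overall, s$mean_pi, s$mean_fst_overall))
  if (!is.null(x$regions)) {
    cat(sprintf("  %d delineated region(s) at p < %g\n",
                nrow(x$regions), x$params$p_threshold))
  }
  invisible(x)
}

#' Tidy the delineated regions of a scan
#'
#' @param x A `radscan_result`.
#' @param ... Unused.
#' @return The region tibble (empty if the bootstrap stage was skipped).
#' @export
#' @exportS3Method generics::tidy
tidy.radscan_result <- function(x, ...) {
  if (is.null(x$regions)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          peak_center = numeric(), peak_value = numeric(),
                          peak_p = numeric()))
  }
  x$regions
}

#' One-row summary of a scan
#'
#' @inheritParams tidy.radscan_result
#' @return A one-row tibble: site, SNP and individual counts, assignment
#'   rate, mean diversity and differentiation, region count.
#' @export
#' @exportS3Method generics::glance
glance.radscan_result <- function(x, ...) {
  x$summary
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
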