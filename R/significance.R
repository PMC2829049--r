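#' Bootstrap replicate plan for window significance
#'
#' Staged replicate escalation: each window starts with a small number of
#' resampling replicates and multiplies it by `factor` until the smaller
#' tail count reaches `trigger` exceedances or the cap is hit, concentrating
#' effort on extreme windows. Statistic-specific defaults follow the scheme
#' used for the oceanic/freshwater scan: 100 initial replicates for `pi`/`h`
#' (cap 1e6), 1000 for `d` (cap 1e6) and 10000 for `fst`/`rho` (cap 1e7).
#'
#' @param statistic One of `"pi"`, `"h"`, `"fst"`, `"rho"`, `"d"`.
#' @param initial,cap Override the per-statistic defaults.
#' @param factor Escalation factor (> 1, default 10).
#' @param trigger Minimum minority-tail count below which replicates are
#'   escalated (default 10).
#' @return A list of class `"bootstrap_plan"`.
#' @export
bootstrap_plan <- function(statistic = c("fst", "pi", "h", "rho", "d"),
                           initial = NULL, cap = NULL,
                           factor = 10, trigger = 10) {
  statistic <- match.arg(statistic)
  defaults <- list(
    pi = c(100, 1e6), h = c(100, 1e6), d = c(1000, 1e6),
    fst = c(10000, 1e7), rho = c(10000, 1e7)
  )[[statistic]]
  initial <- if (is.null(initial)) defaults[1] else initial
  cap <- if (is.null(cap)) defaults[2] else cap
  stopifnot(initial >= 1, initial <= cap, factor > 1, trigger >= 1)
  structure(list(statistic = statistic, initial = initial, cap = cap,
                 factor = factor, trigger = trigger),
            class = "bootstrap_plan")
}

# deterministic per-window, per-round seeds derived from one master seed,
# so results do not depend on the order windows are processed
substream_seeds <- function(seed, n_windows, n_rounds) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(matrix(sample.int(.Machine$integer.max - 1L, n_windows * n_rounds),
                    nrow = n_windows))
}

# one window's escalating bootstrap (compiled inner loop; see
# src/kernels.cpp). Returns c(p_elev, p_red, R). Replicates equal to the
# observed value count toward BOTH tails.
window_bootstrap <- function(obs, kern, pool_v, pool_w, plan, seeds) {
  R <- plan$initial
  round <- 1L
  repeat {
    tails <- cpp_window_boot(obs, kern, pool_v, pool_w, R, seeds[round])
    if (min(tails) >= plan$trigger || R >= plan$cap) {
      return(c(tails[1] / R, tails[2] / R, R))
    }
    R <- min(R * plan$factor, plan$cap)
    round <- round + 1L
  }
}

#' Bootstrap significance of smoothed windows
#'
#' Assigns elevation/reduction p-values to each window of a smoothed track
#' by genome-wide resampling: for each replicate, every contributing site of
#' the window is assigned a `(value, n_k)` pair drawn with replacement from
#' the genome-wide pool of per-site values of the same statistic, the
#' weighted kernel average is recomputed with the original kernel weights,
#' and `p_elevated` (`p_reduced`) is the proportion of replicates at or
#' above (at or below) the observed window value. This yields a null of no
#' spatial autocorrelation while preserving window geometry and the
#' genome-wide distribution of the statistic and its sample sizes.
#' Replicates escalate per the [bootstrap_plan()]. Windows whose observed
#' value exceeds every pool value (or falls below every pool value) are
#' assigned a zero tail at the plan cap without sampling, since no convex
#' combination of pool values can cross the observed value.
#'
#' @param track Smoothed track from [smooth_track()].
#' @param stats The per-site statistics the track was computed from.
#' @param value Name of the statistic column (string), as in
#'   [smooth_track()].
#' @param plan A [bootstrap_plan()].
#' @param seed Master seed; every window/round uses a substream derived
#'   from it, so results are reproducible and order-independent.
#' @inheritParams smooth_track
#' @return `track` with extra columns `p_elevated`, `p_reduced`,
#'   `replicates` and `flag` (`"<1/R"` when a tail had zero exceedances).
#' @export
bootstrap_track <- function(track, stats, value, plan = bootstrap_plan("fst"),
                            seed = 1, sigma = 150000, truncation = 3,
                            weight = c("npairs", "n", "nm1")) {
  weight <- match.arg(weight)
  keep <- !is.na(stats[[value]])
  stats <- stats[keep, ]
  if (nrow(stats) < 2) stop("resampling pool needs at least 2 sites", call. = FALSE)
  pool_v <- stats[[value]]
  pool_w <- site_weight(stats$n_k, weight)
  vmax <- max(pool_v)
  vmin <- min(pool_v)
  radius <- truncation * sigma

  n_rounds <- ceiling(log(plan$cap / plan$initial, plan$factor)) + 1L
  seeds <- substream_seeds(seed, nrow(track), n_rounds)

  p_elev <- p_red <- rep(NA_real_, nrow(track))
  reps <- rep(NA_real_, nrow(track))
  for (ch in unique(track$chrom)) {
    sub <- stats[stats$chrom == ch, ]
    ord <- order(sub$pos)
    p <- sub$pos[ord]
    sw <- pool_w[stats$chrom == ch][ord]
    rows <- which(track$chrom == ch)
    lo <- findInterval(track$center[rows] - radius, p) + 1L
    hi <- findInterval(track$center[rows] + radius, p)
    for (i in seq_along(rows)) {
      r <- rows[i]
      if (hi[i] < lo[i] || is.na(track$value[r])) next
      obs <- track$value[r]
      if (obs > vmax || obs < vmin) {
        p_elev[r] <- as.numeric(obs < vmin)
        p_red[r] <- as.numeric(obs > vmax)
        reps[r] <- plan$cap
        next
      }
      sel <- lo[i]:hi[i]
      kern <- exp(-(p[sel] - track$center[rows[i]])^2 / (2 * sigma^2)) * sw[sel]
      res <- window_bootstrap(obs, kern, pool_v, pool_w, plan,
                              seeds[r, , drop = TRUE])
      p_elev[r] <- res[1]
      p_red[r] <- res[2]
      reps[r] <- res[3]
    }
  }
  track$p_elevated <- p_elev
  track$p_reduced <- p_red
  track$replicates <- reps
  track$flag <- dplyr::case_when(
    is.na(p_elev) ~ NA_character_,
    p_elev == 0 | p_red == 0 ~ "<1/R",
    TRUE ~ ""
  )
  track
}

#' Bootstrap significance of windowed Tajima's D
#'
#' As [bootstrap_track()], but each replicate redraws, for every site of the
#' window, a per-site `(pi, SNP indicator, n_k)` triple from the genome-wide
#' pool and recomputes the D statistic of the resampled window. Replicates
#' for which D is undefined (fewer than 2 resampled SNPs) count toward
#' neither tail.
#'
#' @param track Windowed D track from [tajima_track()].
#' @param stats Per-site statistics the track was computed from.
#' @inheritParams bootstrap_track
#' @param sigma Window half-width in bp (same value used in
#'   [tajima_track()]).
#' @return `track` with columns `p_elevated`, `p_reduced`, `replicates`,
#'   `flag`.
#' @export
bootstrap_tajima <- function(track, stats, plan = bootstrap_plan("d"),
                             seed = 1, sigma = 150000) {
  stats <- stats[!is.na(stats$pi), ]
  if (nrow(stats) < 2) stop("resampling pool needs at least 2 sites", call. = FALSE)
  pool_pi <- stats$pi
  pool_snp <- as.numeric(stats$is_snp)
  pool_nk <- stats$n_k

  n_rounds <- ceiling(log(plan$cap / plan$initial, plan$factor)) + 1L
  seeds <- substream_seeds(seed, nrow(track), n_rounds)

  p_elev <- p_red <- rep(NA_real_, nrow(track))
  reps <- rep(NA_real_, nrow(track))
  for (ch in unique(track$chrom)) {
    sub <- stats[stats$chrom == ch, ]
    p <- sort(sub$pos)
    rows <- which(track$chrom == ch)
    lo <- findInterval(track$center[rows] - sigma, p) + 1L
    hi <- findInterval(track$center[rows] + sigma, p)
    for (i in seq_along(rows)) {
      r <- rows[i]
      m <- hi[i] - lo[i] + 1L
      if (m < 1L || is.na(track$value[r])) next
      obs <- track$value[r]
      R <- plan$initial
      round <- 1L
      repeat {
        tails <- cpp_tajima_boot(obs, m, pool_pi, pool_snp, pool_nk, R,
                                 seeds[r, round])
        if (min(tails[1:2]) >= plan$trigger || R >= plan$cap) {
          p_elev[r] <- tails[1] / R
          p_red[r] <- tails[2] / R
          reps[r] <- R
          break
        }
        R <- min(R * plan$factor, plan$cap)
        round <- round + 1L
      }
    }
  }
  track$p_elevated <- p_elev
  track$p_reduced <- p_red
  track$replicates <- reps
  track$flag <- dplyr::case_when(
    is.na(p_elev) ~ NA_character_,
    p_elev == 0 | p_red == 0 ~ "<1/R",
    TRUE ~ ""
  )
  track
}

#' Benjamini-Hochberg step-up false discovery rate correction
#'
#' Sorts the p-values ascending, finds the largest rank `k` with
#' `p_(k) <= k * alpha / m`, and rejects the `k` smallest hypotheses. The
#' returned `threshold = k * alpha / m` is the equivalent per-test p-value
#' cutoff.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s are dropped from
#'   `m`).
#' @param alpha Target false discovery rate.
#' @return A list with `reject` (logical, aligned with `p`), `n_reject`,
#'   and `threshold`.
#' @examples
#' bh_correct(c(0.01, 0.02, 0.9, 1.0), alpha = 0.05)
#' @export
bh_correct <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  ok <- which(!is.na(p))
  m <- length(ok)
  reject <- rep(FALSE, length(p))
  if (m == 0) return(list(reject = reject, n_reject = 0L, threshold = 0))
  ord <- ok[order(p[ok])]
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * alpha / m)
  k <- if (length(below) > 0) max(below) else 0L
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  list(reject = reject, n_reject = as.integer(k), threshold = k * alpha / m)
}

#' Delineate candidate regions from significant windows
#'
#' Windows significant at `threshold` in *all* supplied p-value tracks
#' (e.g. the overall freshwater-oceanic comparison together with all six
#' pairwise freshwater-oceanic comparisons) are grouped into maximal runs of
#' consecutive grid windows (up to `gap` non-significant windows may be
#' bridged; default 0). Each run is extended by `2 * sigma` beyond its
#' outermost significant window centre, clipped to the chromosome, and
#' overlapping extended runs are merged.
#'
#' @param ptracks A p-value track from [bootstrap_track()], or a list of
#'   them on the identical window grid.
#' @param threshold Significance threshold (default 1e-5); a window passes
#'   when `p < threshold` (a flagged zero tail counts as significant).
#' @param direction `"elevated"` or `"reduced"`: which tail to use.
#' @param genome Tibble with `chrom`, `length` for clipping.
#' @param sigma Kernel bandwidth in bp; margins are `2 * sigma`.
#' @param gap Number of consecutive non-significant windows tolerated
#'   inside a run (default 0).
#' @return A tibble of regions: `chrom`, `start`, `end` (1-based,
#'   inclusive), `n_windows`, `peak_center`, `peak_value`, `peak_p`.
#' @export
delineate_regions <- function(ptracks, threshold = 1e-5,
                              direction = c("elevated", "reduced"),
                              genome = NULL, sigma = 150000, gap = 0) {
  direction <- match.arg(direction)
  if (is.data.frame(ptracks)) ptracks <- list(ptracks)
  grid <- ptracks[[1]][c("chrom", "center")]
  for (t in ptracks[-1]) {
    if (!identical(t[c("chrom", "center")], grid)) {
      stop("all p-value tracks must share one window grid", call. = FALSE)
    }
  }
  pcol <- paste0("p_", direction)
  sig <- rep(TRUE, nrow(grid))
  for (t in ptracks) {
    p <- t[[pcol]]
    sig <- sig & !is.na(p) & p < threshold
  }
  ref <- ptracks[[1]]

  regions <- list()
  for (ch in unique(grid$chrom)) {
    rows <- which(grid$chrom == ch & sig)
    if (length(rows) == 0) next
    centers <- grid$center[rows]
    step <- if (nrow(grid[grid$chrom == ch, ]) > 1) {
      diff(sort(unique(grid$center[grid$chrom == ch])))[1]
    } else {
      2 * sigma
    }
    breaks <- which(diff(centers) > (gap + 1) * step + 1e-9)
    run_id <- cumsum(c(1, seq_along(centers)[-1] %in% (breaks + 1)))
    len <- if (!is.null(genome)) genome$length[match(ch, genome$chrom)] else Inf
    for (g in unique(run_id)) {
      rc <- centers[run_id == g]
      rr <- rows[run_id == g]
      peak_i <- rr[which.max(if (direction == "elevated") ref$value[rr] else -ref$value[rr])]
      regions[[length(regions) + 1L]] <- tibble::tibble(
        chrom = ch,
        start = max(1, min(rc) - 2 * sigma),
        end = min(len, max(rc) + 2 * sigma),
        n_windows = length(rc),
        peak_center = ref$center[peak_i],
        peak_value = ref$value[peak_i],
        peak_p = min(vapply(ptracks, function(t) t[[pcol]][peak_i], numeric(1)))
      )
    }
  }
  if (length(regions) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          peak_center = numeric(), peak_value = numeric(),
                          peak_p = numeric()))
  }
  out <- dplyr::bind_rows(regions) %>% dplyr::arrange(.data$chrom, .data$start)
  # merge extended runs that overlap after adding margins
  merged <- list()
  cur <- out[1, ]
  for (i in seq_len(nrow(out))[-1]) {
    nxt <- out[i, ]
    if (nxt$chrom == cur$chrom && nxt$start <= cur$end) {
      cur$end <- max(cur$end, nxt$end)
      cur$n_windows <- cur$n_windows + nxt$n_windows
      better <- if (direction == "elevated") {
        nxt$peak_value > cur$peak_value
      } else {
        nxt$peak_value < cur$peak_value
      }
      if (isTRUE(better)) {
        cur$peak_center <- nxt$peak_center
        cur$peak_value <- nxt$peak_value
      }
      cur$peak_p <- min(cur$peak_p, nxt$peak_p)
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- nxt
    }
  }
  merged[[length(merged) + 1L]] <- cur
  dplyr::bind_rows(merged)
}
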