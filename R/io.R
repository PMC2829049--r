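#' Read a per-site nucleotide read-count table
#'
#' Tab-separated file with header
#' `chrom pos individual nA nC nG nT` (1-based positions). A fifth
#' nucleotide-count column (ambiguous reads), if present, is dropped with a
#' message — ambiguous reads are excluded from the model. Malformed rows,
#' non-positive positions, negative counts and duplicate
#' `(chrom, pos, individual)` rows are errors.
#'
#' @param path File path.
#' @return A validated tibble ordered by `(chrom, pos, individual)`.
#' @export
read_counts <- function(path) {
  x <- suppressWarnings(readr::read_tsv(path, show_col_types = FALSE,
                                        progress = FALSE))
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    stop("malformed row(s) in ", path, ": line(s) ",
         paste(utils::head(unique(pr$row) + 1L, 5), collapse = ", "),
         call. = FALSE)
  }
  if ("nN" %in% names(x)) {
    message("dropping ambiguous-read column 'nN'")
    x$nN <- NULL
  }
  required <- c("chrom", "pos", "individual", "nA", "nC", "nG", "nT")
  if (!identical(names(x), required)) {
    stop("counts file must have columns: ", paste(required, collapse = " "),
         call. = FALSE)
  }
  num <- c("pos", "nA", "nC", "nG", "nT")
  if (any(!vapply(x[num], is.numeric, logical(1)))) {
    stop("non-numeric values in a numeric column of ", path, call. = FALSE)
  }
  if (anyNA(x)) {
    stop("malformed row(s) in ", path, ": line(s) ",
         paste(utils::head(which(!stats::complete.cases(x)) + 1L, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(x$pos < 1)) {
    stop("positions are 1-based; found pos < 1 at line(s) ",
         paste(utils::head(which(x$pos < 1) + 1L, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(x[c("nA", "nC", "nG", "nT")] < 0)) {
    stop("negative read counts in ", path, call. = FALSE)
  }
  if (vctrs::vec_duplicate_any(x[c("chrom", "pos", "individual")])) {
    stop("duplicate (chrom, pos, individual) rows in ", path, call. = FALSE)
  }
  dplyr::arrange(x, .data$chrom, .data$pos, .data$individual)
}

#' Read a population map
#'
#' Two-column tab-separated file `individual<TAB>pop`, with or without a
#' header line.
#'
#' @param path File path.
#' @return A tibble with columns `individual`, `pop`.
#' @export
read_popmap <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("^individual\t", first)
  x <- readr::read_tsv(path, col_names = c("individual", "pop"),
                       skip = as.integer(has_header),
                       col_types = "cc", progress = FALSE)
  if (anyNA(x) || any(x == "")) stop("malformed popmap ", path, call. = FALSE)
  if (anyDuplicated(x$individual) > 0) {
    stop("duplicate individuals in popmap ", path, call. = FALSE)
  }
  x
}

#' Read a genome layout
#'
#' Two-column tab-separated file `chrom<TAB>length` (bp), with or without a
#' header. Chromosome order in this file defines plotting and output order.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_genome <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("^chrom\t", first)
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       skip = as.integer(has_header),
                       col_types = "cd", progress = FALSE)
  if (anyNA(x) || any(x$length <= 0)) stop("malformed genome table ", path, call. = FALSE)
  if (anyDuplicated(x$chrom) > 0) stop("duplicate chromosomes in ", path, call. = FALSE)
  x
}

#' Write a read-count table
#'
#' Inverse of [read_counts()]; a written file reads back identically.
#'
#' @param counts Count tibble.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Write a smoothed track as bedGraph
#'
#' Each window becomes a 0-based half-open interval of width `step` centred
#' on the window centre, clipped to the chromosome; windows with missing
#' values are skipped.
#'
#' @param track Track tibble (`chrom`, `center`, `value`).
#' @param genome Genome tibble for clipping.
#' @param path Output path.
#' @param step Window grid spacing in bp.
#' @param name Track name written in the bedGraph header line.
#' @export
write_track_bedgraph <- function(track, genome, path, step = 100000,
                                 name = "radscan") {
  keep <- !is.na(track$value)
  t <- track[keep, ]
  len <- genome$length[match(t$chrom, genome$chrom)]
  start <- pmax(0, t$center - step / 2)
  end <- pmin(len, t$center + step / 2)
  lines <- c(
    sprintf("track type=bedGraph name=\"%s\"", name),
    sprintf("%s\t%d\t%d\t%g", t$chrom, as.integer(round(start)),
            as.integer(round(end)), t$value)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write delineated regions as BED
#'
#' 1-based inclusive regions become 0-based half-open BED intervals; the
#' score column is `min(1000, round(-10 * log10(peak p)))`, with p-values of
#' 0 (a zero bootstrap tail) given the maximum score.
#'
#' @param regions Region tibble from [delineate_regions()].
#' @param path Output path.
#' @param name Feature name prefix (statistic/comparison label).
#' @export
write_regions_bed <- function(regions, path, name = "region") {
  score <- ifelse(is.na(regions$peak_p) | regions$peak_p <= 0, 1000,
                  pmin(1000, round(-10 * log10(regions$peak_p))))
  lines <- sprintf("%s\t%d\t%d\t%s_%d\t%d",
                   regions$chrom,
                   as.integer(regions$start - 1),
                   as.integer(regions$end),
                   name, seq_len(nrow(regions)),
                   as.integer(score))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write genotype calls as a minimal VCF
#'
#' Emits VCF 4.2 with genotypes only (GT field), one sample column per
#' individual, at the requested sites (default: all SNP sites, i.e. sites
#' with two or more alleles among assigned genotypes). Unassigned and
#' no-data genotypes become `./.`. The reference allele is the major allele
#' among assigned calls.
#'
#' @param calls Calls from [call_genotypes()].
#' @param path Output path.
#' @param sites Optional tibble of `chrom`, `pos` to restrict output.
#' @export
write_genotypes_vcf <- function(calls, path, sites = NULL) {
  ac <- allele_counts(calls, tibble::tibble(
    individual = unique(calls$individual), pop = "all"
  ))
  tot <- ac %>%
    dplyr::group_by(.data$chrom, .data$pos) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(NUCS), sum), .groups = "drop")
  M <- as.matrix(tot[, NUCS])
  n_alleles <- rowSums(M > 0)
  if (is.null(sites)) {
    tot <- tot[n_alleles >= 2, ]
    M <- M[n_alleles >= 2, , drop = FALSE]
  } else {
    keep <- match(paste(sites$chrom, sites$pos), paste(tot$chrom, tot$pos))
    tot <- tot[keep, ]
    M <- M[keep, , drop = FALSE]
  }
  inds <- sort(unique(calls$individual))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", inds), collapse = "\t")
  )
  rows <- character(nrow(tot))
  calls_key <- paste(calls$chrom, calls$pos, calls$individual)
  for (i in seq_len(nrow(tot))) {
    counts <- M[i, ]
    ord <- order(counts, decreasing = TRUE)
    ref <- ord[1]
    alts <- ord[counts[ord] > 0][-1]
    allele_idx <- integer(4)
    allele_idx[ref] <- 0L
    allele_idx[alts] <- seq_along(alts)
    ck <- match(paste(tot$chrom[i], tot$pos[i], inds), calls_key)
    gt <- vapply(ck, function(k) {
      if (is.na(k) || calls$status[k] != "assigned") return("./.")
      a <- sort(allele_idx[match(c(calls$allele1[k], calls$allele2[k]), NUCS)])
      paste(a, collapse = "/")
    }, character(1))
    alt_str <- if (length(alts) > 0) paste(NUCS[alts], collapse = ",") else "."
    rows[i] <- paste(c(tot$chrom[i], tot$pos[i], ".", NUCS[ref], alt_str,
                       ".", "PASS", ".", "GT", gt), collapse = "\t")
  }
  readr::write_lines(c(header, rows), path)
  invisible(path)
}
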