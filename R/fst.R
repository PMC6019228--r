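#' Sliding-window Hudson Fst between two sample groups
#'
#' Per SNP, with allele frequencies p1, p2 estimated from non-missing
#' genotypes and allele counts n1, n2 (two per genotyped sample), the
#' Hudson-style components are
#' `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`. Window Fst is the ratio of averages
#' `sum(N) / sum(D)` over the SNPs falling in each window. Windows are tiled
#' per chromosome from position 1 in steps of `step_bp`; windows holding no
#' informative SNP get `NaN`. The estimator is chosen for its robustness to
#' the very unequal group sizes of a 3-case versus pooled-control design;
#' negative estimates are reported as-is.
#'
#' @param gm A [genotype_matrix()].
#' @param case_ids,control_ids Disjoint, non-empty sample id sets.
#' @param window_bp Window span in bp.
#' @param step_bp Step between window starts in bp.
#' @return `data.frame` of class `fst_windows`: chrom, start, end, fst,
#'   n_snps. SNPs with fewer than 2 observed alleles in either group are
#'   skipped.
#' @export
windowed_fst <- function(gm, case_ids, control_ids, window_bp = 50000,
                         step_bp = 10000) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(case_ids) < 1 || length(control_ids) < 1) {
    stop("both groups need at least one sample")
  }
  if (length(intersect(case_ids, control_ids))) {
    stop("case and control sets must be disjoint")
  }
  unknown <- setdiff(c(case_ids, control_ids), gm$sample_ids)
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }

  comp <- fst_site_components(gm, case_ids, control_ids)
  v <- gm$variants

  out <- lapply(unique(v$chrom), function(ch) {
    on_ch <- which(v$chrom == ch)
    pos <- v$pos[on_ch]
    informative <- !is.na(comp$N[on_ch])
    max_pos <- max(pos)
    starts <- seq(1L, max_pos, by = step_bp)
    ends <- starts + as.integer(window_bp) - 1L
    # index SNPs into windows via sorted positions and cumulative sums
    pos_i <- pos[informative]
    N_i <- comp$N[on_ch][informative]
    D_i <- comp$D[on_ch][informative]
    cN <- c(0, cumsum(N_i))
    cD <- c(0, cumsum(D_i))
    lo <- findInterval(starts - 1L, pos_i)        # SNPs strictly before start
    hi <- findInterval(ends, pos_i)               # SNPs at or before end
    n_snps <- hi - lo
    sumN <- cN[hi + 1L] - cN[lo + 1L]
    sumD <- cD[hi + 1L] - cD[lo + 1L]
    fst <- ifelse(n_snps > 0 & sumD > 0, sumN / sumD, NaN)
    data.frame(chrom = ch, start = starts, end = ends, fst = fst,
               n_snps = n_snps, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fst_windows", "data.frame")
  res
}

# per-site Hudson components; NA at sites skipped for sample size
fst_site_components <- function(gm, case_ids, control_ids) {
  g1 <- gm$calls[case_ids, , drop = FALSE]
  g2 <- gm$calls[control_ids, , drop = FALSE]
  n1 <- 2L * colSums(g1 != -1L)
  n2 <- 2L * colSums(g2 != -1L)
  alt1 <- colSums(g1 * (g1 != -1L))
  alt2 <- colSums(g2 * (g2 != -1L))
  p1 <- ifelse(n1 > 0, alt1 / n1, NA_real_)
  p2 <- ifelse(n2 > 0, alt2 / n2, NA_real_)
  usable <- n1 >= 2L & n2 >= 2L
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  N[!usable] <- NA_real_
  D[!usable] <- NA_real_
  list(N = N, D = D)
}

#' Empirical top-percentile selection of Fst windows
#'
#' @param windows An `fst_windows` table.
#' @param q Quantile in [0, 1]; the threshold is the empirical `q`-quantile
#'   (linear interpolation) of the non-NaN window Fst values.
#' @return List with `threshold` and `selected` (the windows with
#'   `fst >= threshold`).
#' @export
top_percentile <- function(windows, q = 0.99) {
  vals <- windows$fst[is.finite(windows$fst)]
  if (!length(vals)) stop("no windows with a defined Fst")
  threshold <- unname(stats::quantile(vals, probs = q, type = 7))
  selected <- windows[is.finite(windows$fst) & windows$fst >= threshold, ,
                      drop = FALSE]
  list(threshold = threshold, selected = selected)
}

#' Overlap selected Fst windows with shared ROH regions
#'
#' A window overlaps a region when they share at least one base pair.
#'
#' @param windows Selected `fst_windows` rows.
#' @param regions Shared-region intervals ([genomic_intervals()]).
#' @return `data.frame` with one row per region that is hit: the region, the
#'   number of overlapping windows and the maximum window Fst (`max_fst`).
#' @export
overlap_with_roh <- function(windows, regions) {
  if (nrow(regions) == 0 || nrow(windows) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_fst = numeric(), stringsAsFactors = FALSE))
  }
  win_gr <- as_granges(data.frame(chrom = windows$chrom,
                                  start = windows$start, end = windows$end))
  reg_gr <- as_granges(regions)
  hits <- GenomicRanges::findOverlaps(reg_gr, win_gr)
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_fst = numeric(), stringsAsFactors = FALSE))
  }
  reg_idx <- S4Vectors::queryHits(hits)
  win_idx <- S4Vectors::subjectHits(hits)
  agg <- tapply(windows$fst[win_idx], reg_idx, max, na.rm = TRUE)
  counts <- tapply(win_idx, reg_idx, length)
  keep <- as.integer(names(agg))
  data.frame(chrom = regions$chrom[keep], start = regions$start[keep],
             end = regions$end[keep],
             n_windows = as.integer(counts),
             max_fst = as.numeric(agg), stringsAsFactors = FALSE)
}

#' Merge selected windows into maximal regions
#'
#' Optional post-processing: overlapping or book-ended selected windows are
#' merged into maximal intervals. Both the raw-window and merged-region
#' counts are meaningful summaries of a percentile scan and are reported
#' separately.
#'
#' @param windows Selected `fst_windows` rows.
#' @return A [genomic_intervals()] table of merged regions.
#' @export
merge_selected_windows <- function(windows) {
  if (nrow(windows) == 0) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  merge_intervals(data.frame(chrom = windows$chrom, start = windows$start,
                             end = windows$end))
}
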