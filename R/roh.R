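#' Parameters for the run-of-homozygosity scan
#'
#' Defaults reproduce the PLINK 1.07-style scan used for the pony genomes:
#' 50-SNP sliding windows, at most 3 heterozygous and 10 missing calls per
#' window, runs of at least 50 SNPs and 150 kb, at least one SNP per 3 kb,
#' and no gap above 100 kb between consecutive SNPs of a run. The window-hit
#' threshold (fraction of overlapping homozygous windows needed to flag a
#' SNP) is the PLINK default 0.05; it is not a run-level rule and is exposed
#' because edge behaviour depends on it.
#'
#' @param window_snps Window width in SNPs.
#' @param min_snps Minimum SNPs per reported run.
#' @param min_length_bp Minimum run length in bp.
#' @param max_missing_per_window Missing calls tolerated per window.
#' @param max_het_per_window Heterozygous calls tolerated per window.
#' @param max_gap_bp Maximum distance between consecutive SNPs of a run.
#' @param max_kb_per_snp Density bound: run length in kb divided by SNP count
#'   must not exceed this.
#' @param window_hit_threshold Fraction of overlapping homozygous windows at
#'   which a SNP is flagged homozygous, in (0, 1].
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, min_snps = 50,
                       min_length_bp = 150000,
                       max_missing_per_window = 10,
                       max_het_per_window = 3,
                       max_gap_bp = 100000,
                       max_kb_per_snp = 3,
                       window_hit_threshold = 0.05) {
  counts <- c(window_snps, min_snps, min_length_bp, max_gap_bp, max_kb_per_snp)
  if (any(counts <= 0)) stop("ROH scan counts must be positive")
  if (max_missing_per_window < 0 || max_het_per_window < 0) {
    stop("per-window tolerances must be >= 0")
  }
  if (window_hit_threshold <= 0 || window_hit_threshold > 1) {
    stop("window_hit_threshold must lie in (0, 1]")
  }
  structure(list(window_snps = as.integer(window_snps),
                 min_snps = as.integer(min_snps),
                 min_length_bp = as.integer(min_length_bp),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_gap_bp = as.integer(max_gap_bp),
                 max_kb_per_snp = max_kb_per_snp,
                 window_hit_threshold = window_hit_threshold),
            class = "roh_params")
}

#' Call runs of homozygosity for one sample
#'
#' Two-pass PLINK-style scan per chromosome. Pass 1 slides a window of
#' `window_snps` consecutive SNPs; a window is homozygous when it holds at
#' most `max_het_per_window` heterozygous and `max_missing_per_window`
#' missing calls; a SNP is flagged homozygous when at least
#' `window_hit_threshold` of the windows overlapping it are homozygous.
#' Pass 2 takes maximal runs of flagged SNPs, splits them wherever
#' consecutive SNPs lie more than `max_gap_bp` apart, and keeps runs passing
#' the SNP-count, length and density bounds. Segment boundaries are the
#' first and last SNP positions of the run.
#'
#' @param gm A [genotype_matrix()] (variants sorted; enforced by the class).
#' @param sample_id Sample to scan.
#' @param params A [roh_params()].
#' @return `data.frame` of class `roh_segments`: sample_id, chrom, start,
#'   end, n_snps, length_bp. Chromosomes with fewer SNPs than one window
#'   yield no calls.
#' @export
call_roh <- function(gm, sample_id, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(params, "roh_params"))
  g_all <- gm_sample_calls(gm, sample_id)
  chroms <- unique(gm$variants$chrom)
  res <- lapply(chroms, function(ch) {
    on_ch <- gm$variants$chrom == ch
    roh_scan_chrom(g_all[on_ch], gm$variants$pos[on_ch], params)
  })
  keep <- vapply(res, nrow, integer(1)) > 0
  if (!any(keep)) {
    out <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE)
  } else {
    body <- do.call(rbind, Map(function(ch, df) {
      df$chrom <- ch
      df
    }, chroms[keep], res[keep]))
    out <- data.frame(sample_id = sample_id, chrom = body$chrom,
                      start = body$start, end = body$end,
                      n_snps = body$n_snps, length_bp = body$length_bp,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  class(out) <- c("roh_segments", "data.frame")
  out
}

# one-chromosome scan; g codes and sorted positions
roh_scan_chrom <- function(g, pos, params) {
  empty <- data.frame(start = integer(), end = integer(),
                      n_snps = integer(), length_bp = integer())
  n <- length(g)
  w <- params$window_snps
  if (n < w) return(empty)

  het <- as.integer(g == 1L)
  mis <- as.integer(g == -1L)
  # windowed counts via cumulative sums; window i covers SNPs i..i+w-1
  chet <- c(0L, cumsum(het))
  cmis <- c(0L, cumsum(mis))
  iw <- seq_len(n - w + 1L)
  win_het <- chet[iw + w] - chet[iw]
  win_mis <- cmis[iw + w] - cmis[iw]
  win_ok <- win_het <= params$max_het_per_window &
    win_mis <= params$max_missing_per_window

  cok <- c(0L, cumsum(as.integer(win_ok)))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, n - w + 1L)
  n_cover <- hi - lo + 1L
  n_ok <- cok[hi + 1L] - cok[lo]
  flagged <- n_ok / n_cover >= params$window_hit_threshold

  segs <- list()
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    # split at bp gaps
    if (length(idx) > 1) {
      gap_after <- which(diff(pos[idx]) > params$max_gap_bp)
      piece_start <- c(1L, gap_after + 1L)
      piece_end <- c(gap_after, length(idx))
    } else {
      piece_start <- 1L
      piece_end <- 1L
    }
    for (p in seq_along(piece_start)) {
      sub <- idx[piece_start[p]:piece_end[p]]
      n_snps <- length(sub)
      len <- pos[sub[n_snps]] - pos[sub[1]] + 1L
      if (n_snps >= params$min_snps && len >= params$min_length_bp &&
          len / 1000 <= params$max_kb_per_snp * n_snps) {
        segs[[length(segs) + 1L]] <- data.frame(
          start = pos[sub[1]], end = pos[sub[n_snps]],
          n_snps = n_snps, length_bp = len)
      }
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

#' Regions of homozygosity shared by a set of samples
#'
#' Base-pair intersection: maximal intervals covered by at least one ROH
#' segment of every required sample. A sample with no segments yields an
#' empty result.
#'
#' @param segments `roh_segments` (or any data.frame with sample_id, chrom,
#'   start, end), pooled over samples.
#' @param required_samples Character vector; all of these must cover a bp for
#'   it to be shared.
#' @return A [genomic_intervals()] table of shared regions.
#' @export
shared_regions <- function(segments, required_samples) {
  if (length(required_samples) < 1) stop("required_samples must be non-empty")
  per_sample <- lapply(required_samples, function(s) {
    df <- segments[segments$sample_id == s, , drop = FALSE]
    if (nrow(df) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(as_granges(df))
  })
  shared <- Reduce(function(a, b) {
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  }, per_sample)
  granges_to_df(shared)
}

#' Fraction of the genome covered by a set of regions
#'
#' @param regions Intervals (merged internally before summing).
#' @param chromosome_lengths Named numeric vector of chromosome lengths, bp.
#' @return Proportion in [0, 1]: total merged region length over total
#'   genome length.
#' @export
genome_fraction <- function(regions, chromosome_lengths) {
  if (is.null(names(chromosome_lengths))) {
    stop("chromosome_lengths must be named")
  }
  merged <- merge_intervals(regions)
  if (nrow(merged) > 0) {
    unknown <- setdiff(merged$chrom, names(chromosome_lengths))
    if (length(unknown)) {
      stop("regions on chromosome(s) without a length: ",
           paste(unknown, collapse = ", "))
    }
    if (any(merged$end > chromosome_lengths[merged$chrom])) {
      stop("region extends past its chromosome length")
    }
  }
  sum(as.numeric(merged$end - merged$start + 1L)) /
    sum(as.numeric(chromosome_lengths))
}

#' Date selection from the length of a run of homozygosity
#'
#' A haplotype block of recombination length c Morgans has an expected age of
#' 1/(2c) generations, since recombination erodes shared tracts at rate c per
#' meiosis. With a uniform genetic map, c = length_Mb * cM_per_Mb / 100.
#' Years follow from a fixed generation interval (default 10, as used for
#' horse populations).
#'
#' @param length_mb ROH length in megabases (vectorised; all > 0).
#' @param cm_per_mb Local recombination rate, centimorgans per megabase.
#' @param generation_interval_years Years per generation.
#' @return `data.frame` of class `age_estimate` with columns length_mb,
#'   c_morgans, generations, years (full precision; the print method rounds
#'   to 2 decimals).
#' @examples
#' date_roh(2.522687)  # ~19.82 generations, ~198.20 years
#' @export
date_roh <- function(length_mb, cm_per_mb = 1.0,
                     generation_interval_years = 10) {
  if (any(length_mb <= 0)) stop("length_mb must be > 0")
  if (cm_per_mb <= 0) stop("cm_per_mb must be > 0")
  c_morgans <- length_mb * cm_per_mb / 100
  generations <- 1 / (2 * c_morgans)
  out <- data.frame(length_mb = length_mb, c_morgans = c_morgans,
                    generations = generations,
                    years = generations * generation_interval_years)
  attr(out, "cm_per_mb") <- cm_per_mb
  attr(out, "generation_interval_years") <- generation_interval_years
  class(out) <- c("age_estimate", "data.frame")
  out
}

#' @export
print.age_estimate <- function(x, ...) {
  shown <- data.frame(length_mb = x$length_mb,
                      c_morgans = signif(x$c_morgans, 6),
                      generations = round(x$generations, 2),
                      years = round(x$years, 2))
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
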