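# Independent brute-force oracles used across the suite. These deliberately
# use the dumbest correct algorithm (per-base-pair bitmaps, explicit loops)
# and share no code with the implementation they check.

# maximal runs of TRUE in a logical vector -> data.frame(start, end) (indices)
bool_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# per-bp coverage bitmap of intervals on one toy chromosome
bitmap_cover <- function(df, chrom_len) {
  bit <- rep(FALSE, chrom_len)
  for (i in seq_len(nrow(df))) bit[df$start[i]:df$end[i]] <- TRUE
  bit
}

# bitmap -> intervals data.frame(start, end)
bitmap_to_intervals <- function(bit) {
  runs <- bool_runs(bit)
  names(runs) <- c("start", "end")
  runs
}

# run-level ROH oracle (zero het/missing tolerance): maximal runs of
# homozygous calls, split at bp gaps, filtered by run-level constraints
oracle_roh <- function(g, pos, min_snps = 50, min_length_bp = 150000,
                       max_gap_bp = 100000, max_kb_per_snp = 3) {
  segs <- list()
  hom <- g %in% c(0L, 2L)
  for (run in split(which(hom), cumsum(!hom)[hom])) {
    # split this run of homozygous SNP indices at large gaps
    piece <- list(run[1])
    if (length(run) > 1) {
      for (i in 2:length(run)) {
        if (pos[run[i]] - pos[run[i - 1]] > max_gap_bp) {
          piece[[length(piece) + 1]] <- integer()
        }
        piece[[length(piece)]] <- c(piece[[length(piece)]], run[i])
      }
    }
    for (sub in piece) {
      n <- length(sub)
      len <- pos[sub[n]] - pos[sub[1]] + 1
      if (n >= min_snps && len >= min_length_bp &&
          len / 1000 <= max_kb_per_snp * n) {
        segs[[length(segs) + 1]] <- data.frame(
          start = pos[sub[1]], end = pos[sub[n]], n_snps = n)
      }
    }
  }
  if (!length(segs)) {
    return(data.frame(start = integer(), end = integer(),
                      n_snps = integer()))
  }
  do.call(rbind, segs)
}

# per-SNP Hudson components summed explicitly over one window
oracle_window_fst <- function(case_calls, control_calls) {
  sumN <- 0
  sumD <- 0
  for (j in seq_len(ncol(case_calls))) {
    g1 <- case_calls[, j]
    g2 <- control_calls[, j]
    g1 <- g1[g1 != -1L]
    g2 <- g2[g2 != -1L]
    n1 <- 2 * length(g1)
    n2 <- 2 * length(g2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(g1) / n1
    p2 <- sum(g2) / n2
    sumN <- sumN + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    sumD <- sumD + p1 * (1 - p2) + p2 * (1 - p1)
  }
  sumN / sumD
}

# random interval set on a toy chromosome
random_intervals <- function(n, chrom_len, max_width = 500) {
  start <- sample.int(chrom_len - max_width, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(start = start, end = pmin(start + width - 1L, chrom_len))
}

# small hand-buildable genotype matrix on one chromosome
toy_gm <- function(calls, pos, chrom = "1", ref = "A", alt = "C") {
  genotype_matrix(
    calls,
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    rownames(calls))
}

# reciprocal overlap of two intervals on the same chromosome
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}
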