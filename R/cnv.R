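#' Per-window log2 read-depth ratios
#'
#' For each window, the normalized depth ratio is
#' `r = ((case + 0.5) / (control + 0.5)) * (total_control / total_case)`
#' and the reported value is `log2(r)`. The 0.5 pseudocount keeps the ratio
#' defined at zero-count windows — exactly the windows of a homozygous
#' deletion, the calls of most interest.
#'
#' @param track A [depth_track()].
#' @return The track with a `log2_ratio` column appended.
#' @export
log2_ratios <- function(track) {
  stopifnot(inherits(track, "depth_track"))
  total_case <- sum(track$case_count)
  total_control <- sum(track$control_count)
  if (total_case <= 0 || total_control <= 0) {
    stop("track totals must be positive")
  }
  r <- ((track$case_count + 0.5) / (track$control_count + 0.5)) *
    (total_control / total_case)
  track$log2_ratio <- log2(r)
  track
}

#' Call copy-number variants from a depth track
#'
#' Maximal runs of at least `min_windows` consecutive windows whose log2
#' ratio is entirely at or below `-threshold` (loss) or at or above
#' `+threshold` (gain) become candidate calls. Each call's p-value combines
#' per-window Geary-Hinkley transforms of the count ratio (normal
#' approximation to the ratio of two Poisson counts under the null of equal
#' relative coverage) by Stouffer's method; calls with `p >= alpha` are
#' discarded. Runs are strictly consecutive on the window grid — a single
#' sub-threshold window terminates a run, which is stricter than tools that
#' bridge small gaps.
#'
#' @param track A [depth_track()] (log2 ratios computed internally).
#' @param threshold Absolute log2-ratio threshold.
#' @param min_windows Minimum consecutive windows per call.
#' @param alpha Significance level for the combined p-value.
#' @return `data.frame` of class `cnv_calls`: chrom, start, end, direction
#'   ("loss"/"gain"), mean_log2, n_windows, p_value. Call intervals span the
#'   first window start to the last window end.
#' @export
call_cnvs <- function(track, threshold = 0.7, min_windows = 10,
                      alpha = 0.001) {
  stopifnot(inherits(track, "depth_track"))
  if (threshold <= 0) stop("threshold must be positive")
  track <- log2_ratios(track)
  ws <- attr(track, "window_size")
  n_win <- nrow(track)
  m_case <- sum(track$case_count) / n_win
  m_control <- sum(track$control_count) / n_win

  calls <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    # consecutive on the grid: same state and adjacent window_start
    state <- ifelse(tr$log2_ratio <= -threshold, -1L,
                    ifelse(tr$log2_ratio >= threshold, 1L, 0L))
    adjacent <- c(FALSE, diff(tr$window_start) == ws)
    n_tr <- nrow(tr)
    state_change <- c(TRUE, state[-1] != state[-n_tr])
    run_id <- cumsum(state_change | !adjacent)
    for (rid in unique(run_id)) {
      idx <- which(run_id == rid)
      s <- state[idx[1]]
      if (s == 0L || length(idx) < min_windows) next
      t_w <- gh_transform(tr$case_count[idx], tr$control_count[idx],
                          m_case, m_control)
      z <- sum(t_w) / sqrt(length(idx))
      p <- 2 * stats::pnorm(-abs(z))
      if (p >= alpha) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch,
        start = tr$window_start[idx[1]],
        end = tr$window_start[idx[length(idx)]] + ws - 1L,
        direction = if (s < 0) "loss" else "gain",
        mean_log2 = mean(tr$log2_ratio[idx]),
        n_windows = length(idx),
        p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               direction = character(), mean_log2 = numeric(),
               n_windows = integer(), p_value = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cnv_calls", "data.frame")
  out
}

# Geary-Hinkley transform of a Poisson count ratio x/y against expected
# means (m_x, m_y); approximately standard normal under the null.
gh_transform <- function(x, y, m_x, m_y) {
  r <- (x + 0.5) / (y + 0.5)
  (m_y * r - m_x) / sqrt(r^2 * m_y + m_x)
}

#' Intersect CNV calls across case-control pairings into CNVRs
#'
#' A copy-number region (CNVR) is a maximal interval where every pairing
#' contributes a call of the same direction and the common base-pair
#' intersection is at least `min_overlap_bp`. Direction must match across
#' pairings: a region cannot be a loss against one control panel and a gain
#' against another.
#'
#' @param call_sets List (length >= 2) of `cnv_calls` tables, one per
#'   pairing.
#' @param min_overlap_bp Minimum width of the common intersection.
#' @return `data.frame` of class `cnvr`: chrom, start, end, direction.
#' @export
intersect_cnvrs <- function(call_sets, min_overlap_bp = 50) {
  if (length(call_sets) < 2) stop("need at least two call sets")
  pieces <- lapply(c("loss", "gain"), function(dir) {
    grs <- lapply(call_sets, function(cs) {
      df <- cs[cs$direction == dir, , drop = FALSE]
      if (nrow(df) == 0) return(GenomicRanges::GRanges())
      GenomicRanges::reduce(as_granges(df))
    })
    common <- Reduce(function(a, b) {
      GenomicRanges::intersect(a, b, ignore.strand = TRUE)
    }, grs)
    common <- common[GenomicRanges::width(common) >= min_overlap_bp]
    if (!length(common)) return(NULL)
    df <- granges_to_df(common)
    df$direction <- dir
    df
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               direction = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnvr", "data.frame")
  out
}

#' Classify the zygosity of a CNV call from its mean log2 ratio
#'
#' In a pooled case group, a deletion homozygous in every case drives the
#' depth ratio toward zero (strongly negative log2), while a heterozygous or
#' partially shared loss sits near log2(1/2) = -1.
#'
#' @param mean_log2 Mean log2 ratio of a call (vectorised), or a `cnv_calls`
#'   table.
#' @return Character vector: "homozygous_loss" (<= -2.5),
#'   "heterozygous_loss" (in [-1.5, -0.7]), "gain" (>= 0.7), else
#'   "ambiguous".
#' @export
classify_zygosity <- function(mean_log2) {
  if (is.data.frame(mean_log2)) mean_log2 <- mean_log2$mean_log2
  ifelse(mean_log2 <= -2.5, "homozygous_loss",
         ifelse(mean_log2 >= -1.5 & mean_log2 <= -0.7, "heterozygous_loss",
                ifelse(mean_log2 >= 0.7, "gain", "ambiguous")))
}
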