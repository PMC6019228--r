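# read-depth log2 ratios, CNV run calling, CNVR intersection, zygosity

flat_track <- function(case, control, n = 40, chrom = "1", window = 500L) {
  depth_track(chrom, seq(1L, by = window, length.out = n),
              rep_len(case, n), rep_len(control, n), window)
}

test_that("log2 ratios are zero for balanced tracks and match the formula", {
  tr <- log2_ratios(flat_track(50L, 50L))
  expect_true(all(tr$log2_ratio == 0))
  # a locally halved window sits near -1 (pseudocount shifts it slightly)
  counts <- rep(100L, 100)
  counts[50] <- 50L
  tr2 <- depth_track("1", seq(1L, by = 500L, length.out = 100),
                     counts, rep(100L, 100), 500L)
  v <- log2_ratios(tr2)$log2_ratio
  expect_equal(v[50], -1, tolerance = 0.05)
  expect_true(all(abs(v[-50]) < 0.05))
  # random Poisson tracks against direct evaluation
  set.seed(111)
  cc <- stats::rpois(200, 60)
  ct <- stats::rpois(200, 80)
  tr3 <- depth_track("1", seq(1L, by = 500L, length.out = 200), cc, ct, 500L)
  got <- log2_ratios(tr3)$log2_ratio
  want <- log2(((cc + 0.5) / (ct + 0.5)) * (sum(ct) / sum(cc)))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(log2_ratios(flat_track(0L, 0L)), "totals")
})

test_that("a planted homozygous deletion yields exactly one loss call", {
  # 20 zero-count case windows flanked by balanced coverage
  n <- 60
  cc <- rep(50L, n)
  cc[21:40] <- 0L
  tr <- depth_track("1", seq(1L, by = 500L, length.out = n), cc,
                    rep(50L, n), 500L)
  calls <- call_cnvs(tr)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$direction, "loss")
  expect_equal(calls$start, tr$window_start[21])
  expect_equal(calls$end, tr$window_start[40] + 499L)
  expect_equal(calls$n_windows, 20L)
  expect_lt(calls$p_value, 0.001)
  expect_equal(classify_zygosity(calls), "homozygous_loss")
})

test_that("runs shorter than min_windows produce no call", {
  n <- 40
  cc <- rep(50L, n)
  cc[16:24] <- 0L                       # 9 windows beyond threshold
  tr <- depth_track("1", seq(1L, by = 500L, length.out = n), cc,
                    rep(50L, n), 500L)
  expect_equal(nrow(call_cnvs(tr, min_windows = 10)), 0L)
  expect_equal(nrow(call_cnvs(tr, min_windows = 9)), 1L)
})

test_that("gains are called on elevated runs with matching direction", {
  n <- 200
  cc <- rep(50L, n)
  cc[11:30] <- 100L                     # duplication-like doubling
  tr <- depth_track("1", seq(1L, by = 500L, length.out = n), cc,
                    rep(50L, n), 500L)
  calls <- call_cnvs(tr)
  expect_equal(calls$direction, "gain")
  expect_gt(calls$mean_log2, 0.7)
  expect_equal(classify_zygosity(calls), "gain")
})

test_that("raising threshold or min_windows never adds calls", {
  cfg <- sim_config(chrom_lengths = c(`1` = 1e6), seed = 121,
                    read_depth_mean = 50,
                    cnv_events = data.frame(chrom = "1",
                                            start = c(1e5, 6e5),
                                            end = c(1.2e5, 6.3e5),
                                            copy_number = c(0, 1)))
  tr <- simulate_read_depth(cfg, 500)
  n_calls <- function(thr, mw) nrow(call_cnvs(tr, threshold = thr,
                                              min_windows = mw))
  expect_gte(n_calls(0.5, 10), n_calls(0.7, 10))
  expect_gte(n_calls(0.7, 10), n_calls(1.5, 10))
  expect_gte(n_calls(0.7, 5), n_calls(0.7, 10))
  expect_gte(n_calls(0.7, 10), n_calls(0.7, 25))
})

test_that("runs do not bridge chromosome boundaries", {
  # chrom 1 ends with 8 zero windows, chrom 2 begins with 8: a caller that
  # bridged chromosomes would see a 16-window run and emit a call
  cc1 <- c(rep(50L, 50), rep(0L, 8))
  cc2 <- c(rep(0L, 8), rep(50L, 50))
  both <- depth_track(rep(c("1", "2"), each = 58),
                      rep(seq(1L, by = 500L, length.out = 58), 2),
                      c(cc1, cc2), rep(50L, 116), 500L)
  expect_equal(nrow(call_cnvs(both, min_windows = 10)), 0L)
  expect_equal(nrow(call_cnvs(both, min_windows = 8)), 2L)
})

test_that("four identical loss calls intersect into one CNVR", {
  call <- data.frame(chrom = "17", start = 35418404L, end = 35425648L,
                     direction = "loss", stringsAsFactors = FALSE)
  got <- intersect_cnvrs(rep(list(call), 4))
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 35418404L)
  expect_equal(got$end, 35425648L)
  expect_equal(got$direction, "loss")
})

test_that("the 50 bp minimum overlap is a hard boundary", {
  a <- data.frame(chrom = "1", start = 1000L, end = 2000L,
                  direction = "loss", stringsAsFactors = FALSE)
  b49 <- data.frame(chrom = "1", start = 1952L, end = 3000L,
                    direction = "loss", stringsAsFactors = FALSE)
  b50 <- data.frame(chrom = "1", start = 1951L, end = 3000L,
                    direction = "loss", stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_cnvrs(list(a, b49))), 0L)
  got <- intersect_cnvrs(list(a, b50))
  expect_equal(nrow(got), 1L)
  expect_equal(got$end - got$start + 1L, 50L)
})

test_that("direction must match across pairings", {
  a <- data.frame(chrom = "1", start = 1000L, end = 2000L,
                  direction = "loss", stringsAsFactors = FALSE)
  b <- data.frame(chrom = "1", start = 1000L, end = 2000L,
                  direction = "gain", stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_cnvrs(list(a, b))), 0L)
})

test_that("CNVR intersection matches the bitmap oracle and is commutative", {
  set.seed(131)
  chrom_len <- 10000L
  for (rep in 1:8) {
    sets <- lapply(1:4, function(i) {
      iv <- random_intervals(sample(2:5, 1), chrom_len, max_width = 2000)
      data.frame(chrom = "1", start = iv$start, end = iv$end,
                 direction = sample(c("loss", "gain"), nrow(iv),
                                    replace = TRUE, prob = c(0.8, 0.2)),
                 stringsAsFactors = FALSE)
    })
    got <- intersect_cnvrs(sets, min_overlap_bp = 50)
    for (dir in c("loss", "gain")) {
      bit <- Reduce(`&`, lapply(sets, function(s) {
        d <- s[s$direction == dir, , drop = FALSE]
        if (nrow(d) == 0) rep(FALSE, chrom_len) else
          bitmap_cover(d, chrom_len)
      }))
      want <- bitmap_to_intervals(bit)
      want <- want[want$end - want$start + 1 >= 50, , drop = FALSE]
      sub <- got[got$direction == dir, , drop = FALSE]
      expect_equal(nrow(sub), nrow(want))
      if (nrow(want)) {
        expect_equal(sub$start, want$start)
        expect_equal(sub$end, want$end)
      }
    }
    # commutativity / associativity over pairings
    got_rev <- intersect_cnvrs(rev(sets), min_overlap_bp = 50)
    expect_equal(got, got_rev)
  }
})

test_that("zygosity classification follows the log2 bands", {
  expect_equal(classify_zygosity(c(-4, -2.5, -1.5, -1.0, -0.7, -0.3, 0.7, 2)),
               c("homozygous_loss", "homozygous_loss", "heterozygous_loss",
                 "heterozygous_loss", "heterozygous_loss", "ambiguous",
                 "gain", "gain"))
  expect_equal(classify_zygosity(-2), "ambiguous")   # between the loss bands
})

test_that("simulated heterozygous losses classify as heterozygous", {
  hits <- 0L
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(chrom_lengths = c(`1` = 1e6), seed = 200 + r,
                      read_depth_mean = 400,
                      cnv_events = data.frame(chrom = "1", start = 30001,
                                              end = 50000, copy_number = 1))
    tr <- simulate_read_depth(cfg, 500)
    calls <- call_cnvs(tr)
    loss <- calls[calls$direction == "loss", , drop = FALSE]
    if (nrow(loss) &&
        any(classify_zygosity(loss) == "heterozygous_loss")) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.95)
})
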