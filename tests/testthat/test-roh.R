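# run-of-homozygosity calling, sharing, genome coverage and 1/(2c) dating

test_that("an all-heterozygous sample yields no ROH", {
  n <- 1000
  calls <- matrix(1L, 1, n, dimnames = list("s1", NULL))
  gm <- toy_gm(calls, pos = seq(1000L, by = 1000L, length.out = n))
  expect_equal(nrow(call_roh(gm, "s1")), 0L)
})

test_that("chromosomes with fewer SNPs than one window yield no calls", {
  calls <- matrix(0L, 1, 20, dimnames = list("s1", NULL))
  gm <- toy_gm(calls, pos = seq(1000L, by = 1000L, length.out = 20))
  expect_equal(nrow(call_roh(gm, "s1")), 0L)
})

test_that("a large gap splits a run and each side is filtered independently", {
  # 200 homozygous SNPs at 1.5 kb spacing with one interior 150 kb gap;
  # both sides have 100 SNPs spanning ~148.5 kb: below the 150 kb length
  # floor, so the gap rule plus the length filter kills both pieces
  pos <- c(seq(1000L, by = 1500L, length.out = 100),
           seq(1000L + 99L * 1500L + 150000L, by = 1500L, length.out = 100))
  calls <- matrix(0L, 1, 200, dimnames = list("s1", NULL))
  gm <- toy_gm(calls, pos = pos)
  params <- roh_params(max_het_per_window = 0, max_missing_per_window = 0,
                       window_hit_threshold = 1e-9)
  expect_equal(nrow(call_roh(gm, "s1", params)), 0L)

  # stretch each side past 150 kb and both pieces survive as two segments
  pos2 <- c(seq(1000L, by = 1600L, length.out = 100),
            seq(1000L + 99L * 1600L + 150000L, by = 1600L, length.out = 100))
  gm2 <- toy_gm(calls, pos = pos2)
  segs <- call_roh(gm2, "s1", params)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$n_snps, c(100L, 100L))
  expect_true(all(segs$length_bp >= 150000L))
})

test_that("the density bound discards SNP-sparse runs", {
  # 60 homozygous SNPs spread over 400 kb: 6.7 kb/SNP > 3 kb/SNP
  pos <- seq(1000L, by = 6700L, length.out = 60)
  calls <- matrix(2L, 1, 60, dimnames = list("s1", NULL))
  gm <- toy_gm(calls, pos = pos)
  params <- roh_params(max_het_per_window = 0, max_missing_per_window = 0,
                       window_hit_threshold = 1e-9)
  expect_equal(nrow(call_roh(gm, "s1", params)), 0L)
})

test_that("the caller matches the brute-force run oracle on random instances", {
  # zero-tolerance regime: window vote reduces exactly to maximal-run
  # enumeration, so the optimized scan must agree SNP-for-SNP
  params <- roh_params(max_het_per_window = 0, max_missing_per_window = 0,
                       window_hit_threshold = 1e-9)
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(100:500, 1)
    pos <- sort(sample.int(2e6, n))
    # blocky genotypes: alternate homozygous stretches and noisy stretches
    g <- integer(n)
    i <- 1L
    while (i <= n) {
      len <- sample(10:150, 1)
      block <- min(n, i + len - 1L)
      g[i:block] <- if (stats::runif(1) < 0.5) {
        sample(c(0L, 2L), block - i + 1L, replace = TRUE)
      } else {
        sample(c(-1L, 0L, 1L, 2L), block - i + 1L, replace = TRUE)
      }
      i <- block + 1L
    }
    calls <- matrix(g, 1, n, dimnames = list("s1", NULL))
    gm <- toy_gm(calls, pos = pos)
    got <- call_roh(gm, "s1", params)
    want <- oracle_roh(g, pos)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("relaxing the het tolerance never shrinks the called territory", {
  cfg <- sim_config(chrom_lengths = c(`1` = 2e6), seed = 31,
                    planted_roh = data.frame(sample_id = "case_1",
                                             chrom = "1", start = 5e5,
                                             end = 1e6))
  gm <- simulate_genotypes(cfg)
  total_bp <- function(max_het) {
    segs <- call_roh(gm, "case_1", roh_params(max_het_per_window = max_het))
    sum(segs$length_bp)
  }
  bp <- vapply(0:3, total_bp, numeric(1))
  expect_true(all(diff(bp) >= 0))
})

test_that("every reported segment satisfies its own invariants", {
  cfg <- sim_config(chrom_lengths = c(`1` = 3e6), seed = 41,
                    planted_roh = data.frame(
                      sample_id = c("case_1", "case_1"), chrom = "1",
                      start = c(2e5, 15e5), end = c(8e5, 22e5)))
  gm <- simulate_genotypes(cfg)
  p <- roh_params()
  segs <- call_roh(gm, "case_1", p)
  expect_gt(nrow(segs), 0)
  expect_true(all(segs$n_snps >= p$min_snps))
  expect_true(all(segs$length_bp >= p$min_length_bp))
  expect_true(all(segs$length_bp == segs$end - segs$start + 1L))
  expect_true(all(segs$length_bp / 1000 <= p$max_kb_per_snp * segs$n_snps))
})

test_that("shared regions are the base-pair intersection across samples", {
  seg <- function(s, start, end) {
    data.frame(sample_id = s, chrom = "1", start = start, end = end)
  }
  # identical segment in all three samples comes back unchanged
  segs <- rbind(seg("a", 100, 900), seg("b", 100, 900), seg("c", 100, 900))
  got <- shared_regions(segs, c("a", "b", "c"))
  expect_equal(got$start, 100L)
  expect_equal(got$end, 900L)
  # disjoint segments share nothing
  segs2 <- rbind(seg("a", 100, 200), seg("b", 300, 400), seg("c", 500, 600))
  expect_equal(nrow(shared_regions(segs2, c("a", "b", "c"))), 0L)
  # a sample with no segments at all forces an empty intersection
  expect_equal(nrow(shared_regions(segs, c("a", "b", "c", "d"))), 0L)
})

test_that("shared regions match the per-bp bitmap oracle on random sets", {
  chrom_len <- 10000L
  set.seed(23)
  for (rep in 1:10) {
    per_sample <- lapply(c("a", "b", "c"), function(s) {
      iv <- random_intervals(sample(3:8, 1), chrom_len)
      data.frame(sample_id = s, chrom = "1", start = iv$start, end = iv$end)
    })
    segs <- do.call(rbind, per_sample)
    got <- shared_regions(segs, c("a", "b", "c"))
    bit <- Reduce(`&`, lapply(per_sample, bitmap_cover, chrom_len))
    want <- bitmap_to_intervals(bit)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("genome fraction is total merged coverage over genome length", {
  lens <- c(`1` = 1e6, `2` = 9e6)
  one_chrom <- genomic_intervals("1", 1L, 1e6)
  expect_equal(genome_fraction(one_chrom, lens), 0.10)
  none <- genomic_intervals(character(), integer(), integer())
  expect_equal(genome_fraction(none, lens), 0.0)
  # overlapping input is merged before summing
  twice <- genomic_intervals(c("1", "1"), c(1L, 1L), c(1e6, 1e6))
  expect_equal(genome_fraction(twice, lens), 0.10)
  expect_error(genome_fraction(genomic_intervals("1", 1L, 2e6), lens),
               "past its chromosome")
  # random sets agree with the bitmap oracle
  set.seed(29)
  iv <- random_intervals(12, 10000)
  df <- genomic_intervals("1", iv$start, iv$end)
  want <- sum(bitmap_cover(iv, 10000L)) / 10000
  expect_equal(genome_fraction(df, c(`1` = 10000)), want)
})

test_that("1/(2c) dating reproduces the published tract ages", {
  # ROH sizes (Mb) spanning the four candidate genes in three ponies, with
  # their ages in generations and years under a 1 cM/Mb map and 10-year
  # generation interval
  sizes <- c(2.522687, 1.062162, 3.342086,   # ADAMTS17, ponies 1-3
             0.635954, 2.837501, 0.492062,   # GH1
             0.278201, 0.406642, 0.413306,   # OSTN
             1.498057, 1.945192, 1.118224)   # HMGA2
  gens <- c(19.82, 47.07, 14.96,
            78.62, 17.62, 101.61,
            179.73, 122.96, 120.98,
            33.38, 25.70, 44.71)
  years <- c(198.20, 470.74, 149.61,
             786.22, 176.21, 1016.13,
             1797.26, 1229.58, 1209.76,
             333.77, 257.04, 447.14)
  est <- date_roh(sizes)
  expect_equal(round(est$generations, 2), gens)
  expect_equal(round(est$years, 2), years)
})

test_that("dating unit case and error handling", {
  est <- date_roh(50)   # c = 0.5 Morgans
  expect_equal(est$generations, 1.0)
  expect_equal(est$years, 10.0)
  expect_error(date_roh(0), "length_mb")
  expect_error(date_roh(-1), "length_mb")
})

test_that("dating is strictly decreasing with constant product", {
  l <- sort(stats::runif(50, 0.1, 10))
  est <- date_roh(l)
  expect_true(all(diff(est$generations) < 0))
  expect_equal(est$generations * l, rep(50, 50))
  # halving the map rate doubles the implied age
  est2 <- date_roh(l, cm_per_mb = 0.5)
  expect_equal(est2$generations, 2 * est$generations)
})

test_that("planted tracts >= 300 kb are recovered with high reciprocal overlap", {
  hits <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    start <- 3e5 + (r - 1) * 1e4
    end <- start + 4e5 - 1
    cfg <- sim_config(chrom_lengths = c(`1` = 2e6), seed = 1000 + r,
                      planted_roh = data.frame(sample_id = "case_1",
                                               chrom = "1", start = start,
                                               end = end))
    gm <- simulate_genotypes(cfg)
    segs <- call_roh(gm, "case_1")
    ro <- if (nrow(segs)) {
      max(vapply(seq_len(nrow(segs)), function(i) {
        reciprocal_overlap(segs$start[i], segs$end[i], start, end)
      }, numeric(1)))
    } else 0
    if (ro >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
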