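#' Configuration for a synthetic study population
#'
#' Bundles every knob of the synthetic-data generators. The defaults emulate
#' the study design the pipeline targets: a small case group of 3 ponies
#' against a pooled control panel of 24 equids, autosomal SNPs at roughly one
#' per kilobase, and Poisson read-depth tracks for the copy-number arm.
#'
#' Reproducibility uses a single `seed` with fixed stream offsets per
#' generator: genotypes use `seed + 1`, traits `seed + 2`, read depth
#' `seed + 3`. All offsets stay well below 2^31.
#'
#' @param n_cases,n_controls Sample counts for the two groups.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_variants Named integer vector, SNP count per chromosome (defaults
#'   to one SNP per kb).
#' @param freq_range Background alternate-allele frequencies are drawn
#'   uniformly from this interval.
#' @param planted_roh `data.frame(sample_id, chrom, start, end)`: autozygous
#'   tracts forced homozygous in the given sample.
#' @param divergent_loci `data.frame(chrom, start, end, case_freq,
#'   control_freq)`: intervals where the two groups use different allele
#'   frequencies.
#' @param cnv_events `data.frame(chrom, start, end, copy_number)` with copy
#'   number in \{0, 1, 3, 4\}, carried by the case pool.
#' @param read_depth_mean Expected reads per window (lambda) for the depth
#'   simulation.
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 3, n_controls = 24,
                       chrom_lengths = c(`1` = 10e6, `2` = 5e6),
                       n_variants = NULL,
                       freq_range = c(0.05, 0.95),
                       planted_roh = NULL,
                       divergent_loci = NULL,
                       cnv_events = NULL,
                       read_depth_mean = 50,
                       seed = 1L) {
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (is.null(n_variants)) {
    n_variants <- pmax(10L, as.integer(round(chrom_lengths / 1000)))
    names(n_variants) <- names(chrom_lengths)
  }
  if (any(freq_range < 0) || any(freq_range > 1) ||
      freq_range[1] > freq_range[2]) {
    stop("freq_range must be an increasing interval inside [0, 1]")
  }
  if (!is.null(divergent_loci)) {
    f <- c(divergent_loci$case_freq, divergent_loci$control_freq)
    if (any(f < 0 | f > 1)) stop("divergent-locus frequencies must be in [0,1]")
  }
  if (!is.null(cnv_events) &&
      any(!cnv_events$copy_number %in% c(0, 1, 2, 3, 4))) {
    stop("copy numbers must be in {0, 1, 2, 3, 4}")
  }
  if (read_depth_mean <= 0) stop("read_depth_mean must be positive")
  if (!is.null(planted_roh)) {
    # contradictory overlaps: the same sample planted twice over the same bp
    by_sample <- split(planted_roh, planted_roh$sample_id)
    for (df in by_sample) {
      if (nrow(df) > 1) {
        df <- df[order(df$chrom, df$start), ]
        same <- df$chrom[-1] == df$chrom[-nrow(df)]
        if (any(same & df$start[-1] <= df$end[-nrow(df)])) {
          stop("overlapping planted ROH intervals for sample ",
               df$sample_id[1])
        }
      }
    }
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls,
    chrom_lengths = chrom_lengths, n_variants = n_variants,
    freq_range = freq_range, planted_roh = planted_roh,
    divergent_loci = divergent_loci, cnv_events = cnv_events,
    read_depth_mean = read_depth_mean, seed = as.integer(seed)),
    class = "sim_config")
}

sim_sample_ids <- function(config) {
  c(paste0("case_", seq_len(config$n_cases)),
    paste0("control_", seq_len(config$n_controls)))
}

#' Simulate a diploid genotype matrix with planted structure
#'
#' Loci are independent: each sample's genotype at a locus is
#' Binomial(2, freq). Inside `divergent_loci` intervals cases and controls use
#' different frequencies; inside `planted_roh` intervals the listed sample is
#' forced homozygous (alternate with probability equal to the local
#' frequency, reference otherwise), emulating an autozygous tract.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()]; the per-locus case/control frequencies used
#'   are attached as attribute `truth_freqs`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  samples <- sim_sample_ids(config)
  case_ids <- samples[seq_len(config$n_cases)]
  chroms <- names(config$chrom_lengths)

  var_list <- lapply(chroms, function(ch) {
    n <- config$n_variants[[ch]]
    len <- config$chrom_lengths[[ch]]
    pos <- sort(sample.int(len, n))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, var_list)
  m <- nrow(variants)
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  variants$ref <- ref
  variants$alt <- unname(alt)
  variants$qual <- 100

  base_freq <- stats::runif(m, config$freq_range[1], config$freq_range[2])
  case_freq <- base_freq
  control_freq <- base_freq
  if (!is.null(config$divergent_loci)) {
    for (i in seq_len(nrow(config$divergent_loci))) {
      dv <- config$divergent_loci[i, ]
      in_iv <- variants$chrom == dv$chrom & variants$pos >= dv$start &
        variants$pos <= dv$end
      case_freq[in_iv] <- dv$case_freq
      control_freq[in_iv] <- dv$control_freq
    }
  }

  n <- length(samples)
  freq_mat <- matrix(rep(control_freq, each = n), nrow = n)
  freq_mat[seq_len(config$n_cases), ] <-
    matrix(rep(case_freq, each = config$n_cases), nrow = config$n_cases)
  calls <- matrix(stats::rbinom(n * m, 2L, freq_mat), nrow = n,
                  dimnames = list(samples, NULL))

  if (!is.null(config$planted_roh)) {
    for (i in seq_len(nrow(config$planted_roh))) {
      tr <- config$planted_roh[i, ]
      if (!tr$sample_id %in% samples) {
        stop("planted ROH names unknown sample ", tr$sample_id)
      }
      in_iv <- variants$chrom == tr$chrom & variants$pos >= tr$start &
        variants$pos <= tr$end
      p <- if (tr$sample_id %in% case_ids) case_freq[in_iv] else
        control_freq[in_iv]
      calls[tr$sample_id, in_iv] <-
        2L * stats::rbinom(sum(in_iv), 1L, p)
    }
  }

  gm <- genotype_matrix(calls, variants, samples)
  attr(gm, "truth_freqs") <- data.frame(
    chrom = variants$chrom, pos = variants$pos,
    case_freq = case_freq, control_freq = control_freq)
  gm
}

#' Simulate a quantitative trait from causal loci
#'
#' Additive-dominance architecture:
#' `height = mean + sum_k a_k * (g_k - 1) + sum_k d_k * I(g_k == 1) + eps`,
#' `eps ~ Normal(0, sd^2)`, with `g_k` the count of the size-reducing allele.
#' With the (g - 1) centring, `trait_mean` is the height of an individual
#' heterozygous at every causal locus.
#'
#' @param gm A [genotype_matrix()].
#' @param causal_loci `data.frame(locus, chrom, pos, a, d)`; each (chrom,
#'   pos) must match a variant in `gm` exactly.
#' @param trait_mean Baseline height in cm.
#' @param trait_sd Residual standard deviation in cm (> 0 required; may be
#'   made arbitrarily small for deterministic checks).
#' @param seed Integer seed for the residual draw.
#' @return A `trait_records` data.frame (sample_id, height_cm, cannon_cm and
#'   one genotype code column per causal locus). Samples missing a causal
#'   genotype are dropped with a warning.
#' @export
simulate_trait <- function(gm, causal_loci, trait_mean = 98,
                           trait_sd = 3, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (trait_sd <= 0) stop("trait_sd must be > 0")
  key_gm <- paste(gm$variants$chrom, gm$variants$pos)
  idx <- match(paste(causal_loci$chrom, causal_loci$pos), key_gm)
  if (anyNA(idx)) {
    stop("causal locus not present in genotype matrix: ",
         paste(causal_loci$locus[is.na(idx)], collapse = ", "))
  }
  codes <- gm$calls[, idx, drop = FALSE]
  colnames(codes) <- causal_loci$locus
  complete <- rowSums(codes == -1L) == 0
  if (any(!complete)) {
    warning(sum(!complete), " sample(s) dropped for missing causal genotypes")
  }
  codes <- codes[complete, , drop = FALSE]
  set.seed(seed)
  eps <- stats::rnorm(nrow(codes), 0, trait_sd)
  g <- codes
  height <- trait_mean +
    as.vector((g - 1) %*% causal_loci$a) +
    as.vector((g == 1L) %*% causal_loci$d) +
    eps
  out <- data.frame(sample_id = rownames(codes), height_cm = height,
                    cannon_cm = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(codes))) out[[colnames(codes)[j]]] <- codes[, j]
  rownames(out) <- NULL
  class(out) <- c("trait_records", "data.frame")
  out
}

#' Simulate the validation cohort for the four-locus size model
#'
#' Draws a cohort modelled on a mixed validation panel: a miniature-type
#' stratum with a high frequency of the size-reducing allele at all four
#' candidate loci and a standard/related-breed stratum with a low frequency.
#' The mixture produces the excess homozygosity and the weak inter-locus
#' allele-count correlation characteristic of such panels, without any
#' explicit within-stratum linkage. Defaults: 243 animals, additive effects
#' (-2.0, -1.5, -3.0, -2.74) cm per allele (homozygote-to-homozygote span
#' 18.48 cm), no dominance, residual sd 3 cm.
#'
#' @param n Cohort size.
#' @param loci Locus names for the four candidate variants.
#' @param a Additive effect (cm per size-reducing allele) per locus.
#' @param d Dominance deviation per locus.
#' @param trait_mean Height of the all-heterozygous genotype, cm.
#' @param trait_sd Residual standard deviation, cm.
#' @param p_mini,p_standard Size-allele frequency in the miniature-type and
#'   standard-type strata.
#' @param prop_mini Proportion of the cohort in the miniature-type stratum.
#' @param seed Integer seed.
#' @return A `trait_records` data.frame.
#' @export
simulate_cohort <- function(n = 243,
                            loci = c("ADAMTS17", "OSTN", "GH1", "HMGA2"),
                            a = c(-2.0, -1.5, -3.0, -2.74),
                            d = c(0, 0, 0, 0),
                            trait_mean = 98, trait_sd = 3,
                            p_mini = 0.85, p_standard = 0.35,
                            prop_mini = 0.5, seed = 1L) {
  if (trait_sd <= 0) stop("trait_sd must be > 0")
  stopifnot(length(a) == length(loci), length(d) == length(loci))
  set.seed(seed)
  n_mini <- round(n * prop_mini)
  stratum_p <- c(rep(p_mini, n_mini), rep(p_standard, n - n_mini))
  k <- length(loci)
  codes <- matrix(stats::rbinom(n * k, 2L, rep(stratum_p, k)), nrow = n,
                  dimnames = list(NULL, loci))
  height <- trait_mean +
    as.vector((codes - 1) %*% a) +
    as.vector((codes == 1L) %*% d) +
    stats::rnorm(n, 0, trait_sd)
  out <- data.frame(sample_id = sprintf("pony_%03d", seq_len(n)),
                    height_cm = height, cannon_cm = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[loci[j]]] <- codes[, j]
  class(out) <- c("trait_records", "data.frame")
  out
}

#' Simulate case/control read-depth tracks with copy-number events
#'
#' Control counts per window are Poisson(lambda); case counts are
#' Poisson(lambda * cn / 2) inside planted `cnv_events` and Poisson(lambda)
#' elsewhere. Windows partially overlapped by an event get the
#' coverage-weighted mixture of the two rates, so simulated breakpoints fall
#' inside, not on, window boundaries.
#'
#' @param config A [sim_config()] (uses `chrom_lengths`, `cnv_events`,
#'   `read_depth_mean`, `seed`).
#' @param window_size Window width in bp.
#' @return A [depth_track()].
#' @export
simulate_read_depth <- function(config, window_size = 500) {
  stopifnot(inherits(config, "sim_config"))
  if (window_size < 1) stop("window_size must be >= 1")
  lambda <- config$read_depth_mean
  if (lambda <= 0) stop("read_depth_mean must be positive")
  set.seed(config$seed + 3L)
  tracks <- lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    starts <- seq(1L, as.integer(len) - as.integer(window_size) + 1L,
                  by = as.integer(window_size))
    ends <- starts + as.integer(window_size) - 1L
    case_rate <- rep(lambda, length(starts))
    if (!is.null(config$cnv_events)) {
      ev <- config$cnv_events[config$cnv_events$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        ov <- pmax(0, pmin(ends, ev$end[i]) - pmax(starts, ev$start[i]) + 1)
        f <- ov / window_size
        case_rate <- case_rate *
          (1 - f + f * ev$copy_number[i] / 2)
      }
    }
    data.frame(chrom = ch, window_start = starts,
               case_count = stats::rpois(length(starts), case_rate),
               control_count = stats::rpois(length(starts), lambda),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, tracks)
  depth_track(all$chrom, all$window_start, all$case_count,
              all$control_count, window_size)
}
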