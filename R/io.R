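#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeps biallelic SNVs only, and
#' applies per-sample depth and quality filters: a sample's genotype at a site
#' is set to missing (-1) when its FORMAT/DP falls outside
#' `[min_depth, max_depth]` or its FORMAT/GQ is not greater than `min_qual`.
#' When the file carries no per-sample GQ, sites whose QUAL column is not
#' greater than `min_qual` are dropped. Sites at which every retained sample
#' is missing are dropped. Defaults follow the confident-SNP filtering used
#' for the pony genomes: depth 3-60 and quality > 20.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param sample_subset Optional character vector of sample ids to retain.
#' @param min_depth,max_depth Per-sample depth bounds (inclusive).
#' @param min_qual Quality threshold; genotypes require quality strictly
#'   greater than this.
#' @param include_all_chromosomes Keep chromosome X and unplaced (ChrUn*)
#'   contigs? They are excluded by default, as in the autosomal scans.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_subset = NULL, min_depth = 3,
                     max_depth = 60, min_qual = 20,
                     include_all_chromosomes = FALSE) {
  if (min_depth > max_depth) stop("min_depth must be <= max_depth")
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("VCF parse error in '", path,
                                           "': ", conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_sites <- nrow(fix)
  all_samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_subset)) {
    samples <- all_samples
  } else {
    unknown <- setdiff(sample_subset, all_samples)
    if (length(unknown)) {
      stop("sample id(s) not in VCF: ", paste(unknown, collapse = ", "))
    }
    samples <- sample_subset
  }
  if (n_sites == 0) {
    return(genotype_matrix(
      matrix(integer(), nrow = length(samples), ncol = 0),
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character(), qual = numeric()),
      samples))
  }

  fix$POS <- as.integer(fix$POS)
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  gt <- vcfR::extract.gt(vcf, element = "GT")            # sites x samples
  gt <- gt[, samples, drop = FALSE]
  codes <- gt_string_to_code(gt)

  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(dp) && !all(is.na(dp))) {
    dp <- dp[, samples, drop = FALSE]
    bad_dp <- is.na(dp) | dp < min_depth | dp > max_depth
    codes[bad_dp] <- -1L
  }
  gq <- tryCatch(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE),
                 error = function(e) NULL)
  has_gq <- !is.null(gq) && !all(is.na(gq))
  if (has_gq) {
    gq <- gq[, samples, drop = FALSE]
    codes[is.na(gq) | gq <= min_qual] <- -1L
  }

  keep <- rep(TRUE, n_sites)
  # biallelic SNVs only (multi-allelic and indel records are not confident
  # SNPs for the scan and are dropped)
  nt <- c("A", "C", "G", "T")
  keep <- keep & fix$REF %in% nt & fix$ALT %in% nt
  if (!has_gq) keep <- keep & (is.na(qual) | qual > min_qual)
  if (!include_all_chromosomes) {
    keep <- keep & !grepl("^(chr)?(X|Un)", fix$CHROM, ignore.case = TRUE)
  }
  # drop sites where every sample is missing
  keep <- keep & rowSums(codes != -1L) > 0

  codes <- codes[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  qual <- qual[keep]

  ord <- order(fix$CHROM, fix$POS)
  codes <- codes[ord, , drop = FALSE]
  fix <- fix[ord, , drop = FALSE]
  qual <- qual[ord]

  genotype_matrix(
    t(codes),
    data.frame(chrom = fix$CHROM, pos = fix$POS, ref = fix$REF,
               alt = fix$ALT, qual = qual, stringsAsFactors = FALSE),
    samples)
}

# "0/0"-style GT strings (phased or unphased) -> codes; any "." -> -1
gt_string_to_code <- function(gt) {
  out <- matrix(-1L, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  out[clean %in% c("0/0")] <- 0L
  out[clean %in% c("0/1", "1/0")] <- 1L
  out[clean %in% c("1/1")] <- 2L
  out
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only FORMAT, suitable for round-tripping
#' simulated populations through [read_vcf()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  qual <- if ("qual" %in% names(v)) ifelse(is.na(v$qual), ".", v$qual) else "."
  gt_strings <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=miniscan-simulated",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")), con)
  if (nrow(v) > 0) {
    body <- t(gm$calls)                                   # sites x samples
    gt_cols <- matrix(gt_strings[as.character(body)], nrow = nrow(body))
    lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, "PASS", ".", "GT",
                   apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write genomic intervals as a BED3+ file
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention at this boundary: `(start, end)` becomes
#' `(start - 1, end)`. Payload columns beyond chrom/start/end are written as
#' additional BED columns.
#'
#' @param intervals A [genomic_intervals()] table (or data.frame with columns
#'   `chrom`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- genomic_intervals(intervals$chrom, intervals$start, intervals$end)
  extra <- setdiff(names(intervals), c("chrom", "start", "end"))
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    stringsAsFactors = FALSE)
  for (cn in extra) out[[cn]] <- intervals[[cn]]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file into 1-based inclusive intervals
#'
#' @param path Path to a BED file.
#' @return A [genomic_intervals()] table; any columns past the third are kept
#'   as `payload1`, `payload2`, ...
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- genomic_intervals(raw[[1]], raw[[2]] + 1L, raw[[3]])
  if (ncol(raw) > 3) {
    for (i in seq(4, ncol(raw))) out[[paste0("payload", i - 3)]] <- raw[[i]]
  }
  out
}

#' Read a phenotype table of trait records
#'
#' Expects a TSV with header columns `sample_id`, `height_cm`, optionally
#' `cannon_cm`, followed by one column per candidate locus. Locus columns may
#' hold numeric codes (0/1/2, -1 or NA for missing) or genotype strings such
#' as `"A/A"`, in which case `alt_alleles` must name the size-associated
#' (alternate) allele for that column.
#'
#' @param path Path to the TSV file.
#' @param alt_alleles Named character vector mapping locus column names to
#'   their alternate allele (needed only for string-coded columns).
#' @return A `data.frame` of class `trait_records` with `sample_id`,
#'   `height_cm`, `cannon_cm` (NA when not recorded) and one integer code
#'   column per locus.
#' @export
read_phenotypes <- function(path, alt_alleles = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (!all(c("sample_id", "height_cm") %in% names(raw))) {
    stop("phenotype table needs 'sample_id' and 'height_cm' columns")
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicated sample_id in phenotype table: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "))
  }
  if (any(!is.na(raw$height_cm) & raw$height_cm <= 0)) {
    stop("heights must be positive")
  }
  if (!"cannon_cm" %in% names(raw)) raw$cannon_cm <- NA_real_
  if (any(!is.na(raw$cannon_cm) & raw$cannon_cm <= 0)) {
    stop("cannon bone circumferences must be positive")
  }
  loci <- setdiff(names(raw), c("sample_id", "height_cm", "cannon_cm"))
  for (locus in loci) {
    col <- raw[[locus]]
    if (is.numeric(col)) {
      code <- as.integer(col)
      code[is.na(code)] <- -1L
      if (any(!code %in% c(-1L, 0L, 1L, 2L))) {
        stop("numeric genotype codes in '", locus, "' must be in {-1,0,1,2}")
      }
    } else {
      alt <- alt_alleles[[locus]]
      if (is.null(alt)) {
        stop("string genotypes in '", locus,
             "' but no alt allele given in alt_alleles")
      }
      alleles <- strsplit(gsub("\\|", "/", as.character(col)), "/")
      code <- vapply(alleles, function(a) {
        if (length(a) != 2 || any(is.na(a)) || any(a %in% c(".", "N"))) {
          return(-1L)
        }
        sum(a == alt)
      }, integer(1))
      code[is.na(col)] <- -1L
    }
    raw[[locus]] <- code
  }
  out <- raw[, c("sample_id", "height_cm", "cannon_cm", loci), drop = FALSE]
  class(out) <- c("trait_records", "data.frame")
  out
}

#' Write trait records as a phenotype TSV
#'
#' Inverse of [read_phenotypes()] for numerically coded genotypes.
#'
#' @param records A `trait_records` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a variant annotation table
#'
#' TSV with columns `chrom`, `pos`, `alt`, `effect_class` (one of HIGH,
#' MODERATE, LOW, MODIFIER), optional `sift_score` in [0,1] and optional
#' `gene`. The table is the consumed output of an upstream effect predictor;
#' prediction itself is out of scope here.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with the validated columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "alt", "effect_class")
  if (!all(need %in% names(ann))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  ok_classes <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (any(!ann$effect_class %in% ok_classes)) {
    stop("effect_class must be one of ", paste(ok_classes, collapse = ", "))
  }
  if (!"sift_score" %in% names(ann)) ann$sift_score <- NA_real_
  bad <- !is.na(ann$sift_score) & (ann$sift_score < 0 | ann$sift_score > 1)
  if (any(bad)) stop("sift_score must lie in [0, 1]")
  if (!"gene" %in% names(ann)) ann$gene <- NA_character_
  ann$chrom <- as.character(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  ann
}

#' Construct a read-depth track
#'
#' Per-window read counts for a case pool and a control pool on a fixed,
#' non-overlapping window grid.
#'
#' @param chrom Chromosome labels per window.
#' @param window_start 1-based window start positions.
#' @param case_count,control_count Non-negative integer read counts.
#' @param window_size Window width in bp (constant across the track).
#' @return `data.frame` of class `depth_track` with attribute `window_size`.
#' @export
depth_track <- function(chrom, window_start, case_count, control_count,
                        window_size) {
  if (window_size < 1) stop("window_size must be >= 1")
  if (any(case_count < 0) || any(control_count < 0)) {
    stop("read counts must be non-negative")
  }
  out <- data.frame(chrom = as.character(chrom),
                    window_start = as.integer(window_start),
                    case_count = as.integer(case_count),
                    control_count = as.integer(control_count),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window_size") <- as.integer(window_size)
  class(out) <- c("depth_track", "data.frame")
  out
}

#' Read a read-count TSV into a depth track
#'
#' @param path TSV with columns chrom, window_start, case_count,
#'   control_count and a `window_size` column (constant).
#' @return A [depth_track()].
#' @export
read_depth_track <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "window_start", "case_count", "control_count",
            "window_size")
  if (!all(need %in% names(raw))) {
    stop("depth track needs columns: ", paste(need, collapse = ", "))
  }
  ws <- unique(raw$window_size)
  if (length(ws) != 1) stop("window_size must be constant")
  depth_track(raw$chrom, raw$window_start, raw$case_count,
              raw$control_count, ws)
}

#' Write a depth track as a read-count TSV
#'
#' @param track A [depth_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  out <- as.data.frame(track)
  out$window_size <- attr(track, "window_size")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
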