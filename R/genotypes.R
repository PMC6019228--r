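#' Diploid genotype matrix
#'
#' The central container of the pipeline: a samples x variants matrix of
#' diploid genotype codes together with per-variant site metadata. Codes are
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' -1 = missing.
#'
#' @param calls Integer matrix, one row per sample, one column per variant,
#'   values in \{-1, 0, 1, 2\}.
#' @param variants `data.frame` with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt` and optionally `qual`. Must be sorted by chromosome and
#'   strictly increasing position within chromosome.
#' @param sample_ids Character vector of sample identifiers, one per row of
#'   `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants`, `sample_ids`.
#' @examples
#' gm <- genotype_matrix(
#'   calls = rbind(s1 = c(0L, 2L), s2 = c(1L, -1L)),
#'   variants = data.frame(chrom = "1", pos = c(100L, 200L),
#'                         ref = "A", alt = c("C", "G")),
#'   sample_ids = c("s1", "s2"))
#' gm
#' @export
genotype_matrix <- function(calls, variants, sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) {
    stop("sample_ids are required (or rownames on `calls`)")
  }
  sample_ids <- as.character(sample_ids)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variants table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (nrow(calls) != length(sample_ids)) {
    stop("calls has ", nrow(calls), " rows but ", length(sample_ids),
         " sample ids")
  }
  if (ncol(calls) != nrow(variants)) {
    stop("calls has ", ncol(calls), " columns but ", nrow(variants),
         " variants")
  }
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  bad <- !calls %in% c(-1L, 0L, 1L, 2L)
  if (any(bad)) stop("genotype codes must be in {-1, 0, 1, 2}")
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1L)) stop("positions must be >= 1")
    if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
    ord <- order(variants$chrom, variants$pos)
    if (any(ord != seq_len(nrow(variants)))) {
      stop("variants must be sorted by (chromosome, position)")
    }
    same_chrom <- variants$chrom[-1] == variants$chrom[-nrow(variants)]
    if (nrow(variants) > 1 &&
        any(same_chrom & diff(variants$pos) <= 0L)) {
      stop("positions must be strictly increasing within chromosome")
    }
  }
  rownames(calls) <- sample_ids
  structure(list(calls = calls, variants = variants, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  if (nrow(x$variants) > 0) {
    chroms <- unique(x$variants$chrom)
    cat("  chromosomes: ", paste(utils::head(chroms, 6), collapse = ", "),
        if (length(chroms) > 6) ", ..." else "", "\n", sep = "")
  }
  n_miss <- sum(x$calls == -1L)
  cat("  missing calls: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param gm A [genotype_matrix()].
#' @param samples Character vector of sample ids to keep (default all).
#' @param variant_idx Integer or logical index into the variant table
#'   (default all). Must preserve sort order.
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, variant_idx = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(samples)) samples <- gm$sample_ids
  unknown <- setdiff(samples, gm$sample_ids)
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(variant_idx)) variant_idx <- seq_len(nrow(gm$variants))
  genotype_matrix(gm$calls[samples, variant_idx, drop = FALSE],
                  gm$variants[variant_idx, , drop = FALSE],
                  samples)
}

#' Extract the genotype codes of one sample
#'
#' @param gm A [genotype_matrix()].
#' @param sample_id Sample identifier.
#' @return Integer vector of codes, one per variant.
#' @export
gm_sample_calls <- function(gm, sample_id) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!sample_id %in% gm$sample_ids) stop("unknown sample id: ", sample_id)
  gm$calls[sample_id, ]
}

# ---- genomic intervals ------------------------------------------------------

#' Construct a table of 1-based inclusive genomic intervals
#'
#' All interval coordinates in this package are 1-based and inclusive at both
#' ends, matching the convention genomic positions are reported in; conversion to
#' 0-based half-open happens only at the BED file boundary.
#'
#' @param chrom Character vector of chromosome labels.
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @param ... Further equal-length payload columns.
#' @return `data.frame` with class `genomic_intervals` prepended.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1L)) stop("interval starts must be >= 1")
  if (any(end < start)) stop("interval end < start")
  out <- data.frame(chrom = chrom, start = start, end = end, ...,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

# Internal: intervals data.frame -> GRanges (1-based inclusive both ways,
# GRanges is natively 1-based inclusive so this is a plain repackaging).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
}

# Internal: GRanges -> intervals data.frame
granges_to_df <- function(gr) {
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr))
}

# Internal: merge overlapping/adjacent-by-0 intervals per chromosome
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(genomic_intervals(character(), integer(), integer()))
  granges_to_df(GenomicRanges::reduce(as_granges(df)))
}
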