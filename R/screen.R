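#' Variants located inside a set of genomic regions
#'
#' @param gm A [genotype_matrix()].
#' @param regions Merged, sorted intervals ([genomic_intervals()]).
#' @return Integer vector of variant indices into `gm$variants` whose
#'   position falls inside any region (1-based inclusive at both ends).
#' @export
variants_in_regions <- function(gm, regions) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(regions) == 0 || nrow(gm$variants) == 0) return(integer())
  var_gr <- GenomicRanges::GRanges(
    seqnames = gm$variants$chrom,
    ranges = IRanges::IRanges(start = gm$variants$pos,
                              end = gm$variants$pos))
  hits <- GenomicRanges::findOverlaps(var_gr, as_granges(regions))
  sort(unique(S4Vectors::queryHits(hits)))
}

#' Filter variants by predicted effect class
#'
#' Joins the variant table against an annotation table on (chrom, pos, alt)
#' and keeps variants whose predicted effect class is in `classes`.
#' Unannotated variants are dropped (their count is reported via a message),
#' matching a screen in which only effect-predicted variants move forward.
#'
#' @param variants `data.frame` with chrom, pos, alt (e.g. rows of
#'   `gm$variants`).
#' @param annotations Annotation table as from [read_annotations()].
#' @param classes Effect classes to retain.
#' @return The retained rows of `variants`, with `effect_class`,
#'   `sift_score`, `deleterious` (score < 0.05; NA when no score) and `gene`
#'   columns appended.
#' @export
effect_filter <- function(variants, annotations,
                          classes = c("HIGH", "MODERATE")) {
  key_v <- paste(variants$chrom, variants$pos, variants$alt)
  key_a <- paste(annotations$chrom, annotations$pos, annotations$alt)
  if (anyDuplicated(key_a)) {
    stop("duplicate annotation for key(s): ",
         paste(unique(key_a[duplicated(key_a)]), collapse = "; "))
  }
  idx <- match(key_v, key_a)
  n_unannotated <- sum(is.na(idx))
  if (n_unannotated > 0) {
    message(n_unannotated, " variant(s) without annotation dropped")
  }
  keep <- !is.na(idx) & annotations$effect_class[idx] %in% classes
  out <- variants[keep, , drop = FALSE]
  ai <- idx[keep]
  score <- if ("sift_score" %in% names(annotations)) {
    annotations$sift_score[ai]
  } else {
    rep(NA_real_, length(ai))
  }
  out$effect_class <- annotations$effect_class[ai]
  out$sift_score <- score
  out$deleterious <- ifelse(is.na(score), NA, score < 0.05)
  out$gene <- if ("gene" %in% names(annotations)) annotations$gene[ai] else
    NA_character_
  out
}

#' Case-exclusive homozygous-mutant genotype screen
#'
#' Retains variants at which every case sample is homozygous for the
#' alternate allele (code 2) and every control sample is homozygous
#' reference (code 0). A missing call in any required sample disqualifies
#' the variant: in a candidate screen a false positive costs more than a
#' false negative, so "all" is read strictly. Samples with unclear phenotype
#' (e.g. ancient genomes) should be listed in `exclude_samples`, which
#' removes them from both groups before testing.
#'
#' @param gm A [genotype_matrix()].
#' @param case_ids,control_ids Disjoint sample sets.
#' @param variant_idx Variant indices to test (default: all variants).
#' @param exclude_samples Samples removed from both groups before the test.
#' @param case_code,control_code Genotype codes required in every case and
#'   every control; the defaults give the homozygous-mutant versus
#'   homozygous-wild-type pattern, and other patterns (e.g. tolerating
#'   heterozygous cases) can be screened by changing them.
#' @return The subset of `variant_idx` that passes.
#' @export
exclusivity_filter <- function(gm, case_ids, control_ids,
                               variant_idx = NULL,
                               exclude_samples = character(),
                               case_code = 2L, control_code = 0L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  case_ids <- setdiff(case_ids, exclude_samples)
  control_ids <- setdiff(control_ids, exclude_samples)
  if (length(case_ids) < 1) stop("case set is empty")
  if (length(intersect(case_ids, control_ids))) {
    stop("case and control sets must be disjoint")
  }
  unknown <- setdiff(c(case_ids, control_ids), gm$sample_ids)
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(variant_idx)) variant_idx <- seq_len(nrow(gm$variants))
  if (!length(variant_idx)) return(integer())
  cases <- gm$calls[case_ids, variant_idx, drop = FALSE]
  controls <- gm$calls[control_ids, variant_idx, drop = FALSE]
  pass <- colSums(cases == case_code) == length(case_ids) &
    colSums(controls == control_code) == length(control_ids)
  variant_idx[pass]
}

#' Run the full in-region variant screen
#'
#' Composes [variants_in_regions()], [effect_filter()] and
#' [exclusivity_filter()] into the candidate screen: variants inside shared
#' ROH regions, with a high or moderate predicted effect, homozygous mutant
#' in every case and homozygous wild type in every control.
#'
#' @inheritParams exclusivity_filter
#' @param regions Shared-region intervals.
#' @param annotations Annotation table (or NULL to skip the effect filter).
#' @param classes Effect classes passed to [effect_filter()].
#' @return `data.frame` of surviving variants with annotation columns.
#' @export
screen_variants <- function(gm, regions, annotations, case_ids, control_ids,
                            classes = c("HIGH", "MODERATE"),
                            exclude_samples = character()) {
  idx <- variants_in_regions(gm, regions)
  vars <- gm$variants[idx, , drop = FALSE]
  vars$variant_idx <- idx
  if (!is.null(annotations)) {
    vars <- effect_filter(vars, annotations, classes)
  }
  keep <- exclusivity_filter(gm, case_ids, control_ids,
                             variant_idx = vars$variant_idx,
                             exclude_samples = exclude_samples)
  vars[vars$variant_idx %in% keep, , drop = FALSE]
}
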