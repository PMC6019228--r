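#' Single-locus genotype model for a quantitative trait
#'
#' One-way fixed-effects linear model `trait ~ genotype` with genotype as a
#' categorical factor. Reports the model R-square, F statistic with
#' (k - 1, n - k) degrees of freedom, p-value, and least-squares means per
#' observed genotype class with standard errors `s / sqrt(n_class)` from the
#' pooled residual standard deviation. In a one-factor model the
#' least-squares means equal the class means. Records with a missing
#' genotype or trait are dropped.
#'
#' @param records A `trait_records` data.frame.
#' @param locus Name of the genotype-code column to test.
#' @param trait Trait column, `"height_cm"` or `"cannon_cm"`.
#' @return List of class `glm_result`: locus, n, r_square, f_value, p_value,
#'   and `lsmeans` (data.frame: genotype code, lsmean, se, n).
#' @export
fit_single_locus <- function(records, locus, trait = "height_cm") {
  if (!locus %in% names(records)) stop("no genotype column '", locus, "'")
  g <- records[[locus]]
  y <- records[[trait]]
  ok <- !is.na(y) & g != -1L
  g <- g[ok]
  y <- y[ok]
  if (length(y) < 3) stop("need at least 3 complete records")
  if (length(unique(g)) < 2) stop("no variance in genotype at ", locus)
  fit <- stats::lm(y ~ factor(g))
  an <- stats::anova(fit)
  ss_model <- an$`Sum Sq`[1]
  ss_resid <- an$`Sum Sq`[2]
  r2 <- ss_model / (ss_model + ss_resid)
  s <- sqrt(an$`Mean Sq`[2])
  classes <- sort(unique(g))
  n_class <- vapply(classes, function(cl) sum(g == cl), integer(1))
  lsmean <- vapply(classes, function(cl) mean(y[g == cl]), numeric(1))
  structure(list(
    locus = locus, trait = trait, n = length(y),
    r_square = r2,
    f_value = an$`F value`[1],
    p_value = an$`Pr(>F)`[1],
    lsmeans = data.frame(genotype = classes, lsmean = lsmean,
                         se = s / sqrt(n_class), n = n_class)),
    class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("Genotype effect at ", x$locus, " on ", x$trait,
      " (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  R-square %.3f, F = %.2f, P = %.4g\n",
              x$r_square, x$f_value, x$p_value))
  print(transform(x$lsmeans, lsmean = round(lsmean, 2), se = round(se, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Joint additive (and optionally dominance) model over candidate loci
#'
#' Ordinary least squares on
#' `trait ~ sum_k a_k * code_k + sum_k d_k * I(code_k == 1)`, with dominance
#' indicators fitted only for the loci named in `dominance_for`. The
#' homozygote-to-homozygote span of the fitted architecture,
#' `total_reduction_cm = |2 * sum_k a_k|`, estimates the expected height
#' difference between an individual homozygous wild type at every locus and
#' one homozygous mutant at every locus.
#'
#' @param records A `trait_records` data.frame.
#' @param loci Character vector (length >= 2) of genotype-code columns.
#' @param trait Trait column name.
#' @param dominance_for Subset of `loci` that also get a dominance term.
#' @return List of class `joint_model`: `additive` (data.frame locus,
#'   estimate, se, t, p), `dominance` (same shape, possibly empty),
#'   intercept, r_square, n, total_reduction_cm, and the underlying `fit`.
#' @export
fit_joint_additive <- function(records, loci, trait = "height_cm",
                               dominance_for = character()) {
  if (length(loci) < 2) stop("need at least two loci (use fit_single_locus)")
  missing_loci <- setdiff(loci, names(records))
  if (length(missing_loci)) {
    stop("no genotype column(s): ", paste(missing_loci, collapse = ", "))
  }
  stopifnot(all(dominance_for %in% loci))
  codes <- as.matrix(records[, loci, drop = FALSE])
  y <- records[[trait]]
  ok <- !is.na(y) & rowSums(codes == -1L) == 0
  codes <- codes[ok, , drop = FALSE]
  y <- y[ok]
  X <- codes
  colnames(X) <- loci
  for (locus in dominance_for) {
    X <- cbind(X, as.integer(codes[, locus] == 1L))
    colnames(X)[ncol(X)] <- paste0("dom_", locus)
  }
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design matrix rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  add <- ct[loci, , drop = FALSE]
  additive <- data.frame(locus = loci, estimate = add[, 1], se = add[, 2],
                         t = add[, 3], p = add[, 4], row.names = NULL)
  dominance <- if (length(dominance_for)) {
    dm <- ct[paste0("dom_", dominance_for), , drop = FALSE]
    data.frame(locus = dominance_for, estimate = dm[, 1], se = dm[, 2],
               t = dm[, 3], p = dm[, 4], row.names = NULL)
  } else {
    data.frame(locus = character(), estimate = numeric(), se = numeric(),
               t = numeric(), p = numeric())
  }
  structure(list(
    additive = additive, dominance = dominance,
    intercept = unname(ct["(Intercept)", 1]),
    r_square = sm$r.squared, n = length(y),
    total_reduction_cm = abs(2 * sum(additive$estimate)),
    fit = fit),
    class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat("Joint additive genotype model (n = ", x$n, ", R-square ",
      round(x$r_square, 3), ")\n", sep = "")
  print(transform(x$additive, estimate = round(estimate, 3),
                  se = round(se, 3), t = round(t, 2), p = signif(p, 3)),
        row.names = FALSE)
  if (nrow(x$dominance)) {
    cat("dominance terms:\n")
    print(transform(x$dominance, estimate = round(estimate, 3),
                    se = round(se, 3), t = round(t, 2), p = signif(p, 3)),
          row.names = FALSE)
  }
  cat(sprintf("total homozygote-to-homozygote reduction: %.2f cm\n",
              x$total_reduction_cm))
  invisible(x)
}

#' Linkage disequilibrium r-squared between two loci
#'
#' Squared Pearson correlation of the 0/1/2 allele-count vectors over
#' samples with non-missing genotypes at both loci. Invariant to swapping
#' the reference/alternate coding (code -> 2 - code) at either locus.
#'
#' @param records A `trait_records` data.frame (or any data.frame with
#'   genotype-code columns).
#' @param locus_a,locus_b Column names.
#' @return r-squared in [0, 1], or NA when fewer than 2 complete samples or
#'   no variance at either locus.
#' @export
ld_r2 <- function(records, locus_a, locus_b) {
  ga <- records[[locus_a]]
  gb <- records[[locus_b]]
  ok <- ga != -1L & gb != -1L & !is.na(ga) & !is.na(gb)
  ga <- ga[ok]
  gb <- gb[ok]
  if (length(ga) < 2) return(NA_real_)
  if (stats::var(ga) == 0 || stats::var(gb) == 0) return(NA_real_)
  stats::cor(ga, gb)^2
}

#' Four-locus miniature-size classifier
#'
#' The synergistic genotype rule: an animal is predicted miniature
#' (withers height capped at the ceiling) when it is homozygous for the
#' size-reducing allele at all four candidate loci, or homozygous at three
#' and heterozygous at the fourth. Of the 81 possible four-locus genotype
#' combinations exactly 5 satisfy the rule.
#'
#' @param codes Integer vector of length 4 (codes in \{0, 1, 2\}), or a
#'   matrix/data.frame with 4 such columns (one row per animal).
#' @return Logical (vector).
#' @export
miniature_classifier <- function(codes) {
  if (is.data.frame(codes)) codes <- as.matrix(codes)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  if (ncol(codes) != 4) stop("classifier needs exactly 4 locus codes")
  if (any(codes == -1L | is.na(codes))) stop("missing genotype code")
  if (any(!codes %in% 0:2)) stop("codes must be in {0, 1, 2}")
  n2 <- rowSums(codes == 2L)
  n1 <- rowSums(codes == 1L)
  unname(n2 == 4L | (n2 == 3L & n1 == 1L))
}

#' Check the size ceiling against classifier-positive animals
#'
#' @param records A `trait_records` data.frame with all four candidate
#'   genotype columns complete.
#' @param loci The four genotype-code columns, in order.
#' @param ceiling_cm Height ceiling (cm) the classifier asserts.
#' @return `data.frame` of violating records (classifier true but height
#'   above the ceiling); zero rows means the ceiling claim holds on this
#'   dataset.
#' @export
ceiling_check <- function(records, loci, ceiling_cm = 87.0) {
  codes <- as.matrix(records[, loci, drop = FALSE])
  pred <- miniature_classifier(codes)
  viol <- pred & !is.na(records$height_cm) & records$height_cm > ceiling_cm
  out <- records[viol, , drop = FALSE]
  rownames(out) <- NULL
  out
}
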