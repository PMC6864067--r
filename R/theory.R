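#' Expected cross-spouse correlations under phenotypic assortment
#'
#' Under single-round assortment on a phenotype P with spousal phenotypic
#' correlation C, and a genetic score G satisfying corr(G, P) = sqrt(h2)
#' within individuals (h2 the fraction of phenotypic variance the score
#' explains), joint normality and linear mate selection imply
#'
#' \deqn{corr(G_I, P_{partner}) = C \sqrt{h^2}, \qquad
#'       corr(G_I, G_{partner}) = C h^2.}
#'
#' These are the attenuation factors that make genotype-based estimates of
#' assortment smaller than the phenotypic spousal correlation unless the
#' score explains all phenotypic variance, or unless the estimate is
#' rescaled as in Mendelian randomization (see [mr_rescaling_check()]).
#' They serve as the oracle for the couple simulator and for estimator
#' recovery tests.
#'
#' @param C spousal phenotypic correlation, in \[-1, 1\].
#' @param h2 fraction of phenotypic variance explained by the genetic
#'   score, in \[0, 1\].
#' @return An object of class `theory_expectation`: a list with `C`, `h2`,
#'   `exp_corr_G_Ppartner` and `exp_corr_G_Gpartner`.
#' @examples
#' expected_correlations(C = 0.4, h2 = 0.25)
#' @export
expected_correlations <- function(C, h2) {
  stopifnot(length(C) == 1, length(h2) == 1)
  if (!is.finite(C) || C < -1 || C > 1) stop("C must lie in [-1, 1]")
  if (!is.finite(h2) || h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  structure(
    list(
      C = C, h2 = h2,
      exp_corr_G_Ppartner = C * sqrt(h2),
      exp_corr_G_Gpartner = C * h2
    ),
    class = "theory_expectation"
  )
}

#' @export
print.theory_expectation <- function(x, ...) {
  cat(sprintf(
    paste0("assortment C = %.3f, score h2 = %.3f\n",
           "  expected corr(G_I, P_partner) = %.4f\n",
           "  expected corr(G_I, G_partner) = %.4f\n"),
    x$C, x$h2, x$exp_corr_G_Ppartner, x$exp_corr_G_Gpartner
  ))
  invisible(x)
}

#' Expected two-stage betas and Wald ratio under phenotypic assortment
#'
#' For a variant with per-allele effect `beta_focal` on the phenotype, pure
#' phenotypic assortment with linear mate selection gives an expected
#' exposure-stage slope of `beta_focal` (own genotype on own phenotype) and
#' an expected outcome-stage slope of `C * beta_focal` (own genotype on
#' partner phenotype); their Wald ratio is C, independent of how much of the
#' phenotypic variance genetics explains. This is the sense in which
#' Mendelian randomization rescaling undoes the genotype-level attenuation.
#'
#' @param C spousal phenotypic correlation.
#' @param h2 fraction of variance explained by the genetic score (not used
#'   by the ratio; retained to make the cancellation explicit).
#' @param beta_focal per-allele effect of the variant on the phenotype.
#' @param maf effect-allele frequency in (0, 0.5\] (recorded, not used by the
#'   expectation itself).
#' @return A list with `beta_exposure`, `beta_outcome` and `wald_ratio`.
#' @export
mr_rescaling_check <- function(C, h2 = NULL, beta_focal, maf = NULL) {
  if (!is.finite(C) || C < -1 || C > 1) stop("C must lie in [-1, 1]")
  if (!is.null(maf) && (maf <= 0 || maf > 0.5)) stop("maf must lie in (0, 0.5]")
  list(
    beta_exposure = beta_focal,
    beta_outcome = C * beta_focal,
    wald_ratio = C,
    h2 = h2, maf = maf
  )
}
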