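#' Derive a child seed from a master seed
#'
#' Every stochastic operation in the package draws its own random stream from
#' a master seed through this function, so that the master seed fully
#' determines all output while operations stay order-independent. Streams are
#' numbered; the stream order used by [simulate_cohort()] is documented there.
#'
#' @param master integer master seed.
#' @param stream integer stream index (>= 0).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(stream))
  as.integer((abs(master) + 1000003 * (stream + 1)) %% .Machine$integer.max)
}

#' Construct an association result
#'
#' Light-weight container for a single regression coefficient: estimate,
#' standard error, normal-approximation 95% confidence interval and two-sided
#' p-value.
#'
#' @param beta point estimate.
#' @param se standard error (> 0).
#' @param n number of analysis units (pairs or individuals).
#' @param covariates character vector of covariate names (may be empty).
#' @param term name of the coefficient reported.
#' @return An object of class `assoc_result`: a list with elements `beta`,
#'   `se`, `ci95` (length-2), `p`, `n`, `covariates`, `term`.
#' @export
assoc_result <- function(beta, se, n, covariates = character(), term = "x") {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  z <- beta / se
  structure(
    list(
      beta = beta, se = se,
      ci95 = c(beta - 1.96 * se, beta + 1.96 * se),
      p = 2 * stats::pnorm(-abs(z)),
      n = n, covariates = covariates, term = term
    ),
    class = "assoc_result"
  )
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf(
    "beta %.4g (95%% CI %.4g, %.4g), se %.3g, p = %.3g, n = %d\n",
    x$beta, x$ci95[1], x$ci95[2], x$se, x$p, x$n
  ))
  if (length(x$covariates)) {
    cat("adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

# Extract one term from an lm/glm fit as an assoc_result.
fit_to_assoc <- function(fit, term, covariates = character()) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm) || anyNA(sm[term, 1:2])) {
    stop("model did not yield an estimate for term '", term,
         "' (non-convergence or singular design)", call. = FALSE)
  }
  assoc_result(
    beta = sm[term, 1], se = sm[term, 2],
    n = stats::nobs(fit), covariates = covariates, term = term
  )
}

#' Z-test for a difference between two independent estimates
#'
#' Compares two estimates (for instance the phenotypic concordance slope and
#' the Mendelian randomization causal estimate) assuming independent normal
#' sampling errors: z = (b1 - b2) / sqrt(se1^2 + se2^2).
#'
#' @param beta1,se1 first estimate and its standard error.
#' @param beta2,se2 second estimate and its standard error.
#' @return A list with `z` and the two-sided normal `p`.
#' @export
z_difference <- function(beta1, se1, beta2, se2) {
  stopifnot(se1 >= 0, se2 >= 0, se1 + se2 > 0)
  z <- (beta1 - beta2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Convert a reported 95% confidence interval to a standard error
#'
#' Uses the symmetric-width convention SE = (upper - lower) / (2 * 1.96),
#' appropriate for externally supplied stratum tables that print Wald-type
#' intervals.
#'
#' @param lo,hi interval bounds.
#' @return Standard error.
#' @export
se_from_ci <- function(lo, hi) {
  stopifnot(all(hi >= lo))
  (hi - lo) / 3.92
}
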