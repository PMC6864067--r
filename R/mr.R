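#' Per-variant two-stage summary statistics for cross-spouse MR
#'
#' Container for harmonized summary statistics: the exposure-stage
#' association of each variant with the index individual's phenotype and
#' the outcome-stage association with the partner's phenotype.
#'
#' @param variant variant identifiers.
#' @param beta_exposure,se_exposure exposure-stage slope and SE per effect
#'   allele.
#' @param beta_outcome,se_outcome outcome-stage (partner phenotype) slope
#'   and SE per effect allele.
#' @param effect_allele optional effect-allele labels.
#' @return An object of class `mr_input` (a data frame).
#' @export
mr_input <- function(variant, beta_exposure, se_exposure, beta_outcome,
                     se_outcome, effect_allele = NA_character_) {
  stopifnot(all(se_exposure > 0), all(se_outcome > 0))
  k <- length(beta_exposure)
  stopifnot(length(beta_outcome) == k, length(se_outcome) == k)
  structure(
    data.frame(
      variant = rep_len(as.character(variant), k),
      beta_exposure = beta_exposure, se_exposure = se_exposure,
      beta_outcome = beta_outcome, se_outcome = se_outcome,
      effect_allele = rep_len(effect_allele, k),
      stringsAsFactors = FALSE
    ),
    class = c("mr_input", "data.frame")
  )
}

mr_estimate <- function(method, beta, se, n_snps, extra = list()) {
  z <- beta / se
  structure(
    c(list(
      method = method, beta = beta, se = se,
      ci95 = c(beta - 1.96 * se, beta + 1.96 * se),
      p = 2 * stats::pnorm(-abs(z)), n_snps = n_snps
    ), extra),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta %.4g (95%% CI %.4g, %.4g), p = %.3g, k = %d\n",
              x$method, x$beta, x$ci95[1], x$ci95[2], x$p, x$n_snps))
  if (!is.null(x$Q)) {
    cat(sprintf("  Cochran's Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
                x$Q, x$n_snps - 1L, x$Q_p, 100 * x$I2))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept %.4g (se %.3g, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

#' Per-variant SNP-phenotype association
#'
#' Ordinary least squares of the outcome on each variant's dosage with
#' shared covariates, under an additive (0/1/2) or dominant (0/1) coding.
#'
#' @param genotypes individuals x variants dosage matrix (rows aligned with
#'   `outcome`).
#' @param outcome numeric outcome vector.
#' @param covariates optional data frame of covariates (same row order).
#' @param model `"additive"` or `"dominant"`.
#' @return Data frame with `variant`, `beta`, `se`, `p`, `n`.
#' @export
snp_association <- function(genotypes, outcome,
                            covariates = NULL,
                            model = c("additive", "dominant")) {
  model <- match.arg(model)
  stopifnot(nrow(genotypes) == length(outcome))
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(outcome))
    cm <- stats::model.matrix(~ ., data = covariates)
    if (qr(cm)$rank < ncol(cm)) stop("collinear covariates")
  } else {
    cm <- matrix(1, nrow = length(outcome), ncol = 1)
  }
  res <- lapply(colnames(genotypes), function(vid) {
    g <- genotypes[, vid]
    if (model == "dominant") g <- as.integer(g > 0)
    X <- cbind(g = g, cm)
    ok <- stats::complete.cases(X) & !is.na(outcome)
    fit <- stats::lm.fit(X[ok, , drop = FALSE], outcome[ok])
    rdf <- sum(ok) - fit$rank
    sigma2 <- sum(fit$residuals^2) / rdf
    XtXinv <- chol2inv(chol(crossprod(X[ok, , drop = FALSE])))
    se <- sqrt(sigma2 * XtXinv[1, 1])
    b <- fit$coefficients["g"]
    data.frame(variant = vid, beta = b, se = se,
               p = 2 * stats::pt(-abs(b / se), rdf), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare additive and dominant genotype codings
#'
#' Fits additive (0/1/2), dominant (0/1) and saturated 2-df genotype-factor
#' models for one variant and reports fit statistics with a recommendation:
#' the saturated model's improvement over the additive fit is tested by
#' F-test; if additive is not rejected it is preferred, otherwise the
#' better-AIC coding wins. A variant with no detectable effect at all is
#' flagged.
#'
#' @param g 0/1/2 allele counts.
#' @param outcome numeric outcome.
#' @param alpha level for the additive-adequacy F-test.
#' @return A list with per-model AIC, the genotype-effect p-value, the
#'   additive-vs-saturated p-value and `recommendation` in
#'   `"additive"`/`"dominant"`/`"none"`.
#' @export
compare_additive_dominant <- function(g, outcome, alpha = 0.05) {
  ok <- !is.na(g) & !is.na(outcome)
  g <- g[ok]; outcome <- outcome[ok]
  fit_add <- stats::lm(outcome ~ g)
  fit_dom <- stats::lm(outcome ~ I(as.integer(g > 0)))
  fit_fac <- stats::lm(outcome ~ factor(g))
  p_any <- stats::anova(stats::lm(outcome ~ 1), fit_fac)[2, "Pr(>F)"]
  p_add_ok <- if (length(unique(g)) > 2) {
    stats::anova(fit_add, fit_fac)[2, "Pr(>F)"]
  } else NA_real_
  aics <- c(additive = stats::AIC(fit_add), dominant = stats::AIC(fit_dom))
  rec <- if (is.na(p_any) || p_any > alpha) {
    "none"
  } else if (!is.na(p_add_ok) && p_add_ok < alpha &&
             aics["dominant"] < aics["additive"]) {
    "dominant"
  } else if (is.na(p_add_ok) || p_add_ok >= alpha) {
    "additive"
  } else {
    names(aics)[which.min(aics)]
  }
  list(aic = aics, p_genotype = p_any, p_additive_adequate = p_add_ok,
       recommendation = rec)
}

#' Wald ratio estimate
#'
#' Single-instrument causal estimate: the outcome-stage beta divided by the
#' exposure-stage beta, with a first-order delta-method standard error
#' (exposure-stage uncertainty ignored, `se = se_outcome / |beta_exposure|`),
#' so the confidence bounds are the outcome-stage bounds rescaled by the
#' exposure slope. A second-order SE that propagates exposure-stage
#' uncertainty is available.
#'
#' @param input an [mr_input()] with a single variant.
#' @param se_method `"first"` (default) or `"second"` order delta SE.
#' @return An `mr_estimate`.
#' @examples
#' wald_ratio(mr_input("v", 3.99, 0.237, 1.06, 0.237))
#' @export
wald_ratio <- function(input, se_method = c("first", "second")) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(input, "mr_input"), nrow(input) == 1)
  bx <- input$beta_exposure; by <- input$beta_outcome
  if (bx == 0) stop("weak instrument: exposure-stage beta is zero")
  beta <- by / bx
  se <- if (se_method == "first") {
    input$se_outcome / abs(bx)
  } else {
    sqrt(input$se_outcome^2 / bx^2 +
           by^2 * input$se_exposure^2 / bx^4)
  }
  mr_estimate("wald", beta, se, 1L)
}

# Ratio estimates and their first-order variances; shared by the
# multi-instrument estimators.
ratio_stats <- function(input) {
  list(
    ratio = input$beta_outcome / input$beta_exposure,
    se = input$se_outcome / abs(input$beta_exposure)
  )
}

#' Fixed-effects inverse-variance-weighted estimate
#'
#' Combines per-variant Wald ratios with weights
#' `w_i = beta_exposure_i^2 / se_outcome_i^2` (the inverse first-order
#' ratio variances); equivalent to weighted regression of the outcome-stage
#' betas on the exposure-stage betas through the origin. Reports Cochran's
#' Q over the ratios and `I2 = max(0, (Q - (k - 1)) / Q)`. With one variant
#' it reduces to the Wald ratio.
#'
#' @param input an [mr_input()].
#' @return An `mr_estimate` with `Q`, `Q_p`, `I2`.
#' @export
ivw_fixed <- function(input) {
  stopifnot(inherits(input, "mr_input"), nrow(input) >= 1)
  rs <- ratio_stats(input)
  w <- 1 / rs$se^2
  beta <- sum(w * rs$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  k <- nrow(input)
  Q <- sum(w * (rs$ratio - beta)^2)
  Q_p <- if (k > 1) stats::pchisq(Q, df = k - 1, lower.tail = FALSE) else NA_real_
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  mr_estimate("ivw", beta, se, k, list(Q = Q, Q_p = Q_p, I2 = I2))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome-stage betas on the exposure-stage
#' betas with an intercept, weights `1 / se_outcome^2`, after harmonizing
#' all exposure betas to positive orientation. The slope is the causal
#' estimate; the intercept estimates the average directional pleiotropic
#' effect, and its test is the Egger intercept test.
#'
#' @param input an [mr_input()] with at least three variants.
#' @return An `mr_estimate` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`.
#' @export
mr_egger <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  k <- nrow(input)
  if (k < 3) stop("MR-Egger requires at least 3 variants")
  flip <- sign(input$beta_exposure)
  flip[flip == 0] <- 1
  bx <- input$beta_exposure * flip
  by <- input$beta_outcome * flip
  w <- 1 / input$se_outcome^2
  # weighted normal equations for y = a + b x
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  b <- (sw * swxy - swx * swy) / det
  a <- (swxx * swy - swx * swxy) / det
  resid <- by - a - b * bx
  sigma2 <- sum(w * resid^2) / (k - 2)
  se_b <- sqrt(sigma2 * sw / det)
  se_a <- sqrt(sigma2 * swxx / det)
  t_a <- a / se_a
  mr_estimate("egger", b, se_b, k, list(
    egger_intercept = a, egger_intercept_se = se_a,
    egger_intercept_p = 2 * stats::pt(-abs(t_a), df = k - 2)
  ))
}

# Interpolated weighted median of ratio estimates (weights normalized;
# cumulative weight centred on each order statistic, linear interpolation
# at probability one half).
weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]; wn <- w[o] / sum(w)
  cum <- cumsum(wn) - wn / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  i <- max(which(cum < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

#' Weighted median estimate
#'
#' The inverse-variance weighted median of the per-variant ratio estimates,
#' consistent when variants contributing at least half the weight are valid
#' instruments. The standard error comes from a parametric bootstrap:
#' ratios are resampled from `Normal(ratio_i, se_i)` and the weighted
#' median recomputed.
#'
#' @param input an [mr_input()] with at least three variants.
#' @param n_boot bootstrap draws.
#' @param seed seed for the bootstrap stream.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(input, n_boot = 5000, seed = 1) {
  stopifnot(inherits(input, "mr_input"))
  k <- nrow(input)
  if (k < 3) stop("weighted median requires at least 3 variants")
  rs <- ratio_stats(input)
  w <- 1 / rs$se^2
  beta <- weighted_median_point(rs$ratio, w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    weighted_median_point(stats::rnorm(k, rs$ratio, rs$se), w)
  }, numeric(1))
  mr_estimate("wmedian", beta, stats::sd(boots), k)
}

# Weighted-mode point estimate: normal-kernel density over ratio estimates
# with inverse-variance weights, evaluated on a fixed fine grid; bandwidth
# is `factor` times the modified Silverman rule on the ratios.
weighted_mode_point <- function(ratio, w, bandwidth_factor = 1,
                                n_grid = 10000) {
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * length(ratio)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(ratio) * length(ratio)^(-1 / 5)
  if (s <= 0 || !is.finite(s)) return(list(mode = ratio[1], bandwidth = 0))
  h <- bandwidth_factor * s
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = n_grid)
  wn <- w / sum(w)
  dens <- vapply(grid, function(x) {
    sum(wn * stats::dnorm((x - ratio) / h))
  }, numeric(1))
  list(mode = grid[which.max(dens)], bandwidth = h)
}

#' Weighted mode estimate
#'
#' The mode of the inverse-variance weighted kernel density of the
#' per-variant ratio estimates (normal kernel, bandwidth a multiple of the
#' modified Silverman rule, argmax taken on a fixed fine grid), consistent
#' when the largest group of variants sharing one ratio value is valid.
#' Standard error by parametric bootstrap, as in [weighted_median()].
#'
#' @param input an [mr_input()] with at least three variants.
#' @param bandwidth_factor multiplier on the modified Silverman bandwidth.
#' @param n_boot bootstrap draws.
#' @param seed seed for the bootstrap stream.
#' @return An `mr_estimate` (with the `bandwidth` used).
#' @export
weighted_mode <- function(input, bandwidth_factor = 1, n_boot = 5000,
                          seed = 1) {
  stopifnot(inherits(input, "mr_input"))
  k <- nrow(input)
  if (k < 3) stop("weighted mode requires at least 3 variants")
  rs <- ratio_stats(input)
  w <- 1 / rs$se^2
  pt <- weighted_mode_point(rs$ratio, w, bandwidth_factor)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    weighted_mode_point(stats::rnorm(k, rs$ratio, rs$se), w,
                        bandwidth_factor, n_grid = 512)$mode
  }, numeric(1))
  mr_estimate("wmode", pt$mode, stats::sd(boots), k,
              list(bandwidth = pt$bandwidth))
}

#' Two-stage cross-spouse MR from individual-level data
#'
#' Builds the [mr_input()] for a variant panel from a spouse-pair sample:
#' the exposure stage regresses each individual's phenotype on their own
#' dosage (each individual appearing once), the outcome stage regresses the
#' partner's phenotype on the index dosage with the two-rows-per-couple
#' layout (each individual appearing as both reference and partner).
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param data individual table with `id` and the phenotype.
#' @param genotypes dosage matrix (rownames = ids).
#' @param variants variant IDs (columns of `genotypes`) to use.
#' @param var phenotype column name.
#' @param covariate_cols optional covariate column names in `data`
#'   (index-member values are used for the exposure stage; both members'
#'   for the outcome stage).
#' @param n_pcs number of genotype principal components to adjust for
#'   (0 for none), computed by truncated SVD of the centred-scaled dosages.
#' @return An [mr_input()].
#' @export
mr_stages <- function(pairs, data, genotypes, variants, var,
                      covariate_cols = NULL, n_pcs = 0) {
  stopifnot(all(variants %in% colnames(genotypes)))
  ids <- unique(c(pairs$id_a, pairs$id_b))
  pcs <- if (n_pcs > 0) genotype_pcs(genotypes[ids, , drop = FALSE], n_pcs)
  pheno <- stats::setNames(data[[var]][match(ids, data$id)], ids)
  covs <- function(member_ids, prefix = "") {
    out <- NULL
    if (!is.null(covariate_cols)) {
      out <- data[match(member_ids, data$id), covariate_cols, drop = FALSE]
      names(out) <- paste0(prefix, covariate_cols)
    }
    out
  }
  # exposure stage: one row per individual
  cov_exp <- covs(ids)
  if (!is.null(pcs)) {
    cov_exp <- if (is.null(cov_exp)) as.data.frame(pcs[ids, , drop = FALSE])
    else cbind(cov_exp, as.data.frame(pcs[ids, , drop = FALSE]))
  }
  exp_assoc <- snp_association(genotypes[ids, variants, drop = FALSE],
                               pheno[ids], cov_exp)
  # outcome stage: two rows per couple
  idx <- c(pairs$id_a, pairs$id_b)
  prt <- c(pairs$id_b, pairs$id_a)
  cov_out <- NULL
  ci <- covs(idx); cp <- covs(prt, "partner_")
  # the partner's sex is determined by the index member's in opposite-sex
  # pairs; drop it to keep the design full rank
  if (!is.null(cp)) cp$partner_sex <- NULL
  if (!is.null(ci)) cov_out <- if (ncol(cp)) cbind(ci, cp) else ci
  if (!is.null(pcs)) {
    pc_i <- as.data.frame(pcs[idx, , drop = FALSE])
    pc_p <- as.data.frame(pcs[prt, , drop = FALSE])
    names(pc_p) <- paste0("partner_", names(pc_p))
    cov_out <- if (is.null(cov_out)) cbind(pc_i, pc_p)
    else cbind(cov_out, pc_i, pc_p)
  }
  out_assoc <- snp_association(genotypes[idx, variants, drop = FALSE],
                               as.numeric(pheno[prt]), cov_out)
  mr_input(variants,
           beta_exposure = exp_assoc$beta, se_exposure = exp_assoc$se,
           beta_outcome = out_assoc$beta, se_outcome = out_assoc$se)
}

#' Genotype principal components
#'
#' Top principal components of the centred, variance-standardized dosage
#' matrix by truncated SVD, the standard adjustment for population
#' stratification.
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param k number of components.
#' @return Matrix of scores (individuals x k), rownames preserved.
#' @export
genotype_pcs <- function(genotypes, k = 10) {
  G <- genotypes
  G[is.na(G)] <- 0
  p <- colMeans(G) / 2
  use <- p > 0 & p < 1 & apply(G, 2, stats::sd) > 0
  Z <- scale(G[, use, drop = FALSE])
  k <- min(k, ncol(Z), nrow(Z) - 1)
  sv <- svd(Z, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(genotypes), paste0("PC", seq_len(k)))
  scores
}
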