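#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the proportions implied by the sample allele frequency.
#' Pooled subpopulations with differing allele frequencies show a
#' heterozygote deficit (Wahlund effect), which this test detects.
#'
#' @param genotypes either a vector of 0/1/2 allele counts or a length-3
#'   count vector `c(n0, n1, n2)` of genotypes carrying 0, 1, 2 copies.
#' @return An object of class `hwe_result`: observed and expected counts,
#'   `chi2`, `p`, `maf`, and the heterozygote deficit direction.
#' @examples
#' hwe_test(c(10, 80, 10))
#' @export
hwe_test <- function(genotypes) {
  counts <- if (length(genotypes) == 3 && is.numeric(genotypes) &&
                all(genotypes >= 0) && sum(genotypes) > 3 &&
                !all(genotypes %in% 0:2)) {
    as.numeric(genotypes)
  } else if (length(genotypes) == 3 && all(genotypes %in% 0:2) &&
             is.null(names(genotypes))) {
    # ambiguous tiny input: treat as genotype vector
    as.numeric(tabulate(genotypes + 1, 3))
  } else {
    g <- genotypes[!is.na(genotypes)]
    stopifnot(all(g %in% 0:2))
    as.numeric(tabulate(g + 1, 3))
  }
  N <- sum(counts)
  if (N == 0) stop("no genotype observations")
  p <- (2 * counts[3] + counts[2]) / (2 * N)
  q <- 1 - p
  expected <- N * c(q^2, 2 * p * q, p^2)
  if (p == 0 || q == 0) {
    return(structure(
      list(observed = counts, expected = expected, chi2 = 0, p_value = 1,
           maf = min(p, q), het_deficit = FALSE, monomorphic = TRUE),
      class = "hwe_result"
    ))
  }
  chi2 <- sum((counts - expected)^2 / expected)
  structure(
    list(
      observed = counts, expected = expected, chi2 = chi2,
      p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
      maf = min(p, q), het_deficit = counts[2] < expected[2],
      monomorphic = FALSE
    ),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf(
    "HWE: chi2 = %.2f (p = %.3g), MAF = %.3f; heterozygotes observed %d, expected %.0f%s\n",
    x$chi2, x$p_value, x$maf, round(x$observed[2]), x$expected[2],
    if (x$het_deficit) " (deficit)" else ""
  ))
  invisible(x)
}

#' Allele-frequency difference between two samples
#'
#' 2x2 chi-square on allele counts (effect vs other allele, sample 1 vs
#' sample 2), without continuity correction.
#'
#' @param counts1,counts2 genotype count vectors `c(n0, n1, n2)` or 0/1/2
#'   genotype vectors for the two samples.
#' @return A list with `chi2`, `p`, and the two allele frequencies.
#' @export
allele_freq_diff <- function(counts1, counts2) {
  to_counts <- function(x) {
    if (length(x) == 3 && !all(x %in% 0:2)) as.numeric(x)
    else as.numeric(tabulate(x[!is.na(x)] + 1, 3))
  }
  c1 <- to_counts(counts1); c2 <- to_counts(counts2)
  a1 <- c(2 * c1[1] + c1[2], 2 * c1[3] + c1[2])
  a2 <- c(2 * c2[1] + c2[2], 2 * c2[3] + c2[2])
  tab <- rbind(a1, a2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate allele-count table (zero margin)")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       freq1 = a1[2] / sum(a1), freq2 = a2[2] / sum(a2))
}

#' SNP association with geography and principal components
#'
#' Regresses birth northing, birth easting, and (optionally) each genetic
#' principal component on the variant's allele count — the standard
#' diagnostics for an allele-frequency cline.
#'
#' @param g named or positional 0/1/2 allele counts.
#' @param birth_coords data frame with `birth_north`, `birth_east` (km).
#' @param pcs optional matrix of principal-component scores (same rows).
#' @return Named list of [assoc_result()]s (`north`, `east`, `PC1`, ...).
#' @export
snp_geo_assoc <- function(g, birth_coords, pcs = NULL) {
  stopifnot(nrow(birth_coords) == length(g))
  one <- function(y) {
    ok <- !is.na(y) & !is.na(g)
    if (stats::var(y[ok]) == 0) {
      return(structure(list(beta = 0, se = NA_real_, ci95 = c(0, 0),
                            p = NA_real_, n = sum(ok),
                            covariates = character(), term = "g"),
                       class = "assoc_result"))
    }
    fit_to_assoc(stats::lm(y[ok] ~ g[ok]), "g[ok]")
  }
  out <- list(north = one(birth_coords$birth_north),
              east = one(birth_coords$birth_east))
  if (!is.null(pcs)) {
    for (j in seq_len(ncol(pcs))) out[[colnames(pcs)[j]]] <- one(pcs[, j])
  }
  out
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines per-stratum estimates with weights `1/se^2`; the combined
#' standard error is `1/sqrt(sum(w))`, and Cochran's Q across the stratum
#' betas (df = k - 1) quantifies heterogeneity.
#'
#' @param beta per-stratum estimates.
#' @param se per-stratum standard errors.
#' @param labels optional stratum labels.
#' @param n_pairs optional per-stratum sample sizes.
#' @return An object of class `meta_result`.
#' @export
meta_fixed <- function(beta, se, labels = NULL, n_pairs = NULL) {
  stopifnot(length(beta) == length(se), all(se > 0), length(beta) >= 1)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  k <- length(beta)
  Q <- sum(w * (beta - b)^2)
  structure(
    list(
      strata = data.frame(
        label = if (is.null(labels)) paste0("stratum_", seq_len(k)) else labels,
        n_pairs = if (is.null(n_pairs)) NA_integer_ else n_pairs,
        beta = beta, se = se,
        ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
        stringsAsFactors = FALSE
      ),
      excluded = data.frame(label = character(), reason = character(),
                            stringsAsFactors = FALSE),
      combined_beta = b, combined_se = s,
      combined_ci = c(b - 1.96 * s, b + 1.96 * s),
      combined_p = 2 * stats::pnorm(-abs(b / s)),
      Q = Q,
      Q_p = if (k > 1) stats::pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_,
      k_used = k
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "fixed-effects meta-analysis over %d strata%s:\n  combined %.4g (95%% CI %.4g, %.4g), p = %.3g\n  Cochran's Q = %.2f (p = %.3g)\n",
    x$k_used,
    if (nrow(x$excluded)) sprintf(" (%d excluded)", nrow(x$excluded)) else "",
    x$combined_beta, x$combined_ci[1], x$combined_ci[2], x$combined_p,
    x$Q, x$Q_p
  ))
  invisible(x)
}

#' Within-centre meta-analysis of genotypic concordance
#'
#' Estimates the spousal genotypic concordance separately within each
#' recruitment centre and combines the per-centre slopes by fixed-effects
#' inverse-variance meta-analysis. Centres with fewer pairs than
#' `min_pairs`, or where the regression fails (monomorphic variant,
#' numerical failure), are excluded with the reason recorded.
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param genotypes dosage matrix or named dosage vector (see
#'   [genotypic_concordance()]).
#' @param variant variant ID when `genotypes` is a matrix.
#' @param centres named character vector of centre labels per individual
#'   (both members of a pair must agree; the index member's label is used).
#' @param min_pairs minimum pairs for a centre to enter the meta-analysis.
#' @param orientation allele orientation, as in [genotypic_concordance()].
#' @return A `meta_result` with per-centre strata and exclusions.
#' @export
within_centre_meta <- function(pairs, genotypes, variant = NULL, centres,
                               min_pairs = 50, orientation = "effect") {
  lab <- centres[pairs$id_a]
  strata <- sort(unique(lab))
  est <- list(); excl <- list()
  for (s in strata) {
    sub <- pairs[lab == s, , drop = FALSE]
    if (nrow(sub) < min_pairs) {
      excl[[s]] <- sprintf("only %d pairs (min %d)", nrow(sub), min_pairs)
      next
    }
    r <- tryCatch(
      genotypic_concordance(sub, genotypes, variant, orientation = orientation),
      error = function(e) conditionMessage(e)
    )
    if (is.character(r)) {
      excl[[s]] <- paste("regression failed:", r)
    } else {
      est[[s]] <- data.frame(label = s, n = nrow(sub), beta = r$beta,
                             se = r$se, stringsAsFactors = FALSE)
    }
  }
  if (!length(est)) stop("all centres excluded from meta-analysis")
  tab <- do.call(rbind, est)
  out <- meta_fixed(tab$beta, tab$se, labels = tab$label, n_pairs = tab$n)
  if (length(excl)) {
    out$excluded <- data.frame(label = names(excl),
                               reason = unlist(excl), stringsAsFactors = FALSE)
  }
  out
}

#' Meta-analysis from a pre-made stratum-estimate table
#'
#' Meta-only mode for externally supplied per-stratum tables reporting
#' betas with 95% confidence intervals; standard errors are recovered by
#' the symmetric-width convention `SE = (ci_hi - ci_lo) / 3.92` and
#' combined as in [meta_fixed()].
#'
#' @param table data frame with columns `label`, `n_pairs`, `beta`,
#'   `ci_lo`, `ci_hi` (a path to such a TSV is also accepted).
#' @return A `meta_result`.
#' @export
meta_from_table <- function(table) {
  if (is.character(table)) {
    table <- utils::read.table(table, sep = "\t", header = TRUE,
                               quote = "", stringsAsFactors = FALSE)
  }
  need <- c("label", "n_pairs", "beta", "ci_lo", "ci_hi")
  stopifnot(all(need %in% names(table)))
  meta_fixed(table$beta, se_from_ci(table$ci_lo, table$ci_hi),
             labels = table$label, n_pairs = table$n_pairs)
}

#' Stratify spouse pairs by birth distance
#'
#' Computes the Euclidean km distance between the members' birth
#' coordinates, splits pairs at the threshold (pairs at exactly the
#' threshold count as "within"), reports pairs with missing coordinates
#' separately, and compares the genotypic concordance (and, when a
#' phenotype is supplied, the Wald-ratio MR estimate) between the two
#' strata with a Z-test.
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param data individual table with `id`, `birth_north`, `birth_east`.
#' @param genotypes dosage matrix.
#' @param variant focal variant ID.
#' @param var optional phenotype column for the per-stratum MR estimate.
#' @param threshold_km distance threshold (default 100 km).
#' @param orientation allele orientation for concordance.
#' @return A list with `distance`, the `within`/`beyond` pair sets,
#'   `n_missing`, per-stratum `genotypic` (and `mr`) estimates, and
#'   `z_genotypic` (and `z_mr`) stratum comparisons.
#' @export
distance_stratify <- function(pairs, data, genotypes, variant, var = NULL,
                              threshold_km = 100, orientation = "effect") {
  bn <- stats::setNames(data$birth_north, data$id)
  be <- stats::setNames(data$birth_east, data$id)
  d <- sqrt((bn[pairs$id_a] - bn[pairs$id_b])^2 +
              (be[pairs$id_a] - be[pairs$id_b])^2)
  missing <- is.na(d)
  within <- pairs[!missing & d <= threshold_km, , drop = FALSE]
  beyond <- pairs[!missing & d > threshold_km, , drop = FALSE]
  g_within <- genotypic_concordance(within, genotypes, variant,
                                    orientation = orientation)
  g_beyond <- genotypic_concordance(beyond, genotypes, variant,
                                    orientation = orientation)
  out <- list(
    distance = unname(d), n_missing = sum(missing),
    within = within, beyond = beyond,
    genotypic = list(within = g_within, beyond = g_beyond),
    z_genotypic = z_difference(g_within$beta, g_within$se,
                               g_beyond$beta, g_beyond$se)
  )
  if (!is.null(var)) {
    mr_one <- function(p) {
      wald_ratio(mr_stages(p, data, genotypes, variant, var))
    }
    m_w <- mr_one(within); m_b <- mr_one(beyond)
    out$mr <- list(within = m_w, beyond = m_b)
    out$z_mr <- z_difference(m_w$beta, m_w$se, m_b$beta, m_b$se)
  }
  out
}
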