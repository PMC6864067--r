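# Covariates with a single observed level (e.g. the reference member's sex
# when every index member is male) carry no information and would make the
# design singular; drop them.
drop_constant_covariates <- function(pd, keep = c("y", "x")) {
  drop <- vapply(names(pd), function(nm) {
    !(nm %in% keep) && length(unique(pd[[nm]])) < 2
  }, logical(1))
  pd[!drop]
}

# One row per couple with index/partner roles. The reference member is
# either the first listed member ("first") or randomized per couple
# ("random", seeded); the concordance estimand is symmetric, so the choice
# only perturbs estimates at Monte-Carlo order.
couple_frame <- function(pairs, ref = c("first", "random"), seed = NULL) {
  ref <- match.arg(ref)
  idx <- pairs$id_a; prt <- pairs$id_b
  if (ref == "random") {
    if (!is.null(seed)) set.seed(seed)
    flip <- stats::runif(nrow(pairs)) < 0.5
    tmp <- idx[flip]; idx[flip] <- prt[flip]; prt[flip] <- tmp
  }
  data.frame(index = idx, partner = prt, stringsAsFactors = FALSE)
}

# Assemble a couple-level regression table: partner outcome, index
# exposure, and covariates of both members where requested.
build_pair_data <- function(pairs, data, var, covariates = NULL,
                            ref = "first", seed = NULL) {
  stopifnot(all(c(pairs$id_a, pairs$id_b) %in% data$id))
  cf <- couple_frame(pairs, ref, seed)
  di <- data[match(cf$index, data$id), ]
  dp <- data[match(cf$partner, data$id), ]
  out <- data.frame(
    y = dp[[var]], x = di[[var]],
    sex = factor(di$sex), age = di$age, partner_age = dp$age,
    stringsAsFactors = FALSE
  )
  for (cv in setdiff(covariates, c("sex", "age", "partner_age"))) {
    if (!cv %in% names(data)) stop("unknown covariate: ", cv)
    out[[cv]] <- di[[cv]]
    out[[paste0("partner_", cv)]] <- dp[[cv]]
  }
  out
}

#' Spousal phenotypic concordance
#'
#' Regresses the partner's phenotype on the index member's phenotype across
#' couples, one row per couple, with linear or logistic link and the
#' requested covariates (sex, both ages, and any further columns — e.g.
#' recruitment centre, height, education — entered for both members).
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param data individual table with `id`, `sex`, `age` and the phenotype.
#' @param var name of the phenotype column.
#' @param family `"linear"` for a Gaussian model or `"logistic"` for a
#'   binary trait (log-odds returned).
#' @param covariates character vector of covariate names; `"sex"`, `"age"`,
#'   `"partner_age"` refer to the standard adjustment, other names are
#'   taken from `data` for both members.
#' @param ref which member is the reference individual: `"first"` (as
#'   listed) or `"random"` (seeded).
#' @param seed seed for `ref = "random"`.
#' @return An [assoc_result()].
#' @export
phenotypic_concordance <- function(pairs, data, var,
                                   family = c("linear", "logistic"),
                                   covariates = NULL, ref = "first",
                                   seed = NULL) {
  family <- match.arg(family)
  pd <- build_pair_data(pairs, data, var, covariates, ref, seed)
  keep <- intersect(names(pd), c(
    "y", "x",
    intersect(covariates, c("sex", "age", "partner_age")),
    setdiff(names(pd), c("y", "x", "sex", "age", "partner_age"))
  ))
  pd <- pd[keep]
  pd <- pd[stats::complete.cases(pd), , drop = FALSE]
  if (!nrow(pd)) stop("no complete couples for phenotypic concordance")
  pd <- drop_constant_covariates(pd)
  form <- stats::as.formula(paste("y ~", paste(setdiff(names(pd), "y"),
                                               collapse = " + ")))
  fit <- if (family == "linear") {
    stats::lm(form, data = pd)
  } else {
    stats::glm(form, data = pd, family = stats::binomial())
  }
  if (family == "logistic" && !fit$converged) {
    stop("logistic regression did not converge (separation?)")
  }
  fit_to_assoc(fit, "x", covariates = setdiff(names(pd), c("y", "x")))
}

#' Spousal genotypic concordance for one variant
#'
#' Linear regression of the partner's effect-allele count on the index
#' member's count, one row per couple, unadjusted unless covariates are
#' passed. With `orientation = "major"` dosages are flipped to count the
#' major allele, matching the reporting convention for a low-MAF variant.
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param genotypes named vector of 0/1/2 allele counts, or a dosage matrix
#'   with `variant` naming the column.
#' @param variant column name when `genotypes` is a matrix.
#' @param data optional individual table for covariates.
#' @param covariates optional covariate names (see
#'   [phenotypic_concordance()]).
#' @param orientation count the stored effect allele (`"effect"`) or flip
#'   to the major allele (`"major"`).
#' @param ref,seed reference-member convention, as in
#'   [phenotypic_concordance()].
#' @return An [assoc_result()].
#' @export
genotypic_concordance <- function(pairs, genotypes, variant = NULL,
                                  data = NULL, covariates = NULL,
                                  orientation = c("effect", "major"),
                                  ref = "first", seed = NULL) {
  orientation <- match.arg(orientation)
  g <- if (is.matrix(genotypes)) {
    stopifnot(!is.null(variant), variant %in% colnames(genotypes))
    stats::setNames(genotypes[, variant], rownames(genotypes))
  } else genotypes
  g <- g[!is.na(g)]
  if (stats::var(g) == 0) stop("monomorphic variant: concordance undefined")
  if (orientation == "major" && mean(g) / 2 < 0.5) g <- 2 - g
  cf <- couple_frame(pairs, ref, seed)
  ok <- cf$index %in% names(g) & cf$partner %in% names(g)
  cf <- cf[ok, , drop = FALSE]
  pd <- data.frame(y = as.numeric(g[cf$partner]), x = as.numeric(g[cf$index]))
  if (!is.null(covariates) && !is.null(data)) {
    di <- data[match(cf$index, data$id), ]
    for (cv in covariates) pd[[cv]] <- di[[cv]]
    pd$sex <- if ("sex" %in% covariates) factor(di$sex) else pd$sex
  }
  pd <- pd[stats::complete.cases(pd), , drop = FALSE]
  pd <- drop_constant_covariates(pd)
  fit <- stats::lm(y ~ ., data = pd)
  fit_to_assoc(fit, "x", covariates = setdiff(names(pd), c("y", "x")))
}

#' Compute polygenic scores from dosages and weights
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param weights data frame with `id` (variant) and `weight`, or a named
#'   numeric vector.
#' @param standardize scale scores to mean 0, SD 1 (the analysis
#'   convention).
#' @return Named numeric vector of scores.
#' @export
pgs_score <- function(genotypes, weights, standardize = TRUE) {
  w <- if (is.data.frame(weights)) {
    stats::setNames(weights$weight, weights$id)
  } else weights
  w <- w[!is.na(w)]
  use <- intersect(names(w), colnames(genotypes))
  if (!length(use)) stop("no weight variants present in genotypes")
  s <- as.numeric(genotypes[, use, drop = FALSE] %*% w[use])
  names(s) <- rownames(genotypes)
  if (standardize) {
    if (stats::sd(s, na.rm = TRUE) == 0) stop("zero-variance polygenic score")
    s <- as.numeric(scale(s)); names(s) <- rownames(genotypes)
  }
  s
}

#' Spousal polygenic-score concordance
#'
#' Regresses the partner's standardized polygenic score on the index
#' member's, one row per couple. With standardized scores the slope equals
#' the cross-spouse score correlation, whose expectation under phenotypic
#' assortment is `C * h2` (see [expected_correlations()]).
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param genotypes individuals x variants dosage matrix.
#' @param weights variant weights (see [pgs_score()]).
#' @param ref,seed reference-member convention.
#' @return An [assoc_result()].
#' @export
pgs_concordance <- function(pairs, genotypes, weights, ref = "first",
                            seed = NULL) {
  s <- pgs_score(genotypes, weights, standardize = TRUE)
  cf <- couple_frame(pairs, ref, seed)
  pd <- data.frame(y = s[cf$partner], x = s[cf$index])
  pd <- pd[stats::complete.cases(pd), , drop = FALSE]
  fit <- stats::lm(y ~ x, data = pd)
  fit_to_assoc(fit, "x")
}

#' Relationship-length proxy association
#'
#' Regresses the absolute within-couple difference of a phenotype (or
#' allele count) on the couple's mean age — the proxy for relationship
#' length — adjusted for the sex of the reference individual. A negative
#' slope means older couples are more similar.
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param data individual table with `id`, `sex`, `age`.
#' @param values named numeric vector (phenotype or allele count per id).
#' @param ref,seed reference-member convention.
#' @return An [assoc_result()] for the mean-age slope (change in absolute
#'   difference per year).
#' @export
relationship_length_proxy <- function(pairs, data, values, ref = "first",
                                      seed = NULL) {
  cf <- couple_frame(pairs, ref, seed)
  di <- data[match(cf$index, data$id), ]
  dp <- data[match(cf$partner, data$id), ]
  pd <- data.frame(
    diff = abs(values[cf$index] - values[cf$partner]),
    mean_age = (di$age + dp$age) / 2,
    sex = factor(di$sex)
  )
  pd <- pd[stats::complete.cases(pd), , drop = FALSE]
  if (stats::var(pd$diff) == 0) {
    return(structure(list(beta = 0, se = NA_real_, ci95 = c(0, 0), p = NA_real_,
                          n = nrow(pd), covariates = "sex", term = "mean_age"),
                     class = "assoc_result"))
  }
  pd <- drop_constant_covariates(pd, keep = c("diff", "mean_age"))
  form <- if ("sex" %in% names(pd)) diff ~ mean_age + sex else diff ~ mean_age
  fit <- stats::lm(form, data = pd)
  fit_to_assoc(fit, "mean_age",
               covariates = intersect("sex", names(pd)))
}
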