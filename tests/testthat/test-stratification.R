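test_that("the HWE chi-square matches hand arithmetic and is relabeling invariant", {
  # exact HWE proportions
  exact <- hwe_test(c(2500, 5000, 2500))
  expect_equal(exact$chi2, 0, tolerance = 1e-10)
  # hand case: p = 0.5, expected (25, 50, 25) -> chi2 = 9 + 18 + 9 = 36
  hand <- hwe_test(c(10, 80, 10))
  expect_equal(hand$chi2, 36, tolerance = 1e-10)
  expect_false(hand$het_deficit)
  # allele relabeling (swap homozygote classes) leaves the statistic alone
  asym <- hwe_test(c(700, 250, 50))
  swap <- hwe_test(c(50, 250, 700))
  expect_equal(asym$chi2, swap$chi2, tolerance = 1e-10)
  expect_equal(asym$maf, swap$maf)
  mono <- hwe_test(c(1000, 0, 0))
  expect_true(mono$monomorphic)
  expect_equal(mono$chi2, 0)
  # genotype-vector input agrees with count input
  g <- rep(c(0L, 1L, 2L), c(120, 60, 20))
  expect_equal(hwe_test(g)$chi2, hwe_test(c(120, 60, 20))$chi2)
})

test_that("allele-frequency comparison reproduces the textbook 2x2 chi-square", {
  c1 <- c(8000, 1800, 200); c2 <- c(8600, 1300, 100)
  afd <- allele_freq_diff(c1, c2)
  a1 <- c(2 * c1[1] + c1[2], 2 * c1[3] + c1[2])
  a2 <- c(2 * c2[1] + c2[2], 2 * c2[3] + c2[2])
  tab <- rbind(a1, a2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_hand <- sum((tab - expected)^2 / expected)
  expect_equal(afd$chi2, chi2_hand, tolerance = 1e-10)
  same <- allele_freq_diff(c1, c1 * 3)
  expect_lt(same$chi2, 1e-10)
  expect_error(allele_freq_diff(c(10, 0, 0), c(20, 0, 0)), "zero margin")
})

test_that("SNP-geography regressions recover a simulated cline and stay null without one", {
  coh <- simulate_cohort(sim_config(
    n_individuals = 30000, n_pgs_snps = 5, mechanism = "none",
    cline_gradients = c(north = 0.004, east = 0), seed = 61
  ))
  g <- focal_genotype(coh)
  res <- snp_geo_assoc(g, coh$individuals[c("birth_north", "birth_east")])
  expect_gt(res$north$beta, 0)       # effect allele more frequent northwards
  expect_lt(res$north$p, 1e-10)
  expect_lt(abs(res$east$beta / res$east$se), 3)
  # brute-force slope check
  expect_equal(res$north$beta,
               cov(coh$individuals$birth_north, g) / var(g),
               tolerance = 1e-8)
  # no cline: null; constant coordinate: exactly zero
  coh0 <- simulate_cohort(sim_config(
    n_individuals = 20000, n_pgs_snps = 5, mechanism = "none",
    cline_gradients = c(north = 0, east = 0), seed = 62
  ))
  g0 <- focal_genotype(coh0)
  res0 <- snp_geo_assoc(g0, coh0$individuals[c("birth_north", "birth_east")])
  expect_lt(abs(res0$north$beta / res0$north$se), 3.5)
  const <- snp_geo_assoc(g0, data.frame(
    birth_north = rep(1, length(g0)), birth_east = rep(2, length(g0))
  ))
  expect_equal(const$north$beta, 0)
})

test_that("fixed-effects combination matches hand arithmetic and an independent meta-analysis package", {
  beta <- c(0.05, -0.01, 0.08); se <- c(0.02, 0.05, 0.04)
  m <- meta_fixed(beta, se)
  w <- 1 / se^2
  expect_equal(m$combined_beta, sum(w * beta) / sum(w), tolerance = 1e-12)
  expect_equal(m$combined_se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_lte(m$combined_se, min(se))
  skip_if_not_installed("metafor")
  ref <- metafor::rma(yi = beta, sei = se, method = "FE")
  expect_equal(m$combined_beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(m$combined_se, ref$se, tolerance = 1e-10)
  expect_equal(m$Q, ref$QE, tolerance = 1e-10)
  expect_equal(m$Q_p, ref$QEp, tolerance = 1e-10)
  single <- meta_fixed(0.02, 0.01)
  expect_equal(single$combined_beta, 0.02)
  expect_equal(single$Q, 0)
})

test_that("one-stratum meta reproduces the unstratified estimate; small strata are excluded with reasons", {
  coh <- simulate_cohort(sim_config(
    n_individuals = 8000, n_pgs_snps = 5, assort_C = 0.4, maf_focal = 0.3,
    beta_focal = 6, censor = FALSE, couple_fraction = 1, n_centres = 4,
    cline_gradients = c(north = 0, east = 0), seed = 63
  ))
  pr <- truth_pairs(coh)
  centres <- stats::setNames(coh$individuals$centre, coh$individuals$id)
  whole <- genotypic_concordance(pr, coh$genotypes, "focal_1")
  one <- within_centre_meta(pr, coh$genotypes, "focal_1",
                            stats::setNames(rep("all", nrow(coh$individuals)),
                                            coh$individuals$id))
  expect_equal(one$combined_beta, whole$beta, tolerance = 1e-12)
  expect_equal(one$combined_se, whole$se, tolerance = 1e-12)
  by_centre <- within_centre_meta(pr, coh$genotypes, "focal_1", centres,
                                  min_pairs = 600)
  expect_true(all(grepl("pairs", by_centre$excluded$reason)))
  expect_equal(by_centre$k_used + nrow(by_centre$excluded),
               length(unique(centres[pr$id_a])))
})

test_that("the heterogeneity p-value is uniform when strata share one true effect", {
  set.seed(64)
  ps <- replicate(400, {
    se <- runif(8, 0.01, 0.05)
    meta_fixed(rnorm(8, 0.02, se), se)$Q_p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("birth-distance stratification uses the stated boundary and attenuates a geographic signal", {
  # boundary: a 3-4-5 triangle at 100 km lands in the 'within' stratum
  d <- data.frame(
    id = c("a", "b", "c", "d"), sex = c("male", "female", "male", "female"),
    age = 50,
    birth_north = c(0, 60, 10, 10), birth_east = c(0, 80, 20, 20),
    stringsAsFactors = FALSE
  )
  g <- stats::setNames(c(0L, 1L, 2L, 1L), d$id)
  pr <- data.frame(id_a = c("a", "c"), id_b = c("b", "d"),
                   stringsAsFactors = FALSE)
  G <- cbind(v = g)
  rownames(G) <- d$id
  # distances: exactly 100 (within) and 0 (within)
  bn <- stats::setNames(d$birth_north, d$id)
  be <- stats::setNames(d$birth_east, d$id)
  dist <- sqrt((bn[pr$id_a] - bn[pr$id_b])^2 + (be[pr$id_a] - be[pr$id_b])^2)
  expect_equal(unname(dist), c(100, 0))
  # geographic homogamy with a cline: conditioning on birth proximity
  # attenuates the genotypic concordance
  # pairing on pure geographic proximity: the phenotypic target is far
  # above what the cline alone can induce, so calibration flags it and
  # falls back to maximal geographic pairing — exactly the scenario wanted
  coh <- suppressWarnings(simulate_cohort(sim_config(
    n_individuals = 30000, n_pgs_snps = 5, mechanism = "homogamy",
    homogamy_on = "geography", assort_C = 0.05,
    cline_gradients = c(north = 0.004, east = 0), censor = FALSE,
    couple_fraction = 1, seed = 65
  )))
  pr2 <- truth_pairs(coh)
  st <- distance_stratify(pr2, coh$individuals, coh$genotypes, "focal_1",
                          threshold_km = 100)
  full <- genotypic_concordance(pr2, coh$genotypes, "focal_1")
  expect_gt(full$beta, 0.02)
  expect_lt(abs(st$genotypic$within$beta), full$beta)
  expect_equal(nrow(st$within) + nrow(st$beyond) + st$n_missing, nrow(pr2))
  # stratum membership respects the boundary convention (<= goes within)
  bn2 <- stats::setNames(coh$individuals$birth_north, coh$individuals$id)
  be2 <- stats::setNames(coh$individuals$birth_east, coh$individuals$id)
  dist_of <- function(p) sqrt((bn2[p$id_a] - bn2[p$id_b])^2 +
                                (be2[p$id_a] - be2[p$id_b])^2)
  expect_lte(max(dist_of(st$within)), 100)
  expect_gt(min(dist_of(st$beyond)), 100)
})

test_that("meta-only mode recovers a published-style stratum table through the CI convention", {
  tab <- data.frame(label = c("x", "y"), n_pairs = c(100, 200),
                    beta = c(0.05, 0.01),
                    ci_lo = c(0.05 - 1.96 * 0.02, 0.01 - 1.96 * 0.01),
                    ci_hi = c(0.05 + 1.96 * 0.02, 0.01 + 1.96 * 0.01))
  m <- meta_from_table(tab)
  w <- c(1 / 0.02^2, 1 / 0.01^2)
  expect_equal(m$combined_beta, sum(w * c(0.05, 0.01)) / sum(w),
               tolerance = 1e-6)
  expect_equal(se_from_ci(0, 3.92), 1)
})
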