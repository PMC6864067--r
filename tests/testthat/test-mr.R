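test_that("per-variant associations recover simulated effects under both codings", {
  coh <- simulate_cohort(sim_config(
    n_individuals = 10000, n_pgs_snps = 5, mechanism = "none",
    maf_focal = 0.25, beta_focal = 4, censor = FALSE,
    cline_gradients = c(north = 0, east = 0), seed = 51
  ))
  lat <- coh$individuals$latent_pheno
  a <- snp_association(coh$genotypes[, "focal_1", drop = FALSE], lat)
  expect_lt(abs(a$beta - 4), 3 * a$se)
  # independent outcome: null
  a0 <- snp_association(coh$genotypes[, "focal_1", drop = FALSE],
                        sample(lat))
  expect_lt(abs(a0$beta / a0$se), 3)
  # dominant recode contract: 0/1/2 -> 0/1/1
  g <- coh$genotypes[, "focal_1"]
  y_dom <- 2.5 * (g > 0) + rnorm(length(g))
  ad <- snp_association(coh$genotypes[, "focal_1", drop = FALSE], y_dom,
                        model = "dominant")
  expect_lt(abs(ad$beta - 2.5), 3 * ad$se)
  expect_error(
    snp_association(coh$genotypes[, 1:2], lat,
                    covariates = data.frame(c1 = g, c2 = 2 * g)),
    "collinear"
  )
})

test_that("the additive/dominant model check recommends the generating model", {
  set.seed(52)
  g <- rbinom(20000, 2, 0.3)
  add <- compare_additive_dominant(g, 2 * g + rnorm(length(g), 0, 3))
  expect_equal(add$recommendation, "additive")
  dom <- compare_additive_dominant(g, 4 * (g > 0) + rnorm(length(g), 0, 3))
  expect_equal(dom$recommendation, "dominant")
  null <- compare_additive_dominant(g, rnorm(length(g)))
  expect_equal(null$recommendation, "none")
})

test_that("the Wald ratio is exact division with a rescaled outcome-stage interval", {
  set.seed(53)
  for (i in 1:25) {
    inp <- random_mr_input(1)
    if (inp$beta_exposure == 0) next
    w <- wald_ratio(inp)
    expect_equal(w$beta, inp$beta_outcome / inp$beta_exposure,
                 tolerance = 1e-12)
    expect_equal(w$se, inp$se_outcome / abs(inp$beta_exposure),
                 tolerance = 1e-12)
    w2 <- wald_ratio(inp, se_method = "second")
    expect_gte(w2$se, w$se)
  }
  expect_equal(wald_ratio(mr_input("v", 2, 0.1, 0, 0.1))$beta, 0)
  expect_error(wald_ratio(mr_input("v", 0, 0.1, 1, 0.1)), "weak instrument")
})

test_that("IVW matches hand arithmetic, degenerates to Wald at k = 1, and is orientation invariant", {
  # ratios 0.2 (se 0.1) and 0.4 (se 0.2) combine to 0.24
  inp <- mr_input(c("a", "b"), beta_exposure = c(1, 1),
                  se_exposure = c(0.01, 0.01),
                  beta_outcome = c(0.2, 0.4), se_outcome = c(0.1, 0.2))
  est <- ivw_fixed(inp)
  expect_equal(est$beta, 0.24, tolerance = 1e-12)
  expect_equal(est$se, 1 / sqrt(1 / 0.01 + 1 / 0.04), tolerance = 1e-12)
  one <- random_mr_input(1)
  expect_equal(ivw_fixed(one)$beta, wald_ratio(one)$beta, tolerance = 1e-12)
  expect_equal(ivw_fixed(one)$se, wald_ratio(one)$se, tolerance = 1e-12)
  # equal ratios: no heterogeneity
  same <- mr_input(c("a", "b", "c"), c(1, 2, 4), rep(0.1, 3),
                   c(0.3, 0.6, 1.2), c(0.1, 0.1, 0.1))
  expect_equal(ivw_fixed(same)$Q, 0, tolerance = 1e-20)
  expect_equal(ivw_fixed(same)$I2, 0)
  # flipping one variant's effect allele negates both stage betas
  set.seed(54)
  inp2 <- random_mr_input(6)
  flip <- inp2
  flip$beta_exposure[3] <- -flip$beta_exposure[3]
  flip$beta_outcome[3] <- -flip$beta_outcome[3]
  expect_equal(ivw_fixed(flip)$beta, ivw_fixed(inp2)$beta, tolerance = 1e-12)
  expect_equal(ivw_fixed(flip)$Q, ivw_fixed(inp2)$Q, tolerance = 1e-12)
})

test_that("MR-Egger separates a constant pleiotropic offset from the causal slope", {
  set.seed(55)
  k <- 30
  bx <- runif(k, 0.5, 2)
  se_out <- runif(k, 0.05, 0.2)
  by <- 0.3 * bx + rnorm(k, 0, se_out)
  inp <- mr_input(paste0("v", 1:k), bx, rep(0.02, k), by, se_out)
  e0 <- mr_egger(inp)
  expect_lt(abs(e0$egger_intercept), 3 * e0$egger_intercept_se)
  expect_lt(abs(e0$beta - ivw_fixed(inp)$beta), 0.1)
  # add a constant offset b to every outcome beta: intercept shifts by b,
  # slope unchanged (exact regression algebra)
  off <- inp
  off$beta_outcome <- off$beta_outcome + 0.7
  e1 <- mr_egger(off)
  expect_equal(e1$beta, e0$beta, tolerance = 1e-10)
  expect_equal(e1$egger_intercept, e0$egger_intercept + 0.7,
               tolerance = 1e-10)
  expect_error(mr_egger(random_mr_input(2)), "at least 3")
})

test_that("weighted median and mode behave on textbook configurations", {
  eq <- mr_input(c("a", "b", "c"), rep(1, 3), rep(0.01, 3),
                 c(0.1, 0.2, 0.9), rep(0.3, 3))
  expect_equal(weighted_median(eq, n_boot = 200, seed = 1)$beta, 0.2,
               tolerance = 1e-12)
  # majority-valid scenario: median tracks the valid 60%, IVW is dragged
  set.seed(56)
  k <- 20
  valid <- rep(c(TRUE, FALSE), c(12, 8))
  bx <- runif(k, 0.8, 1.6)
  ratio_true <- ifelse(valid, 0.3, 1.2)
  se_out <- rep(0.02, k)
  inp <- mr_input(paste0("v", 1:k), bx, rep(0.01, k),
                  ratio_true * bx + rnorm(k, 0, se_out), se_out)
  med <- weighted_median(inp, n_boot = 500, seed = 2)
  expect_lt(abs(med$beta - 0.3), 0.1)
  expect_gt(ivw_fixed(inp)$beta, med$beta + 0.1)
  # tight cluster plus one outlier: mode sits on the cluster
  cl <- mr_input(paste0("v", 1:6), rep(1, 6), rep(0.01, 6),
                 c(0.29, 0.3, 0.31, 0.3, 0.305, 2.5), rep(0.05, 6))
  mode_est <- weighted_mode(cl, n_boot = 200, seed = 3)
  expect_lt(abs(mode_est$beta - 0.3), mode_est$bandwidth + 0.05)
  expect_error(weighted_mode(random_mr_input(2)), "at least 3")
  # bootstrap ses are reproducible under the seed
  m1 <- weighted_median(inp, n_boot = 300, seed = 9)
  m2 <- weighted_median(inp, n_boot = 300, seed = 9)
  expect_identical(m1$se, m2$se)
})

test_that("z-test for estimate differences follows the normal form", {
  expect_equal(z_difference(0.3, 0.1, 0.3, 0.2)$p, 1)
  zd <- z_difference(0.37, 0.0051, 0.26, 0.0587)
  expect_equal(zd$z, (0.37 - 0.26) / sqrt(0.0051^2 + 0.0587^2),
               tolerance = 1e-12)
  expect_lt(abs(zd$p - 0.062), 0.02)  # printed-input rounding keeps this loose
  expect_gt(z_difference(0.3, 0.1, -4, 1e6)$p, 0.999)
})

test_that("the two-stage layout uses each individual once for exposure and twice for outcome", {
  coh <- simulate_cohort(sim_config(
    n_individuals = 12000, n_pgs_snps = 5, assort_C = 0.4,
    maf_focal = 0.25, beta_focal = 4, var_confounder = 0.05,
    censor = FALSE, couple_fraction = 1,
    cline_gradients = c(north = 0, east = 0), seed = 57
  ))
  pr <- truth_pairs(coh)
  ind <- coh$individuals
  ind$pheno <- ind$latent_pheno
  inp <- mr_stages(pr, ind, coh$genotypes, "focal_1", "pheno")
  # exposure stage at 2n individuals, outcome stage at 2n couple-rows:
  # betas should recover beta_focal and C * beta_focal
  expect_lt(abs(inp$beta_exposure - 4), 3 * inp$se_exposure)
  expect_lt(abs(inp$beta_outcome - 0.4 * 4), 3 * inp$se_outcome)
  w <- wald_ratio(inp)
  expect_lt(abs(w$beta - 0.4), 3 * w$se)
})
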