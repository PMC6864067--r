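#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()]. Defaults
#' emulate a UK-Biobank-like cohort assorting on weekly alcohol consumption:
#' a low-frequency large-effect variant (ADH1B-style: effect-allele frequency
#' 2.5%, about 4 units/week per allele), a polygenic component explaining 13%
#' of phenotypic variance, a geographic allele-frequency cline on a planar km
#' grid, and a target spousal phenotypic correlation of 0.37.
#'
#' @param n_individuals number of individuals to simulate.
#' @param maf_focal focal effect-allele frequency at the grid centre, in
#'   (0, 0.5].
#' @param beta_focal additive effect of each focal effect allele on the
#'   phenotype (units/week). Negative by default: the rare allele lowers
#'   consumption, as for ADH1B rs1229984.
#' @param n_pgs_snps number of independent polygenic-score variants.
#' @param h2_pgs fraction of phenotypic variance explained by the polygenic
#'   score, in \[0, 1\].
#' @param var_confounder fraction of phenotypic variance from the shared
#'   social confounder, in \[0, 1\]; `h2_pgs + var_confounder` must not
#'   exceed 1.
#' @param pheno_mean,pheno_sd mean and standard deviation of the latent
#'   phenotype (units/week).
#' @param assort_C target spousal correlation of the formation-time
#'   phenotype (assortative mating) or of the realized phenotype (social
#'   homogamy), in \[-1, 1\].
#' @param mechanism character vector drawn from `"assortative"`,
#'   `"homogamy"`, `"interaction"`, `"dissolution"`, `"none"`. Mechanisms
#'   compose sequentially: one formation mechanism (assortative, homogamy or
#'   random) is followed, if requested, by partner interaction during the
#'   relationship and by dissolution at sampling.
#' @param homogamy_on what social homogamy pairs on: the latent confounder
#'   (`"confounder"`) or geographic birth proximity along the cline axis
#'   (`"geography"`).
#' @param interaction_kappa convergence fraction per year of relationship;
#'   a couple of duration d has converged by weight `min(1, kappa * d)`.
#' @param dissolution_lambda increase in log-odds of dissolution per unit of
#'   absolute within-couple phenotype difference.
#' @param dissolution_base baseline log-odds of dissolution.
#' @param cline_gradients named numeric, per-km change in the logit focal
#'   allele frequency along northing and easting.
#' @param n_centres number of recruitment centres placed on the grid.
#' @param couple_fraction fraction of individuals assigned to couples.
#' @param censor left-censor observed phenotypes at 0 and derive them from
#'   integer beverage counts (the realistic questionnaire scale). Set to
#'   `FALSE` to expose the continuous realized phenotype, e.g. for
#'   theory-recovery checks unaffected by censoring attenuation.
#' @param n_ld_block number of additional mutually correlated variants in a
#'   tight physical window (a fixture for LD-pruning checks; they carry zero
#'   polygenic weight).
#' @param ld_block_r2 target pairwise r-squared within the block.
#' @param seed master seed; it fully determines the cohort.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 4000,
                       maf_focal = 0.025,
                       beta_focal = -4,
                       n_pgs_snps = 1000,
                       h2_pgs = 0.13,
                       var_confounder = 0.10,
                       pheno_mean = 10,
                       pheno_sd = 9,
                       assort_C = 0.37,
                       mechanism = "assortative",
                       homogamy_on = c("confounder", "geography"),
                       interaction_kappa = 0.05,
                       dissolution_lambda = 0.3,
                       dissolution_base = -2,
                       cline_gradients = c(north = -0.0015, east = 0.001),
                       n_centres = 8,
                       couple_fraction = 0.9,
                       censor = TRUE,
                       n_ld_block = 0,
                       ld_block_r2 = 0.5,
                       seed = 1) {
  homogamy_on <- match.arg(homogamy_on)
  mechanism <- match.arg(
    mechanism,
    c("assortative", "homogamy", "interaction", "dissolution", "none"),
    several.ok = TRUE
  )
  if ("none" %in% mechanism && length(mechanism) > 1) {
    stop("mechanism 'none' cannot be combined with other mechanisms")
  }
  if (all(c("assortative", "homogamy") %in% mechanism)) {
    stop("at most one formation mechanism (assortative or homogamy)")
  }
  if (maf_focal <= 0 || maf_focal > 0.5) stop("maf_focal must lie in (0, 0.5]")
  if (abs(assort_C) > 1) stop("assort_C must lie in [-1, 1]")
  if (h2_pgs < 0 || var_confounder < 0 || h2_pgs + var_confounder > 1) {
    stop("impossible variance budget: need h2_pgs + var_confounder <= 1")
  }
  var_focal <- beta_focal^2 * 2 * maf_focal * (1 - maf_focal)
  if (var_focal > pheno_sd^2 * (1 - h2_pgs - var_confounder)) {
    stop("impossible variance budget: focal variant explains more variance ",
         "than the residual budget allows")
  }
  stopifnot(n_individuals >= 4, n_pgs_snps >= 0, n_centres >= 1,
            couple_fraction > 0, couple_fraction <= 1,
            interaction_kappa >= 0, length(cline_gradients) == 2)
  structure(
    list(
      n_individuals = as.integer(n_individuals), maf_focal = maf_focal,
      beta_focal = beta_focal, n_pgs_snps = as.integer(n_pgs_snps),
      h2_pgs = h2_pgs, var_confounder = var_confounder,
      pheno_mean = pheno_mean, pheno_sd = pheno_sd,
      assort_C = assort_C, mechanism = mechanism, homogamy_on = homogamy_on,
      interaction_kappa = interaction_kappa,
      dissolution_lambda = dissolution_lambda,
      dissolution_base = dissolution_base,
      cline_gradients = c(north = unname(cline_gradients[1]),
                          east = unname(cline_gradients[2])),
      n_centres = as.integer(n_centres), couple_fraction = couple_fraction,
      censor = isTRUE(censor), n_ld_block = as.integer(n_ld_block),
      ld_block_r2 = ld_block_r2, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Focal effect-allele frequency at a birth location: logistic cline on the
# planar km grid, anchored at the grid centre (500, 500).
focal_freq_at <- function(north, east, config) {
  lg <- stats::qlogis(config$maf_focal) +
    config$cline_gradients["north"] * (north - 500) +
    config$cline_gradients["east"] * (east - 500)
  pmin(pmax(stats::plogis(lg), 1e-4), 0.5)
}

# Variant metadata for one simulated marker panel.
build_variant_meta <- function(config, pgs_freq, pgs_weight) {
  meta <- data.frame(
    id = "focal_1", chrom = "1", pos = 1000000L,
    ref = "C", alt = "T", effect_allele = "T",
    freq = config$maf_focal, weight = NA_real_, type = "focal",
    stringsAsFactors = FALSE
  )
  if (config$n_pgs_snps > 0) {
    meta <- rbind(meta, data.frame(
      id = paste0("pgs_", seq_len(config$n_pgs_snps)), chrom = "1",
      pos = 1000000L + 100000L * seq_len(config$n_pgs_snps),
      ref = "A", alt = "G", effect_allele = "G",
      freq = pgs_freq, weight = pgs_weight, type = "pgs",
      stringsAsFactors = FALSE
    ))
  }
  if (config$n_ld_block > 0) {
    meta <- rbind(meta, data.frame(
      id = paste0("block_", seq_len(config$n_ld_block)), chrom = "2",
      pos = 1000000L + 2000L * (seq_len(config$n_ld_block) - 1L),
      ref = "A", alt = "G", effect_allele = "G",
      freq = 0.5, weight = 0, type = "block",
      stringsAsFactors = FALSE
    ))
  }
  meta
}

# Draw genotypes for n individuals at the panel in `meta`, with the focal
# variant following the cline (HWE within each birth neighbourhood) and the
# LD block built from correlated haplotype copies of its first member.
draw_genotypes <- function(n, north, east, meta, config) {
  G <- matrix(0L, nrow = n, ncol = nrow(meta),
              dimnames = list(NULL, meta$id))
  p_loc <- focal_freq_at(north, east, config)
  G[, 1] <- stats::rbinom(n, 2, p_loc)
  pgs_idx <- which(meta$type == "pgs")
  for (j in pgs_idx) G[, j] <- stats::rbinom(n, 2, meta$freq[j])
  blk <- which(meta$type == "block")
  if (length(blk)) {
    q <- 0.5
    cc <- sqrt(config$ld_block_r2)  # allele-level copy probability => r2
    a1 <- stats::rbinom(n, 1, q); a2 <- stats::rbinom(n, 1, q)
    for (j in blk) {
      keep1 <- stats::rbinom(n, 1, cc)
      keep2 <- stats::rbinom(n, 1, cc)
      b1 <- ifelse(keep1 == 1, a1, stats::rbinom(n, 1, q))
      b2 <- ifelse(keep2 == 1, a2, stats::rbinom(n, 1, q))
      G[, j] <- b1 + b2
    }
  }
  G
}

# Latent (formation-time) phenotype from its variance components.
latent_phenotype <- function(G, meta, config, n) {
  g_focal <- G[, 1]
  pgs_idx <- which(meta$type == "pgs")
  score <- if (length(pgs_idx)) {
    as.numeric(G[, pgs_idx, drop = FALSE] %*% meta$weight[pgs_idx])
  } else rep(0, n)
  score_c <- if (length(pgs_idx)) {
    score - sum(2 * meta$freq[pgs_idx] * meta$weight[pgs_idx])
  } else score
  u <- stats::rnorm(n, 0, sqrt(config$var_confounder) * config$pheno_sd)
  var_foc <- config$beta_focal^2 * 2 * config$maf_focal * (1 - config$maf_focal)
  resid_var <- config$pheno_sd^2 * (1 - config$h2_pgs - config$var_confounder) -
    var_foc
  e <- stats::rnorm(n, 0, sqrt(max(resid_var, 1e-8)))
  latent <- config$pheno_mean +
    config$beta_focal * (g_focal - 2 * config$maf_focal) + score_c + u + e
  list(latent = latent, confounder = u, pgs = score_c)
}

# Rank pairing with calibrated score noise. Males and females are sorted by
# (standardized score + sqrt(v) * noise) and paired by rank; v is found by
# bisection with common random numbers so the achieved correlation of the
# objective values hits the target. Returns male/female index pairs and the
# achieved correlation.
rank_pair_calibrated <- function(score_m, score_f, obj_m, obj_f, target,
                                 log = character()) {
  n <- length(score_m)
  dir <- if (target < 0) -1 else 1
  z_m <- stats::rnorm(n); z_f <- stats::rnorm(n)
  s_m <- as.numeric(scale(score_m)); s_f <- as.numeric(scale(score_f))
  achieved <- function(v) {
    om <- order(s_m + sqrt(v) * z_m)
    of <- order(dir * (s_f + sqrt(v) * z_f))
    stats::cor(obj_m[om], obj_f[of])
  }
  tol <- max(1e-4, 0.1 / sqrt(n))
  c0 <- achieved(0)
  if (dir * c0 < abs(target) - max(0.02, 3 / sqrt(n))) {
    warning(sprintf(
      "target spousal correlation %.3f unreachable; best achievable %.3f",
      target, c0), call. = FALSE)
    log <- c(log, sprintf("assort_C %.3f unreachable (max %.3f); used v = 0",
                          target, c0))
    om <- order(s_m); of <- order(dir * s_f)
    return(list(pairs = cbind(male = om, female = of), achieved = c0,
                v = 0, log = log))
  }
  lo <- 0; hi <- 1
  while (dir * achieved(hi) > abs(target) && hi < 2^16) hi <- hi * 4
  v <- hi
  for (i in 1:60) {
    v <- (lo + hi) / 2
    a <- achieved(v)
    if (abs(dir * a - abs(target)) < tol) break
    if (dir * a > abs(target)) lo <- v else hi <- v
  }
  om <- order(s_m + sqrt(v) * z_m)
  of <- order(dir * (s_f + sqrt(v) * z_f))
  list(pairs = cbind(male = om, female = of),
       achieved = stats::cor(obj_m[om], obj_f[of]), v = v, log = log)
}

# Decompose weekly units into questionnaire-style beverage counts
# (1 unit/measure of spirits, 2/glass of wine, 2.5/pint of beer or cider).
beverages_from_units <- function(units) {
  u <- pmax(0, units)
  beer <- pmax(0L, as.integer(round(0.4 * u / 2.5)))
  red <- pmax(0L, as.integer(round(0.2 * u / 2)))
  white <- pmax(0L, as.integer(round(0.1 * u / 2)))
  spirits <- pmax(0L, as.integer(round(u - 2.5 * beer - 2 * (red + white))))
  data.frame(
    bev_red_wine = red, bev_white_wine = white,
    bev_champagne = 0L, bev_fortified_wine = 0L,
    bev_beer = beer, bev_cider = 0L, bev_spirits = spirits
  )
}

freq_levels <- c("daily", "3-4/week", "1-2/week", "1-3/month",
                 "special occasions", "never")

# Questionnaire fields consistent with the observed weekly units.
questionnaire_fields <- function(units) {
  n <- length(units)
  freq <- character(n)
  pos <- units > 0
  qs <- stats::quantile(units[pos], c(1 / 3, 2 / 3), na.rm = TRUE)
  freq[pos] <- ifelse(units[pos] <= qs[1], "1-2/week",
                      ifelse(units[pos] <= qs[2], "3-4/week", "daily"))
  freq[!pos] <- sample(c("1-3/month", "special occasions", "never"),
                       sum(!pos), replace = TRUE, prob = c(0.4, 0.35, 0.25))
  status <- rep("current", n)
  status[freq == "never"] <- "never"
  prev <- !pos & freq != "never" & stats::runif(n) < 0.25
  status[prev] <- "previous"
  list(frequency_category = factor(freq, levels = freq_levels),
       drinker_status = status)
}

#' Simulate a cohort of individuals and couples
#'
#' Generates a cohort with the statistical structure assumed by the
#' downstream analyses: genotypes in Hardy-Weinberg equilibrium within each
#' birth neighbourhood with the focal allele frequency following a logistic
#' geographic cline, a latent phenotype built from the focal variant, a
#' polygenic score, a social confounder and residual noise, and couples
#' formed under the configured mechanisms:
#'
#' * `assortative` — noisy-rank pairing on the latent phenotype, calibrated
#'   by bisection so that the spousal correlation of formation-time
#'   phenotypes matches `assort_C`;
#' * `homogamy` — pairing on the social confounder (or on geographic birth
#'   proximity), never on the phenotype itself;
#' * `interaction` — random formation followed by within-couple convergence
#'   of the phenotype at rate `interaction_kappa` per year of relationship;
#' * `dissolution` — random formation followed by couple removal with
#'   probability `plogis(base + lambda * |phenotype difference|)`;
#' * `none` — random pairing.
#'
#' Household fields (the eight matching variables used for spouse-pair
#' derivation) are identical within surviving couples; dissolved couples and
#' singles receive their own households.
#'
#' Random streams are derived from the master seed in a fixed order
#' (geography; marker panel; genotypes; phenotype components; pairing;
#' durations and dissolution; demographics; questionnaire), so a
#' configuration reproduces bit-identical cohorts.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `cohort`: a list with `individuals` (one row
#'   per individual), `genotypes` (individuals x variants dosage matrix),
#'   `truth` (formed couples with mechanism labels, durations, dissolution
#'   flags), `variant_meta`, `config` and `log`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 400, seed = 1))
#' head(coh$truth)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  mech <- config$mechanism

  # -- geography and demographics scaffold (stream 1)
  set.seed(child_seed(config$seed, 1))
  birth_north <- stats::runif(n, 0, 1000)
  birth_east <- stats::runif(n, 0, 1000)
  centre_north <- stats::runif(config$n_centres, 100, 900)
  centre_east <- stats::runif(config$n_centres, 100, 900)
  sex <- rep(c("male", "female"), length.out = n)

  # -- marker panel (stream 2)
  set.seed(child_seed(config$seed, 2))
  pgs_freq <- if (config$n_pgs_snps) stats::runif(config$n_pgs_snps, 0.1, 0.9)
  pgs_w_raw <- if (config$n_pgs_snps) stats::rnorm(config$n_pgs_snps)
  if (config$n_pgs_snps) {
    var_raw <- sum(pgs_w_raw^2 * 2 * pgs_freq * (1 - pgs_freq))
    pgs_w <- pgs_w_raw * sqrt(config$h2_pgs * config$pheno_sd^2 / var_raw)
  } else {
    pgs_freq <- numeric(0); pgs_w <- numeric(0)
  }
  meta <- build_variant_meta(config, pgs_freq, pgs_w)

  # -- genotypes (stream 3)
  set.seed(child_seed(config$seed, 3))
  G <- draw_genotypes(n, birth_north, birth_east, meta, config)

  # -- phenotype components (stream 4)
  set.seed(child_seed(config$seed, 4))
  ph <- latent_phenotype(G, meta, config, n)
  latent <- ph$latent

  # -- couple formation (stream 5)
  set.seed(child_seed(config$seed, 5))
  males <- which(sex == "male"); females <- which(sex == "female")
  n_c <- floor(min(length(males), length(females)) * config$couple_fraction)
  males <- males[seq_len(n_c)]; females <- females[seq_len(n_c)]
  log <- character()
  if ("assortative" %in% mech) {
    rp <- rank_pair_calibrated(latent[males], latent[females],
                               latent[males], latent[females],
                               config$assort_C, log)
    pairs_idx <- rp$pairs; log <- rp$log
    log <- c(log, sprintf("assortative pairing: achieved corr %.4f (v = %.4g)",
                          rp$achieved, rp$v))
  } else if ("homogamy" %in% mech) {
    sc_m <- if (config$homogamy_on == "confounder") {
      ph$confounder[males]
    } else {
      config$cline_gradients["north"] * birth_north[males] +
        config$cline_gradients["east"] * birth_east[males]
    }
    sc_f <- if (config$homogamy_on == "confounder") {
      ph$confounder[females]
    } else {
      config$cline_gradients["north"] * birth_north[females] +
        config$cline_gradients["east"] * birth_east[females]
    }
    rp <- rank_pair_calibrated(sc_m, sc_f, latent[males], latent[females],
                               config$assort_C, log)
    pairs_idx <- rp$pairs; log <- rp$log
    log <- c(log, sprintf("homogamy pairing on %s: achieved corr %.4f",
                          config$homogamy_on, rp$achieved))
  } else {
    pairs_idx <- cbind(male = sample(seq_len(n_c)),
                       female = sample(seq_len(n_c)))
  }
  id_m <- males[pairs_idx[, "male"]]
  id_f <- females[pairs_idx[, "female"]]

  # -- durations, interaction, dissolution (stream 6)
  set.seed(child_seed(config$seed, 6))
  duration <- stats::runif(n_c, 0, 40)
  realized <- latent
  if ("interaction" %in% mech && config$interaction_kappa > 0) {
    w <- pmin(1, config$interaction_kappa * duration)
    cm <- (latent[id_m] + latent[id_f]) / 2
    realized[id_m] <- (1 - w) * latent[id_m] + w * cm
    realized[id_f] <- (1 - w) * latent[id_f] + w * cm
  }
  dissolved <- rep(FALSE, n_c)
  if ("dissolution" %in% mech && config$dissolution_lambda != 0) {
    p_d <- stats::plogis(config$dissolution_base +
                           config$dissolution_lambda *
                           abs(realized[id_m] - realized[id_f]))
    dissolved <- stats::runif(n_c) < p_d
    log <- c(log, sprintf("dissolution removed %d of %d couples",
                          sum(dissolved), n_c))
  }
  coupled <- rep(FALSE, n)
  coupled[c(id_m[!dissolved], id_f[!dissolved])] <- TRUE

  # -- ages, households, demographics (stream 7)
  set.seed(child_seed(config$seed, 7))
  age <- stats::runif(n, 40, 69)
  mean_age <- 32 + duration + stats::rnorm(n_c, 0, 2)
  half_gap <- stats::rnorm(n_c, 0, 1.5)
  age[id_m] <- mean_age + half_gap
  age[id_f] <- mean_age - half_gap

  years_at_address <- sample(1:30, n, replace = TRUE)
  n_occupants <- rep(1L, n)
  n_vehicles <- sample(0:3, n, replace = TRUE)
  accom_type <- sample(c("house", "flat", "bungalow"), n, replace = TRUE,
                       prob = c(0.7, 0.2, 0.1))
  rental_status <- sample(c("own", "rent"), n, replace = TRUE,
                          prob = c(0.75, 0.25))
  home_north <- round(birth_north + stats::rnorm(n, 0, 30))
  home_east <- round(birth_east + stats::rnorm(n, 0, 30))
  keep <- !dissolved
  for (fld in c("years_at_address", "n_vehicles", "accom_type",
                "rental_status", "home_north", "home_east")) {
    v <- get(fld)
    v[id_f[keep]] <- v[id_m[keep]]
    assign(fld, v)
  }
  occ <- sample(2:5, n_c, replace = TRUE, prob = c(0.45, 0.3, 0.17, 0.08))
  n_occupants[id_m[keep]] <- occ[keep]
  n_occupants[id_f[keep]] <- occ[keep]
  spouse_cohab <- coupled
  centre <- paste0("centre_", apply(
    cbind(home_north, home_east), 1,
    function(x) which.min((centre_north - x[1])^2 + (centre_east - x[2])^2)
  ))

  height <- ifelse(sex == "male", 175.6, 162.4) + stats::rnorm(n, 0, 6.9)
  education_years <- sample(c(15, 16, 17, 18, 21), n, replace = TRUE,
                            prob = c(0.15, 0.3, 0.1, 0.2, 0.25))
  country_of_birth <- sample(c("England", "Scotland", "Wales", "Other"), n,
                             replace = TRUE, prob = c(0.8, 0.08, 0.05, 0.07))
  father_death_age <- ifelse(stats::runif(n) < 0.65, NA_real_,
                             round(stats::rnorm(n, 76, 8)))
  mother_death_age <- ifelse(stats::runif(n) < 0.7, NA_real_,
                             round(stats::rnorm(n, 81, 8)))

  # -- questionnaire-scale phenotype (stream 8)
  set.seed(child_seed(config$seed, 8))
  bev <- beverages_from_units(realized)
  units_q <- 1 * bev$bev_spirits +
    2 * (bev$bev_red_wine + bev$bev_white_wine +
           bev$bev_champagne + bev$bev_fortified_wine) +
    2.5 * (bev$bev_beer + bev$bev_cider)
  qf <- questionnaire_fields(units_q)
  observed <- if (config$censor) units_q else realized

  ids <- sprintf("id_%06d", seq_len(n))
  rownames(G) <- ids
  individuals <- data.frame(
    id = ids, sex = sex, age = round(age, 1),
    birth_north = round(birth_north, 1), birth_east = round(birth_east, 1),
    centre = centre,
    spouse_cohab = spouse_cohab, years_at_address = years_at_address,
    n_occupants = n_occupants, n_vehicles = n_vehicles,
    accom_type = accom_type, rental_status = rental_status,
    home_north = home_north, home_east = home_east,
    latent_pheno = ph$latent, observed_pheno = observed,
    bev, frequency_category = as.character(qf$frequency_category),
    drinker_status = qf$drinker_status,
    height = round(height, 1), education_years = education_years,
    country_of_birth = country_of_birth,
    father_death_age = father_death_age,
    mother_death_age = mother_death_age,
    decoy = "", stringsAsFactors = FALSE
  )
  truth <- data.frame(
    couple_id = seq_len(n_c),
    id_a = ids[id_m], id_b = ids[id_f],
    mechanism = paste(mech, collapse = "+"),
    duration = duration, dissolved = dissolved,
    stringsAsFactors = FALSE
  )
  structure(
    list(individuals = individuals, genotypes = G, truth = truth,
         variant_meta = meta, config = config, log = log),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "cohort: %d individuals, %d variants, %d formed couples (%d surviving), mechanism %s\n",
    nrow(x$individuals), ncol(x$genotypes), nrow(x$truth),
    sum(!x$truth$dissolved), x$truth$mechanism[1]
  ))
  if (any(x$individuals$decoy != "")) {
    cat("decoys:", paste(names(table(x$individuals$decoy[x$individuals$decoy != ""])),
                         table(x$individuals$decoy[x$individuals$decoy != ""]),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Focal-variant genotype of every individual
#'
#' @param cohort a [simulate_cohort()] cohort.
#' @return Named integer vector of focal effect-allele counts.
#' @export
focal_genotype <- function(cohort) {
  g <- cohort$genotypes[, cohort$variant_meta$id[cohort$variant_meta$type == "focal"][1]]
  stats::setNames(as.integer(g), rownames(cohort$genotypes))
}

# Generate k fresh individuals with the same schema as simulate_cohort,
# used for decoy injection. Genotypes follow the cohort's panel.
draw_decoy_individuals <- function(k, cohort, sex) {
  config <- cohort$config
  north <- stats::runif(k, 0, 1000); east <- stats::runif(k, 0, 1000)
  G <- draw_genotypes(k, north, east, cohort$variant_meta, config)
  ph <- latent_phenotype(G, cohort$variant_meta, config, k)
  bev <- beverages_from_units(ph$latent)
  units_q <- 1 * bev$bev_spirits +
    2 * (bev$bev_red_wine + bev$bev_white_wine +
           bev$bev_champagne + bev$bev_fortified_wine) +
    2.5 * (bev$bev_beer + bev$bev_cider)
  qf <- questionnaire_fields(units_q)
  observed <- if (config$censor) units_q else ph$latent
  ind <- data.frame(
    id = NA_character_, sex = sex, age = round(stats::runif(k, 40, 69), 1),
    birth_north = round(north, 1), birth_east = round(east, 1),
    centre = sample(unique(cohort$individuals$centre), k, replace = TRUE),
    spouse_cohab = TRUE,
    years_at_address = sample(1:30, k, replace = TRUE),
    n_occupants = 2L,
    n_vehicles = sample(0:3, k, replace = TRUE),
    accom_type = sample(c("house", "flat", "bungalow"), k, replace = TRUE),
    rental_status = sample(c("own", "rent"), k, replace = TRUE),
    home_north = round(north + stats::rnorm(k, 0, 30)),
    home_east = round(east + stats::rnorm(k, 0, 30)),
    latent_pheno = ph$latent, observed_pheno = observed,
    bev, frequency_category = as.character(qf$frequency_category),
    drinker_status = qf$drinker_status,
    height = round(ifelse(sex == "male", 175.6, 162.4) +
                     stats::rnorm(k, 0, 6.9), 1),
    education_years = sample(c(15, 16, 17, 18, 21), k, replace = TRUE),
    country_of_birth = sample(c("England", "Scotland", "Wales", "Other"), k,
                              replace = TRUE, prob = c(0.8, 0.08, 0.05, 0.07)),
    father_death_age = NA_real_, mother_death_age = NA_real_,
    decoy = "", stringsAsFactors = FALSE
  )
  list(individuals = ind, genotypes = G)
}

# Make members of each consecutive group share one household key.
share_household <- function(ind, group) {
  first <- !duplicated(group)
  for (fld in c("years_at_address", "n_vehicles", "accom_type",
                "rental_status", "home_north", "home_east", "centre")) {
    ind[[fld]] <- ind[[fld]][first][match(group, group[first])]
  }
  sizes <- table(group)
  ind$n_occupants <- as.integer(sizes[as.character(group)])
  ind$spouse_cohab <- TRUE
  ind
}

#' Inject non-spouse decoys into a cohort
#'
#' Adds three classes of household-sharing non-spouses that the derivation
#' pipeline must reject: same-sex cohabiting pairs, opposite-sex full-sibling
#' pairs (genotypes drawn by Mendelian transmission from simulated parents,
#' expected relatedness 0.5), and trios sharing one household key. Injected
#' individuals are flagged in the `decoy` column and recorded in
#' `cohort$decoy_pairs`.
#'
#' @param cohort a [simulate_cohort()] cohort.
#' @param n_same_sex number of same-sex pairs to add.
#' @param n_sib_pairs number of sibling pairs to add.
#' @param n_key_trios number of household-key trios to add.
#' @param seed seed for the decoy stream (defaults to a child of the
#'   cohort's master seed).
#' @return The augmented cohort.
#' @export
inject_decoys <- function(cohort, n_same_sex = 0, n_sib_pairs = 0,
                          n_key_trios = 0, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(seed)) seed <- child_seed(cohort$config$seed, 99)
  set.seed(seed)
  add_ind <- list(); add_G <- list(); decoy_pairs <- list()

  if (n_same_sex > 0) {
    sexes <- rep(rep(c("male", "female"), length.out = n_same_sex), each = 2)
    d <- draw_decoy_individuals(2 * n_same_sex, cohort, sexes)
    d$individuals <- share_household(d$individuals,
                                     rep(seq_len(n_same_sex), each = 2))
    d$individuals$decoy <- "same_sex"
    add_ind <- c(add_ind, list(d$individuals)); add_G <- c(add_G, list(d$genotypes))
    decoy_pairs <- c(decoy_pairs, list(data.frame(
      slot_a = seq(1, 2 * n_same_sex, 2), slot_b = seq(2, 2 * n_same_sex, 2),
      class = "same_sex", offset = 0L
    )))
  }

  if (n_sib_pairs > 0) {
    sexes <- rep(c("male", "female"), n_sib_pairs)
    d <- draw_decoy_individuals(2 * n_sib_pairs, cohort, sexes)
    # redraw genotypes by transmission: two children per simulated parental pair
    meta <- cohort$variant_meta
    for (s in seq_len(n_sib_pairs)) {
      i1 <- 2 * s - 1; i2 <- 2 * s
      p_loc <- focal_freq_at(d$individuals$birth_north[i1],
                             d$individuals$birth_east[i1], cohort$config)
      p_vec <- ifelse(meta$type == "focal", p_loc, meta$freq)
      f1 <- stats::rbinom(nrow(meta), 1, p_vec)
      f2 <- stats::rbinom(nrow(meta), 1, p_vec)
      m1 <- stats::rbinom(nrow(meta), 1, p_vec)
      m2 <- stats::rbinom(nrow(meta), 1, p_vec)
      pick <- function() cbind(
        ifelse(stats::rbinom(nrow(meta), 1, 0.5) == 1, f1, f2),
        ifelse(stats::rbinom(nrow(meta), 1, 0.5) == 1, m1, m2)
      )
      d$genotypes[i1, ] <- rowSums(pick())
      d$genotypes[i2, ] <- rowSums(pick())
      # sibs were born in the same place
      d$individuals$birth_north[i2] <- d$individuals$birth_north[i1]
      d$individuals$birth_east[i2] <- d$individuals$birth_east[i1]
    }
    d$individuals <- share_household(d$individuals,
                                     rep(seq_len(n_sib_pairs), each = 2))
    d$individuals$decoy <- "sib"
    add_ind <- c(add_ind, list(d$individuals)); add_G <- c(add_G, list(d$genotypes))
    decoy_pairs <- c(decoy_pairs, list(data.frame(
      slot_a = seq(1, 2 * n_sib_pairs, 2), slot_b = seq(2, 2 * n_sib_pairs, 2),
      class = "sib", offset = if (length(add_ind) > 1) nrow(add_ind[[1]]) else 0L
    )))
  }

  if (n_key_trios > 0) {
    sexes <- sample(c("male", "female"), 3 * n_key_trios, replace = TRUE)
    d <- draw_decoy_individuals(3 * n_key_trios, cohort, sexes)
    d$individuals <- share_household(d$individuals,
                                     rep(seq_len(n_key_trios), each = 3))
    d$individuals$decoy <- "key_trio"
    add_ind <- c(add_ind, list(d$individuals)); add_G <- c(add_G, list(d$genotypes))
  }

  if (!length(add_ind)) return(cohort)
  new_ind <- do.call(rbind, add_ind)
  new_G <- do.call(rbind, add_G)
  n0 <- nrow(cohort$individuals)
  new_ind$id <- sprintf("id_%06d", n0 + seq_len(nrow(new_ind)))
  rownames(new_G) <- new_ind$id
  cohort$individuals <- rbind(cohort$individuals, new_ind)
  cohort$genotypes <- rbind(cohort$genotypes, new_G)
  if (length(decoy_pairs)) {
    dp <- do.call(rbind, decoy_pairs)
    cohort$decoy_pairs <- data.frame(
      id_a = new_ind$id[dp$offset + dp$slot_a],
      id_b = new_ind$id[dp$offset + dp$slot_b],
      class = dp$class, stringsAsFactors = FALSE
    )
  }
  cohort
}
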