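toy_records <- function() {
  data.frame(
    id = c("p1", "p2", "t1", "t2", "t3", "s1", "m1"),
    sex = c("male", "female", "male", "female", "male", "female", "male"),
    spouse_cohab = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    years_at_address = c(5, 5, 9, 9, 9, 4, NA),
    n_occupants = c(2, 2, 3, 3, 3, 2, 2),
    n_vehicles = c(1, 1, 2, 2, 2, 0, 1),
    accom_type = "house", rental_status = "own",
    home_north = c(100, 100, 200, 200, 200, 300, 400),
    home_east = c(50, 50, 60, 60, 60, 70, 80),
    father_death_age = NA_real_, mother_death_age = NA_real_,
    stringsAsFactors = FALSE
  )
}

test_that("household matching pairs identical keys, rejects key trios and near-misses", {
  m <- match_households(toy_records())
  expect_equal(nrow(m$pairs), 1)
  expect_setequal(c(m$pairs$id_a, m$pairs$id_b), c("p1", "p2"))
  expect_setequal(m$ledger$id[m$ledger$reason == "key_trio"],
                  c("t1", "t2", "t3"))
  expect_true("m1" %in% m$ledger$id[m$ledger$reason == "missing_matching_field"])
  # one km of coordinate difference breaks the match
  rec <- toy_records()[1:2, ]
  rec$home_north[2] <- 101
  expect_equal(nrow(match_households(rec)$pairs), 0)
})

test_that("same-sex and parental-death filters apply their published rules", {
  rec <- data.frame(
    id = c("a", "b", "c", "d", "e", "f", "g", "h"),
    sex = c("male", "female", "female", "female", "male", "female",
            "male", "female"),
    father_death_age = c(NA, NA, 70, 70, 70, 70, 70, NA),
    mother_death_age = c(NA, NA, 81, 81, 81, 82, 81, NA),
    stringsAsFactors = FALSE
  )
  pr <- data.frame(id_a = c("a", "c", "e", "g"), id_b = c("b", "d", "f", "h"),
                   stringsAsFactors = FALSE)
  s <- filter_same_sex(pr, rec)
  expect_equal(pair_key(s$pairs), pair_key(pr[c(1, 3, 4), ]))
  expect_setequal(s$ledger$id, c("c", "d"))
  d <- filter_parental_death(s$pairs, rec)
  # (e,f): father matches but mothers differ -> retained
  # (g,h): h reports nothing -> retained
  expect_equal(pair_key(d$pairs), pair_key(pr[c(1, 3, 4), ]))
  both <- filter_parental_death(pr, rec)
  expect_false("c" %in% c(both$pairs$id_a, both$pairs$id_b))
  # filters commute and handle empty input
  empty <- pr[0, ]
  expect_equal(nrow(filter_same_sex(empty, rec)$pairs), 0)
  ab <- filter_parental_death(filter_same_sex(pr, rec)$pairs, rec)$pairs
  ba <- filter_same_sex(filter_parental_death(pr, rec)$pairs, rec)$pairs
  expect_setequal(pair_key(ab), pair_key(ba))
})

test_that("LD pruning keeps one member of a correlated block and leaves independent markers alone", {
  set.seed(31)
  n <- 800
  base <- rbinom(n, 2, 0.5)
  dup <- base                       # r2 = 1, 1 kb away
  ind1 <- rbinom(n, 2, 0.3); ind2 <- rbinom(n, 2, 0.4)
  mono <- rep(1L, n)
  G <- cbind(v1 = base, v2 = dup, v3 = ind1, v4 = ind2, v5 = mono)
  meta <- data.frame(id = colnames(G), chrom = "1",
                     pos = c(1000, 2000, 100000, 200000, 201000))
  kept <- ld_prune(G, meta)
  expect_true(("v1" %in% kept) != ("v2" %in% kept))
  expect_true(all(c("v3", "v4") %in% kept))
  expect_false("v5" %in% kept)  # monomorphic dropped first
  # simulator block with r2 ~ 0.5: a single survivor, and every retained
  # within-window pair has r2 below threshold (brute force)
  coh <- simulate_cohort(sim_config(n_individuals = 2000, n_pgs_snps = 10,
                                    n_ld_block = 6, ld_block_r2 = 0.5,
                                    seed = 32))
  kept2 <- ld_prune(coh$genotypes, coh$variant_meta)
  expect_equal(sum(grepl("^block_", kept2)), 1)
  km <- coh$variant_meta[match(kept2, coh$variant_meta$id), ]
  for (i in seq_along(kept2)) for (j in seq_len(i - 1)) {
    if (km$chrom[i] == km$chrom[j] && abs(km$pos[i] - km$pos[j]) <= 50000) {
      r2 <- cor(coh$genotypes[, kept2[i]], coh$genotypes[, kept2[j]])^2
      expect_lt(r2, 0.1)
    }
  }
})

test_that("the GRM estimator separates identical, sibling and unrelated pairs", {
  coh <- simulate_cohort(sim_config(n_individuals = 600, n_pgs_snps = 1000,
                                    couple_fraction = 1, seed = 33))
  # MZ-like: duplicate an individual's genotype row
  G <- coh$genotypes
  G <- rbind(G, mz_copy = G[1, ])
  rownames(G)[nrow(G)] <- "mz_copy"
  # allele frequencies come from the candidate sample, so the duplicated
  # pair is assessed among the ordinary candidate pairs
  cand <- rbind(truth_pairs(coh),
                data.frame(id_a = rownames(G)[1], id_b = "mz_copy",
                           stringsAsFactors = FALSE))
  mz <- estimate_relatedness(G, cand)
  expect_gt(mz$relatedness[nrow(mz)], 0.8)
  unrel <- estimate_relatedness(coh$genotypes, truth_pairs(coh))
  expect_lt(abs(mean(unrel$relatedness)), 0.02)
  expect_lt(mean(abs(unrel$relatedness) > 0.1), 0.01)
  expect_warning(
    estimate_relatedness(coh$genotypes[, 1:50], truth_pairs(coh)),
    "usable markers"
  )
})

test_that("full derivation recovers true couples and excludes each decoy class at the right step", {
  coh <- simulate_cohort(sim_config(n_individuals = 2000, n_pgs_snps = 1000,
                                    seed = 34))
  coh <- inject_decoys(coh, n_same_sex = 15, n_sib_pairs = 15, n_key_trios = 4)
  sps <- derive_spouse_pairs(coh$individuals, coh$genotypes, coh$variant_meta)
  truth <- truth_pairs(coh)
  recall <- mean(pair_key(truth) %in% pair_key(sps$pairs))
  expect_gte(recall, 0.99)
  led <- sps$ledger
  ind <- coh$individuals
  trio_ids <- ind$id[ind$decoy == "key_trio"]
  expect_true(all(trio_ids %in% led$id[led$reason == "key_trio"]))
  ss_ids <- ind$id[ind$decoy == "same_sex"]
  expect_true(all(ss_ids %in% led$id[led$reason == "same_sex"]))
  sib_ids <- ind$id[ind$decoy == "sib"]
  expect_true(all(sib_ids %in% led$id[led$reason == "relatedness"]))
  # sib decoys reach the relatedness step (not excluded earlier)
  expect_false(any(sib_ids %in% led$id[led$step != "filter_relatedness"]))
  expect_false(any(pair_key(coh$decoy_pairs) %in% pair_key(sps$pairs)))
  # step counts are consistent with the ledger
  expect_equal(unname(sps$step_counts["candidates"] -
                        sps$step_counts["after_same_sex"]),
               sum(led$reason %in% c("same_sex", "missing_sex")) / 2)
})

test_that("derivation is idempotent: retained pairs violate no filter on re-check", {
  coh <- simulate_cohort(sim_config(n_individuals = 1500, n_pgs_snps = 1000,
                                    seed = 35))
  sps <- derive_spouse_pairs(coh$individuals, coh$genotypes, coh$variant_meta)
  keep_ids <- c(sps$pairs$id_a, sps$pairs$id_b)
  rec2 <- coh$individuals[coh$individuals$id %in% keep_ids, ]
  sps2 <- derive_spouse_pairs(rec2, coh$genotypes[keep_ids, ],
                              coh$variant_meta)
  expect_setequal(pair_key(sps2$pairs), pair_key(sps$pairs))
  expect_true(all(sps$pairs$relatedness <= 0.1))
  # singletons derive to an empty set
  singles <- coh$individuals[!coh$individuals$spouse_cohab, ]
  expect_equal(nrow(match_households(singles)$pairs), 0)
})
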