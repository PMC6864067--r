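household_fields <- c("spouse_cohab", "years_at_address", "n_occupants",
                      "n_vehicles", "accom_type", "rental_status",
                      "home_north", "home_east")

# Canonical household key: the eight matching fields pasted after rounding
# coordinates to integer km. Records must report living with a spouse to
# receive a key at all.
household_key <- function(records) {
  miss <- !stats::complete.cases(records[household_fields])
  key <- rep(NA_character_, nrow(records))
  ok <- !miss & records$spouse_cohab
  key[ok] <- paste(
    records$spouse_cohab[ok], records$years_at_address[ok],
    records$n_occupants[ok], records$n_vehicles[ok],
    records$accom_type[ok], records$rental_status[ok],
    round(as.numeric(records$home_north[ok])),
    round(as.numeric(records$home_east[ok])),
    sep = "|"
  )
  list(key = key, missing = miss)
}

#' Match households into candidate spouse pairs
#'
#' Pairs individuals identical on all eight household matching fields
#' (spouse-cohabiting flag, years at address, number of occupants, number of
#' vehicles, accommodation type, rental status, and home coordinates rounded
#' to the km). Any key shared by more than two individuals is excluded
#' entirely; individuals with missing matching fields are skipped and
#' logged.
#'
#' @param records data frame with an `id` column and the household fields.
#' @return A list with `pairs` (data frame `id_a`, `id_b`) and `ledger`
#'   (per-individual exclusion reasons at this step).
#' @export
match_households <- function(records) {
  stopifnot("id" %in% names(records),
            all(household_fields %in% names(records)))
  hk <- household_key(records)
  ledger <- data.frame(id = character(), step = character(),
                       reason = character(), stringsAsFactors = FALSE)
  if (any(hk$missing)) {
    ledger <- rbind(ledger, data.frame(
      id = records$id[hk$missing], step = "match_households",
      reason = "missing_matching_field", stringsAsFactors = FALSE
    ))
  }
  key <- hk$key
  tab <- table(key)
  trio_keys <- names(tab)[tab > 2]
  pair_keys <- names(tab)[tab == 2]
  if (length(trio_keys)) {
    trio_ids <- records$id[!is.na(key) & key %in% trio_keys]
    ledger <- rbind(ledger, data.frame(
      id = trio_ids, step = "match_households", reason = "key_trio",
      stringsAsFactors = FALSE
    ))
  }
  two <- !is.na(key) & key %in% pair_keys
  ids <- records$id[two]; ks <- key[two]
  o <- order(ks, ids)
  ids <- ids[o]
  if (length(ids)) {
    first <- seq(1, length(ids), by = 2)
    pairs <- data.frame(id_a = ids[first], id_b = ids[first + 1],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(id_a = character(), id_b = character(),
                        stringsAsFactors = FALSE)
  }
  list(pairs = pairs, ledger = ledger)
}

#' Remove same-sex candidate pairs
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param records data frame with `id` and `sex` (`"male"`/`"female"`).
#' @return A list with the retained `pairs` and a `ledger` of exclusions
#'   (reason `same_sex`, or `missing_sex` when sex is unavailable).
#' @export
filter_same_sex <- function(pairs, records) {
  sex <- stats::setNames(records$sex, records$id)
  sa <- sex[pairs$id_a]; sb <- sex[pairs$id_b]
  miss <- is.na(sa) | is.na(sb)
  same <- !miss & sa == sb
  ledger <- data.frame(
    id = c(pairs$id_a[same], pairs$id_b[same],
           pairs$id_a[miss], pairs$id_b[miss]),
    step = rep("filter_same_sex", 2 * (sum(same) + sum(miss))),
    reason = c(rep("same_sex", 2 * sum(same)), rep("missing_sex", 2 * sum(miss))),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs[!same & !miss, , drop = FALSE], ledger = ledger)
}

#' Remove pairs reporting identical parental ages at death
#'
#' A pair is removed only when both members report the same father's age at
#' death and the same mother's age at death, all four values non-missing —
#' the signature of siblings mistaken for spouses. Missing values never
#' trigger removal.
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param records data frame with `id`, `father_death_age`,
#'   `mother_death_age`.
#' @return A list with retained `pairs` and a `ledger` (reason
#'   `parental_death_match`).
#' @export
filter_parental_death <- function(pairs, records) {
  fa <- stats::setNames(records$father_death_age, records$id)
  mo <- stats::setNames(records$mother_death_age, records$id)
  match_both <- !is.na(fa[pairs$id_a]) & !is.na(fa[pairs$id_b]) &
    !is.na(mo[pairs$id_a]) & !is.na(mo[pairs$id_b]) &
    fa[pairs$id_a] == fa[pairs$id_b] & mo[pairs$id_a] == mo[pairs$id_b]
  ledger <- data.frame(
    id = c(pairs$id_a[match_both], pairs$id_b[match_both]),
    step = rep("filter_parental_death", 2 * sum(match_both)),
    reason = rep("parental_death_match", 2 * sum(match_both)),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs[!match_both, , drop = FALSE], ledger = ledger)
}

#' Greedy windowed LD pruning
#'
#' Walks variants in position order within each chromosome and keeps a
#' variant only if its squared correlation with every already-kept variant
#' within the physical window is below `r2_max`, so that every retained
#' within-window pair has r-squared below the threshold. Monomorphic
#' variants (undefined r-squared) are dropped first.
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param variant_meta data frame with `id`, `chrom`, `pos` for the columns
#'   of `genotypes`.
#' @param window_kb physical window in kb.
#' @param step_kb step size in kb (interface compatibility; the single
#'   left-to-right pass already enforces the window guarantee).
#' @param r2_max retention threshold on pairwise r-squared.
#' @return Character vector of retained variant IDs.
#' @export
ld_prune <- function(genotypes, variant_meta, window_kb = 50, step_kb = 5,
                     r2_max = 0.1) {
  stopifnot(ncol(genotypes) == nrow(variant_meta))
  v <- apply(genotypes, 2, stats::var, na.rm = TRUE)
  poly <- which(v > 0 & !is.na(v))
  meta <- variant_meta[poly, , drop = FALSE]
  G <- genotypes[, poly, drop = FALSE]
  keep <- character(0)
  for (ch in unique(meta$chrom)) {
    idx <- which(meta$chrom == ch)
    idx <- idx[order(meta$pos[idx])]
    kept_idx <- integer(0)
    for (i in idx) {
      in_window <- kept_idx[abs(meta$pos[kept_idx] - meta$pos[i]) <=
                              window_kb * 1000]
      ok <- TRUE
      for (j in in_window) {
        r <- stats::cor(G[, i], G[, j], use = "complete.obs")
        if (!is.na(r) && r^2 >= r2_max) { ok <- FALSE; break }
      }
      if (ok) kept_idx <- c(kept_idx, i)
    }
    keep <- c(keep, meta$id[kept_idx])
  }
  keep
}

#' Estimate genomic relatedness for candidate pairs
#'
#' For a pair (j, k), relatedness is the GRM entry
#' \deqn{\frac{1}{M}\sum_i \frac{(g_{ij}-2p_i)(g_{ik}-2p_i)}{2p_i(1-p_i)},}
#' with allele frequencies taken from the candidate-pair analysis sample
#' itself. Markers fixed in the sample are excluded; fewer than 100 usable
#' markers triggers a warning (the estimator's sampling standard deviation
#' is about 1/sqrt(M)).
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param pairs data frame `id_a`, `id_b`.
#' @param markers character vector of marker IDs to use (e.g. from
#'   [ld_prune()]); defaults to all columns.
#' @return The input pairs with a `relatedness` column.
#' @export
estimate_relatedness <- function(genotypes, pairs, markers = colnames(genotypes)) {
  if (!nrow(pairs)) return(cbind(pairs, relatedness = numeric(0)))
  sample_ids <- unique(c(pairs$id_a, pairs$id_b))
  G <- genotypes[sample_ids, intersect(markers, colnames(genotypes)),
                 drop = FALSE]
  p <- colMeans(G, na.rm = TRUE) / 2
  usable <- p > 0 & p < 1
  if (sum(usable) < 100) {
    warning(sprintf("only %d usable markers for relatedness (>= 100 recommended)",
                    sum(usable)), call. = FALSE)
  }
  if (!any(usable)) stop("no polymorphic markers available for relatedness")
  G <- G[, usable, drop = FALSE]
  p <- p[usable]
  Z <- sweep(G, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  rel <- vapply(seq_len(nrow(pairs)), function(i) {
    za <- Z[pairs$id_a[i], ]; zb <- Z[pairs$id_b[i], ]
    mean(za * zb, na.rm = TRUE)
  }, numeric(1))
  pairs$relatedness <- rel
  pairs
}

#' Derive spouse pairs from household records and genotypes
#'
#' Runs the full derivation pipeline in the published order — household
#' matching (with key-trio exclusion), same-sex filter, parental-death
#' filter, then genomic-relatedness filter (estimates above the threshold
#' are excluded) — and returns the retained pairs with a complete per-step
#' exclusion ledger.
#'
#' @param records individual table with `id`, `sex`, parental death ages and
#'   the eight household matching fields.
#' @param genotypes individuals x variants dosage matrix (rownames = ids).
#' @param variant_meta variant table with `id`, `chrom`, `pos`; when
#'   supplied, markers are LD-pruned before the GRM step.
#' @param relatedness_max exclusion threshold; pairs with estimated
#'   relatedness strictly greater are removed.
#' @param prune whether to LD-prune markers before relatedness estimation.
#' @return An object of class `spouse_pair_set`: list with `pairs` (with a
#'   `relatedness` column), `ledger` (id, step, reason), `step_counts`
#'   (candidate pairs surviving each step) and `markers_used`.
#' @export
derive_spouse_pairs <- function(records, genotypes, variant_meta = NULL,
                                relatedness_max = 0.1, prune = !is.null(variant_meta)) {
  m <- match_households(records)
  ledger <- m$ledger
  counts <- c(candidates = nrow(m$pairs))
  s <- filter_same_sex(m$pairs, records)
  ledger <- rbind(ledger, s$ledger)
  counts <- c(counts, after_same_sex = nrow(s$pairs))
  d <- filter_parental_death(s$pairs, records)
  ledger <- rbind(ledger, d$ledger)
  counts <- c(counts, after_parental_death = nrow(d$pairs))
  markers <- colnames(genotypes)
  if (prune && !is.null(variant_meta)) {
    markers <- ld_prune(genotypes, variant_meta)
  }
  pr <- estimate_relatedness(genotypes, d$pairs, markers)
  related <- pr$relatedness > relatedness_max
  if (any(related)) {
    ledger <- rbind(ledger, data.frame(
      id = c(pr$id_a[related], pr$id_b[related]),
      step = "filter_relatedness", reason = "relatedness",
      stringsAsFactors = FALSE
    ))
  }
  retained <- pr[!related, , drop = FALSE]
  counts <- c(counts, retained = nrow(retained))
  structure(
    list(pairs = retained, ledger = ledger, step_counts = counts,
         markers_used = markers),
    class = "spouse_pair_set"
  )
}

#' @export
print.spouse_pair_set <- function(x, ...) {
  cat("spouse-pair derivation:\n")
  for (i in seq_along(x$step_counts)) {
    cat(sprintf("  %-22s %d\n", names(x$step_counts)[i], x$step_counts[i]))
  }
  if (nrow(x$ledger)) {
    tt <- table(x$ledger$reason)
    cat("exclusions:", paste(names(tt), tt, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}
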