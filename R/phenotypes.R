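unit_factors <- c(spirits = 1, wine = 2, beer = 2.5)
weekly_categories <- c("daily", "3-4/week", "1-2/week")

#' Derive weekly alcohol units from beverage intakes
#'
#' Converts questionnaire beverage counts to units/week using the standard
#' equivalences — 1 unit per measure of spirits, 2 units per glass of wine
#' (red, white, champagne or fortified), 2.5 units per pint of beer or
#' cider. Individuals reporting an intake frequency below weekly
#' ("1-3/month", "special occasions", "never") are assigned 0 units
#' regardless of (typically uncollected) intake fields.
#'
#' @param intakes data frame with columns `bev_spirits`, `bev_red_wine`,
#'   `bev_white_wine`, `bev_champagne`, `bev_fortified_wine`, `bev_beer`,
#'   `bev_cider` (weekly counts; NAs allowed when frequency is below
#'   weekly).
#' @param frequency_category character/factor with levels among "daily",
#'   "3-4/week", "1-2/week", "1-3/month", "special occasions", "never".
#' @return Numeric vector of weekly units (NA when a weekly-frequency
#'   individual has missing intakes).
#' @export
derive_weekly_units <- function(intakes, frequency_category) {
  cols <- c("bev_spirits", "bev_red_wine", "bev_white_wine", "bev_champagne",
            "bev_fortified_wine", "bev_beer", "bev_cider")
  stopifnot(all(cols %in% names(intakes)))
  if (any(unlist(intakes[cols]) < 0, na.rm = TRUE)) {
    stop("negative beverage intake")
  }
  freq <- as.character(frequency_category)
  units <- unit_factors["spirits"] * intakes$bev_spirits +
    unit_factors["wine"] * (intakes$bev_red_wine + intakes$bev_white_wine +
                              intakes$bev_champagne + intakes$bev_fortified_wine) +
    unit_factors["beer"] * (intakes$bev_beer + intakes$bev_cider)
  units[!is.na(freq) & !(freq %in% weekly_categories)] <- 0
  as.numeric(units)
}

#' Derived alcohol phenotypes for a cohort table
#'
#' Computes the three analysis measures from raw questionnaire fields:
#' `weekly_units` (via [derive_weekly_units()]), `ever_drinker` (current or
#' former versus never) and `frequent_drinker` (three or more times a week
#' among current drinkers; NA otherwise). "Prefer not to say" and other
#' unrecognised categories propagate as missing.
#'
#' @param data individual table with the beverage columns,
#'   `frequency_category` and `drinker_status`.
#' @return `data` with `weekly_units`, `ever_drinker`, `frequent_drinker`
#'   columns appended.
#' @export
derive_alcohol_phenotypes <- function(data) {
  data$weekly_units <- derive_weekly_units(data, data$frequency_category)
  status <- as.character(data$drinker_status)
  data$ever_drinker <- ifelse(status %in% c("current", "previous"), 1L,
                              ifelse(status == "never", 0L, NA_integer_))
  freq <- as.character(data$frequency_category)
  data$frequent_drinker <- ifelse(
    status == "current" & freq %in% freq_levels,
    as.integer(freq %in% c("daily", "3-4/week")), NA_integer_
  )
  data
}

#' Exclude spouse pairs with outlying weekly consumption
#'
#' The mean and standard deviation are computed on individuals with
#' non-zero weekly units; a pair is removed when either member lies more
#' than `k` standard deviations from that mean. The default applies the
#' rule two-sided (absolute deviation); `side = "upper"` removes only
#' high outliers.
#'
#' @param pairs data frame `id_a`, `id_b`.
#' @param weekly_units named numeric vector of weekly units (names = ids).
#' @param k standard-deviation multiple.
#' @param side `"both"` (default) or `"upper"`.
#' @return A list with retained `pairs`, `n_removed`, and the `mean` and
#'   `sd` used.
#' @export
exclude_outlier_pairs <- function(pairs, weekly_units, k = 5,
                                  side = c("both", "upper")) {
  side <- match.arg(side)
  nz <- weekly_units[!is.na(weekly_units) & weekly_units != 0]
  if (!length(nz)) {
    warning("no non-zero weekly units; outlier rule not applied", call. = FALSE)
    return(list(pairs = pairs, n_removed = 0L, mean = NA_real_, sd = NA_real_))
  }
  m <- mean(nz); s <- stats::sd(nz)
  is_out <- function(u) {
    dev <- if (side == "both") abs(u - m) else (u - m)
    !is.na(u) & dev > k * s
  }
  out <- is_out(weekly_units[pairs$id_a]) | is_out(weekly_units[pairs$id_b])
  list(pairs = pairs[!out, , drop = FALSE], n_removed = sum(out),
       mean = m, sd = s)
}

#' Recode educational attainment to leaving age in years
#'
#' Degree holders are assigned a leaving age of 21; self-reported leaving
#' ages below 15 are floored at 15; other leaving ages pass through.
#' Individuals born outside England, Scotland or Wales are marked excluded
#' (schooling-system differences) and return NA.
#'
#' @param leaving_age numeric self-reported age left full-time education
#'   (NA for degree holders if `degree` is used).
#' @param degree logical, college or university degree.
#' @param country_of_birth character country of birth.
#' @return Numeric years (NA where excluded or unavailable).
#' @export
recode_education <- function(leaving_age, degree = FALSE,
                             country_of_birth = "England") {
  n <- max(length(leaving_age), length(degree), length(country_of_birth))
  leaving_age <- rep_len(leaving_age, n)
  degree <- rep_len(degree, n)
  country_of_birth <- rep_len(country_of_birth, n)
  out <- ifelse(degree, 21, ifelse(!is.na(leaving_age) & leaving_age < 15,
                                   15, leaving_age))
  out[!(country_of_birth %in% c("England", "Scotland", "Wales"))] <- NA_real_
  as.numeric(out)
}
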