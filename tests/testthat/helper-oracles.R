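# Independent brute-force reference implementations used to check the MR
# estimator suite, plus small fixture builders shared across test files.

# ratio estimates and first-order ses, written out longhand
oracle_ratios <- function(inp) {
  k <- nrow(inp)
  ratio <- numeric(k); se <- numeric(k)
  for (i in seq_len(k)) {
    ratio[i] <- inp$beta_outcome[i] / inp$beta_exposure[i]
    se[i] <- inp$se_outcome[i] / abs(inp$beta_exposure[i])
  }
  list(ratio = ratio, se = se)
}

oracle_ivw <- function(inp) {
  rs <- oracle_ratios(inp)
  num <- 0; den <- 0
  for (i in seq_along(rs$ratio)) {
    w <- 1 / rs$se[i]^2
    num <- num + w * rs$ratio[i]
    den <- den + w
  }
  beta <- num / den
  Q <- 0
  for (i in seq_along(rs$ratio)) {
    Q <- Q + (rs$ratio[i] - beta)^2 / rs$se[i]^2
  }
  list(beta = beta, se = sqrt(1 / den), Q = Q)
}

# weighted least squares with intercept through lm(), an independent route
oracle_egger <- function(inp) {
  flip <- ifelse(inp$beta_exposure < 0, -1, 1)
  bx <- inp$beta_exposure * flip
  by <- inp$beta_outcome * flip
  fit <- stats::lm(by ~ bx, weights = 1 / inp$se_outcome^2)
  sm <- summary(fit)$coefficients
  list(beta = sm["bx", 1], se = sm["bx", 2],
       intercept = sm["(Intercept)", 1], intercept_se = sm["(Intercept)", 2])
}

# interpolated weighted median rebuilt with approx()
oracle_wmedian <- function(inp) {
  rs <- oracle_ratios(inp)
  o <- order(rs$ratio)
  r <- rs$ratio[o]
  w <- (1 / rs$se[o]^2)
  w <- w / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  stats::approx(cum, r, xout = 0.5)$y
}

# weighted kernel-density argmax recomputed with a double loop on the same
# fixed grid convention as the implementation
oracle_wmode <- function(inp, bandwidth_factor = 1, n_grid = 10000) {
  rs <- oracle_ratios(inp)
  r <- rs$ratio
  w <- 1 / rs$se^2
  w <- w / sum(w)
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(r) * length(r)^(-1 / 5)
  h <- bandwidth_factor * s
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = n_grid)
  # accumulate the weighted kernel density variant by variant (the
  # implementation instead walks the grid and sums across variants)
  dens <- numeric(n_grid)
  for (i in seq_along(r)) {
    dens <- dens + w[i] * stats::dnorm((grid - r[i]) / h)
  }
  grid[which.max(dens)]
}

random_mr_input <- function(k) {
  mr_input(
    variant = paste0("v", seq_len(k)),
    beta_exposure = stats::rnorm(k, 0.2, 0.5),
    se_exposure = stats::runif(k, 0.01, 0.1),
    beta_outcome = stats::rnorm(k, 0.05, 0.2),
    se_outcome = stats::runif(k, 0.01, 0.2)
  )
}

# surviving true couples as an id_a/id_b pair table
truth_pairs <- function(cohort) {
  tr <- cohort$truth[!cohort$truth$dissolved, c("id_a", "id_b")]
  rownames(tr) <- NULL
  tr
}

pair_key <- function(pairs) {
  paste(pmin(pairs$id_a, pairs$id_b), pmax(pairs$id_a, pairs$id_b))
}

couple_cor <- function(cohort, col = "latent_pheno", pairs = truth_pairs(cohort)) {
  v <- stats::setNames(cohort$individuals[[col]], cohort$individuals$id)
  stats::cor(v[pairs$id_a], v[pairs$id_b])
}

# minimal individual table for concordance tests built from raw vectors
toy_data <- function(n_pairs, x_a, x_b, var = "pheno") {
  ids_a <- sprintf("a%04d", seq_len(n_pairs))
  ids_b <- sprintf("b%04d", seq_len(n_pairs))
  d <- data.frame(
    id = c(ids_a, ids_b),
    sex = rep(c("male", "female"), each = n_pairs),
    age = 50, stringsAsFactors = FALSE
  )
  d[[var]] <- c(x_a, x_b)
  list(pairs = data.frame(id_a = ids_a, id_b = ids_b,
                          stringsAsFactors = FALSE),
       data = d)
}
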