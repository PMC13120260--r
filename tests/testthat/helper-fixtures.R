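# Shared fixtures and independent oracles.

fixture_path <- function() {
  system.file("extdata", "table1_carp_pfoa.csv", package = "mbindex")
}

fixture_table <- function() read_feature_table(fixture_path())

fixture_samples <- function() {
  build_group_samples(zscore_table(fixture_table()))
}

GROUPS <- c("unexposed", "PFOA_200ng_L", "PFOA_2mg_L")

# Definitional tie-corrected Kruskal-Wallis oracle: explicit rank-sum
# formula with explicit tie-group enumeration, independent of the package's
# pooled representation.
oracle_kw_H <- function(samples) {
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  N <- length(x)
  r <- rank(x)
  Rsum <- tapply(r, g, sum)
  n <- lengths(samples)
  H0 <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  ties <- table(x)
  H0 / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Brute-force pairwise-dominance oracle for the rank-biserial correlation.
oracle_rrb <- function(a, b) {
  fav <- unfav <- 0
  for (x in a) for (y in b) {
    if (x > y) fav <- fav + 1
    else if (x < y) unfav <- unfav + 1
    else { fav <- fav + 0.5; unfav <- unfav + 0.5 }
  }
  (fav - unfav) / (length(a) * length(b))
}

# Brute-force per-pixel loop oracle for area fractions.
oracle_area_fraction <- function(class_mask, total_mask) {
  n_class <- 0L; n_total <- 0L
  for (i in seq_len(nrow(total_mask))) for (j in seq_len(ncol(total_mask))) {
    if (total_mask[i, j]) n_total <- n_total + 1L
    if (class_mask[i, j]) n_class <- n_class + 1L
  }
  n_class / n_total
}

# Random small group samples, with optional forced ties via value rounding.
random_samples <- function(k = 3, n_range = 2:6, ties = TRUE) {
  n <- sample(n_range, k, replace = TRUE)
  lapply(seq_len(k), function(i) {
    v <- stats::rnorm(n[i])
    if (ties) round(v * 2) / 2 else v
  })
}
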