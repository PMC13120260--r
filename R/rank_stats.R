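# Nonparametric inference on pooled index replicates: tie-corrected
# Kruskal-Wallis, rank epsilon-squared, Monte Carlo permutation p, Dunn
# pairwise z with Holm adjustment, rank-biserial correlations.

# Pooled representation shared by every rank computation.  Mid-ranks for
# ties throughout; no random tie breaking ever.
pool_samples <- function(samples) {
  if (inherits(samples, "group_samples")) samples <- samples$samples
  if (!is.list(samples) || length(samples) < 2L)
    stop("need a list of at least two group sample vectors")
  if (any(lengths(samples) < 1L)) stop("every group needs >= 1 replicate")
  x <- unlist(samples, use.names = FALSE)
  if (any(!is.finite(x))) stop("non-finite replicate value")
  n <- lengths(samples)
  N <- length(x)
  if (length(unique(x)) == 1L)
    stop(structure(class = c("mbi_degenerate_data", "error", "condition"),
                   list(message = "degenerate data: all pooled replicates identical",
                        call = sys.call(-1L))))
  r <- rank(x)                          # mid-ranks
  tie_sizes <- tabulate(match(x, unique(x)))
  list(x = x, r = r, n = n, N = N,
       g = rep(seq_along(samples), n),
       groups = names(samples),
       tie_term = sum(tie_sizes^3 - tie_sizes))
}

#' Tie-corrected Kruskal-Wallis test statistic
#'
#' Computes `H = [12/(N(N+1)) * sum n_g (Rbar_g - (N+1)/2)^2] / C` over the
#' mid-ranks of the pooled replicates, with the standard tie correction
#' `C = 1 - sum(t^3 - t) / (N^3 - N)` over tie groups of size `t`.
#'
#' @param samples a `"group_samples"` object (see [build_group_samples()]) or
#'   a plain named list of numeric vectors, one per group.
#' @return A list with `H`, `df` (= number of groups - 1), and `n_per_group`.
#' @section Errors: an all-identical pooled sample leaves H undefined (the
#'   tie correction divides by zero) and raises a condition of class
#'   `"mbi_degenerate_data"`.
#' @export
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
kruskal_wallis <- function(samples) {
  p <- pool_samples(samples)
  rbar <- tapply(p$r, p$g, mean)
  H0 <- 12 / (p$N * (p$N + 1)) * sum(p$n * (rbar - (p$N + 1) / 2)^2)
  C <- 1 - p$tie_term / (p$N^3 - p$N)
  list(H = H0 / C, df = length(p$n) - 1L,
       n_per_group = stats::setNames(as.integer(p$n), p$groups))
}

#' Rank epsilon-squared effect size
#'
#' `epsilon^2 = H / (N - 1)`, the proportion-of-rank-variance effect size for
#' the Kruskal-Wallis test, clipped to `[0, 1]`.
#'
#' @param H Kruskal-Wallis statistic.
#' @param N total number of pooled replicates (>= 2).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' epsilon_squared(25.12, 36)
epsilon_squared <- function(H, N) {
  stopifnot(H >= 0, N >= 2)
  min(max(H / (N - 1), 0), 1)
}

#' Asymptotic Kruskal-Wallis p-value
#'
#' Upper-tail chi-square probability of `H` on `df` degrees of freedom (for
#' `df = 2` this is exactly `exp(-H/2)`).
#'
#' @param H statistic (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return The upper-tail probability.
#' @export
asymptotic_p <- function(H, df) {
  stopifnot(H >= 0, df >= 1)
  stats::pchisq(H, df, lower.tail = FALSE)
}

# Run fn with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# H for a permuted assignment of the fixed pooled ranks; the tie correction
# and rank vector never change under relabelling, so only group rank means
# are recomputed.
kw_from_ranks <- function(r, g, n, N, C) {
  rbar <- tapply(r, g, mean)
  (12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)) / C
}

#' Monte Carlo permutation p-value for the Kruskal-Wallis test
#'
#' Estimates the permutation p-value by randomly reassigning the pooled
#' replicates to groups (group sizes preserved) `B` times and counting
#' permutations whose tie-corrected H meets or exceeds the observed one,
#' using the add-one estimator `(1 + #exceedances) / (B + 1)` so the estimate
#' is never exactly zero.  The confidence interval for the estimate is
#' Clopper-Pearson binomial on the exceedance count.
#'
#' @inheritParams kruskal_wallis
#' @param B number of random permutations (>= 100; default 10000).
#' @param seed optional integer seed; the estimate is deterministic given it.
#' @param conf confidence level of the binomial interval (default 0.99).
#' @return A list with `p` (point estimate), `ci` (lower, upper), `B`,
#'   `conf` and `H_obs`.
#' @export
#' @examples
#' s <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
#' montecarlo_p(s, B = 1000, seed = 1)
montecarlo_p <- function(samples, B = 10000L, seed = NULL, conf = 0.99) {
  stopifnot(B >= 100L)
  p <- pool_samples(samples)
  C <- 1 - p$tie_term / (p$N^3 - p$N)
  H_obs <- kw_from_ranks(p$r, p$g, p$n, p$N, C)
  # >= with an absolute tolerance: permuted H equal to H_obs must count,
  # and rank arithmetic can differ in the last ulp across orderings.
  thr <- H_obs - 1e-9
  exceed <- with_seed(seed, function() {
    sum(vapply(seq_len(B), function(b)
      kw_from_ranks(sample(p$r), p$g, p$n, p$N, C) >= thr, logical(1L)))
  })
  ci <- c(lower = if (exceed == 0L) 0 else
            stats::qbeta((1 - conf) / 2, exceed, B - exceed + 1),
          upper = if (exceed == B) 1 else
            stats::qbeta(1 - (1 - conf) / 2, exceed + 1, B - exceed))
  list(p = (1 + exceed) / (B + 1), ci = ci, B = as.integer(B), conf = conf,
       H_obs = H_obs)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates every distinct assignment of the pooled replicates to groups
#' with the observed group sizes and returns the exact proportion whose
#' tie-corrected H is at least the observed H.  Feasible only for small
#' samples (e.g. 1680 assignments for group sizes 3/3/3); serves as the
#' ground-truth reference for [montecarlo_p()].
#'
#' @inheritParams kruskal_wallis
#' @param max_assignments safety cap on the number of enumerated assignments
#'   (default 2e6).
#' @return A list with `p` (exact), `n_assignments` and `H_obs`.
#' @export
exact_permutation_p <- function(samples, max_assignments = 2e6) {
  p <- pool_samples(samples)
  k <- length(p$n)
  n_assign <- prod(choose(cumsum(rev(p$n)), rev(p$n)))
  if (n_assign > max_assignments)
    stop("exhaustive enumeration infeasible: ", format(n_assign),
         " assignments")
  C <- 1 - p$tie_term / (p$N^3 - p$N)
  H_obs <- kw_from_ranks(p$r, p$g, p$n, p$N, C)
  thr <- H_obs - 1e-9
  count <- 0L; total <- 0L
  # recursively choose which pooled positions go to each group
  recurse <- function(remaining, gi, gvec) {
    if (gi == k) {
      gvec[remaining] <- k
      count <<- count + (kw_from_ranks(p$r, gvec, p$n, p$N, C) >= thr)
      total <<- total + 1L
      return(invisible())
    }
    for (idx in utils::combn(remaining, p$n[gi], simplify = FALSE)) {
      gvec[idx] <- gi
      recurse(setdiff(remaining, idx), gi + 1L, gvec)
    }
  }
  recurse(seq_len(p$N), 1L, integer(p$N))
  list(p = count / total, n_assignments = total, H_obs = H_obs)
}

#' Dunn pairwise comparisons
#'
#' Post-hoc pairwise z statistics after a Kruskal-Wallis test.  Ranks are
#' computed once on the pooled sample; for groups i and j,
#' `z_ij = (Rbar_i - Rbar_j) / SE` with the tie-corrected pooled-rank
#' standard error
#' `SE = sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j))`.
#' Two-sided standard-normal p-values; pairs are ordered (i before j) by the
#' group order of the input.
#'
#' @inheritParams kruskal_wallis
#' @return A data frame with one row per unordered pair: `group_i`,
#'   `group_j`, `z`, `p_raw`.
#' @export
dunn_pairwise <- function(samples) {
  p <- pool_samples(samples)
  rbar <- tapply(p$r, p$g, mean)
  v <- p$N * (p$N + 1) / 12 - p$tie_term / (12 * (p$N - 1))
  k <- length(p$n)
  pairs <- utils::combn(k, 2L)
  z <- apply(pairs, 2L, function(ij) {
    (rbar[ij[1L]] - rbar[ij[2L]]) /
      sqrt(v * (1 / p$n[ij[1L]] + 1 / p$n[ij[2L]]))
  })
  labels <- if (is.null(p$groups)) as.character(seq_len(k)) else p$groups
  data.frame(group_i = labels[pairs[1L, ]], group_j = labels[pairs[2L, ]],
             z = as.numeric(z),
             p_raw = 2 * stats::pnorm(-abs(as.numeric(z))),
             stringsAsFactors = FALSE)
}

#' Holm step-down adjustment
#'
#' Sorts the raw p-values ascending, multiplies the i-th by `m - i + 1`,
#' enforces the running maximum, caps at 1 and restores input order.  The
#' family is the set of pairwise comparisons of one index (m = 3 for three
#' groups), never the comparisons pooled across indices.
#'
#' @param p_raw numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.00085, 0.02, 0.3))  # 0.00255 0.04 0.3
holm_adjust <- function(p_raw) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1))
  m <- length(p_raw)
  o <- order(p_raw)
  adj <- pmin(cummax(p_raw[o] * (m - seq_len(m) + 1L)), 1)
  adj[order(o)]
}

#' Rank-biserial correlation between two samples
#'
#' The pairwise-dominance effect size: over all `n_i * n_j` cross pairs,
#' `r = (#\{x > y\} - #\{x < y\}) / (n_i * n_j)`, with exact ties crediting
#' half a pair to each side (hence contributing zero net).  `+1` when every
#' first-sample value exceeds every second-sample value, `-1` for the
#' reverse; antisymmetric in its arguments.
#'
#' @param sample_i,sample_j non-empty numeric vectors.
#' @return A number in `[-1, +1]`.
#' @export
#' @examples
#' rank_biserial(c(3, 4, 5), c(1, 2, 3))
rank_biserial <- function(sample_i, sample_j) {
  if (!length(sample_i) || !length(sample_j)) stop("empty sample")
  if (any(!is.finite(c(sample_i, sample_j)))) stop("non-finite value")
  d <- sign(outer(sample_i, sample_j, "-"))
  sum(d) / length(d)
}

#' Full inference report for one index
#'
#' Assembles the omnibus and pairwise layers for one replicate set: the
#' tie-corrected Kruskal-Wallis H with asymptotic and Monte Carlo p-values,
#' rank epsilon-squared (with an optional seeded percentile-bootstrap CI),
#' and all pairwise Dunn comparisons with Holm-adjusted p-values and
#' rank-biserial correlations (the Holm family is this index's pairs only).
#'
#' @inheritParams kruskal_wallis
#' @param B Monte Carlo permutation count (default 10000); `B = 0` skips the
#'   Monte Carlo estimate.
#' @param seed optional integer seed driving the Monte Carlo permutations and
#'   the bootstrap.
#' @param conf confidence level for the Monte Carlo interval (default 0.99).
#' @param eps_boot percentile-bootstrap resample count for the
#'   epsilon-squared CI (default 2000; `0` skips it).  The bootstrap
#'   resamples replicates within groups.  Note this CI is exploratory: with
#'   handfuls of replicates per group it is noisy and can sit asymmetrically
#'   around the point estimate.
#' @param eps_conf confidence level for the bootstrap CI (default 0.95).
#' @return An object of class `"index_report"`: a list with `index`, `kw`
#'   (H, df, p_asymptotic, p_montecarlo, mc_ci, B, epsilon_sq, epsilon_ci,
#'   n_per_group) and `dunn` (data frame: group_i, group_j, z, p_raw,
#'   p_holm, r_rb).
#' @export
#' @examples
#' path <- system.file("extdata", "table1_carp_pfoa.csv", package = "mbindex")
#' gs <- build_group_samples(zscore_table(read_feature_table(path)))
#' analyse_index(gs$thyrotoxic, B = 1000, seed = 1)
analyse_index <- function(samples, B = 10000L, seed = NULL, conf = 0.99,
                          eps_boot = 2000L, eps_conf = 0.95) {
  label <- if (inherits(samples, "group_samples")) samples$index_label else ""
  kw <- kruskal_wallis(samples)
  N <- sum(kw$n_per_group)
  eps <- epsilon_squared(kw$H, N)
  mc <- if (B > 0) montecarlo_p(samples, B = B, seed = seed, conf = conf)
        else NULL
  eps_ci <- if (eps_boot > 0)
    with_seed(if (is.null(seed)) NULL else seed + 1L, function()
      bootstrap_epsilon_ci(samples, eps_boot, eps_conf))
  else NULL

  raw <- if (inherits(samples, "group_samples")) samples$samples else samples
  if (is.null(names(raw))) names(raw) <- as.character(seq_along(raw))
  dunn <- dunn_pairwise(samples)
  dunn$p_holm <- holm_adjust(dunn$p_raw)
  dunn$r_rb <- mapply(function(i, j) rank_biserial(raw[[i]], raw[[j]]),
                      dunn$group_i, dunn$group_j)
  structure(list(index = label,
                 kw = list(H = kw$H, df = kw$df,
                           p_asymptotic = asymptotic_p(kw$H, kw$df),
                           p_montecarlo = if (is.null(mc)) NA_real_ else mc$p,
                           mc_ci = if (is.null(mc)) c(NA_real_, NA_real_)
                                   else mc$ci,
                           B = if (is.null(mc)) 0L else mc$B,
                           epsilon_sq = eps, epsilon_ci = eps_ci,
                           n_per_group = kw$n_per_group),
                 dunn = dunn),
            class = "index_report")
}

# Percentile bootstrap of epsilon^2, resampling replicates within groups.
bootstrap_epsilon_ci <- function(samples, nboot, conf) {
  raw <- if (inherits(samples, "group_samples")) samples$samples else samples
  N <- sum(lengths(raw))
  stat <- vapply(seq_len(nboot), function(b) {
    res <- lapply(raw, function(v) v[sample.int(length(v), replace = TRUE)])
    kw <- tryCatch(kruskal_wallis(res), mbi_degenerate_data = function(e) NULL)
    if (is.null(kw)) return(NA_real_)
    epsilon_squared(kw$H, N)
  }, numeric(1L))
  stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                  na.rm = TRUE, names = FALSE)
}

#' @export
print.index_report <- function(x, digits = 3, ...) {
  k <- x$kw
  cat(sprintf("Index '%s': H = %.*f, df = %d, p = %.4g, eps^2 = %.*f\n",
              x$index, digits, k$H, k$df, k$p_asymptotic, digits,
              k$epsilon_sq))
  if (!is.na(k$p_montecarlo))
    cat(sprintf("  Monte Carlo p = %.4g (%.0f%% CI %.4g-%.4g, B = %d)\n",
                k$p_montecarlo, 100 * 0.99, k$mc_ci[1L], k$mc_ci[2L], k$B))
  d <- x$dunn
  d$z <- round(d$z, digits); d$r_rb <- round(d$r_rb, digits)
  d$p_raw <- signif(d$p_raw, digits); d$p_holm <- signif(d$p_holm, digits)
  print(d, row.names = FALSE, ...)
  invisible(x)
}

#' Analyse every index of a feature table
#'
#' Convenience driver: z-scores the table, validates the hierarchy, pools the
#' replicate sets and runs [analyse_index()] on every subindex and on the
#' multipurpose index.
#'
#' @param table a [feature_table()].
#' @inheritParams analyse_index
#' @param on_constant passed to [zscore_table()].
#' @return A named list of [analyse_index()] reports (subindices first,
#'   multipurpose last), with the z-score matrix attached as attribute
#'   `"zscores"`.
#' @export
analyse_table <- function(table, B = 10000L, seed = NULL, conf = 0.99,
                          eps_boot = 2000L, on_constant = "error") {
  zmat <- zscore_table(table, on_constant = on_constant)
  hier <- validate_hierarchy(table)
  gs <- build_group_samples(zmat, hier)
  reports <- lapply(seq_along(gs), function(i)
    analyse_index(gs[[i]], B = B, conf = conf, eps_boot = eps_boot,
                  seed = if (is.null(seed)) NULL else seed + i))
  names(reports) <- names(gs)
  attr(reports, "zscores") <- zmat
  reports
}

#' Tabulate index reports
#'
#' Flattens a list of [analyse_index()] reports into the two standard report
#' tables: the omnibus table (one row per index: H, df, asymptotic and Monte
#' Carlo p, epsilon-squared) and the pairwise table (one row per contrast:
#' Dunn z, rank-biserial r, Holm-adjusted p).
#'
#' @param reports a list of `"index_report"` objects ([analyse_table()]
#'   output).
#' @param digits rounding for the presentation columns (default 3); the
#'   full-precision columns are always kept.
#' @return A list with data frames `omnibus` and `pairwise`.
#' @export
summary_tables <- function(reports, digits = 3) {
  omnibus <- do.call(rbind, lapply(reports, function(r)
    data.frame(index = r$index, H = r$kw$H, df = r$kw$df,
               p_asymptotic = r$kw$p_asymptotic,
               p_montecarlo = r$kw$p_montecarlo,
               epsilon_sq = r$kw$epsilon_sq, stringsAsFactors = FALSE)))
  omnibus$H_rounded <- round(omnibus$H, digits)
  omnibus$p_rounded <- round(omnibus$p_asymptotic, digits)
  omnibus$epsilon_sq_rounded <- round(omnibus$epsilon_sq, digits)
  pairwise <- do.call(rbind, lapply(reports, function(r) {
    d <- r$dunn
    d$index <- r$index
    d[, c("index", "group_i", "group_j", "z", "r_rb", "p_raw", "p_holm")]
  }))
  pairwise$z_rounded <- round(pairwise$z, digits)
  pairwise$r_rb_rounded <- round(pairwise$r_rb, digits)
  pairwise$p_holm_rounded <- round(pairwise$p_holm, digits)
  rownames(omnibus) <- rownames(pairwise) <- NULL
  list(omnibus = omnibus, pairwise = pairwise)
}
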