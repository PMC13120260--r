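test_that("kruskal_wallis handles degenerate and null configurations", {
  expect_equal(kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))$H, 0)
  expect_error(kruskal_wallis(list(a = c(1, 1), b = c(1, 1))),
               class = "mbi_degenerate_data")
  expect_error(kruskal_wallis(list(a = 1:3)), "two group")
  kw <- kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$df, 2L)
  expect_equal(unname(kw$n_per_group), rep(3L, 3))
})

test_that("tie-corrected H matches independent implementations on random data", {
  set.seed(101)
  for (case in 1:300) {
    s <- random_samples(k = sample(2:4, 1), ties = case %% 2 == 0)
    if (length(unique(unlist(s))) == 1L) next
    H <- kruskal_wallis(s)$H
    expect_equal(H, oracle_kw_H(s), tolerance = 1e-10)
    # cross-check against the reference implementation in stats
    ref <- stats::kruskal.test(unlist(s),
                               rep(seq_along(s), lengths(s)))
    expect_equal(H, unname(ref$statistic), tolerance = 1e-10)
    expect_gte(H, 0)
  }
})

test_that("rank sums are conserved in the pooled representation", {
  set.seed(5)
  for (case in 1:50) {
    s <- random_samples()
    if (length(unique(unlist(s))) == 1L) next
    p <- mbindex:::pool_samples(s)
    expect_equal(sum(tapply(p$r, p$g, sum)), p$N * (p$N + 1) / 2)
  }
})

test_that("epsilon_squared is H/(N-1) clipped to [0, 1]", {
  expect_equal(round(epsilon_squared(25.12, 36), 3), 0.718)
  expect_equal(round(epsilon_squared(11.450, 15), 3), 0.818)
  expect_equal(epsilon_squared(0, 10), 0)
  expect_equal(epsilon_squared(50, 10), 1)  # clipped
  set.seed(7)
  for (case in 1:100) {
    s <- random_samples()
    if (length(unique(unlist(s))) == 1L) next
    kw <- kruskal_wallis(s)
    N <- sum(lengths(s))
    expect_equal(epsilon_squared(kw$H, N), kw$H / (N - 1))
  }
})

test_that("asymptotic_p is the chi-square upper tail", {
  expect_equal(asymptotic_p(0, 2), 1)
  expect_equal(asymptotic_p(11.45, 2), exp(-11.45 / 2))
  expect_equal(round(asymptotic_p(11.450, 2), 3), 0.003)
  expect_equal(round(asymptotic_p(6.489, 2), 3), 0.039)
})

test_that("montecarlo_p is deterministic, add-one, and exact on tied groups", {
  s <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  mc <- montecarlo_p(s, B = 200, seed = 1)
  expect_equal(mc$p, 1)  # H = 0 is met by every permutation
  expect_gte(mc$ci[["upper"]], mc$p - 1e-12)

  s2 <- list(a = stats::rnorm(4), b = stats::rnorm(4) + 2,
             c = stats::rnorm(4))
  m1 <- montecarlo_p(s2, B = 500, seed = 99)
  m2 <- montecarlo_p(s2, B = 500, seed = 99)
  expect_identical(m1, m2)
  expect_true(m1$ci[["lower"]] <= m1$p & m1$p <= m1$ci[["upper"]] + 1 / 501)
  expect_error(montecarlo_p(s2, B = 10), "B >= 100")
})

test_that("Monte Carlo agrees with exhaustive enumeration for sizes (3,3,3)", {
  set.seed(21)
  s <- list(a = stats::rnorm(3), b = stats::rnorm(3) + 1.5,
            c = stats::rnorm(3))
  ex <- exact_permutation_p(s)
  expect_equal(ex$n_assignments, 1680L)
  mc <- montecarlo_p(s, B = 4000, seed = 2)
  expect_gte(ex$p, mc$ci[["lower"]])
  expect_lte(ex$p, mc$ci[["upper"]])
  # enumeration refuses infeasible problems
  big <- lapply(1:3, function(i) stats::rnorm(8))
  expect_error(exact_permutation_p(big, max_assignments = 1000),
               "infeasible")
})

test_that("Dunn z uses pooled mid-ranks with the tie-corrected SE", {
  # a group against an identical copy scores z = 0
  d0 <- dunn_pairwise(list(a = c(1, 3, 5), b = c(1, 3, 5)))
  expect_equal(d0$z, 0)
  # sign follows the mean-rank difference, pairs follow group order
  d <- dunn_pairwise(list(lo = c(1, 2), hi = c(9, 10), mid = c(4, 5)))
  expect_identical(d$group_i, c("lo", "lo", "hi"))
  expect_identical(d$group_j, c("hi", "mid", "mid"))
  expect_lt(d$z[1], 0); expect_gt(d$z[3], 0)
  expect_equal(d$p_raw, 2 * stats::pnorm(-abs(d$z)))
})

test_that("for two groups the Dunn z squares to the tie-corrected H", {
  set.seed(77)
  for (case in 1:200) {
    s <- random_samples(k = 2)
    if (length(unique(unlist(s))) == 1L) next
    z <- dunn_pairwise(s)$z
    H <- kruskal_wallis(s)$H
    expect_equal(z^2, H, tolerance = 1e-6)
  }
})

test_that("holm_adjust applies the step-down rule and matches p.adjust", {
  expect_equal(holm_adjust(c(0.00085, 0.02, 0.3)), c(0.00255, 0.04, 0.3))
  expect_equal(holm_adjust(rep(0.2, 3)), rep(0.6, 3))  # all equal -> m * p
  expect_equal(holm_adjust(rep(0.4, 3)), rep(1, 3))    # capped at 1
  set.seed(13)
  for (case in 1:100) {
    p <- stats::runif(sample(1:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "holm"))
    expect_true(all(adj >= p))
  }
})

test_that("rank_biserial counts dominance with half-credited ties", {
  expect_equal(rank_biserial(c(3, 4, 5), c(1, 2, 2.5)), 1)
  expect_equal(rank_biserial(c(1, 2), c(8, 9)), -1)
  expect_equal(rank_biserial(c(1, 2), c(1, 2)), 0)
  expect_error(rank_biserial(numeric(0), 1), "empty")
  set.seed(31)
  for (case in 1:200) {
    a <- round(stats::rnorm(sample(2:6, 1)), 1)
    b <- round(stats::rnorm(sample(2:6, 1)), 1)
    r <- rank_biserial(a, b)
    expect_equal(r, oracle_rrb(a, b))
    expect_equal(r, -rank_biserial(b, a))      # antisymmetry
    expect_lte(abs(r), 1)
    # Mann-Whitney identity: r = 2 W / (n1 n2) - 1
    W <- suppressWarnings(stats::wilcox.test(a, b)$statistic)
    expect_equal(r, unname(2 * W / (length(a) * length(b)) - 1),
                 tolerance = 1e-12)
  }
})

test_that("analyse_index assembles omnibus and pairwise layers coherently", {
  gs <- fixture_samples()
  rep <- analyse_index(gs$immunotoxic, B = 500, seed = 4)
  expect_s3_class(rep, "index_report")
  expect_equal(rep$index, "immunotoxic")
  expect_equal(nrow(rep$dunn), 3L)
  expect_equal(rep$kw$epsilon_sq,
               epsilon_squared(rep$kw$H, sum(rep$kw$n_per_group)))
  expect_true(all(rep$dunn$p_holm >= rep$dunn$p_raw - 1e-15))
  expect_length(rep$kw$epsilon_ci, 2L)
  expect_error(analyse_index(list(a = 1:3)), "two group")
})

test_that("summary_tables flattens reports into the two report skeletons", {
  reports <- analyse_table(fixture_table(), B = 0, eps_boot = 0)
  st <- summary_tables(reports)
  expect_equal(nrow(st$omnibus), 4L)
  expect_equal(nrow(st$pairwise), 12L)
  expect_identical(st$omnibus$index,
                   c("nephrotoxic", "thyrotoxic", "immunotoxic",
                     "multipurpose"))
  expect_true(all(st$pairwise$p_holm >= st$pairwise$p_raw - 1e-15))
})
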