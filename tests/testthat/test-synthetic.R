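null_spec <- function(n = 3, noise = 1) {
  generator_spec(subindices = list(
    s1 = list(n_features = n, pattern = effect_pattern("null"),
              noise_sd = noise),
    s2 = list(n_features = n, pattern = effect_pattern("null"),
              noise_sd = noise),
    s3 = list(n_features = n, pattern = effect_pattern("null"),
              noise_sd = noise)))
}

# The three dose-response archetypes of the kidney study: high-dose-only
# nephron damage, low-dose goitrogenic peak (with the two size endpoints
# dropping), and dose-related immune activation.
archetype_spec <- function(magnitude = 2, noise = 0.5) {
  generator_spec(subindices = list(
    nephrotoxic = list(n_features = 5,
                       pattern = effect_pattern("plateau", magnitude),
                       noise_sd = noise),
    thyrotoxic = list(n_features = 4,
                      pattern = list(effect_pattern("inverted_u", magnitude),
                                     effect_pattern("inverted_u", magnitude),
                                     effect_pattern("u_shaped", magnitude),
                                     effect_pattern("u_shaped", magnitude)),
                      noise_sd = noise),
    immunotoxic = list(n_features = 3,
                       pattern = effect_pattern("monotonic_up", magnitude),
                       noise_sd = noise)))
}

test_that("generation is deterministic given the seed", {
  spec <- archetype_spec()
  t1 <- generate_table(spec, seed = 123)
  t2 <- generate_table(spec, seed = 123)
  expect_identical(t1$values, t2$values)
  t3 <- generate_table(spec, seed = 124)
  expect_false(identical(t1$values, t3$values))
})

test_that("pattern shapes place their extremes as constructed", {
  spec <- generator_spec(subindices = list(
    thy = list(n_features = 4,
               pattern = effect_pattern("inverted_u", magnitude = 2),
               noise_sd = 0)))
  tab <- generate_table(spec, seed = 1)
  # middle group holds the extreme value for every noiseless inverted-U row
  expect_true(all(apply(tab$values, 1L, which.max) == 2L))

  down <- generate_table(generator_spec(subindices = list(
    s = list(n_features = 2, pattern = effect_pattern("monotonic_down", 1),
             noise_sd = 0))), seed = 1)
  expect_equal(unname(down$meta$direction), c(-1L, -1L))
  expect_true(all(diff(t(down$values)) < 0))
})

test_that("a noiseless null spec exercises the constant-feature path", {
  tab <- generate_table(null_spec(noise = 0), seed = 9)
  expect_error(zscore_table(tab), "constant")
  expect_error(suppressWarnings(zscore_table(tab, on_constant = "drop")), NA)
})

test_that("generated tables always pass feature-model validation", {
  spec <- archetype_spec()
  for (seed in 1:20) {
    tab <- generate_table(spec, seed = seed)
    expect_s3_class(tab, "feature_table")
    h <- validate_hierarchy(tab)
    expect_equal(lengths(h$subindices),
                 c(nephrotoxic = 5L, thyrotoxic = 4L, immunotoxic = 3L))
  }
})

test_that("verbatim offsets with zero noise reproduce a target table", {
  ft <- fixture_table()
  subs <- lapply(seq_len(nrow(ft$values)), function(i)
    list(n_features = 1,
         pattern = effect_pattern(offsets = ft$values[i, ], magnitude = 1),
         noise_sd = 0))
  names(subs) <- ft$meta$feature
  tab <- generate_table(generator_spec(groups = ft$groups,
                                       subindices = subs), seed = 1)
  expect_equal(unname(tab$values), unname(ft$values))
})

test_that("generator specs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("groups: [unexposed, low, high]",
               "seed: 42",
               "subindices:",
               "  neph:",
               "    n_features: 5",
               "    noise_sd: 0.3",
               "    pattern: {shape: plateau, magnitude: 2, baseline: 10, scale: 3}",
               "  imm:",
               "    n_features: 3",
               "    noise_sd: 0.3",
               "    pattern: {shape: monotonic_up, magnitude: 2}"), path)
  spec <- read_generator_spec(path)
  expect_s3_class(spec, "generator_spec")
  expect_equal(spec$seed, 42)
  expect_equal(spec$subindices$neph$pattern$shape, "plateau")
  tab <- generate_table(spec)
  expect_equal(nrow(tab$values), 8L)
  # baseline + scale land on the measurement scale
  expect_gt(mean(tab$values[1:5, "high"]), mean(tab$values[1:5, "unexposed"]))
})

test_that("rejection rates increase with effect magnitude", {
  weak <- simulate_operating_characteristics(archetype_spec(magnitude = 0),
                                             replicates = 60, seed = 15)
  strong <- simulate_operating_characteristics(archetype_spec(magnitude = 3),
                                               replicates = 60, seed = 15)
  expect_identical(weak$index, strong$index)
  for (i in seq_len(nrow(weak)))
    expect_gt(strong$rejection_rate[i], weak$rejection_rate[i])
  expect_equal(strong$rejection_rate["multipurpose" == strong$index], 1)
})

test_that("invalid generator parameters are rejected", {
  expect_error(effect_pattern("plateau", magnitude = -1), "magnitude")
  expect_error(effect_pattern("plateau", scale = 0), "positive")
  expect_error(effect_pattern("custom"), "offsets")
  expect_error(generator_spec(subindices = list(s = list(n_features = 0))),
               "n_features")
})
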