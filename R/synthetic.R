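# Synthetic feature-table generator: dose-response archetypes with noise,
# for pipeline testing and operating-characteristic simulation.

# Canonical per-shape offset vectors for three exposure groups
# (reference, low, high), in within-feature SD-like units before `magnitude`
# scaling.  "plateau" is the high-dose-only kidney-damage archetype,
# "inverted_u" the low-dose-peak goitrogenic archetype, "monotonic_up" the
# dose-related immune-activation archetype.  For k != 3 groups the vectors
# are linearly interpolated along the dose axis.
.pattern_shapes <- list(
  null           = c(0, 0, 0),
  monotonic_up   = c(0, 0.5, 1),
  monotonic_down = c(1, 0.5, 0),
  u_shaped       = c(0, -1, -0.2),
  inverted_u     = c(0, 1, 0.2),
  plateau        = c(0, 0, 1)
)

pattern_offsets <- function(shape, k = 3L) {
  base <- .pattern_shapes[[shape]]
  if (is.null(base)) stop("unknown pattern shape: ", shape)
  if (k == 3L) return(base)
  stats::approx(seq(0, 1, length.out = 3L), base,
                xout = seq(0, 1, length.out = k))$y
}

#' Describe one feature's dose-response pattern
#'
#' @param shape one of `"null"`, `"monotonic_up"`, `"monotonic_down"`,
#'   `"u_shaped"`, `"inverted_u"`, `"plateau"`, or `"custom"` with explicit
#'   `offsets`.
#' @param magnitude non-negative effect size multiplying the shape's unit
#'   offsets (roughly the range of the group effects in noise-SD units when
#'   `scale = 1`).
#' @param baseline value of the reference group before noise.
#' @param scale positive scalar mapping the dimensionless offsets onto the
#'   feature's measurement scale.
#' @param offsets optional explicit per-group offset vector (overrides
#'   `shape`'s canonical vector; still scaled by `magnitude`).
#' @return An object of class `"effect_pattern"`.
#' @export
#' @examples
#' effect_pattern("inverted_u", magnitude = 2, baseline = 10, scale = 5)
effect_pattern <- function(shape = "null", magnitude = 1, baseline = 0,
                           scale = 1, offsets = NULL) {
  if (is.null(offsets)) {
    shape <- match.arg(shape, c(names(.pattern_shapes), "custom"))
    if (shape == "custom") stop("shape = \"custom\" requires `offsets`")
  } else shape <- "custom"
  if (magnitude < 0) stop("`magnitude` must be >= 0")
  if (scale <= 0) stop("`scale` must be positive")
  if (shape == "null" && magnitude != 0) magnitude <- 0  # null means null
  structure(list(shape = shape, magnitude = magnitude, baseline = baseline,
                 scale = scale, offsets = offsets),
            class = "effect_pattern")
}

# Decrease-under-toxicity archetypes carry direction -1 in the generated
# table, mirroring how a pathologist would tag such endpoints.
pattern_direction <- function(pattern) {
  if (pattern$shape %in% c("monotonic_down", "u_shaped")) -1L else 1L
}

#' Specify a synthetic study
#'
#' @param groups character vector of group labels in exposure order
#'   (reference first); default three groups.
#' @param subindices named list: subindex label -> list with `n_features`
#'   (>= 1), `pattern` (an [effect_pattern()] or list of them, recycled over
#'   the features) and `noise_sd` (>= 0, SD of the zero-mean Gaussian noise
#'   added to each representative value).
#' @param seed optional default RNG seed for [generate_table()].
#' @return An object of class `"generator_spec"`.
#' @export
#' @examples
#' spec <- generator_spec(
#'   subindices = list(
#'     nephrotoxic = list(n_features = 5,
#'                        pattern = effect_pattern("plateau", 2),
#'                        noise_sd = 0.3),
#'     immunotoxic = list(n_features = 3,
#'                        pattern = effect_pattern("monotonic_up", 2),
#'                        noise_sd = 0.3)))
#' generate_table(spec, seed = 1)
generator_spec <- function(groups = c("unexposed", "low", "high"),
                           subindices, seed = NULL) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (!length(subindices) || is.null(names(subindices)))
    stop("`subindices` must be a non-empty named list")
  for (s in names(subindices)) {
    sub <- subindices[[s]]
    if (is.null(sub$n_features) || sub$n_features < 1L)
      stop("subindex '", s, "': `n_features` must be >= 1")
    if (is.null(sub$noise_sd)) subindices[[s]]$noise_sd <- 0
    if (subindices[[s]]$noise_sd < 0) stop("`noise_sd` must be >= 0")
    if (is.null(sub$pattern)) subindices[[s]]$pattern <- effect_pattern()
  }
  structure(list(groups = groups, subindices = subindices, seed = seed),
            class = "generator_spec")
}

#' Generate a synthetic feature table
#'
#' Each feature's representative value in group g is
#' `baseline + scale * magnitude * offset_g + noise`, with the offsets given
#' by the feature's dose-response archetype and noise drawn i.i.d.
#' `N(0, noise_sd^2)`.  Deterministic given the seed.  Directions are
#' assigned from the pattern shape (decrease-under-toxicity shapes get -1).
#'
#' @param spec a [generator_spec()].
#' @param seed integer RNG seed (overrides `spec$seed`).
#' @return A [feature_table()].
#' @export
generate_table <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(seed)) seed <- spec$seed
  k <- length(spec$groups)
  with_seed(seed, function() {
    rows <- list(); subindex <- direction <- character(0)
    for (s in names(spec$subindices)) {
      sub <- spec$subindices[[s]]
      pats <- if (inherits(sub$pattern, "effect_pattern"))
        rep(list(sub$pattern), sub$n_features)
      else rep_len(sub$pattern, sub$n_features)
      for (i in seq_len(sub$n_features)) {
        p <- pats[[i]]
        off <- if (!is.null(p$offsets)) rep_len(p$offsets, k)
               else pattern_offsets(p$shape, k)
        v <- p$baseline + p$scale * p$magnitude * off +
          stats::rnorm(k, 0, sub$noise_sd)
        nm <- sprintf("%s_f%02d", s, i)
        rows[[nm]] <- v
        subindex <- c(subindex, s)
        direction <- c(direction, pattern_direction(p))
      }
    }
    vals <- do.call(rbind, rows)
    colnames(vals) <- spec$groups
    feature_table(vals, subindex = subindex,
                  direction = as.integer(direction))
  })
}

#' Simulate operating characteristics of the index pipeline
#'
#' Repeatedly generates tables from a spec, runs the z-score/pooling/
#' Kruskal-Wallis pipeline on each, and reports the fraction of replicates
#' whose asymptotic p falls below `alpha`, per subindex and for the
#' multipurpose index.  Constant features (possible under `noise_sd = 0`)
#' make a replicate fail; such replicates are dropped and counted.
#'
#' @param spec a [generator_spec()].
#' @param replicates number of generated tables (>= 100 for stable rates).
#' @param alpha rejection level (default 0.05).
#' @param seed integer RNG seed.
#' @return A data frame with one row per index: `index`, `rejections`,
#'   `replicates_used`, `rejection_rate`.
#' @export
simulate_operating_characteristics <- function(spec, replicates = 200L,
                                               alpha = 0.05, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"), replicates >= 1L)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  labels <- c(names(spec$subindices), "multipurpose")
  rej <- stats::setNames(integer(length(labels)), labels)
  used <- 0L
  seeds <- with_seed(seed, function()
    sample.int(.Machine$integer.max - 1L, replicates))
  for (b in seq_len(replicates)) {
    tab <- generate_table(spec, seed = seeds[b])
    gs <- tryCatch(build_group_samples(zscore_table(tab)),
                   error = function(e) NULL)
    if (is.null(gs)) next
    used <- used + 1L
    for (lab in labels) {
      kw <- kruskal_wallis(gs[[lab]])
      if (asymptotic_p(kw$H, kw$df) < alpha)
        rej[lab] <- rej[lab] + 1L
    }
  }
  if (used == 0L) stop("every generated replicate was degenerate")
  data.frame(index = labels, rejections = as.integer(rej),
             replicates_used = used,
             rejection_rate = as.numeric(rej) / used,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a generator spec from YAML
#'
#' Expected schema: top-level `groups` (list of labels), `seed` (optional)
#' and `subindices` (map: label -> `n_features`, `noise_sd`, `pattern` with
#' `shape`, `magnitude`, `baseline`, `scale`, optional `offsets`).
#'
#' @param path YAML file path.
#' @return A [generator_spec()].
#' @export
read_generator_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$subindices)) stop("generator YAML needs `subindices`")
  subs <- lapply(y$subindices, function(s) {
    p <- s$pattern
    pat <- if (is.null(p)) effect_pattern()
      else effect_pattern(shape = if (is.null(p$shape)) "custom" else p$shape,
                          magnitude = if (is.null(p$magnitude)) 1 else p$magnitude,
                          baseline = if (is.null(p$baseline)) 0 else p$baseline,
                          scale = if (is.null(p$scale)) 1 else p$scale,
                          offsets = if (is.null(p$offsets)) NULL
                                    else as.numeric(p$offsets))
    list(n_features = s$n_features, pattern = pat,
         noise_sd = if (is.null(s$noise_sd)) 0 else s$noise_sd)
  })
  generator_spec(groups = if (is.null(y$groups))
                   c("unexposed", "low", "high") else unlist(y$groups),
                 subindices = subs, seed = y$seed)
}
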