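# Z-scoring across group representative values and hierarchical pooling.

#' Z-score one feature across its group representative values
#'
#' Standardises the per-group representative values of a single feature:
#' `z_g = direction * (X_g - mu) / sigma`, with `mu` the mean and `sigma` the
#' *sample* (n-1 denominator) standard deviation across groups, both computed
#' on the raw values before the direction sign is applied.
#'
#' Tie structure is load-bearing downstream (the rank tests apply tie
#' corrections), so features whose group values follow affinely equivalent
#' patterns must yield *bitwise identical* z rows — e.g. every `(x, x, y)`
#' feature must give exactly `(-1/sqrt(3), -1/sqrt(3), 2/sqrt(3))`.  Naive
#' floating-point standardisation breaks such ties in the last ulp, so the
#' values are first mapped affinely onto the unit interval (a mathematical
#' no-op for z-scores, exact in floating point for shared patterns) and
#' standardised there.  No jitter is ever added.
#'
#' @param values numeric vector of per-group representative values (length
#'   >= 2), optionally named by group.
#' @param direction +1 or -1; applied as a final sign flip.
#' @return A list with `z` (named numeric vector), `mu` and `sigma` (raw-scale
#'   mean and sample SD).
#' @section Errors: all-equal values have `sigma = 0` and raise a condition of
#'   class `"mbi_constant_feature"`; [zscore_table()] can be told to drop such
#'   features with a warning instead.
#' @export
#' @examples
#' zscore_feature(c(228, 228, 286))         # the pedicel-width worked example
#' zscore_feature(c(829, 295, 461), -1)     # a decrease-under-toxicity endpoint
zscore_feature <- function(values, direction = 1) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two groups")
  if (any(!is.finite(values))) stop("non-finite representative value")
  if (!direction %in% c(-1, 1)) stop("`direction` must be +1 or -1")
  lo <- min(values); hi <- max(values)
  if (lo == hi)
    stop(structure(class = c("mbi_constant_feature", "error", "condition"),
                   list(message = "constant feature: zero standard deviation across groups",
                        call = sys.call(-1L))))
  u <- (values - lo) / (hi - lo)          # affine canonical form, z-invariant
  z <- direction * (u - mean(u)) / stats::sd(u)
  names(z) <- names(values)
  list(z = z, mu = mean(values), sigma = stats::sd(values))
}

#' Z-score every feature of a table
#'
#' Applies [zscore_feature()] row-wise, producing the direction-aligned
#' standardized score matrix that feeds the subindex pooling and the radar
#' plot.
#'
#' @param table a [feature_table()].
#' @param on_constant `"error"` (default) to fail on a zero-variance feature,
#'   or `"drop"` to remove it with a warning.
#' @return An object of class `"zscore_matrix"`: a list with `z` (features x
#'   groups matrix of dimensionless scores), `mu`, `sigma` (per-feature
#'   raw-scale scalars), `meta` and `groups` as in the input table.
#' @export
#' @examples
#' path <- system.file("extdata", "table1_carp_pfoa.csv", package = "mbindex")
#' zm <- zscore_table(read_feature_table(path))
#' round(zm$z, 2)
zscore_table <- function(table, on_constant = c("error", "drop")) {
  stopifnot(inherits(table, "feature_table"))
  on_constant <- match.arg(on_constant)
  n <- nrow(table$values)
  z <- matrix(NA_real_, n, length(table$groups),
              dimnames = dimnames(table$values))
  mu <- sigma <- stats::setNames(numeric(n), rownames(table$values))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    res <- tryCatch(zscore_feature(table$values[i, ],
                                   table$meta$direction[i]),
                    mbi_constant_feature = function(e) e)
    if (inherits(res, "mbi_constant_feature")) {
      if (on_constant == "error")
        stop("feature '", table$meta$feature[i],
             "' is constant across groups (sigma = 0); ",
             "use on_constant = \"drop\" to discard it")
      warning("dropping constant feature '", table$meta$feature[i], "'")
      keep[i] <- FALSE
    } else {
      z[i, ] <- res$z
      mu[i] <- res$mu
      sigma[i] <- res$sigma
    }
  }
  structure(list(z = z[keep, , drop = FALSE], mu = mu[keep],
                 sigma = sigma[keep],
                 meta = table$meta[keep, , drop = FALSE],
                 groups = table$groups),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Z-score matrix: %d features x %d groups\n",
              nrow(x$z), length(x$groups)))
  print(round(x$z, digits), ...)
  invisible(x)
}

#' Write a z-score matrix to CSV
#'
#' The numeric source layer of the radar plot: one row per feature with its
#' subindex, direction, per-group z-scores, and the raw-scale `mu`/`sigma`.
#'
#' @param x a [zscore_table()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zscores <- function(x, path) {
  stopifnot(inherits(x, "zscore_matrix"))
  out <- data.frame(feature = x$meta$feature, subindex = x$meta$subindex,
                    direction = x$meta$direction,
                    as.data.frame(x$z, row.names = NULL),
                    mu = as.numeric(x$mu), sigma = as.numeric(x$sigma),
                    check.names = FALSE)
  names(out)[3L + seq_along(x$groups)] <- x$groups
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Pool z-scores into per-index replicate sets
#'
#' Features serve as replicates: for each subindex (and for the multipurpose
#' index, the union of all subindices) the member features' z-scores are
#' pooled per group, in table feature order.
#'
#' @param zmat a [zscore_table()] result (or a [feature_table()], which is
#'   z-scored first).
#' @param hierarchy an [validate_hierarchy()] result; computed from the table
#'   metadata when omitted.
#' @param multipurpose_label label for the global index (default
#'   `"multipurpose"`).
#' @return A named list of `"group_samples"` objects, one per subindex plus
#'   the multipurpose set.  Each has `index_label` and `samples` (named list,
#'   group -> numeric vector of z replicates, one per member feature).
#' @export
#' @examples
#' path <- system.file("extdata", "table1_carp_pfoa.csv", package = "mbindex")
#' gs <- build_group_samples(zscore_table(read_feature_table(path)))
#' lengths(gs$multipurpose$samples)
build_group_samples <- function(zmat, hierarchy = NULL,
                                multipurpose_label = "multipurpose") {
  if (inherits(zmat, "feature_table")) zmat <- zscore_table(zmat)
  stopifnot(inherits(zmat, "zscore_matrix"))
  if (is.null(hierarchy)) {
    subs <- split(zmat$meta$feature,
                  factor(zmat$meta$subindex, levels = unique(zmat$meta$subindex)))
    hierarchy <- structure(list(subindices = subs,
                                multipurpose = zmat$meta$feature),
                           class = "index_hierarchy")
  }
  stopifnot(inherits(hierarchy, "index_hierarchy"))
  missing <- setdiff(hierarchy$multipurpose, rownames(zmat$z))
  if (length(missing))
    stop("hierarchy names feature(s) absent from the z matrix: ",
         paste(missing, collapse = ", "))
  if (multipurpose_label %in% names(hierarchy$subindices))
    stop("`multipurpose_label` collides with a subindex label")

  make_one <- function(label, feats) {
    samples <- lapply(zmat$groups, function(g) {
      stats::setNames(zmat$z[feats, g], feats)
    })
    names(samples) <- zmat$groups
    structure(list(index_label = label, samples = samples),
              class = "group_samples")
  }
  out <- lapply(names(hierarchy$subindices), function(s)
    make_one(s, hierarchy$subindices[[s]]))
  names(out) <- names(hierarchy$subindices)
  out[[multipurpose_label]] <- make_one(multipurpose_label,
                                        hierarchy$multipurpose)
  out
}

#' @export
print.group_samples <- function(x, ...) {
  cat(sprintf("Group samples for index '%s': %d replicates per group\n",
              x$index_label, length(x$samples[[1L]])))
  print(do.call(cbind, x$samples), ...)
  invisible(x)
}
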