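# Domain types for feature tables and the subindex hierarchy.

#' Construct a feature table
#'
#' A feature table is the sole required input of the index pipeline: one
#' representative value (mean, median, ratio or factor score) per feature and
#' exposure group, with each feature assigned to exactly one subindex and
#' carrying a direction of effect.
#'
#' @param values numeric matrix of representative values, one row per feature
#'   and one column per group.  Row names (or `features`) give feature names,
#'   column names (or `groups`) give group labels in exposure order
#'   (reference/unexposed group first).
#' @param subindex character vector, one subindex label per feature (e.g.
#'   `"nephrotoxic"`; any label set is allowed).
#' @param direction integer vector of +1/-1 per feature: the sign such that
#'   `direction * raw value` increases with pathological alteration.
#'   Endpoints that *decrease* under toxic response (e.g. thyroid follicle
#'   cross-sectional area under goitrogenic activation) take -1.
#' @param units optional character vector of measurement units (documentation
#'   only).
#' @param representative_stat optional character vector labelling the summary
#'   statistic behind each value (`"mean"`, `"median"`, `"ratio"`,
#'   `"factor_score"`); documentation only, never used in computation.
#' @param weight optional numeric per-feature weight.  Defaults to 1 for every
#'   feature (equal weighting); other values are experimental.
#' @param groups,features optional character vectors overriding the dimnames
#'   of `values`.
#'
#' @return An object of class `"feature_table"`: a list with elements
#'   `values` (features x groups matrix), `meta` (per-feature data frame with
#'   columns `feature`, `subindex`, `direction`, `units`,
#'   `representative_stat`, `weight`) and `groups`.
#' @seealso [read_feature_table()], [validate_hierarchy()], [zscore_table()]
#' @export
#' @examples
#' ft <- feature_table(
#'   values = rbind(pedicel_width = c(228, 228, 286),
#'                  follicle_area = c(829, 295, 461)),
#'   subindex = c("nephrotoxic", "thyrotoxic"),
#'   direction = c(+1, -1),
#'   groups = c("unexposed", "low", "high"))
#' ft
feature_table <- function(values, subindex, direction,
                          units = NULL, representative_stat = NULL,
                          weight = NULL, groups = NULL, features = NULL) {
  values <- as.matrix(values)
  if (!is.null(features)) rownames(values) <- features
  if (!is.null(groups)) colnames(values) <- groups
  if (is.null(rownames(values)))
    stop("feature names are required (row names of `values` or `features`)")
  if (is.null(colnames(values)))
    stop("group labels are required (column names of `values` or `groups`)")
  storage.mode(values) <- "double"

  feats <- rownames(values)
  grps <- colnames(values)
  nf <- length(feats)
  if (ncol(values) < 2L)
    stop("a feature table needs at least two groups")
  if (anyDuplicated(feats))
    stop("duplicated feature name(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  if (anyDuplicated(grps))
    stop("duplicated group label(s): ",
         paste(unique(grps[duplicated(grps)]), collapse = ", "))

  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop("missing/non-finite cell(s): ",
         paste(sprintf("%s @ %s", feats[bad[, 1L]], grps[bad[, 2L]]),
               collapse = "; "))
  }

  subindex <- rep_len(as.character(subindex), nf)
  direction <- rep_len(direction, nf)
  if (!all(direction %in% c(-1, 1)))
    stop("`direction` must be +1 or -1 for every feature")
  units <- rep_len(if (is.null(units)) "" else as.character(units), nf)
  representative_stat <-
    rep_len(if (is.null(representative_stat)) "" else
            as.character(representative_stat), nf)
  weight <- rep_len(if (is.null(weight)) 1 else as.numeric(weight), nf)
  if (any(!is.finite(weight) | weight <= 0))
    stop("`weight` must be positive and finite")
  if (any(weight != 1))
    warning("non-unit feature weights are experimental; ",
            "the reference analysis uses equal weighting")

  meta <- data.frame(feature = feats, subindex = subindex,
                     direction = as.integer(direction), units = units,
                     representative_stat = representative_stat,
                     weight = weight, stringsAsFactors = FALSE,
                     row.names = NULL)
  structure(list(values = values, meta = meta, groups = grps),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d features x %d groups\n",
              nrow(x$values), length(x$groups)))
  cat("Groups:", paste(x$groups, collapse = ", "), "\n")
  tab <- table(x$meta$subindex)
  cat("Subindices:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  print(cbind(x$meta[, c("subindex", "direction")],
              as.data.frame(x$values)), ...)
  invisible(x)
}

#' Read a feature table from CSV
#'
#' Expected header: `feature,subindex,direction,units,representative_stat,`
#' followed by one column per group.  An optional `weight` column is honoured.
#' Values use the decimal point; the file is UTF-8.
#'
#' @param path path to the CSV file.
#' @param groups optional character vector selecting and ordering the group
#'   columns (reference group first).  Defaults to the file's column order.
#' @param direction_overrides optional named numeric vector
#'   (feature name -> +1/-1) replacing the `direction` column for the named
#'   features.
#' @return A [feature_table()].
#' @export
#' @examples
#' path <- system.file("extdata", "table1_carp_pfoa.csv", package = "mbindex")
#' ft <- read_feature_table(path)
#' table(ft$meta$subindex)
read_feature_table <- function(path, groups = NULL,
                               direction_overrides = NULL) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  required <- c("feature", "subindex", "direction")
  if (!all(required %in% names(df)))
    stop("feature-table CSV must have columns ",
         paste(required, collapse = ", "))
  known <- c("feature", "subindex", "direction", "units",
             "representative_stat", "weight")
  group_cols <- setdiff(names(df), known)
  if (is.null(groups)) groups <- group_cols
  missing_groups <- setdiff(groups, group_cols)
  if (length(missing_groups))
    stop("group column(s) not in file: ",
         paste(missing_groups, collapse = ", "))

  vals <- matrix(NA_real_, nrow(df), length(groups),
                 dimnames = list(df$feature, groups))
  for (g in groups) {
    cell <- df[[g]]
    blank <- is.na(cell) | !nzchar(trimws(cell))
    if (any(blank))
      stop("empty cell(s): ",
           paste(sprintf("feature '%s' @ group '%s'", df$feature[blank], g),
                 collapse = "; "))
    num <- suppressWarnings(as.numeric(cell))
    if (anyNA(num))
      stop("non-numeric cell(s): ",
           paste(sprintf("feature '%s' @ group '%s'",
                         df$feature[is.na(num)], g), collapse = "; "))
    vals[, g] <- num
  }

  direction <- suppressWarnings(as.numeric(df$direction))
  if (anyNA(direction) || !all(direction %in% c(-1, 1)))
    stop("`direction` column must be +1 or -1 for every feature")
  if (!is.null(direction_overrides)) {
    unknown <- setdiff(names(direction_overrides), df$feature)
    if (length(unknown))
      stop("direction override for unknown feature(s): ",
           paste(unknown, collapse = ", "))
    direction[match(names(direction_overrides), df$feature)] <-
      direction_overrides
  }

  feature_table(vals, subindex = df$subindex, direction = direction,
                units = df$units, representative_stat = df$representative_stat,
                weight = if ("weight" %in% names(df))
                  as.numeric(df$weight) else NULL)
}

#' Write a feature table to CSV
#'
#' Values are serialised with 17 significant digits so that
#' `read_feature_table(write_feature_table(x, f))` round-trips every double
#' bit-identically.
#'
#' @param x a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  num <- apply(x$values, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1L)  # single feature
  out <- cbind(x$meta[, c("feature", "subindex", "direction", "units",
                          "representative_stat", "weight")],
               as.data.frame(num, stringsAsFactors = FALSE))
  names(out)[-(1:6)] <- x$groups
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate the subindex hierarchy of a feature table
#'
#' Checks that every feature belongs to exactly one subindex and assembles the
#' hierarchy: one replicate set per subindex plus the multipurpose index as
#' their disjoint union (individual features serve as replicates within each
#' subindex).
#'
#' @param table a [feature_table()].
#' @return An object of class `"index_hierarchy"`: a list with `subindices`
#'   (named list, subindex label -> feature names) and `multipurpose`
#'   (character vector of all features, in table order).
#' @export
#' @examples
#' path <- system.file("extdata", "table1_carp_pfoa.csv", package = "mbindex")
#' h <- validate_hierarchy(read_feature_table(path))
#' lengths(h$subindices)
validate_hierarchy <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  meta <- table$meta
  if (anyDuplicated(meta$feature))
    stop("duplicated feature name(s): ",
         paste(unique(meta$feature[duplicated(meta$feature)]), collapse = ", "))
  subs <- split(meta$feature, factor(meta$subindex,
                                     levels = unique(meta$subindex)))
  if (any(lengths(subs) == 0L))
    stop("empty subindex declared")
  multipurpose <- meta$feature
  # disjoint-union invariant: each feature sits in exactly one subindex
  stopifnot(sum(lengths(subs)) == length(multipurpose))
  structure(list(subindices = subs, multipurpose = multipurpose),
            class = "index_hierarchy")
}

#' @export
print.index_hierarchy <- function(x, ...) {
  cat("Index hierarchy\n")
  for (s in names(x$subindices))
    cat(sprintf("  %s: %s\n", s, paste(x$subindices[[s]], collapse = ", ")))
  cat(sprintf("  multipurpose: %d features\n", length(x$multipurpose)))
  invisible(x)
}
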