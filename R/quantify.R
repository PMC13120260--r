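# Computational cores of the two de-novo morphometric quantifications:
# area fraction from binary ROI masks and effete-cell proportion from counts.

#' Area fraction of a classified region within an ROI
#'
#' The ratio of classified (e.g. vesiculated cytoplasm) pixel area to total
#' ROI (e.g. total cytoplasm) pixel area, from a pair of aligned binary
#' masks.  Pixel classification/segmentation itself is out of scope: inputs
#' are already-binary rasters.
#'
#' @param class_mask logical (or 0/1) matrix marking classified pixels.
#' @param total_mask logical (or 0/1) matrix of the same shape marking the
#'   ROI; every classified pixel must lie inside it.
#' @return The proportion in `[0, 1]`.
#' @export
#' @examples
#' total <- matrix(TRUE, 10, 10)
#' cls <- total; cls[6:10, ] <- FALSE
#' area_fraction(cls, total)  # 0.5
area_fraction <- function(class_mask, total_mask) {
  class_mask <- as_binary_mask(class_mask)
  total_mask <- as_binary_mask(total_mask)
  if (!identical(dim(class_mask), dim(total_mask)))
    stop("mask shapes differ: ", paste(dim(class_mask), collapse = "x"),
         " vs ", paste(dim(total_mask), collapse = "x"))
  n_total <- sum(total_mask)
  if (n_total == 0L) stop("empty total mask: no ROI pixels")
  if (any(class_mask & !total_mask))
    stop("classified pixel(s) outside the total ROI mask")
  sum(class_mask) / n_total
}

as_binary_mask <- function(m) {
  if (is.logical(m)) {
    if (anyNA(m)) stop("mask contains NA")
    return(m)
  }
  if (is.numeric(m)) {
    if (anyNA(m) || !all(m %in% c(0, 1)))
      stop("numeric mask must contain only 0 and 1")
    return(array(m == 1, dim = dim(m)))
  }
  stop("mask must be a logical or 0/1 numeric matrix")
}

#' Proportion of effete cells
#'
#' Effete cells (those that have fully expelled their cytoplasmic content)
#' relative to all cells counted in the micrographs.
#'
#' @param effete non-negative integer count of effete cells.
#' @param total positive integer count of all cells.
#' @return `effete / total`, in `[0, 1]`.
#' @export
#' @examples
#' effete_proportion(7, 20)  # 0.35
effete_proportion <- function(effete, total) {
  stopifnot(length(effete) == 1L, length(total) == 1L)
  if (!is.finite(effete) || !is.finite(total) ||
      effete != round(effete) || total != round(total))
    stop("counts must be integers")
  if (total <= 0) stop("total count must be positive")
  if (effete < 0 || effete > total)
    stop("effete count must lie in [0, total]")
  effete / total
}

#' Read a binary mask from file
#'
#' Accepts greyscale/bilevel PNG (requires the `png` package; pixels > 0.5
#' are foreground) or a plain-text raster: CSV of 0/1, or ASCII PBM (`P1`).
#'
#' @param path path to the mask file.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG masks requires the 'png' package")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel
    return(img > 0.5)
  }
  if (ext %in% c("pbm", "pnm")) {
    tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    if (tok[1L] != "P1") stop("only ASCII PBM (P1) rasters are supported")
    w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
    bits <- as.integer(unlist(strsplit(paste(tok[-(1:3)], collapse = ""), "")))
    if (length(bits) != w * h) stop("PBM pixel count mismatch")
    return(matrix(bits == 1L, nrow = h, ncol = w, byrow = TRUE))
  }
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  as_binary_mask(unname(m))
}

#' Area-fraction feature row from per-group mask sets
#'
#' Computes one representative value per group from >= 1 ROI mask pairs and
#' returns it as a single-feature [feature_table()] row that can be merged
#' into an analysis table.  ROIs are treated as replicates: the default
#' aggregates with the unweighted mean of per-ROI fractions; `"pixel_pooled"`
#' instead pools pixel counts across ROIs before dividing.
#'
#' @param mask_sets named list (one element per group, in exposure order) of
#'   lists of mask pairs; each pair is `list(class = , total = )`.
#' @param name feature name.
#' @param subindex subindex label.
#' @param direction +1 or -1 (default +1).
#' @param units,representative_stat metadata (defaults `"ratio"`).
#' @param aggregate `"roi_mean"` (default) or `"pixel_pooled"`.
#' @return A one-row [feature_table()].
#' @export
masks_to_feature_row <- function(mask_sets, name, subindex, direction = 1,
                                 units = "", representative_stat = "ratio",
                                 aggregate = c("roi_mean", "pixel_pooled")) {
  aggregate <- match.arg(aggregate)
  if (is.null(names(mask_sets)) || any(!nzchar(names(mask_sets))))
    stop("`mask_sets` must be named by group")
  if (any(lengths(mask_sets) == 0L))
    stop("group(s) with zero mask pairs: ",
         paste(names(mask_sets)[lengths(mask_sets) == 0L], collapse = ", "))
  vals <- vapply(mask_sets, function(pairs) {
    fr <- vapply(pairs, function(p) area_fraction(p$class, p$total),
                 numeric(1L))
    if (aggregate == "roi_mean") mean(fr)
    else sum(vapply(pairs, function(p) sum(as_binary_mask(p$class)),
                    numeric(1L))) /
         sum(vapply(pairs, function(p) sum(as_binary_mask(p$total)),
                    numeric(1L)))
  }, numeric(1L))
  feature_table(matrix(vals, nrow = 1L,
                       dimnames = list(name, names(mask_sets))),
                subindex = subindex, direction = direction, units = units,
                representative_stat = representative_stat)
}
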