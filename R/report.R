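# Radar-plot rendering of the z-score matrix, report export, and the
# end-to-end pipeline driver.

#' Radar plot of a z-score matrix
#'
#' One closed polygon per exposure group over one axis per feature, with the
#' features of each subindex occupying contiguous angular sectors (axis order
#' = table row order by default).  The figure is a view of the z-score
#' matrix: the plotted radii equal the z entries exactly, never a
#' recomputation.
#'
#' @param zmat a [zscore_table()] result.
#' @param path output file; `NULL` draws on the current device.
#' @param format `"svg"` or `"png"` (used when `path` is given; default from
#'   the file extension, falling back to SVG).
#' @param zmax radial limit; default `ceiling(max(abs(z)) * 10) / 10`, so the
#'   axis range is symmetric and nothing is clipped.
#' @param colors one colour per group.
#' @param width,height device size in inches.
#' @param main plot title.
#' @return Invisibly, an object of class `"radar_spec"` with the exact data
#'   layer: `axes` (feature names), `subindex` (per axis), `series` (features
#'   x groups matrix, identical to `zmat$z`), `zmax` and `angles` (radians,
#'   one per axis).
#' @export
#' @examples
#' path <- system.file("extdata", "table1_carp_pfoa.csv", package = "mbindex")
#' zm <- zscore_table(read_feature_table(path))
#' rs <- render_radar(zm, path = file.path(tempdir(), "radar.svg"))
#' rs$zmax
render_radar <- function(zmat, path = NULL, format = NULL, zmax = NULL,
                         colors = NULL, width = 8, height = 8,
                         main = "Z-scored features by subindex") {
  stopifnot(inherits(zmat, "zscore_matrix"))
  z <- zmat$z
  nf <- nrow(z)
  if (nf < 3L)
    stop("a radar polygon needs >= 3 feature axes; ",
         "with fewer features use a bar chart instead")
  if (is.null(zmax)) zmax <- ceiling(max(abs(z)) * 10) / 10
  if (zmax <= 0) zmax <- 1
  angles <- pi / 2 - (seq_len(nf) - 1L) * 2 * pi / nf  # clockwise from 12
  spec <- structure(list(axes = rownames(z), subindex = zmat$meta$subindex,
                         series = z, groups = zmat$groups, zmax = zmax,
                         angles = angles),
                    class = "radar_spec")
  if (is.null(colors))
    colors <- grDevices::hcl.colors(max(3L, ncol(z)), "Dark 3")[seq_len(ncol(z))]

  draw <- function() {
    op <- graphics::par(mar = c(1, 1, 3, 1), xpd = NA)
    on.exit(graphics::par(op))
    graphics::plot.new()
    graphics::plot.window(c(-1.45, 1.45), c(-1.45, 1.45), asp = 1)
    graphics::title(main = main)
    # grid rings; radius 0.5 marks z = 0 (axes span [-zmax, +zmax])
    for (f in c(0.25, 0.5, 0.75, 1)) {
      tt <- seq(0, 2 * pi, length.out = 181L)
      graphics::lines(f * cos(tt), f * sin(tt), col = "grey80",
                      lty = if (f == 0.5) 1 else 3)
    }
    graphics::text(0, 0.5, "z = 0", col = "grey50", cex = 0.6, pos = 3)
    for (i in seq_len(nf)) {
      graphics::lines(c(0, cos(angles[i])), c(0, sin(angles[i])),
                      col = "grey85")
      lab_r <- 1.08
      graphics::text(lab_r * cos(angles[i]), lab_r * sin(angles[i]),
                     rownames(z)[i], cex = 0.6,
                     srt = 0, adj = c(0.5, 0.5))
    }
    # subindex sector labels at each block's mid angle
    blocks <- rle(zmat$meta$subindex)
    ends <- cumsum(blocks$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (b in seq_along(blocks$values)) {
      mid <- mean(angles[c(starts[b], ends[b])])
      graphics::text(1.32 * cos(mid), 1.32 * sin(mid), blocks$values[b],
                     cex = 0.85, font = 2)
    }
    radius <- function(v) (v + zmax) / (2 * zmax)  # [-zmax, zmax] -> [0, 1]
    for (j in seq_len(ncol(z))) {
      rr <- radius(z[, j])
      xs <- rr * cos(angles); ys <- rr * sin(angles)
      graphics::polygon(c(xs, xs[1L]), c(ys, ys[1L]), border = colors[j],
                        col = grDevices::adjustcolor(colors[j], 0.15),
                        lwd = 2)
    }
    graphics::legend("bottomright", legend = colnames(z), col = colors,
                     lwd = 2, bty = "n", cex = 0.8)
  }

  if (is.null(path)) {
    draw()
  } else {
    if (is.null(format)) {
      ext <- tolower(tools::file_ext(path))
      format <- if (ext %in% c("svg", "png")) ext else "svg"
    }
    format <- match.arg(format, c("svg", "png"))
    if (format == "svg") grDevices::svg(path, width = width, height = height)
    else grDevices::png(path, width = width, height = height, units = "in",
                        res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  }
  invisible(spec)
}

#' Read a run configuration from YAML
#'
#' Schema (all keys optional unless noted): `features` (CSV path,
#' required), `groups` (ordered labels, reference first),
#' `direction_overrides` (map feature -> +1/-1), `mc_reps` (Monte Carlo B,
#' default 10000), `seed` (default 1), `alpha` (default 0.05),
#' `eps_bootstrap` (default 2000), `out_dir` (default `"mbindex_out"`).
#'
#' @param path YAML file path.
#' @return A validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  # a relative feature path is resolved against the config file's directory
  if (!is.null(y$features) && !file.exists(y$features)) {
    candidate <- file.path(dirname(path), y$features)
    if (file.exists(candidate)) y$features <- candidate
  }
  run_config(features = y$features,
             groups = if (is.null(y$groups)) NULL else unlist(y$groups),
             direction_overrides = if (is.null(y$direction_overrides)) NULL
               else unlist(y$direction_overrides),
             mc_reps = if (is.null(y$mc_reps)) 10000L else y$mc_reps,
             seed = if (is.null(y$seed)) 1L else y$seed,
             alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
             eps_bootstrap = if (is.null(y$eps_bootstrap)) 2000L
               else y$eps_bootstrap,
             out_dir = if (is.null(y$out_dir)) "mbindex_out" else y$out_dir)
}

#' @rdname read_run_config
#' @param features feature-table CSV path.
#' @param groups,direction_overrides passed to [read_feature_table()].
#' @param mc_reps,seed,alpha,eps_bootstrap,out_dir run parameters.
#' @export
run_config <- function(features, groups = NULL, direction_overrides = NULL,
                       mc_reps = 10000L, seed = 1L, alpha = 0.05,
                       eps_bootstrap = 2000L, out_dir = "mbindex_out") {
  if (is.null(features)) stop("run config needs `features` (CSV path)")
  if (mc_reps != 0 && mc_reps < 100) stop("`mc_reps` must be 0 or >= 100")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  structure(list(features = features, groups = groups,
                 direction_overrides = direction_overrides,
                 mc_reps = as.integer(mc_reps), seed = as.integer(seed),
                 alpha = alpha, eps_bootstrap = as.integer(eps_bootstrap),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full index pipeline
#'
#' Loads and validates the feature table, z-scores it, pools the replicate
#' sets, runs the full inference layer on every index, and writes the
#' artifacts to the output directory: `zscores.csv`, `kruskal_wallis.tsv`
#' (one row per index), `pairwise.tsv` (one row per Dunn contrast),
#' `radar.svg` and `run_log.txt` (seed, B, direction vector, package
#' version).  Numeric TSVs are byte-identical across runs with the same
#' config and seed.
#'
#' @param config a [run_config()] (or a YAML path, read via
#'   [read_run_config()]).
#' @return Invisibly, a list with the `reports`, the `tables` from
#'   [summary_tables()] and the artifact `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- "load"
  withCallingHandlers({
    table <- read_feature_table(config$features, groups = config$groups,
                                direction_overrides =
                                  config$direction_overrides)
    stage <- "validate"
    validate_hierarchy(table)
    stage <- "analyse"
    reports <- analyse_table(table, B = config$mc_reps, seed = config$seed,
                             eps_boot = config$eps_bootstrap)
    zmat <- attr(reports, "zscores")
    tables <- summary_tables(reports)
    stage <- "write"
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(config$out_dir,
                       c(zscores = "zscores.csv",
                         omnibus = "kruskal_wallis.tsv",
                         pairwise = "pairwise.tsv",
                         radar = "radar.svg",
                         log = "run_log.txt"))
    names(paths) <- c("zscores", "omnibus", "pairwise", "radar", "log")
    write_zscores(zmat, paths[["zscores"]])
    write_tsv_full <- function(df, path) {
      num <- vapply(df, is.numeric, logical(1L)) &
        !vapply(df, is.integer, logical(1L))
      df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    write_tsv_full(tables$omnibus, paths[["omnibus"]])
    write_tsv_full(tables$pairwise, paths[["pairwise"]])
    render_radar(zmat, path = paths[["radar"]])
    writeLines(c(sprintf("mbindex version: %s",
                         as.character(utils::packageVersion("mbindex"))),
                 sprintf("features: %s", config$features),
                 sprintf("groups: %s", paste(table$groups, collapse = ", ")),
                 sprintf("directions: %s",
                         paste(sprintf("%s=%+d", table$meta$feature,
                                       table$meta$direction),
                               collapse = "; ")),
                 sprintf("seed: %d", config$seed),
                 sprintf("mc_reps (B): %d", config$mc_reps),
                 sprintf("alpha: %g", config$alpha),
                 sprintf("eps_bootstrap: %d", config$eps_bootstrap)),
               paths[["log"]])
    invisible(list(reports = reports, tables = tables, paths = paths))
  }, error = function(e) {
    message("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
}
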