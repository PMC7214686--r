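#' Assemble a pipeline configuration
#'
#' Collects input paths and the analysis parameters; all defaults are the
#' values used throughout the package (2 kb window, bandwidth 15 bp, 500 bp
#' active radius, 30 x 30 joint map). Can also be loaded from a YAML file
#' with [read_pipeline_config()].
#'
#' @param peaks named list of peak file paths, names among
#'   `H3K4me1`, `H3K4me3`, `H3K27me3`, `H3K27ac`.
#' @param tss TSS file path (GTF or BED6).
#' @param tpm optional abundance TSV path.
#' @param window nearest-neighbor / inclusion window in bp.
#' @param bandwidth KDE bandwidth in bp.
#' @param active_radius |d(TSS, nearest H3K4me3 center)| bound for the
#'   active call under the H3K4me1-led rule.
#' @param nbins joint-map bins per axis.
#' @param grid_step density grid step in bp.
#' @param tpm_aggregate how a merged TSS combines member TPMs.
#' @param strict escalate chromosome-name mismatch warnings to errors.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(peaks, tss, tpm = NULL, window = 2000,
                            bandwidth = 15, active_radius = 500, nbins = 30,
                            grid_step = 10, tpm_aggregate = "sum",
                            strict = FALSE) {
  stopifnot(window > 0, bandwidth > 0, active_radius > 0, nbins >= 2,
            grid_step > 0)
  if (is.null(names(peaks)) || !all(names(peaks) %in% HISTONE_MARKS))
    stop("peaks must be a named list with names among: ",
         paste(HISTONE_MARKS, collapse = ", "))
  structure(list(peaks = peaks, tss = tss, tpm = tpm, window = window,
                 bandwidth = bandwidth, active_radius = active_radius,
                 nbins = nbins, grid_step = grid_step,
                 tpm_aggregate = tpm_aggregate, strict = strict),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

require_marks <- function(cfg, marks, stage) {
  missing <- setdiff(marks, names(cfg$peaks))
  if (length(missing))
    stop(stage, " requires peak files for: ",
         paste(missing, collapse = ", "))
  for (mk in marks)
    if (!file.exists(cfg$peaks[[mk]]))
      stop(stage, ": peak file for ", mk, " not found: ", cfg$peaks[[mk]])
}

tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full promoter-shape analysis
#'
#' Executes density profiling, both classification rules, the joint 2D
#' distance map and the grouped rank tests, writing every result as TSV
#' (plus the poised peak list as BED) under `outdir`, together with a
#' manifest recording the configuration, input file checksums and package
#' version. All outputs are deterministic for fixed inputs. Every TSV
#' carries `#` header lines naming units and conventions.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @param outdir output directory, created if needed.
#' @return Named list of output paths, invisibly. Stage results are also
#'   returned in the `results` attribute.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$tss)) stop("TSS file not found: ", config$tss)
  if (config$strict) {
    op <- options(warn = 2)
    on.exit(options(op), add = TRUE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  results <- list()

  tss <- read_tss(config$tss)
  if (!is.null(config$tpm))
    tss <- add_tpm(tss, read_tpm(config$tpm), aggregate = config$tpm_aggregate)
  message("pipeline: ", nrow(tss), " TSS loaded")

  grid <- seq(-config$window, config$window, by = config$grid_step)
  peaks <- list()
  shape_rows <- list()
  for (mk in names(config$peaks)) {
    require_marks(config, mk, "density")
    peaks[[mk]] <- read_peaks(config$peaks[[mk]], mark = mk)
    d <- peak_to_tss_distances(peaks[[mk]], tss, window = config$window)
    message("density [", mk, "]: ", length(d), " peak-TSS distances, ",
            attr(d, "n_excluded"), " peaks beyond the window")
    prof <- gaussian_density(d, bandwidth = config$bandwidth, grid = grid)
    out[[paste0("density_", mk)]] <-
      write_profile(prof, file.path(outdir, paste0("density_", mk, ".tsv")),
                    label = mk)
    ss <- shape_summary(d)
    shape_rows[[mk]] <- data.frame(mark = mk,
                                   n = ss$n,
                                   n_excluded = attr(d, "n_excluded"),
                                   center_fraction = ss$center_fraction,
                                   flank_fraction = ss$flank_fraction,
                                   bimodality_ratio = ss$bimodality_ratio)
    results$profiles[[mk]] <- prof
    results$shapes[[mk]] <- ss
  }
  out$shape_summary <- tsv_with_header(
    do.call(rbind, shape_rows), file.path(outdir, "shape_summary.tsv"),
    c("per-mark distance shape summary",
      "center: |d| < 300 bp; flank: 300 <= |d| <= 1000 bp; d in bp, negative = upstream"))

  require_marks(config, c("H3K4me1", "H3K4me3", "H3K27me3"), "classify")
  poised <- poised_peaks(peaks$H3K4me3, peaks$H3K27me3)
  out$poised_peaks <- write_intervals(poised,
                                      file.path(outdir, "poised_peaks.bed"))
  message("classify: ", nrow(poised), " poised (bivalent) H3K4me3 peaks")

  calls3 <- classify_by_k4me3(tss, peaks$H3K4me3, peaks$H3K27me3,
                              window = config$window)
  calls1 <- classify_by_k4me1(tss, peaks$H3K4me1, peaks$H3K4me3,
                              peaks$H3K27me3,
                              active_radius = config$active_radius,
                              window = config$window)
  calls <- rbind(calls3, calls1)
  out$promoter_calls <- tsv_with_header(
    calls, file.path(outdir, "promoter_calls.tsv"),
    c("per-TSS promoter state calls under both rules",
      "d_* in bp (peak center to TSS, negative = upstream); bins B1: tpm<=1, B2: 1<tpm<=5, B3: 5<tpm<=10, B4: tpm>10"))
  results$calls_by_k4me3 <- calls3
  results$calls_by_k4me1 <- calls1

  jm <- joint_distance_map(tss, peaks$H3K4me1, peaks$H3K4me3,
                           window = config$window, nbins = config$nbins)
  mat <- jm$counts
  dimnames(mat) <- list(
    k4me1_bin_start = utils::head(jm$x_edges, -1),
    k4me3_bin_start = utils::head(jm$y_edges, -1))
  out$joint_map <- tsv_with_header(
    data.frame(k4me1_bin_start = rep(utils::head(jm$x_edges, -1),
                                     times = ncol(mat)),
               k4me3_bin_start = rep(utils::head(jm$y_edges, -1),
                                     each = nrow(mat)),
               count = as.vector(mat)),
    file.path(outdir, "joint_map.tsv"),
    c(paste0("joint 2D bin counts of per-TSS distances; n_tss=", jm$n_tss),
      "bin starts in bp over [-window, window], uniform edges"))
  results$joint_map <- jm

  results$group_stats <- group_stats(calls1)
  out$group_stats <- tsv_with_header(
    results$group_stats, file.path(outdir, "group_stats.tsv"),
    c("Kruskal-Wallis rank tests on |d(TSS, nearest H3K4me1 center)| in bp",
      "groups: the four expression bins, and poised vs active state"))

  manifest <- list(
    package = "promshape",
    version = as.character(utils::packageVersion("promshape")),
    config = unclass(config),
    inputs = as.list(tools::md5sum(unlist(c(config$peaks, config$tss,
                                            config$tpm)))),
    n_tss = nrow(tss))
  out$manifest <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, out$manifest)
  structure(out, results = results)
}

#' Grouped Kruskal-Wallis report for a call table
#'
#' Two analyses on |d(TSS, nearest H3K4me1)|: across the four expression
#' bins (does the shape track expression?), and poised versus active state
#' (does it track chromatin state?). Groups with no members are dropped
#' from a test; a test with fewer than 2 non-empty groups is reported with
#' NA statistics.
#'
#' @param calls data.frame from [classify_by_k4me1()].
#' @return data.frame: `analysis`, `k`, `group_sizes`, `H`, `df`, `p`.
#' @export
group_stats <- function(calls) {
  rows <- list()
  bins <- distance_by_group(calls, "expression_bin")
  g <- bins$d_abs[bins$n > 0]
  rows$bins <- kw_row("abs_d_k4me1_by_expression_bin", g)
  keep <- calls$state %in% c("poised", "active") & !is.na(calls$d_k4me1)
  g <- split(abs(calls$d_k4me1[keep]), calls$state[keep])
  rows$state <- kw_row("abs_d_k4me1_poised_vs_active", g)
  do.call(rbind, rows)
}

kw_row <- function(label, groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2)
    return(data.frame(analysis = label, k = length(groups),
                      group_sizes = paste(lengths(groups), collapse = ","),
                      H = NA_real_, df = NA_integer_, p = NA_real_))
  kw <- suppressWarnings(kruskal_wallis(groups))
  data.frame(analysis = label, k = length(groups),
             group_sizes = paste(kw$group_sizes, collapse = ","),
             H = kw$H, df = kw$df, p = kw$p_value)
}
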