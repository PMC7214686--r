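#' Configuration for the synthetic chromatin landscape
#'
#' One linear chromosome (`chrS`) carries `n_genes` evenly spaced TSS with
#' alternating strand (even index `+`, odd `-`), each assigned a ground
#' truth state. Active promoters receive an H3K4me3 peak just downstream of
#' the TSS, two H3K4me1 peaks displaced 300-1000 bp on either side, and an
#' H3K27ac peak; poised promoters receive overlapping H3K4me3 and H3K27me3
#' peaks plus a single TSS-centered H3K4me1 peak; silent promoters receive
#' no peaks. Distal background H3K4me1 peaks are placed at least 2 kb from
#' every TSS. TPM is drawn from a state-dependent model whose supports
#' overlap, so expression alone cannot separate the states.
#'
#' @param n_genes number of promoters (default 2000).
#' @param intergenic_spacing bp between consecutive TSS (default 10000);
#'   must exceed twice (max flank offset + max peak width) so neighboring
#'   promoters cannot interfere.
#' @param fraction_poised,fraction_silent state fractions (defaults 0.3 and
#'   0.1); counts are exact, `round(fraction * n_genes)`, assigned by a
#'   seeded shuffle.
#' @param flank_offset_range bp range of the active-promoter H3K4me1 flank
#'   displacement, uniform (default 300-1000).
#' @param poised_k4me1_sd sd (bp) of the TSS-centered H3K4me1 offset at
#'   poised promoters (default 100).
#' @param k4me3_offset_mean,k4me3_offset_sd normal model of the H3K4me3
#'   (and H3K27ac) center offset downstream of the TSS (default 100 / 50).
#' @param peak_width_ranges named list of bp ranges per mark.
#' @param n_background_k4me1 distal background H3K4me1 peaks (default
#'   `n_genes`).
#' @param tpm_high_meanlog,tpm_high_sdlog log-normal TPM model for active
#'   promoters (default meanlog 2, sdlog 1).
#' @param tpm_poised_zero_prob,tpm_poised_meanlog,tpm_poised_sdlog poised
#'   TPM model: a point mass at 0 (default 0.7) mixed with a low log-normal
#'   (default meanlog 0.5, sdlog 1).
#' @param seed master seed; every stage derives its own sub-stream from it
#'   so draws for one mark do not perturb another.
#' @return List of class `landscape_config`.
#' @export
landscape_config <- function(n_genes = 2000,
                             intergenic_spacing = 10000,
                             fraction_poised = 0.3,
                             fraction_silent = 0.1,
                             flank_offset_range = c(300, 1000),
                             poised_k4me1_sd = 100,
                             k4me3_offset_mean = 100,
                             k4me3_offset_sd = 50,
                             peak_width_ranges = list(
                               H3K4me1 = c(300, 700),
                               H3K4me3 = c(400, 800),
                               H3K27me3 = c(500, 1500),
                               H3K27ac = c(300, 700)),
                             n_background_k4me1 = n_genes,
                             tpm_high_meanlog = 2,
                             tpm_high_sdlog = 1,
                             tpm_poised_zero_prob = 0.7,
                             tpm_poised_meanlog = 0.5,
                             tpm_poised_sdlog = 1,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (fraction_poised < 0 || fraction_silent < 0 ||
      fraction_poised + fraction_silent > 1)
    stop("state fractions must be non-negative and sum to at most 1")
  max_off <- max(flank_offset_range, k4me3_offset_mean + 4 * k4me3_offset_sd)
  max_w <- max(vapply(peak_width_ranges, max, numeric(1)))
  if (intergenic_spacing <= 2 * (max_off + max_w))
    stop("intergenic_spacing too small: neighboring promoters could interfere",
         " (need > ", 2 * (max_off + max_w), " bp)")
  if (n_genes < 1) stop("n_genes must be >= 1")
  structure(cfg, class = "landscape_config")
}

# independent seed per stage, kept under 2^31
stage_seed <- function(seed, stage) {
  offsets <- c(states = 11L, H3K4me3 = 23L, H3K27me3 = 37L, H3K4me1 = 41L,
               H3K27ac = 53L, background = 67L, tpm = 79L)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

# interval of width w whose floor-midpoint center is exactly `center`
interval_at <- function(center, w) {
  start <- center - w %/% 2L
  cbind(start = start, end = start + w)
}

draw_width <- function(n, range) {
  as.integer(round(stats::runif(n, range[1], range[2])))
}

#' Simulate a chromatin landscape in memory
#'
#' Deterministic for a fixed config (the seed lives in the config): two
#' identical calls produce identical objects. See [landscape_config()] for
#' the generative model.
#'
#' @param config a [landscape_config()].
#' @return List of class `synthetic_landscape`: `peaks` (named list of
#'   [peak_set] per mark), `tss` (a [tss_set] with TPM attached), `tpm`
#'   (named vector), `truth` (data.frame `tss_id`, `true_state`, `tpm`,
#'   `peak_ids`), and the `config`.
#' @export
simulate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  n <- config$n_genes
  spacing <- config$intergenic_spacing
  tss_pos <- as.integer(seq_len(n) - 1) * spacing + spacing %/% 2L
  strand <- ifelse(seq_len(n) %% 2 == 1, "+", "-")   # alternating
  sgn <- ifelse(strand == "+", 1L, -1L)
  tss_id <- sprintf("tss_%05d", seq_len(n))

  set.seed(stage_seed(config$seed, "states"))
  n_poised <- round(config$fraction_poised * n)
  n_silent <- round(config$fraction_silent * n)
  state <- rep("active", n)
  perm <- sample.int(n)
  state[perm[seq_len(n_poised)]] <- "poised"
  if (n_silent > 0)
    state[perm[n_poised + seq_len(n_silent)]] <- "silent"
  poised_i <- which(state == "poised")
  active_i <- which(state == "active")

  wr <- config$peak_width_ranges
  marks <- list()
  peak_owner <- list()

  # H3K4me3: at every non-silent promoter, center offset ~ N(mean, sd)
  # downstream in gene orientation
  set.seed(stage_seed(config$seed, "H3K4me3"))
  on_i <- sort(c(active_i, poised_i))
  off3 <- round(stats::rnorm(length(on_i), config$k4me3_offset_mean,
                             config$k4me3_offset_sd))
  c3 <- tss_pos[on_i] + sgn[on_i] * as.integer(off3)
  iv3 <- interval_at(c3, draw_width(length(on_i), wr$H3K4me3))
  marks$H3K4me3 <- data.frame(start = iv3[, 1], end = iv3[, 2],
                              owner = on_i,
                              name = sprintf("k4me3_%05d", seq_along(on_i)))

  # H3K27me3: poised promoters only; forced to overlap that promoter's
  # H3K4me3 interval by >= 1 bp
  set.seed(stage_seed(config$seed, "H3K27me3"))
  j <- match(poised_i, on_i)
  shift <- as.integer(round(stats::runif(length(poised_i), -200, 200)))
  w27 <- draw_width(length(poised_i), wr$H3K27me3)
  c27 <- c3[j] + shift
  iv27 <- interval_at(c27, w27)
  # clamp into overlap with the paired H3K4me3 peak
  iv27[, 1] <- pmin(iv27[, 1], iv3[j, 2] - 1L)
  iv27[, 2] <- pmax(iv27[, 2], iv3[j, 1] + 1L)
  marks$H3K27me3 <- data.frame(start = iv27[, 1], end = iv27[, 2],
                               owner = poised_i,
                               name = sprintf("k27me3_%05d",
                                              seq_along(poised_i)))

  # H3K4me1: two flanking peaks per active promoter, one centered peak per
  # poised promoter
  set.seed(stage_seed(config$seed, "H3K4me1"))
  up_off <- round(stats::runif(length(active_i), config$flank_offset_range[1],
                               config$flank_offset_range[2]))
  dn_off <- round(stats::runif(length(active_i), config$flank_offset_range[1],
                               config$flank_offset_range[2]))
  ctr_off <- round(stats::rnorm(length(poised_i), 0, config$poised_k4me1_sd))
  cen1 <- c(tss_pos[active_i] - sgn[active_i] * as.integer(up_off),
            tss_pos[active_i] + sgn[active_i] * as.integer(dn_off),
            tss_pos[poised_i] + as.integer(ctr_off))
  own1 <- c(active_i, active_i, poised_i)
  iv1 <- interval_at(cen1, draw_width(length(cen1), wr$H3K4me1))
  marks$H3K4me1 <- data.frame(start = iv1[, 1], end = iv1[, 2], owner = own1,
                              name = sprintf("k4me1_%05d", seq_along(own1)))

  # H3K27ac: active promoters, near the TSS
  set.seed(stage_seed(config$seed, "H3K27ac"))
  offac <- round(stats::rnorm(length(active_i), config$k4me3_offset_mean,
                              config$k4me3_offset_sd))
  cac <- tss_pos[active_i] + sgn[active_i] * as.integer(offac)
  ivac <- interval_at(cac, draw_width(length(active_i), wr$H3K27ac))
  marks$H3K27ac <- data.frame(start = ivac[, 1], end = ivac[, 2],
                              owner = active_i,
                              name = sprintf("k27ac_%05d",
                                             seq_along(active_i)))

  # background H3K4me1, uniform but kept > 2 kb (plus margin) from any TSS
  set.seed(stage_seed(config$seed, "background"))
  nb <- config$n_background_k4me1
  if (nb > 0) {
    slot <- sample.int(n, nb, replace = TRUE)
    a <- floor(stats::runif(nb, 0, spacing - 4200))
    off <- ifelse(a < spacing %/% 2 - 2100, a, a + 4200)
    cb <- as.integer(slot - 1L) * spacing + as.integer(off)
    ivb <- interval_at(cb, draw_width(nb, wr$H3K4me1))
    ivb[, 1] <- pmax(ivb[, 1], 0L)
    bg <- data.frame(start = ivb[, 1], end = ivb[, 2], owner = NA_integer_,
                     name = sprintf("k4me1_bg_%05d", seq_len(nb)))
    marks$H3K4me1 <- rbind(marks$H3K4me1, bg)
  }

  set.seed(stage_seed(config$seed, "tpm"))
  tpm <- numeric(n)
  tpm[active_i] <- stats::rlnorm(length(active_i), config$tpm_high_meanlog,
                                 config$tpm_high_sdlog)
  zero <- stats::runif(length(poised_i)) < config$tpm_poised_zero_prob
  tpm[poised_i] <- ifelse(zero, 0,
                          stats::rlnorm(length(poised_i),
                                        config$tpm_poised_meanlog,
                                        config$tpm_poised_sdlog))
  tpm <- round(tpm, 4)

  peaks <- lapply(names(marks), function(mk) {
    m <- marks[[mk]]
    peak_set(rep("chrS", nrow(m)), m$start, m$end, m$name,
             score = 0, strand = ".", mark = mk, source = "synthetic")
  })
  names(peaks) <- names(marks)

  owners <- do.call(c, unname(lapply(marks, function(m)
    stats::setNames(m$owner, m$name))))
  owners <- owners[!is.na(owners)]
  by_owner <- split(names(owners), owners)
  peak_ids <- character(n)
  peak_ids[as.integer(names(by_owner))] <-
    vapply(by_owner, function(v) paste(sort(v), collapse = ","),
           character(1))

  tss <- tss_set(rep("chrS", n), tss_pos, strand, tss_id, tpm = tpm)
  truth <- data.frame(tss_id = tss_id, true_state = state, tpm = tpm,
                      peak_ids = peak_ids, stringsAsFactors = FALSE)
  structure(list(peaks = peaks, tss = tss,
                 tpm = stats::setNames(tpm, tss_id), truth = truth,
                 config = config),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("synthetic_landscape:", nrow(x$tss), "promoters on chrS (",
      paste(names(table(x$truth$true_state)),
            table(x$truth$true_state), collapse = ", "), ")\n")
  for (mk in names(x$peaks))
    cat(" ", mk, ":", nrow(x$peaks[[mk]]), "peaks\n")
  invisible(x)
}

#' Write a simulated landscape to disk
#'
#' Emits exactly the formats the readers consume: one BED file per mark,
#' the TSS as BED6 (single-base intervals), the TPM table as a
#' kallisto-style TSV (`target_id`, `tpm`), and the ground truth as TSV.
#' Output is byte-identical across runs with the same config.
#'
#' @param landscape from [simulate_landscape()], or a [landscape_config()]
#'   to simulate first.
#' @param dir output directory, created if needed.
#' @return Named list of the written paths, invisibly.
#' @export
generate_landscape <- function(landscape, dir) {
  if (inherits(landscape, "landscape_config"))
    landscape <- simulate_landscape(landscape)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (mk in names(landscape$peaks)) {
    paths[[mk]] <- file.path(dir, paste0(mk, ".bed"))
    write_intervals(landscape$peaks[[mk]], paths[[mk]])
  }
  tss <- landscape$tss
  paths$tss <- file.path(dir, "tss.bed")
  utils::write.table(
    data.frame(tss$chrom, tss$position, tss$position + 1L,
               tss$transcript_id, 0, tss$strand),
    paths$tss, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  paths$tpm <- file.path(dir, "tpm.tsv")
  utils::write.table(
    data.frame(target_id = names(landscape$tpm), tpm = landscape$tpm),
    paths$tpm, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(landscape$truth, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Force expression/state discordance into a TPM table
#'
#' Moves a chosen number of truth-poised promoters into the highest
#' expression bin (tpm > 10) and truth-active promoters into the lowest
#' (tpm <= 1), without touching any peak — the configuration needed to ask
#' whether the H3K4me1 shape tracks chromatin state or expression when the
#' two disagree. Promoters are picked deterministically in `tss_id` order.
#'
#' @param tpm named TPM vector (as in `simulate_landscape()$tpm`).
#' @param truth the matching truth data.frame.
#' @param n_poised_high poised promoters forced high (default 50).
#' @param n_active_low active promoters forced low (default 50).
#' @param high_tpm,low_tpm values used for the overrides (defaults 20, 0.5).
#' @return The modified named TPM vector.
#' @export
make_discordant_subset <- function(tpm, truth, n_poised_high = 50,
                                   n_active_low = 50, high_tpm = 20,
                                   low_tpm = 0.5) {
  poised_ids <- sort(truth$tss_id[truth$true_state == "poised"])
  active_ids <- sort(truth$tss_id[truth$true_state == "active"])
  if (n_poised_high > length(poised_ids))
    stop("requested ", n_poised_high, " poised overrides but only ",
         length(poised_ids), " poised promoters exist")
  if (n_active_low > length(active_ids))
    stop("requested ", n_active_low, " active overrides but only ",
         length(active_ids), " active promoters exist")
  tpm[poised_ids[seq_len(n_poised_high)]] <- high_tpm
  tpm[active_ids[seq_len(n_active_low)]] <- low_tpm
  tpm
}
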