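as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

subset_peaks <- function(peaks, idx) {
  out <- peaks[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, mark = attr(peaks, "mark"), source = attr(peaks, "source"),
            class = c("peak_set", "data.frame"))
}

#' Poised (bivalent) peak list by overlap
#'
#' Returns the subset of H3K4me3 peaks that overlap (>= 1 bp, half-open
#' semantics) at least one H3K27me3 peak, each reported once with its
#' original coordinates — the bivalent promoter regions carrying both the
#' activating and the Polycomb-repressive mark.
#'
#' @param k4me3,k27me3 [peak_set]s.
#' @return A [peak_set], subset of `k4me3`.
#' @export
poised_peaks <- function(k4me3, k27me3) {
  if (nrow(k4me3) == 0 || nrow(k27me3) == 0)
    return(subset_peaks(k4me3, integer(0)))
  hits <- GenomicRanges::findOverlaps(as_granges(k4me3), as_granges(k27me3),
                                      minoverlap = 1L)
  subset_peaks(k4me3, sort(unique(S4Vectors::queryHits(hits))))
}

#' H3K4me1 peaks over poised regions
#'
#' Subset of H3K4me1 peaks overlapping (>= 1 bp) any poised (bivalent)
#' peak, reported once each with original coordinates.
#'
#' @param k4me1 [peak_set] of H3K4me1 peaks.
#' @param poised [peak_set] from [poised_peaks()].
#' @return A [peak_set], subset of `k4me1`.
#' @export
poised_k4me1 <- function(k4me1, poised) {
  if (nrow(k4me1) == 0 || nrow(poised) == 0)
    return(subset_peaks(k4me1, integer(0)))
  hits <- GenomicRanges::findOverlaps(as_granges(k4me1), as_granges(poised),
                                      minoverlap = 1L)
  subset_peaks(k4me1, sort(unique(S4Vectors::queryHits(hits))))
}

new_state_calls <- function(tss, rule) {
  data.frame(tss_id = tss$transcript_id,
             state = "other",
             rule = rule,
             d_k4me1 = NA_integer_,
             d_k4me3 = NA_integer_,
             tpm = tss$tpm,
             expression_bin = assign_expression_bin(tss$tpm),
             stringsAsFactors = FALSE)
}

#' Classify TSS by the bivalency of the nearest H3K4me3 peak
#'
#' The direct rule: a TSS is `poised` when its nearest H3K4me3 peak (within
#' `window` bp) overlaps H3K27me3, `active` when a nearest H3K4me3 exists
#' but is not bivalent, and `other` when no H3K4me3 lies within the window.
#'
#' @param tss a [tss_set] (run [add_tpm()] first for expression bins).
#' @param k4me3,k27me3 [peak_set]s.
#' @param window search window in bp (default 2000).
#' @return data.frame with one row per TSS: `tss_id`, `state`, `rule`
#'   (`"by_k4me3"`), `d_k4me1` (NA here), `d_k4me3`, `tpm`,
#'   `expression_bin`.
#' @export
classify_by_k4me3 <- function(tss, k4me3, k27me3, window = 2000) {
  calls <- new_state_calls(tss, "by_k4me3")
  poised <- poised_peaks(k4me3, k27me3)
  hits <- nearest_peak(tss, k4me3, window)
  calls$d_k4me3 <- hits$distance
  has_hit <- !is.na(hits$subject_id)
  is_poised <- has_hit & hits$subject_id %in% poised$name
  calls$state[has_hit] <- "active"
  calls$state[is_poised] <- "poised"
  calls
}

#' Classify TSS by the poised status of the nearest H3K4me1 peak
#'
#' The H3K4me1-led rule: a TSS is `poised` when its nearest H3K4me1 peak
#' overlaps a poised (bivalent) region — the unimodal TSS-centered H3K4me1
#' configuration. A non-poised TSS is `active` when the center of its
#' nearest H3K4me3 peak lies within `active_radius` bp of the TSS; anything
#' else is `other`. Poised takes precedence: a TSS is never both.
#'
#' @param tss a [tss_set].
#' @param k4me1,k4me3,k27me3 [peak_set]s.
#' @param active_radius |center-to-TSS| bound for the active call
#'   (default 500 bp).
#' @param window nearest-peak search window in bp (default 2000).
#' @return data.frame as in [classify_by_k4me3()], `rule = "by_k4me1"`.
#' @export
classify_by_k4me1 <- function(tss, k4me1, k4me3, k27me3,
                              active_radius = 500, window = 2000) {
  calls <- new_state_calls(tss, "by_k4me1")
  poised <- poised_peaks(k4me3, k27me3)
  pk1 <- poised_k4me1(k4me1, poised)
  h1 <- nearest_peak(tss, k4me1, window)
  h3 <- nearest_peak(tss, k4me3, window)
  calls$d_k4me1 <- h1$distance
  calls$d_k4me3 <- h3$distance
  is_poised <- !is.na(h1$subject_id) & h1$subject_id %in% pk1$name
  is_active <- !is_poised & !is.na(h3$distance) &
    abs(h3$distance) <= active_radius
  calls$state[is_active] <- "active"
  calls$state[is_poised] <- "poised"
  calls
}

#' Expression bin from a TPM value
#'
#' The four bins partition `[0, Inf)` with inclusive upper boundaries:
#' B1: tpm <= 1; B2: 1 < tpm <= 5; B3: 5 < tpm <= 10; B4: tpm > 10.
#' Silent promoters (tpm = 0) fall in B1; `NA` (no abundance record) stays
#' `NA`.
#'
#' @param tpm numeric vector, each value >= 0 or NA.
#' @return Character vector in `{"B1","B2","B3","B4", NA}`.
#' @examples
#' assign_expression_bin(c(0, 1, 5, 10, 10.000001))  # B1 B1 B2 B3 B4
#' @export
assign_expression_bin <- function(tpm) {
  if (any(!is.na(tpm) & tpm < 0)) stop("negative tpm")
  out <- rep(NA_character_, length(tpm))
  ok <- !is.na(tpm)
  out[ok & tpm <= 1] <- "B1"
  out[ok & tpm > 1 & tpm <= 5] <- "B2"
  out[ok & tpm > 5 & tpm <= 10] <- "B3"
  out[ok & tpm > 10] <- "B4"
  out
}

EXPRESSION_BINS <- c("B1", "B2", "B3", "B4")

#' Joint 2D map of per-TSS distances to the two H3K4 marks
#'
#' For each TSS, the signed distances to the nearest H3K4me1 and nearest
#' H3K4me3 peak are binned on a uniform 2D grid over `[-window, window]`.
#' Only TSS with both marks within the window contribute, so the count
#' matrix sums exactly to `n_tss`. In this map, active promoters form
#' "wings" (H3K4me1 displaced, H3K4me3 central) and poised promoters a
#' central cluster.
#'
#' @param tss a [tss_set].
#' @param k4me1,k4me3 [peak_set]s.
#' @param window inclusion window in bp (default 2000).
#' @param nbins bins per axis (default 30).
#' @param states optional character vector aligned with `tss` rows; when
#'   given, one map per distinct state is returned as a named list.
#' @return Object of class `JointDistanceMap` (`x_edges` for H3K4me1,
#'   `y_edges` for H3K4me3, integer matrix `counts`, `n_tss`), or a named
#'   list of them when `states` is supplied.
#' @export
joint_distance_map <- function(tss, k4me1, k4me3, window = 2000, nbins = 30,
                               states = NULL) {
  if (nbins < 2) stop("nbins must be >= 2")
  d1 <- nearest_peak(tss, k4me1, window)$distance
  d3 <- nearest_peak(tss, k4me3, window)$distance
  if (!is.null(states)) {
    maps <- lapply(split(seq_len(nrow(tss)), states), function(i)
      bin_joint(d1[i], d3[i], window, nbins))
    return(maps)
  }
  bin_joint(d1, d3, window, nbins)
}

bin_joint <- function(d1, d3, window, nbins) {
  edges <- seq(-window, window, length.out = nbins + 1)
  keep <- !is.na(d1) & !is.na(d3)
  ix <- findInterval(d1[keep], edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(d3[keep], edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, nbins, nbins)
  for (k in seq_along(ix))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  structure(list(x_edges = edges, y_edges = edges, counts = counts,
                 n_tss = sum(keep)),
            class = "JointDistanceMap")
}

#' @export
print.JointDistanceMap <- function(x, ...) {
  cat("JointDistanceMap:", x$n_tss, "TSS with both marks in window;",
      nrow(x$counts), "x", ncol(x$counts), "bins over [",
      min(x$x_edges), ",", max(x$x_edges), "] bp\n")
  invisible(x)
}

#' @export
plot.JointDistanceMap <- function(x, ...,
                                  xlab = "distance to nearest H3K4me1 (bp)",
                                  ylab = "distance to nearest H3K4me3 (bp)") {
  cx <- (x$x_edges[-1] + x$x_edges[-length(x$x_edges)]) / 2
  cy <- (x$y_edges[-1] + x$y_edges[-length(x$y_edges)]) / 2
  graphics::image(cx, cy, x$counts, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Per-group distance vectors for violin plots and rank tests
#'
#' Groups promoter-state calls by expression bin, or by state x expression
#' bin, and collects the signed and absolute H3K4me1 distances of each
#' group. Every group in the cross of levels is emitted, empty or not, so
#' downstream code sees a stable layout. Calls without an expression bin
#' (no TPM record) are excluded from binned groupings.
#'
#' @param calls data.frame from a `classify_*` function.
#' @param grouping `"expression_bin"` or `"state_expression_bin"` (states
#'   `poised` and `active` crossed with the four bins).
#' @return data.frame with one row per group: `state` (NA for pure bin
#'   grouping), `expression_bin`, `n`, and list-columns `d_signed`,
#'   `d_abs`.
#' @export
distance_by_group <- function(calls,
                              grouping = c("expression_bin",
                                           "state_expression_bin")) {
  grouping <- match.arg(grouping)
  calls <- calls[!is.na(calls$d_k4me1) & !is.na(calls$expression_bin), ,
                 drop = FALSE]
  if (grouping == "expression_bin") {
    grid <- data.frame(state = NA_character_,
                       expression_bin = EXPRESSION_BINS,
                       stringsAsFactors = FALSE)
    key <- calls$expression_bin
    gkey <- grid$expression_bin
  } else {
    grid <- expand.grid(state = c("poised", "active"),
                        expression_bin = EXPRESSION_BINS,
                        stringsAsFactors = FALSE)
    key <- paste(calls$state, calls$expression_bin)
    gkey <- paste(grid$state, grid$expression_bin)
  }
  grid$n <- 0L
  grid$d_signed <- I(vector("list", nrow(grid)))
  grid$d_abs <- I(vector("list", nrow(grid)))
  for (i in seq_len(nrow(grid))) {
    d <- calls$d_k4me1[key == gkey[i]]
    grid$n[i] <- length(d)
    grid$d_signed[[i]] <- as.numeric(d)
    grid$d_abs[[i]] <- abs(as.numeric(d))
  }
  grid
}
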