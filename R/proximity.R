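#' Peak center coordinate
#'
#' The representative point of a peak interval: `floor((start + end) / 2)`,
#' always inside `[start, end)`. All distances in this package are measured
#' center-to-point, never edge-to-point.
#'
#' @param start,end integer vectors (0-based half-open), or `start` may be a
#'   [peak_set] in which case `end` is ignored.
#' @return Integer vector of center coordinates.
#' @examples
#' peak_center(100, 200)  # 150
#' peak_center(100, 201)  # 150 (floor of 150.5)
#' @export
peak_center <- function(start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end
    start <- start$start
  }
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Strand-aware signed distance from a point to a TSS
#'
#' Oriented by gene direction: negative = upstream of the TSS, positive =
#' downstream. On the `+` strand this is `point - position`; on the `-`
#' strand, `position - point`. Flipping the TSS strand negates the distance.
#'
#' @param point integer genomic coordinate(s) (e.g. a peak center).
#' @param position TSS coordinate(s), 0-based.
#' @param strand `"+"` or `"-"`, recycled against `point`.
#' @return Integer vector of signed base-pair distances.
#' @export
signed_distance <- function(point, position, strand) {
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  n <- max(length(point), length(position), length(strand))
  point <- rep_len(as.numeric(point), n)
  position <- rep_len(as.numeric(position), n)
  strand <- rep_len(strand, n)
  as.integer(ifelse(strand == "+", point - position, position - point))
}

# records sorted by position on one chromosome; returns for each query the
# index range of records lying at the two distinct positions bracketing it
candidate_rows <- function(qpos, recpos) {
  up <- unique(recpos)                    # recpos sorted, so up is sorted
  first <- match(up, recpos)
  last <- c(first[-1] - 1L, length(recpos))
  j <- findInterval(qpos, up)
  lapply(seq_along(qpos), function(i) {
    ji <- j[i]
    rows <- integer(0)
    if (ji >= 1L) rows <- first[ji]:last[ji]
    if (ji < length(up)) rows <- c(rows, first[ji + 1L]:last[ji + 1L])
    rows
  })
}

#' Nearest TSS for each peak center
#'
#' For every query point, returns the TSS minimizing the absolute
#' strand-aware signed distance, or a miss (`NA` row) when no TSS lies
#' within `window` bp. Exact ties in |distance| resolve to the TSS with the
#' smaller chromosomal coordinate, then the lexicographically smaller
#' `transcript_id`, so results are deterministic.
#'
#' @param centers integer vector of query coordinates (peak centers).
#' @param chroms chromosome of each query.
#' @param tss a [tss_set].
#' @param window maximum |distance| in bp (default 2000).
#' @param query_id optional identifiers for the queries.
#' @return data.frame with one row per query: `query_id`, `subject_id`
#'   (transcript_id), `distance` (signed bp, NA on miss), `overlap_flag`
#'   (TRUE when center coincides with the TSS base).
#' @export
nearest_tss <- function(centers, chroms, tss, window = 2000,
                        query_id = NULL) {
  if (nrow(tss) == 0) stop("empty TSS set")
  n <- length(centers)
  if (is.null(query_id)) query_id <- as.character(seq_len(n))
  out <- data.frame(query_id = query_id,
                    subject_id = NA_character_,
                    distance = NA_integer_,
                    overlap_flag = NA,
                    stringsAsFactors = FALSE)
  for (ch in unique(chroms)) {
    trows <- which(tss$chrom == ch)
    if (!length(trows)) next
    qrows <- which(chroms == ch)
    recpos <- tss$position[trows]         # sorted: tss_set sorts on build
    cand <- candidate_rows(centers[qrows], recpos)
    for (k in seq_along(qrows)) {
      rows <- trows[cand[[k]]]
      if (!length(rows)) next
      d <- signed_distance(centers[qrows[k]], tss$position[rows],
                           tss$strand[rows])
      ok <- abs(d) <= window
      if (!any(ok)) next
      rows <- rows[ok]; d <- d[ok]
      best <- order(abs(d), tss$position[rows], tss$transcript_id[rows])[1]
      i <- qrows[k]
      out$subject_id[i] <- tss$transcript_id[rows[best]]
      out$distance[i] <- d[best]
      out$overlap_flag[i] <- centers[qrows[k]] == tss$position[rows[best]]
    }
  }
  out
}

#' Nearest peak for each TSS
#'
#' Distance is measured from the TSS to the peak *center*, signed by the
#' TSS strand (negative = upstream). Ties in |distance| prefer the upstream
#' (negative) hit, then the smaller center coordinate, then the
#' lexicographically smaller peak name. `overlap_flag` is TRUE when the TSS
#' base lies inside the winning peak interval.
#'
#' @param tss a [tss_set].
#' @param peaks a [peak_set].
#' @param window maximum |distance| in bp (default 2000).
#' @return data.frame with one row per TSS: `query_id` (transcript_id),
#'   `subject_id` (peak name), `distance`, `overlap_flag`.
#' @export
nearest_peak <- function(tss, peaks, window = 2000) {
  out <- data.frame(query_id = tss$transcript_id,
                    subject_id = NA_character_,
                    distance = NA_integer_,
                    overlap_flag = NA,
                    stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) return(out)
  centers <- peak_center(peaks)
  for (ch in unique(tss$chrom)) {
    prows <- which(peaks$chrom == ch)
    if (!length(prows)) next
    ord <- prows[order(centers[prows], peaks$name[prows])]
    cpos <- centers[ord]
    qrows <- which(tss$chrom == ch)
    cand <- candidate_rows(tss$position[qrows], cpos)
    for (k in seq_along(qrows)) {
      rows <- cand[[k]]
      if (!length(rows)) next
      i <- qrows[k]
      d <- signed_distance(cpos[rows], tss$position[i], tss$strand[i])
      ok <- abs(d) <= window
      if (!any(ok)) next
      rows <- rows[ok]; d <- d[ok]
      best <- order(abs(d), d >= 0, cpos[rows], peaks$name[ord[rows]])[1]
      hit <- ord[rows[best]]
      out$subject_id[i] <- peaks$name[hit]
      out$distance[i] <- d[best]
      out$overlap_flag[i] <- tss$position[i] >= peaks$start[hit] &&
        tss$position[i] < peaks$end[hit]
    }
  }
  out
}

#' Do two intervals overlap by at least 1 bp?
#'
#' Half-open semantics: `[100,200)` and `[200,300)` abut but do not overlap.
#' Vectorized elementwise over the six argument vectors.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b interval fields.
#' @return Logical vector.
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}
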