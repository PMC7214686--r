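# Independent brute-force oracles: each re-derives the quantity from the
# documented definitions with plain loops, sharing no code with the package
# internals they check.

# signed distance per the documented convention (negative = upstream)
oracle_signed <- function(point, pos, strand) {
  if (strand == "+") point - pos else pos - point
}

# nearest TSS for one query point: scan every TSS; ties by smaller
# coordinate, then transcript_id
oracle_nearest_tss <- function(center, chrom, tss, window) {
  best <- NULL
  for (i in seq_len(nrow(tss))) {
    if (tss$chrom[i] != chrom) next
    d <- oracle_signed(center, tss$position[i], tss$strand[i])
    if (abs(d) > window) next
    cand <- list(d = d, pos = tss$position[i], id = tss$transcript_id[i])
    if (is.null(best) ||
        abs(cand$d) < abs(best$d) ||
        (abs(cand$d) == abs(best$d) && cand$pos < best$pos) ||
        (abs(cand$d) == abs(best$d) && cand$pos == best$pos &&
         cand$id < best$id))
      best <- cand
  }
  best
}

# nearest peak for one TSS: ties prefer upstream (negative d), then smaller
# center, then name
oracle_nearest_peak <- function(tss_row, peaks, window) {
  best <- NULL
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != tss_row$chrom) next
    ctr <- floor((peaks$start[i] + peaks$end[i]) / 2)
    d <- oracle_signed(ctr, tss_row$position, tss_row$strand)
    if (abs(d) > window) next
    cand <- list(d = d, ctr = ctr, id = peaks$name[i])
    better <- is.null(best) ||
      abs(cand$d) < abs(best$d) ||
      (abs(cand$d) == abs(best$d) &&
         ((cand$d < 0) > (best$d < 0) ||
          ((cand$d < 0) == (best$d < 0) &&
             (cand$ctr < best$ctr ||
              (cand$ctr == best$ctr && cand$id < best$id)))))
    if (better) best <- cand
  }
  best
}

# full-scan variants: one pass over every subject per query, vectorized over
# subjects but re-deriving distances and tie-breaks from the definitions
oracle_scan_tss <- function(centers, chroms, tss, window) {
  out <- data.frame(subject_id = NA_character_, distance = NA_integer_)
  out <- out[rep(1, length(centers)), ]
  rownames(out) <- NULL
  for (i in seq_along(centers)) {
    on <- tss$chrom == chroms[i]
    if (!any(on)) next
    pos <- tss$position[on]
    d <- ifelse(tss$strand[on] == "+", centers[i] - pos, pos - centers[i])
    ok <- abs(d) <= window
    if (!any(ok)) next
    pick <- which(on)[ok][order(abs(d[ok]), pos[ok],
                                tss$transcript_id[on][ok])[1]]
    out$subject_id[i] <- tss$transcript_id[pick]
    out$distance[i] <- (ifelse(tss$strand[pick] == "+",
                               centers[i] - tss$position[pick],
                               tss$position[pick] - centers[i]))
  }
  out
}

oracle_scan_peak <- function(tss, peaks, window) {
  out <- data.frame(subject_id = NA_character_, distance = NA_integer_)
  out <- out[rep(1, nrow(tss)), ]
  rownames(out) <- NULL
  ctr <- floor((peaks$start + peaks$end) / 2)
  for (i in seq_len(nrow(tss))) {
    on <- peaks$chrom == tss$chrom[i]
    if (!any(on)) next
    d <- if (tss$strand[i] == "+") ctr[on] - tss$position[i]
         else tss$position[i] - ctr[on]
    ok <- abs(d) <= window
    if (!any(ok)) next
    pick <- order(abs(d[ok]), d[ok] >= 0, ctr[on][ok],
                  peaks$name[on][ok])[1]
    out$subject_id[i] <- peaks$name[on][ok][pick]
    out$distance[i] <- d[ok][pick]
  }
  out
}

# direct double-loop KDE
oracle_kde <- function(grid, distances, h) {
  out <- numeric(length(grid))
  for (g in seq_along(grid)) {
    s <- 0
    for (d in distances)
      s <- s + exp(-(grid[g] - d)^2 / (2 * h^2))
    out[g] <- s / (length(distances) * h * sqrt(2 * pi))
  }
  out
}

# random query/subject instance on a coarse coordinate lattice so exact
# |distance| ties occur often
random_instance <- function(n_peaks, n_tss, coord_max = 5000, step = 10) {
  chroms <- c("c1", "c2")
  pk_chrom <- sample(chroms, n_peaks, replace = TRUE)
  s <- sample.int(coord_max / step, n_peaks, replace = TRUE) * step
  w <- sample.int(20, n_peaks, replace = TRUE) * step
  peaks <- peak_set(pk_chrom, s, s + w)
  tss <- tss_set(sample(chroms, n_tss, replace = TRUE),
                 sample.int(coord_max / step, n_tss, replace = TRUE) * step,
                 sample(c("+", "-"), n_tss, replace = TRUE),
                 sprintf("t%04d", sample.int(9999, n_tss)))
  list(peaks = peaks, tss = tss)
}

# shared default synthetic landscape, built once per test run
default_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_landscape(landscape_config(n_genes = 2000, seed = 1))
    cache
  }
})
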