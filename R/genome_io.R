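#' Construct a peak set
#'
#' A peak set is a data.frame of genomic intervals in the internal coordinate
#' convention (0-based, half-open) carrying a histone-mark label. It is the
#' container for ChIP-seq peak calls consumed by every downstream stage.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; 0-based half-open, `0 <= start < end`.
#' @param name peak identifiers; auto-generated (`peak_1`, ...) when `NULL`.
#' @param score optional numeric score (e.g. narrowPeak column 5).
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param mark histone-mark label, one of `"H3K4me1"`, `"H3K4me3"`,
#'   `"H3K27me3"`, `"H3K27ac"`, or `NA` for unlabelled interval sets.
#' @param source free-text provenance string (typically the file path).
#'
#' @return A `data.frame` of class `peak_set`, sorted by `(chrom, start)`,
#'   with attributes `mark` and `source`.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NA_real_,
                     strand = ".", mark = NA_character_, source = "") {
  n <- length(start)
  if (is.null(name)) {
    name <- if (n > 0) paste0("peak_", seq_len(n)) else character(0)
  }
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  if (!is.na(mark) && !mark %in% HISTONE_MARKS) {
    stop("unknown mark label '", mark, "'; expected one of: ",
         paste(HISTONE_MARKS, collapse = ", "))
  }
  df <- df[order(df$chrom, df$start, df$end, df$name), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, mark = mark, source = source,
            class = c("peak_set", "data.frame"))
}

HISTONE_MARKS <- c("H3K4me1", "H3K4me3", "H3K27me3", "H3K27ac")

validate_intervals <- function(df) {
  if (any(!nzchar(df$chrom))) stop("empty chromosome name")
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("non-integer interval coordinates")
  if (any(df$start < 0)) stop("negative start coordinate")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("empty or inverted interval (start >= end) at record ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(df)
}

#' @export
print.peak_set <- function(x, ...) {
  mk <- attr(x, "mark")
  cat("peak_set:", nrow(x), "intervals",
      if (!is.na(mk)) paste0("[", mk, "]") else "", "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more\n")
  invisible(x)
}

#' Construct a TSS record table
#'
#' A strand-bearing catalogue of transcription start points. Positions are
#' 0-based single-base coordinates; strand must be `+` or `-` because every
#' downstream signed distance is oriented by gene direction.
#'
#' @param chrom,position,strand,transcript_id,gene_id,tpm vectors of equal
#'   length; `tpm` is `NA` for transcripts without an abundance estimate
#'   (absence of quantification is not zero expression).
#' @return A `data.frame` of class `tss_set`, sorted by `(chrom, position)`.
#' @export
tss_set <- function(chrom, position, strand, transcript_id,
                    gene_id = NA_character_, tpm = NA_real_) {
  n <- length(position)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    position = as.integer(position),
    strand = rep_len(as.character(strand), n),
    transcript_id = as.character(transcript_id),
    gene_id = rep_len(as.character(gene_id), n),
    tpm = rep_len(as.numeric(tpm), n),
    stringsAsFactors = FALSE
  )
  if (any(df$position < 0)) stop("negative TSS position")
  bad <- !df$strand %in% c("+", "-")
  if (any(bad))
    stop("TSS without usable strand: ",
         paste(utils::head(df$transcript_id[bad], 5), collapse = ", "))
  if (any(!is.na(df$tpm) & df$tpm < 0)) stop("negative tpm")
  df <- df[order(df$chrom, df$position, df$strand, df$transcript_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("tss_set", "data.frame"))
}

#' @export
print.tss_set <- function(x, ...) {
  cat("tss_set:", nrow(x), "transcription start sites on",
      length(unique(x$chrom)), "chromosome(s)\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

split_fields <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' Read peak calls from BED / narrowPeak / broadPeak
#'
#' Coordinates are taken as-is (these formats are already 0-based half-open).
#' Parsing is total: every line is either converted or produces an error
#' naming its line number; nothing is silently dropped. `track`, `browser`
#' and `#` comment lines are skipped.
#'
#' @param path path to the peak file.
#' @param format `"bed"` (3+ columns), `"narrowPeak"` (exactly 10),
#'   `"broadPeak"` (exactly 9), or `"auto"` to infer from the extension and
#'   column count.
#' @param mark optional histone-mark label attached to the result.
#' @return A [peak_set] sorted by `(chrom, start)`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chrX\t0\t50", f)
#' read_peaks(f, format = "bed")
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak", "broadPeak"),
                       mark = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file not found: ", path)
  parsed <- split_fields(path)
  fields <- parsed$fields
  lineno <- parsed$lineno
  if (!length(fields))
    return(peak_set(character(0), integer(0), integer(0), mark = mark,
                    source = path))
  nf <- lengths(fields)
  if (format == "auto") {
    format <- if (grepl("narrowPeak$", path) || all(nf == 10)) "narrowPeak"
      else if (grepl("broadPeak$", path) || all(nf == 9)) "broadPeak"
      else "bed"
  }
  need <- switch(format, narrowPeak = 10L, broadPeak = 9L, bed = 3L)
  bad <- if (format == "bed") nf < need else nf != need
  if (any(bad))
    stop(format, " parse error: expected ",
         if (format == "bed") ">= " else "exactly ", need,
         " tab-separated fields at line ",
         paste(utils::head(lineno[bad], 5), collapse = ", "))
  get_col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1))
  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("non-integer coordinates at line ",
         paste(utils::head(lineno[bad], 5), collapse = ", "))
  bad <- start >= end
  if (any(bad))
    stop("empty or inverted interval (start >= end) at line ",
         paste(utils::head(lineno[bad], 5), collapse = ", "))
  name <- get_col(4)
  name[is.na(name) | !nzchar(name) | name == "."] <- NA
  if (anyNA(name)) {
    auto <- paste0("peak_", seq_along(chrom))
    name[is.na(name)] <- auto[is.na(name)]
  }
  score <- suppressWarnings(as.numeric(get_col(5)))
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  peak_set(chrom, start, end, name, score, strand, mark = mark, source = path)
}

#' Read a TSS catalogue from GTF or BED6
#'
#' For GTF `transcript` features (1-based inclusive), the TSS is `start - 1`
#' in 0-based coordinates on the `+` strand and `end - 1` on the `-` strand.
#' BED6 features (0-based half-open) yield `start` on `+` and `end - 1` on
#' `-`. Records identical in `(chrom, position, strand)` are merged into one
#' TSS whose `transcript_id` concatenates all members with `","`; transcripts
#' lacking a strand are rejected by identifier.
#'
#' @param path GTF or BED6 file.
#' @param format `"gtf"` or `"bed6"`; `"auto"` infers from the extension.
#' @param dedup merge coordinate-identical records (default `TRUE`).
#' @return A [tss_set].
#' @export
read_tss <- function(path, format = c("auto", "gtf", "bed6"), dedup = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("TSS file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(gtf|gff)(\\.gz)?$", path)) "gtf" else "bed6"
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "transcript"]
    if (!length(gr)) stop("no transcript features in GTF: ", path)
    strand <- as.character(BiocGenerics::strand(gr))
    tid <- as.character(gr$transcript_id)
    bad <- !strand %in% c("+", "-")
    if (any(bad))
      stop("transcript without strand rejected: ",
           paste(utils::head(tid[bad], 5), collapse = ", "))
    chrom <- as.character(GenomicRanges::seqnames(gr))
    # import() keeps GTF 1-based starts; shift to the 0-based convention
    position <- ifelse(strand == "+",
                       BiocGenerics::start(gr) - 1L,
                       BiocGenerics::end(gr) - 1L)
    gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else NA_character_
    tss <- tss_set(chrom, position, strand, tid, gid)
  } else {
    parsed <- split_fields(path)
    nf <- lengths(parsed$fields)
    bad <- nf < 6
    if (any(bad))
      stop("bed6 requires 6 fields; line ",
           paste(utils::head(parsed$lineno[bad], 5), collapse = ", "))
    m <- do.call(rbind, parsed$fields)
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    if (anyNA(start) || anyNA(end))
      stop("non-integer coordinates at line ",
           paste(utils::head(parsed$lineno[is.na(start) | is.na(end)], 5),
                 collapse = ", "))
    strand <- m[, 6]
    bad <- !strand %in% c("+", "-")
    if (any(bad))
      stop("TSS without usable strand rejected: ",
           paste(utils::head(m[bad, 4], 5), collapse = ", "))
    position <- ifelse(strand == "+", start, end - 1L)
    tss <- tss_set(m[, 1], position, strand, m[, 4])
  }
  if (dedup) tss <- dedup_tss(tss) else tss
}

dedup_tss <- function(tss) {
  key <- paste(tss$chrom, tss$position, tss$strand, sep = "\r")
  if (!anyDuplicated(key)) return(tss)
  idx <- split(seq_len(nrow(tss)), key)
  merged <- lapply(idx, function(i) {
    first <- tss[i[1], , drop = FALSE]
    first$transcript_id <- paste(sort(tss$transcript_id[i]), collapse = ",")
    gids <- unique(tss$gene_id[i][!is.na(tss$gene_id[i])])
    first$gene_id <- if (length(gids)) paste(sort(gids), collapse = ",") else NA
    first
  })
  out <- do.call(rbind, merged)
  tss_set(out$chrom, out$position, out$strand, out$transcript_id,
          out$gene_id, out$tpm)
}

#' Read a kallisto-style transcript abundance table
#'
#' Expects a TSV with a header naming a transcript-identifier column
#' (`target_id` or `transcript_id`) and a `tpm` column. Transcripts absent
#' from the table are treated downstream as "abundance unavailable", never
#' as zero.
#'
#' @param path TSV file.
#' @return Named numeric vector mapping `transcript_id` to TPM.
#' @export
read_tpm <- function(path) {
  if (!file.exists(path)) stop("TPM file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  idcol <- intersect(c("target_id", "transcript_id"), names(tab))
  tpmcol <- intersect(c("tpm", "TPM"), names(tab))
  if (!length(idcol) || !length(tpmcol))
    stop("abundance table needs a transcript id column ",
         "(target_id/transcript_id) and a tpm column; got: ",
         paste(names(tab), collapse = ", "))
  if (nrow(tab) == 0) return(stats::setNames(numeric(0), character(0)))
  ids <- as.character(tab[[idcol[1]]])
  tpm <- as.numeric(tab[[tpmcol[1]]])
  if (anyNA(tpm)) stop("non-numeric tpm value in ", path)
  if (any(tpm < 0))
    stop("negative tpm for: ",
         paste(utils::head(ids[tpm < 0], 5), collapse = ", "))
  dup <- duplicated(ids)
  if (any(dup))
    stop("duplicate transcript_id: ",
         paste(utils::head(unique(ids[dup]), 5), collapse = ", "))
  stats::setNames(tpm, ids)
}

#' Attach TPM values to a TSS catalogue
#'
#' A merged TSS (several transcripts sharing one coordinate) receives the
#' sum of its member transcripts' TPMs by default — total promoter output —
#' or the maximum with `aggregate = "max"`. Members absent from the table
#' contribute nothing; a TSS with no quantified member keeps `tpm = NA`.
#'
#' @param tss a [tss_set].
#' @param tpm named numeric vector from [read_tpm()].
#' @param aggregate `"sum"` (default) or `"max"` over member transcripts.
#' @return The `tss_set` with its `tpm` column filled.
#' @export
add_tpm <- function(tss, tpm, aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "sum") sum else max
  tss$tpm <- vapply(strsplit(tss$transcript_id, ",", fixed = TRUE),
                    function(ids) {
                      v <- tpm[ids[ids %in% names(tpm)]]
                      if (length(v)) agg(v) else NA_real_
                    }, numeric(1))
  tss
}

#' Write intervals as BED6
#'
#' Writes `(chrom, start, end, name, score, strand)` sorted by
#' `(chrom, start)`; `score` NA becomes 0, strand NA becomes ".". Reading
#' the file back with [read_peaks()] reproduces `(chrom, start, end, name,
#' strand)` field-for-field.
#'
#' @param intervals a [peak_set] or compatible data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  df <- as.data.frame(intervals)
  if (nrow(df)) {
    df <- df[order(df$chrom, df$start, df$end, df$name), , drop = FALSE]
    score <- if ("score" %in% names(df)) df$score else NA_real_
    score[is.na(score)] <- 0
    strand <- if ("strand" %in% names(df)) df$strand else "."
    strand[is.na(strand)] <- "."
    out <- data.frame(df$chrom, df$start, df$end, df$name, score, strand)
  } else {
    out <- data.frame()
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Warn when two inputs disagree on chromosome naming
#'
#' A chr-prefix mismatch between peak and TSS files silently yields zero
#' overlaps everywhere; this check surfaces it. No normalization is applied.
#'
#' @param a_chroms,b_chroms character vectors of chromosome names.
#' @param a_label,b_label labels used in the warning.
#' @return `TRUE` invisibly if the sets share at least one name.
#' @export
check_chrom_names <- function(a_chroms, b_chroms,
                              a_label = "peaks", b_label = "TSS") {
  a <- unique(a_chroms); b <- unique(b_chroms)
  only_a <- setdiff(a, b); only_b <- setdiff(b, a)
  if (length(only_a) || length(only_b))
    warning("chromosome names not shared between ", a_label, " and ", b_label,
            ": ", paste(utils::head(c(only_a, only_b), 10), collapse = ", "),
            call. = FALSE)
  invisible(length(intersect(a, b)) > 0)
}
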