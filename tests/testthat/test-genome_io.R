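test_that("narrowPeak, broadPeak and plain BED lines map to intervals", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t600\tpeak_1\t80\t.\t5.1\t9.2\t7.7\t250", f)
  pk <- read_peaks(f, format = "narrowPeak")
  expect_equal(pk$chrom, "chr1")
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 600L)
  expect_equal(pk$name, "peak_1")
  expect_equal(pk$score, 80)

  b <- withr::local_tempfile(fileext = ".broadPeak")
  writeLines(c("chr2\t10\t50\tbp1\t5\t.\t1\t2\t3",
               "chr1\t5\t25\tbp2\t5\t.\t1\t2\t3"), b)
  pk <- read_peaks(b, format = "broadPeak")
  expect_equal(pk$chrom, c("chr1", "chr2"))  # sorted by (chrom, start)
  expect_equal(pk$start, c(5L, 10L))

  bed3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrX\t0\t50", bed3)
  pk <- read_peaks(bed3, format = "bed")
  expect_equal(pk$start, 0L)
  expect_equal(pk$end, 50L)
  expect_match(pk$name, "^peak_")  # auto-generated name
})

test_that("malformed peak lines raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t100\t100"), f)
  expect_error(read_peaks(f, format = "bed"), "line 2")

  writeLines(c("chr1\tabc\t200"), f)
  expect_error(read_peaks(f, format = "bed"), "non-integer.*line 1")

  writeLines("chr1\t100\t200\tp\t1\t.\t1\t2\t3", f)  # 9 cols, not 10
  expect_error(read_peaks(f, format = "narrowPeak"), "10")
  expect_error(read_peaks("/nonexistent/x.bed"), "not found")
})

test_that("GTF transcripts yield strand-correct 0-based TSS", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "g1"; transcript_id "t_plus";'
  attr2 <- 'gene_id "g1"; transcript_id "t_minus";'
  writeLines(c(
    paste("chr1", "src", "transcript", "1000", "2000", ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "src", "transcript", "1000", "2000", ".", "-", ".", attr2,
          sep = "\t")), gtf)
  tss <- read_tss(gtf, format = "gtf")
  expect_equal(tss$position[tss$transcript_id == "t_plus"], 999L)
  expect_equal(tss$position[tss$transcript_id == "t_minus"], 1999L)
  # TSS lies inside [start-1, end) of its transcript
  expect_true(all(tss$position >= 999 & tss$position < 2000))
})

test_that("coordinate-identical transcripts merge into one TSS", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  mk <- function(id) paste("chr1", "s", "transcript", "500", "900", ".", "+",
                           ".", sprintf('gene_id "g"; transcript_id "%s";', id),
                           sep = "\t")
  writeLines(c(mk("tA"), mk("tB")), gtf)
  tss <- read_tss(gtf, format = "gtf")
  expect_equal(nrow(tss), 1L)
  expect_equal(tss$transcript_id, "tA,tB")
  expect_equal(nrow(read_tss(gtf, format = "gtf", dedup = FALSE)), 2L)
})

test_that("strandless transcripts are rejected with their identifier", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "s", "transcript", "10", "90", ".", ".", ".",
                   'gene_id "g"; transcript_id "t_none";', sep = "\t"), gtf)
  expect_error(read_tss(gtf, format = "gtf"), "t_none")
})

test_that("BED6 TSS reading honors strand and 0-based half-open ends", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ttx_p\t0\t+",
               "chr1\t100\t200\ttx_m\t0\t-"), bed)
  tss <- read_tss(bed, format = "bed6")
  expect_equal(tss$position[tss$transcript_id == "tx_p"], 100L)
  expect_equal(tss$position[tss$transcript_id == "tx_m"], 199L)
})

test_that("TPM tables parse, reject bad rows, and attach to TSS", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("target_id\ttpm", "ENSMUST0001\t12.5", "tx2\t0"), f)
  tpm <- read_tpm(f)
  expect_equal(unname(tpm["ENSMUST0001"]), 12.5)

  writeLines(c("target_id\ttpm", "tx1\t-1"), f)
  expect_error(read_tpm(f), "negative tpm")
  writeLines(c("target_id\ttpm", "tx1\t1", "tx1\t2"), f)
  expect_error(read_tpm(f), "duplicate")
  writeLines("target_id\ttpm", f)
  expect_length(read_tpm(f), 0)

  tss <- tss_set("c1", c(10, 50), c("+", "+"), c("a,b", "c"))
  got <- add_tpm(tss, c(a = 1, b = 2.5, other = 9))
  expect_equal(got$tpm, c(3.5, NA))  # sum over members; unquantified -> NA
  got <- add_tpm(tss, c(a = 1, b = 2.5), aggregate = "max")
  expect_equal(got$tpm[1], 2.5)
})

test_that("BED write -> read round-trips intervals field-for-field", {
  withr::local_seed(42)
  n <- 100
  s <- sample.int(1e6, n)
  pk <- peak_set(sample(c("chr1", "chr2", "chrX"), n, replace = TRUE),
                 s, s + sample.int(1000, n),
                 name = sprintf("pk%03d", seq_len(n)),
                 strand = sample(c("+", "-", "."), n, replace = TRUE))
  f <- withr::local_tempfile(fileext = ".bed")
  write_intervals(pk, f)
  back <- read_peaks(f, format = "bed")
  for (col in c("chrom", "start", "end", "name", "strand"))
    expect_equal(back[[col]], pk[[col]], info = col)

  write_intervals(peak_set(character(0), integer(0), integer(0)), f)
  expect_equal(nrow(read_peaks(f, format = "bed")), 0L)
})

test_that("chromosome-name mismatches warn with the unshared names", {
  expect_warning(check_chrom_names(c("chr1", "chr2"), c("1", "2")),
                 "chr1")
  expect_silent(check_chrom_names("chr1", "chr1"))
})
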