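test_that("poised peak lists follow -wa overlap semantics", {
  k4me3 <- peak_set("c1", c(100, 400), c(200, 500), name = c("a", "b"),
                    mark = "H3K4me3")
  k27 <- peak_set("c1", 150, 250, mark = "H3K27me3")
  got <- poised_peaks(k4me3, k27)
  expect_equal(got$name, "a")
  expect_equal(got$start, 100L)  # original coordinates, not the intersection

  # half-open abutment is not an overlap
  k27 <- peak_set("c1", 200, 300, mark = "H3K27me3")
  expect_equal(nrow(poised_peaks(k4me3, k27)), 0L)

  # one bivalent peak over two repressive peaks is reported once
  k27 <- peak_set("c1", c(110, 150), c(130, 260), mark = "H3K27me3")
  expect_equal(poised_peaks(k4me3, k27)$name, "a")

  # idempotent and a subset of the first argument
  withr::local_seed(5)
  s1 <- sample.int(1e5, 50); s2 <- sample.int(1e5, 50)
  a <- peak_set("c1", s1, s1 + 500, mark = "H3K4me3")
  b <- peak_set("c1", s2, s2 + 500, mark = "H3K27me3")
  p1 <- poised_peaks(a, b)
  expect_lte(nrow(p1), nrow(a))
  expect_true(all(p1$name %in% a$name))
  expect_equal(poised_peaks(p1, b)$name, p1$name)
})

test_that("poised H3K4me1 lists mirror the overlap rule", {
  k4me1 <- peak_set("c1", 90, 310, name = "m", mark = "H3K4me1")
  poised <- peak_set("c1", 100, 200, mark = "H3K4me3")
  expect_equal(poised_k4me1(k4me1, poised)$name, "m")
  expect_equal(nrow(poised_k4me1(k4me1, peak_set("c1", 5000, 6000))), 0L)
  expect_equal(nrow(poised_k4me1(k4me1, k4me1)), 1L)
})

test_that("classification by nearest H3K4me3 bivalency", {
  tss <- tss_set("c1", c(1000, 9000, 30000), c("+", "+", "+"),
                 c("t_poised", "t_active", "t_other"))
  k4me3 <- peak_set("c1", c(900, 8900), c(1100, 9100), name = c("p1", "p2"),
                    mark = "H3K4me3")
  k27 <- peak_set("c1", 950, 1050, mark = "H3K27me3")
  calls <- classify_by_k4me3(tss, k4me3, k27)
  expect_equal(calls$state[calls$tss_id == "t_poised"], "poised")
  expect_equal(calls$state[calls$tss_id == "t_active"], "active")
  expect_equal(calls$state[calls$tss_id == "t_other"], "other")
  expect_equal(calls$rule, rep("by_k4me3", 3))
})

test_that("classification by nearest H3K4me1: poised precedes active", {
  k4me3 <- peak_set("c1", c(900, 20000), c(1100, 20400),
                    name = c("bi", "mono"), mark = "H3K4me3")
  k27 <- peak_set("c1", 950, 1050, mark = "H3K27me3")
  # nearest H3K4me1 overlaps the bivalent peak -> poised even though the
  # nearest H3K4me3 is within 500 bp
  tss <- tss_set("c1", 1000, "+", "t1")
  k4me1 <- peak_set("c1", 800, 1200, name = "m1", mark = "H3K4me1")
  calls <- classify_by_k4me1(tss, k4me1, k4me3, k27)
  expect_equal(calls$state, "poised")

  # non-poised H3K4me1, H3K4me3 center 300 bp away -> active
  tss <- tss_set("c1", 19900, "+", "t2")
  k4me1 <- peak_set("c1", 19000, 19400, name = "m2", mark = "H3K4me1")
  calls <- classify_by_k4me1(tss, k4me1, k4me3, k27)
  expect_equal(calls$state, "active")
  expect_lte(abs(calls$d_k4me3), 500)

  # H3K4me3 center 800 bp away -> other
  tss <- tss_set("c1", 19400, "+", "t3")
  calls <- classify_by_k4me1(tss, k4me1, k4me3, k27)
  expect_equal(calls$state, "other")
})

test_that("expression bins partition [0, Inf) at the stated boundaries", {
  expect_equal(assign_expression_bin(c(0, 1, 1.0000001, 5, 5.1, 10, 10.000001)),
               c("B1", "B1", "B2", "B2", "B3", "B3", "B4"))
  expect_true(is.na(assign_expression_bin(NA_real_)))
  expect_error(assign_expression_bin(-1), "negative")
})

test_that("joint distance maps conserve the contributing TSS count", {
  tss <- tss_set("c1", c(1000, 5000, 9000), c("+", "+", "+"),
                 c("a", "b", "c"))
  k4me1 <- peak_set("c1", tss$position - 200, tss$position + 200,
                    mark = "H3K4me1")
  k4me3 <- peak_set("c1", tss$position - 100, tss$position + 100,
                    mark = "H3K4me3")
  jm <- joint_distance_map(tss, k4me1, k4me3)
  expect_equal(sum(jm$counts), 3L)
  expect_equal(jm$n_tss, 3L)
  # all three at (0, 0): a single central bin holds them
  expect_equal(max(jm$counts), 3L)

  # a TSS whose H3K4me1 is beyond the window drops out entirely
  k4me1_far <- peak_set("c1", c(1000 - 200, 5000 - 200, 9000 + 2300),
                        c(1000 + 200, 5000 + 200, 9000 + 2700),
                        mark = "H3K4me1")
  jm <- joint_distance_map(tss, k4me1_far, k4me3)
  expect_equal(jm$n_tss, 2L)
  expect_equal(sum(jm$counts), 2L)

  # conservation on a random landscape
  ls0 <- default_landscape()
  jm <- joint_distance_map(ls0$tss, ls0$peaks$H3K4me1, ls0$peaks$H3K4me3)
  expect_equal(sum(jm$counts), jm$n_tss)
  expect_error(joint_distance_map(tss, k4me1, k4me3, nbins = 1), "nbins")
})

test_that("distance_by_group emits every group, including empty ones", {
  calls <- data.frame(
    tss_id = c("a", "b", "c", "d"),
    state = c("poised", "poised", "active", "active"),
    rule = "by_k4me1",
    d_k4me1 = c(0L, 10L, 400L, 500L),
    d_k4me3 = NA_integer_,
    tpm = c(0.5, 0.5, 20, 20),
    expression_bin = c("B1", "B1", "B4", "B4"))
  tab <- distance_by_group(calls, "expression_bin")
  expect_equal(tab$expression_bin, c("B1", "B2", "B3", "B4"))
  expect_equal(tab$n, c(2L, 0L, 0L, 2L))
  expect_equal(tab$d_signed[[1]], c(0, 10))
  expect_equal(tab$d_abs[[4]], c(400, 500))

  tab <- distance_by_group(calls, "state_expression_bin")
  expect_equal(nrow(tab), 8L)  # 2 states x 4 bins, empties retained
  expect_equal(sum(tab$n), 4L)

  empty <- distance_by_group(calls[0, ], "expression_bin")
  expect_equal(empty$n, rep(0L, 4))
})

test_that("state recovery on the default landscape is >= 99% for both rules", {
  ls0 <- default_landscape()
  tr <- ls0$truth
  c3 <- classify_by_k4me3(ls0$tss, ls0$peaks$H3K4me3, ls0$peaks$H3K27me3)
  c1 <- classify_by_k4me1(ls0$tss, ls0$peaks$H3K4me1, ls0$peaks$H3K4me3,
                          ls0$peaks$H3K27me3)
  for (calls in list(c3, c1)) {
    expect_gte(mean(calls$state[tr$true_state == "poised"] == "poised"), 0.99)
    expect_gte(mean(calls$state[tr$true_state == "active"] == "active"), 0.99)
  }
  # under by_k4me1 every active call has its H3K4me3 center within 500 bp
  act <- c1[c1$state == "active", ]
  expect_true(all(abs(act$d_k4me3) <= 500))
})

test_that("poised medians undercut active medians in every populated bin", {
  ls0 <- default_landscape()
  tpm2 <- make_discordant_subset(ls0$tpm, ls0$truth,
                                 n_poised_high = 50, n_active_low = 50)
  tss <- add_tpm(ls0$tss, tpm2)
  calls <- classify_by_k4me1(tss, ls0$peaks$H3K4me1, ls0$peaks$H3K4me3,
                             ls0$peaks$H3K27me3)
  tab <- distance_by_group(calls, "state_expression_bin")
  for (bin in unique(tab$expression_bin)) {
    po <- tab$d_abs[tab$state == "poised" & tab$expression_bin == bin][[1]]
    ac <- tab$d_abs[tab$state == "active" & tab$expression_bin == bin][[1]]
    if (length(po) >= 20 && length(ac) >= 20)
      expect_lt(stats::median(po), stats::median(ac))
  }
})
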