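sizes1 <- c(chr1 = 1e6)

two_member_group <- function(s1, e1, s2, e2, smt1 = NA, smt2 = NA) {
  group_peaks(list(A = pk("chr1", s1, e1, smt1, "A"),
                   B = pk("chr1", s2, e2, smt2, "B")))
}

test_that("MAX spans the members; SMT runs summit to summit inclusive", {
  g <- two_member_group(100, 200, 150, 300)
  cons <- build_consensus(g, "MAX", sizes1)
  expect_equal(c(cons$start, cons$end), c(100, 300))

  g <- two_member_group(100, 200, 200, 300, 150, 250)
  # abutting -> two groups; use overlapping members instead
  g <- two_member_group(100, 220, 180, 300, 150, 250)
  cons <- build_consensus(g, "SMT", sizes1)
  expect_equal(c(cons$start, cons$end), c(150, 251))
  # SMT within MAX before widening
  mx <- build_consensus(g, "MAX", sizes1)
  expect_gte(cons$start, mx$start)
  expect_lte(cons$end, mx$end)
})

test_that("narrow SMT regions widen symmetrically to the minimum width", {
  g <- two_member_group(100, 220, 180, 300, 200, 210)
  cons <- build_consensus(g, "SMT", sizes1, min_width = 50)
  expect_equal(cons$end - cons$start, 50)
  expect_equal(c(cons$start, cons$end), c(181, 231))  # [200,211) padded 19/20
})

test_that("ASF centres the footprint on the rounded average summit", {
  g <- two_member_group(100, 220, 180, 300, 150, 250)
  cons <- build_consensus(g, "ASF", sizes1, footprint = 100)
  expect_equal(cons$avg_summit, 200)
  expect_equal(c(cons$start, cons$end), c(150, 250))
  expect_error(build_consensus(g, "ASF", sizes1), "footprint")
  # odd footprint: floor/ceiling halves
  cons <- build_consensus(g, "ASF", sizes1, footprint = 101)
  expect_equal(c(cons$start, cons$end), c(150, 251))
})

test_that("ASW defaults to the pooled mean peak width", {
  g <- two_member_group(100, 220, 180, 300, 150, 250)  # widths 120, 120
  cons <- build_consensus(g, "ASW", sizes1)
  expect_equal(cons$end - cons$start, 120)
  expect_equal(c(cons$start, cons$end), c(200 - 60, 200 + 60))
})

test_that("summitless members fall back to midpoints; regions clip to the chromosome", {
  g <- two_member_group(100, 220, 180, 300)   # no summits
  cons <- build_consensus(g, "SMT", sizes1)
  expect_equal(attr(cons, "summit_fallback"), 1)
  # midpoints 160 and 240 -> [160, 241)
  expect_equal(c(cons$start, cons$end), c(160, 241))

  g <- two_member_group(0, 100, 50, 160, 10, 90)
  cons <- build_consensus(g, "ASF", c(chr1 = 120), footprint = 200)
  expect_equal(c(cons$start, cons$end), c(0, 120))
  expect_error(build_consensus(g, "MAX", c(chrX = 1e6)), "unknown chromosome")
})

test_that("reference regions come from the deepest replicate, ties break by label", {
  sets <- list(A = pk("chr1", 100, 200, rep_id = "A"),
               B = pk("chr1", c(300, 600), c(400, 700), rep_id = "B"))
  r <- reference_regions(sets, c(A = 1e7, B = 1.2e7))
  expect_equal(attr(r, "reference"), "B")
  expect_equal(nrow(r), 2)
  r <- reference_regions(sets, c(A = 1e7, B = 1e7))
  expect_equal(attr(r, "reference"), "A")
})

test_that("RPKM follows count * 1e9 / (len * total) and is scale invariant", {
  reg <- data.frame(group_id = "g1", chrom = "chr1", start = 1000, end = 1500)
  rs <- rd("chr1", 1100 + seq_len(100), 1100 + seq_len(100) + 36)
  cov <- quantify(reg, list(A = rs), totals = c(A = 2e7))
  expect_equal(unname(cov$rpkm[1, 1]), 10.0)   # 100 reads, 500 bp, 20M total

  cov0 <- quantify(data.frame(group_id = "g", chrom = "chr1",
                              start = 5e5, end = 5e5 + 500),
                   list(A = rs), totals = c(A = 2e7))
  expect_equal(unname(cov0$rpkm[1, 1]), 0)

  cov2 <- quantify(reg, list(A = rbind(rs, rs)), totals = c(A = 4e7))
  expect_equal(cov2$rpkm, cov$rpkm)

  expect_error(quantify(data.frame(group_id = "g", chrom = "chr1",
                                   start = 10, end = 10), list(A = rs)),
               "zero-length")
})

test_that("dabg z-test matches the hand-computed example and is monotone", {
  bg <- c(1, 1, 2, 2)
  res <- dabg(3.0, bg)
  expect_equal(res$z, 1.5 / sqrt(1 / 3), tolerance = 1e-12)  # 2.598076
  expect_equal(res$p, 0.0047, tolerance = 1e-2)
  expect_true(res$detected)

  res <- dabg(mean(bg), bg)
  expect_equal(res$z, 0)
  expect_equal(res$p, 0.5)
  expect_false(res$detected)

  expect_false(dabg(100, bg, alpha = 0)$detected)
  expect_error(dabg(1, c(2, 2, 2)), "zero spread")
  expect_error(dabg(1, c(1, 2)), ">= 3")

  set.seed(8)
  bg <- runif(20)
  targets <- sort(runif(50, 0, 3))
  zs <- vapply(targets, function(t) dabg(t, bg)$z, numeric(1))
  expect_true(all(diff(zs) >= 0))
})

test_that("dabg_screen tests only replicates outside a group's support", {
  sets <- list(A = pk("chr1", c(100, 5000), c(200, 5100), rep_id = "A"),
               B = pk("chr1", 120, 210, rep_id = "B"),
               C = pk("chr1", 150, 220, rep_id = "C"))
  g <- classify_groups(group_peaks(sets))
  reg <- build_consensus(g, "MAX", sizes1)
  set.seed(2)
  st <- sample.int(9e5, 3000)
  rs <- lapply(c(A = 1, B = 2, C = 3),
               function(i) rd("chr1", st + i, st + i + 36))
  cov <- quantify(reg, rs)
  peak_rpkms <- lapply(rs, function(r) runif(20, 1, 2))
  res <- dabg_screen(g, cov, peak_rpkms)
  # group 1 supported by A,B,C -> no tests; group 2 unique to A -> B and C
  expect_equal(sort(unique(res$replicate_id)), c("B", "C"))
  expect_equal(unique(res$class), "unique")
  expect_equal(nrow(res), 2)

  peak_rpkms$B <- runif(5)  # too few peaks -> skipped with a warning
  expect_warning(res <- dabg_screen(g, cov, peak_rpkms), "background too small")
  expect_equal(unique(res$replicate_id), "C")
})
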