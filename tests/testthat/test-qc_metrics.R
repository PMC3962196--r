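test_that("pbc counts distinct 5'-end triples", {
  # all distinct -> 1.0
  r <- rd("chr1", c(100, 200, 300, 400, 500), c(136, 236, 336, 436, 536))
  expect_equal(pbc(r)$pbc, 1.0)
  # 4 duplicates at one start + 1 elsewhere -> 2/5
  r <- rd("chr1", c(100, 100, 100, 100, 200), c(136, 136, 136, 136, 236))
  expect_equal(pbc(r)$pbc, 0.4)
  expect_false(pbc(r)$flag_ok)
  expect_true(pbc(rd("chr1", 1:10 * 100, 1:10 * 100 + 36))$flag_ok)
  expect_error(pbc(rd(character(), numeric(), numeric(), character())),
               "nonempty")
})

test_that("pbc properties: order-invariant; self-concatenation halves a duplicate-free set", {
  set.seed(3)
  st <- sample.int(1e5, 50)
  r <- rd("chr1", st, st + 36, sample(c("+", "-"), 50, TRUE))
  expect_equal(pbc(r)$pbc, pbc(r[sample.int(50), ])$pbc)
  expect_equal(pbc(rbind(r, r))$pbc, pbc(r)$pbc / 2)
})

test_that("frip counts each read once and is monotone in added peaks", {
  r <- rd("chr1", c(100, 150, 300, 400, 500), c(136, 186, 336, 436, 536))
  p1 <- pk("chr1", 90, 200)
  expect_equal(frip(r, p1), 0.4)               # 2 of 5 inside the peak
  expect_equal(frip(r, pk("chr1", 0, 1000)), 1.0)
  expect_equal(frip(r, p1[0, ]), 0.0)
  p2 <- rbind(p1, pk("chr1", 290, 350))
  expect_gte(frip(r, p2), frip(r, p1))
  # a read spanning two peaks still counts once
  expect_equal(frip(rd("chr1", 100, 300), pk("chr1", c(90, 250), c(150, 400))),
               1.0)
})

test_that("cross-correlation peaks at the constructed strand offset", {
  set.seed(11)
  p5 <- rep(sort(sample(2000:20000, 80)), sample(1:5, 80, TRUE))
  d <- 100
  # + 5' ends at p5 with varying multiplicity; - reads whose 5' end (end-1)
  # sits at p5 + d, so the count vectors match exactly at shift d
  r <- rbind(rd("chr1", p5, p5 + 36, "+"),
             rd("chr1", p5 + d - 36 + 1, p5 + d + 1, "-"))
  prof <- strand_cross_correlation(r, c(0, 200), read_length = 36)
  expect_equal(prof$fragment_peak_shift, d)
  expect_gt(max(prof$cc), 0.99)
  expect_error(strand_cross_correlation(rd("chr1", p5, p5 + 36, "+"),
                                        c(0, 200), 36),
               "both strands")
})

test_that("cross-correlation is symmetric under strand reflection", {
  set.seed(12)
  p5 <- sort(sample(3000:10000, 40))
  r <- rbind(rd("chr1", p5, p5 + 36, "+"),
             rd("chr1", p5 + 64, p5 + 100, "-"))
  # reflect the genome: position x -> M - x maps + reads to - reads
  M <- 20000
  refl <- rd("chr1", M - r$end, M - r$start,
             ifelse(r$strand == "+", "-", "+"))
  a <- strand_cross_correlation(r, c(50, 150), 36)
  b <- strand_cross_correlation(refl, c(50, 150), 36)
  expect_equal(a$cc, b$cc, tolerance = 1e-12)
})

test_that("nsc_rsc follows the peak/background ratios", {
  mk <- function(shifts, cc, frag, rl) {
    structure(list(shifts = shifts, cc = cc, fragment_peak_shift = frag,
                   read_length = rl), class = "cc_profile")
  }
  # cc(frag)=0.30, cc(readlen)=0.15, min=0.10 -> nsc 3, rsc 4
  p <- mk(c(10, 36, 150), c(0.10, 0.15, 0.30), 150, 36)
  nr <- nsc_rsc(p)
  expect_equal(nr$nsc, 3.0)
  expect_equal(nr$rsc, 4.0)
  # flat profile -> nsc 1
  p <- mk(c(10, 36, 150), c(0.2, 0.2, 0.2), 150, 36)
  expect_equal(suppressWarnings(nsc_rsc(p))$nsc, 1.0)
  # cc(readlen) at the background minimum -> rsc undefined
  p <- mk(c(10, 36, 150), c(0.2, 0.1, 0.3), 150, 36)
  expect_warning(nr <- nsc_rsc(p), "RSC undefined")
  expect_true(is.na(nr$rsc))
})
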