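test_that("one shared nucleotide links peaks; abutting half-open intervals do not", {
  g <- group_peaks(list(A = pk("chr1", 100, 200), B = pk("chr1", 199, 300)))
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$groups$support, "A,B")

  g <- group_peaks(list(A = pk("chr1", 100, 200), B = pk("chr1", 200, 300)))
  expect_equal(nrow(g$groups), 2)
})

test_that("single linkage chains members that never touch directly", {
  g <- group_peaks(list(A = pk("chr1", 100, 200),
                        B = pk("chr1", 150, 250),
                        C = pk("chr1", 240, 260)))
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$groups$support, "A,B,C")
  expect_equal(g$groups$start, 100)
  expect_equal(g$groups$end, 260)
})

test_that("grouping matches the O(n^2) union-find oracle and is replicate-order invariant", {
  set.seed(101)
  for (trial in 1:25) {
    n_rep <- sample(2:4, 1)
    sets <- setNames(lapply(seq_len(n_rep), function(i) {
      n <- sample(5:30, 1)
      st <- sample.int(5000, n)
      pk(sample(c("c1", "c2"), n, TRUE), st, st + sample(20:400, n, TRUE))
    }), paste0("r", seq_len(n_rep)))
    g <- group_peaks(sets)
    expect_identical(partition_of(g), oracle_group(g$peaks))
    # invariance to replicate ordering
    g2 <- group_peaks(rev(sets))
    expect_identical(g$groups[c("chrom", "start", "end", "support")],
                     g2$groups[c("chrom", "start", "end", "support")])
    # partition property: members cover every input peak exactly once
    expect_equal(nrow(g$peaks), sum(vapply(sets, nrow, integer(1))))
  }
})

test_that("classification uses a strict majority and nests common_all", {
  mk <- function(n_sup, n_rep) {
    sets <- setNames(lapply(seq_len(n_rep), function(i) {
      if (i <= n_sup) pk("chr1", 100, 200) else pk("chr1", 5000, 5100)
    }), paste0("r", seq_len(n_rep)))
    g <- classify_groups(group_peaks(sets))
    g$groups$class[g$groups$start == 100]
  }
  expect_equal(mk(3, 5), "majority")       # 3 of 5
  expect_equal(mk(2, 4), "partial")        # 50% is not > 50%
  expect_equal(mk(3, 3), "common_all")     # nested: also majority rule
  expect_equal(mk(2, 3), "majority")
  expect_equal(mk(1, 5), "unique")

  sets <- list(A = pk("chr1", 100, 200), B = pk("chr1", 150, 250),
               C = pk("chr1", 9000, 9100))
  g <- classify_groups(group_peaks(sets))
  expect_true(all(g$groups$is_majority[g$groups$class == "common_all"]))
  expect_equal(sum(g$class_counts[c("unique", "partial", "majority",
                                    "common_all")]),
               nrow(g$groups))
})

test_that("duplicate replicate labels are rejected", {
  expect_error(group_peaks(setNames(list(pk("chr1", 1, 2), pk("chr1", 5, 6)),
                                    c("A", "A"))),
               "duplicate")
})

test_that("simple agreement and McNemar follow their stated formulas", {
  # 3 A-peaks, 2 B-peaks, exactly one overlapping pair -> (1+1)/5
  a <- pk("chr1", c(100, 500, 900), c(200, 600, 1000), rep_id = "A")
  b <- pk("chr1", c(150, 2000), c(250, 2100), rep_id = "B")
  res <- pair_agreement(a, b)
  expect_equal(res$simple_agreement, 0.4)

  # identical sets: perfect agreement, no asymmetry
  res <- pair_agreement(a, a)
  expect_equal(res$simple_agreement, 1.0)
  expect_equal(res$mcnemar_statistic, 0)
  expect_equal(res$mcnemar_p, 1)

  # b = 15, c = 5 -> (10)^2/20 = 5
  shared <- pk("chr1", (1:5) * 10000, (1:5) * 10000 + 100)
  a <- rbind(shared, pk("chr1", (1:15) * 1000 + 100000,
                        (1:15) * 1000 + 100050))
  b <- rbind(shared, pk("chr1", (1:5) * 1000 + 300000,
                        (1:5) * 1000 + 300050))
  res <- pair_agreement(a, b)
  expect_equal(res$mcnemar_statistic, 5.0)
  o <- oracle_mcnemar(15, 5)
  expect_equal(res$mcnemar_p, o$p, tolerance = 1e-12)

  expect_error(pair_agreement(a[0, ], b), "nonempty")
})

test_that("McNemar matches the oracle across random discordant counts", {
  set.seed(55)
  for (i in 1:100) {
    b <- sample(0:40, 1); c <- sample(0:40, 1)
    shared <- pk("chr1", 100, 200)
    a <- rbind(shared, if (b) pk("chr1", (1:b) * 1000 + 1e5,
                                (1:b) * 1000 + 1e5 + 50))
    bb <- rbind(shared, if (c) pk("chr1", (1:c) * 1000 + 5e5,
                                 (1:c) * 1000 + 5e5 + 50))
    res <- pair_agreement(a, bb)
    o <- oracle_mcnemar(b, c)
    expect_equal(res$mcnemar_statistic, o$stat, tolerance = 1e-10)
    expect_equal(res$mcnemar_p, o$p, tolerance = 1e-10)
  }
})
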