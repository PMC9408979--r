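# Interval algebra: coverage fractions, the strict >50% TE rule, summit
# membership, nearest distances and bins, merging, random controls, GC.

test_that("coverage_fraction unions subjects and matches a bitmap oracle", {
  q <- iv("chr1", 100, 200)
  expect_equal(coverage_fraction(q, iv("chr1", 100, 200)), 1.0)
  expect_equal(coverage_fraction(q, iv("chr1", c(100, 140), c(150, 180))), 0.8)
  expect_equal(coverage_fraction(q, iv("chr1", 300, 400)), 0.0)
  expect_equal(coverage_fraction(q, q[0, ]), 0.0)

  set.seed(101)
  for (rep in 1:25) {
    q <- random_intervals(1)
    s <- random_intervals(sample(0:6, 1))
    expect_equal(coverage_fraction(q, s),
                 oracle_coverage(q$start, q$end, s))
  }
})

test_that("TE-derived calls are strict at the 50% boundary", {
  acr <- iv("chr1", 0, 100)
  expect_false(is_te_derived(acr, iv("chr1", 0, 50)))    # exactly half
  expect_true(is_te_derived(acr, iv("chr1", 0, 51)))
  expect_false(is_te_derived(acr, iv("chr1", 500, 600)))
})

test_that("summit coverage respects half-open TE boundaries", {
  tes <- iv("chr1", 100, 200)
  mk <- function(summit) iv("chr1", 0, 300, summit_offset = summit)
  expect_true(summit_covered(mk(150), tes))
  expect_false(summit_covered(mk(200), tes))   # end is exclusive
  expect_true(summit_covered(mk(100), tes))    # start is inclusive
})

test_that("summit attribution picks the innermost covering TE once", {
  tes <- te("chr1", c(100, 140), c(300, 180),
            superfamily = c("Gypsy", "hAT"),
            te_class = c("retrotransposon", "DNA"))
  acr <- iv("chr1", 0, 400, summit_offset = 150)
  att <- summit_te_attribution(acr, tes)
  expect_true(att$covered)
  expect_equal(att$superfamily, "hAT")  # shorter, nested TE wins
})

test_that("nearest_distance and its bins follow the edge-gap convention", {
  q <- iv("chr1", 100, 200)
  expect_equal(nearest_distance(q, iv("chr1", 150, 300)), 0)
  expect_equal(nearest_distance(q, iv("chr1", 370, 400)), 170)
  expect_equal(nearest_distance(q, iv("chr1", 371, 400)), 171)
  expect_equal(nearest_distance(q, iv("chr2", 100, 200)), Inf)
  expect_equal(as.character(bin_distance(c(0, 170, 171, 500, 501, 1000, 1001,
                                           Inf))),
               c("0", "1-170", "171-500", "171-500", "501-1000", "501-1000",
                 ">1000", ">1000"))

  # symmetry for singleton query/subject, plus oracle agreement
  set.seed(202)
  for (rep in 1:25) {
    a <- random_intervals(1); b <- random_intervals(1)
    expect_equal(nearest_distance(a, b), nearest_distance(b, a))
    s <- random_intervals(sample(1:5, 1))
    expect_equal(nearest_distance(a, s), oracle_nearest(a$start, a$end, s))
  }
})

test_that("merge_acrs merges transitively, keeps abutting apart, idempotent", {
  m <- merge_acrs(list(iv("chr1", 100, 200), iv("chr1", 150, 250)))
  expect_equal(m[, c("start", "end")], data.frame(start = 100, end = 250))

  m2 <- merge_acrs(list(iv("chr1", 100, 200), iv("chr1", 200, 300)))
  expect_equal(nrow(m2), 2L)  # half-open abutting, no shared bp

  same <- replicate(6, iv("chr1", 5, 50), simplify = FALSE)
  expect_equal(nrow(merge_acrs(same)), 1L)

  set.seed(303)
  x <- random_intervals(60)
  m3 <- merge_acrs(x)
  expect_equal(merge_acrs(m3)[, 1:3], m3[, 1:3])
  # pairwise non-overlapping
  expect_true(all(m3$start[-1] >= m3$end[-nrow(m3)]))
})

test_that("random control regions conserve lengths and are uniform", {
  tpl <- iv("chr1", c(10, 400), c(510, 480))
  sizes <- c(chr1 = 10000, chr2 = 20000)
  sets <- random_matched_regions(tpl, sizes, n_sets = 3, seed = 5)
  expect_length(sets, 3)
  for (s in sets) {
    expect_equal(s$end - s$start, tpl$end - tpl$start)
    expect_true(all(s$start >= 0 & s$end <= sizes[s$chrom]))
  }
  expect_identical(random_matched_regions(tpl, sizes, 2, seed = 9),
                   random_matched_regions(tpl, sizes, 2, seed = 9))

  # empirical uniformity of starts on a single chromosome
  many <- random_matched_regions(iv("chr1", rep(0, 10000), rep(100, 10000)),
                                 c(chr1 = 10100), 1, seed = 31)[[1]]
  ct <- table(cut(many$start, breaks = seq(0, 10000, by = 1000)))
  expect_gt(chisq.test(ct)$p.value, 0.01)
})

test_that("gc_content excludes N from the denominator", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ANGC"), 2 / 3)
  expect_true(is.na(gc_content("NNNN")))
})

test_that("te_class_rollup assigns the class with more covered bp, DNA on tie", {
  acr <- iv("chr1", 0, 100)
  tes <- te("chr1", c(0, 50), c(40, 100),
            superfamily = c("hAT", "Gypsy"),
            te_class = c("DNA", "retrotransposon"))
  expect_equal(te_class_rollup(acr, tes), "retrotransposon")  # 50 bp beats 40
  tes2 <- te("chr1", c(0, 50), c(50, 100),
             superfamily = c("hAT", "Gypsy"),
             te_class = c("DNA", "retrotransposon"))
  expect_equal(te_class_rollup(acr, tes2), "DNA")
  expect_true(is.na(te_class_rollup(iv("chr1", 500, 600), tes)))
})
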