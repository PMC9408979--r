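# Metaprofiles: feature counts and signal means around anchors, scaled-body
# layouts, and the read-weighted methylation wrapper.

test_that("feature_count_profile counts per bin and averages over anchors", {
  a1 <- iv("chr1", 9000, 9200, summit_offset = 100)
  big_te <- iv("chr1", 5000, 13000)
  p <- feature_count_profile(a1, big_te, flank = 2000, bin = 50)
  expect_equal(nrow(p), 80)
  expect_true(all(p$value == 1))

  a2 <- iv("chr1", c(9000, 50000), c(9200, 50200))
  p2 <- feature_count_profile(a2, big_te)
  expect_true(all(p2$value %in% c(0, 0.5)))
  expect_equal(p2$value[p2$bin_start == 0], 0.5)

  p3 <- feature_count_profile(a1, big_te[0, ])
  expect_true(all(p3$value == 0))
  expect_error(feature_count_profile(a1[0, ], big_te), "no anchors")

  # anchor order must not matter
  set.seed(7)
  anchors <- random_intervals(15, max_pos = 50000)
  feats <- random_intervals(30, max_pos = 50000)
  p4 <- feature_count_profile(anchors, feats)
  p5 <- feature_count_profile(anchors[sample(15), ], feats)
  expect_equal(p4$value, p5$value)
})

test_that("signal_profile averages bedGraph signal, matching per-bp oracle", {
  anchors <- iv("chr1", c(3000, 6000), c(3400, 6400))
  const <- iv("chr1", 0, 10000, value = 3.5)
  p <- signal_profile(anchors, const)
  expect_true(all(abs(p$value - 3.5) < 1e-12))

  # nonzero only at one bp lights up a single central bin
  spike <- iv("chr1", 3200, 3201, value = 10)
  p2 <- signal_profile(iv("chr1", 3000, 3400), spike)
  expect_equal(sum(p2$value > 0), 1)
  expect_equal(p2$value[p2$bin_start == 0], 10 / 50)

  # brute-force per-bp oracle on a 10 kb toy chromosome
  set.seed(505)
  base <- numeric(10000)
  for (i in 1:40) {
    s <- sample.int(9900, 1); w <- sample.int(100, 1)
    base[s:(s + w - 1)] <- base[s:(s + w - 1)] + runif(1, 0, 5)
  }
  runs <- rle(base)
  ends <- cumsum(runs$lengths)
  bg <- iv("chr1", c(0, ends[-length(ends)]), ends, value = runs$values)
  bg <- bg[bg$value != 0, ]
  anchors <- iv("chr1", c(2500, 4000, 7000), c(2700, 4400, 7100))
  got <- signal_profile(anchors, bg, flank = 1000, bin = 100)
  centers <- anchors$start + (anchors$end - anchors$start) %/% 2
  want <- sapply(seq(-1000, 900, 100), function(off) {
    mean(sapply(centers, function(c0) mean(base[(c0 + off + 1):(c0 + off + 100)])))
  })
  expect_equal(got$value, want, tolerance = 1e-12)
})

test_that("missing-skip mode reports NaN for unscored bins", {
  sparse <- iv("chr1", 3200, 3250, value = 2)
  p <- signal_profile(iv("chr1", 3000, 3400), sparse, missing = "skip")
  expect_true(all(is.nan(p$value[p$bin_start != 0])))
  expect_equal(p$value[p$bin_start == 0], 2)
})

test_that("scaled_body_profile rescales bodies and honours strand", {
  feats <- iv("chr1", c(10000, 30000), c(12000, 33000), strand = c("+", "+"))
  const <- iv("chr1", 0, 40000, value = 1.5)
  p <- scaled_body_profile(feats, const)
  expect_equal(nrow(p), 40 + 40 + 40)
  expect_true(all(abs(p$value - 1.5) < 1e-12))

  # signal confined to bodies
  body_only <- iv("chr1", c(10000, 30000), c(12000, 33000), value = 1)
  p2 <- scaled_body_profile(feats, body_only)
  expect_true(all(abs(p2$value[p2$region == "body"] - 1) < 1e-12))
  expect_true(all(p2$value[p2$region != "body"] == 0))

  # an asymmetric profile mirrors when the feature flips strand
  asym <- iv("chr1", 10000, 10500, value = 7)  # 5' quarter of the + body
  plusf <- iv("chr1", 10000, 12000, strand = "+")
  minusf <- iv("chr1", 10000, 12000, strand = "-")
  pp <- scaled_body_profile(plusf, asym)
  pm <- scaled_body_profile(minusf, asym)
  expect_equal(pm$value, rev(pp$value))

  expect_message(
    scaled_body_profile(iv("chr1", c(100, 5000), c(120, 7000)), const),
    "excluded 1")
})

test_that("methylation body profile is the read-weighted level per bin", {
  # two cytosines in one bin with different depths: level must be
  # sum(mC)/sum(reads), not the mean of the two site levels
  sites <- data.frame(chrom = "chr1", pos = c(10010, 10020),
                      nucleotide = "C", context = "CG", dinucleotide = "CG",
                      methylated = c(9, 0), total = c(9, 1), covered = TRUE)
  feat <- iv("chr1", 10000, 12000, strand = "+")
  p <- methylation_body_profile(feat, sites, "CG", body_bins = 4,
                                flank = 200, flank_bin = 50)
  first_body <- p$value[p$region == "body"][1]
  expect_equal(first_body, 9 / 10)
  expect_true(all(is.nan(p$value[p$region != "body"])))
})

test_that("profiles on random matched controls approximate the genome mean", {
  set.seed(606)
  # block signal over ~half the chromosome
  bg <- iv("chr1", seq(0, 99000, 2000), seq(1000, 100000, 2000), value = 2)
  controls <- random_matched_regions(iv("chr1", rep(0, 200), rep(400, 200)),
                                     c(chr1 = 100000), 1, seed = 44)[[1]]
  controls <- controls[controls$start >= 2000 & controls$end <= 98000, ]
  p <- signal_profile(controls, bg, flank = 2000, bin = 50)
  expect_lt(abs(mean(p$value) - 1), 0.15)  # genome-wide mean is 1.0
})
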