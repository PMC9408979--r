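# Positional classes, tertiles, gene association, RPKM.

gene <- function(chrom, start, end, strand = "+", gene_id = "g1") {
  iv(chrom, start, end, strand = strand, gene_id = gene_id)
}

test_that("positional classes follow strand-aware windows and precedence", {
  g <- gene("chr1", 10000, 12000, "+")
  # wholly inside the gene body
  expect_equal(as.character(classify_position(iv("chr1", 10500, 10800), g)$class),
               "gACR")
  # overlapping both promoter window and gene body: promoter wins
  expect_equal(as.character(classify_position(iv("chr1", 9500, 10500), g)$class),
               "pACR")
  # downstream of the TTS on + strand
  expect_equal(as.character(classify_position(iv("chr1", 12100, 12400), g)$class),
               "dnACR")
  # minus-strand gene: promoter sits right of the body
  gm <- gene("chr1", 10000, 12000, "-")
  expect_equal(as.character(classify_position(iv("chr1", 12100, 12400), gm)$class),
               "pACR")
  expect_equal(as.character(classify_position(iv("chr1", 9500, 9900), gm)$class),
               "dnACR")
})

test_that("distal calls flip exactly at the 2 kb gene-body distance", {
  g <- gene("chr1", 10000, 12000, "+")
  at_gap <- function(gap) iv("chr1", 12000 + gap, 12300 + gap)
  expect_equal(as.character(classify_position(at_gap(2001), g)$class), "dACR")
  expect_false(as.character(classify_position(at_gap(2000), g)$class) == "dACR")
  expect_equal(as.character(classify_position(iv("chr1", 100, 200),
                                              g[0, ])$class), "dACR")
})

test_that("classification agrees with a brute-force scan and partitions", {
  set.seed(404)
  # independent per-gene scan over all class conditions: promoter-side
  # association means some part of the peak lies within 2 kb on the gene's
  # upstream side (similarly downstream); distal only when the gap to every
  # gene body is strictly greater than 2 kb
  brute_class <- function(a, genes) {
    best <- "dACR"
    rank <- c(pACR = 1, gACR = 2, dnACR = 3, dACR = 4)
    for (i in seq_len(nrow(genes))) {
      s <- genes$start[i]; e <- genes$end[i]; plus <- genes$strand[i] == "+"
      left <- a$start < s && (s - a$end) <= 2000   # reaches left of the body
      right <- a$end > e && (a$start - e) <= 2000  # reaches right of the body
      body <- a$end > s && a$start < e
      prom <- if (plus) left else right
      down <- if (plus) right else left
      for (cand in c("pACR", "gACR", "dnACR")[c(prom, body, down)])
        if (rank[cand] < rank[best]) best <- cand
    }
    best
  }
  for (rep in 1:10) {
    genes <- random_intervals(8, max_pos = 40000, max_len = 3000)
    genes$strand <- sample(c("+", "-"), 8, replace = TRUE)
    genes$gene_id <- sprintf("g%d", 1:8)
    acrs <- random_intervals(40, max_pos = 45000, max_len = 800)
    got <- classify_position(acrs, genes)
    want <- vapply(seq_len(nrow(acrs)),
                   function(i) brute_class(acrs[i, ], genes), character(1))
    expect_equal(as.character(got$class), want)
    expect_equal(sum(table(got$class)), nrow(acrs))  # partition
  }
})

test_that("tertiles split ranked RPKM into near-equal groups", {
  expect_equal(as.character(accessibility_tertiles(1:9)),
               rep(c("low", "mid", "high"), each = 3))
  expect_equal(sort(as.character(accessibility_tertiles(c(5, 1, 9)))),
               c("high", "low", "mid"))
  # invariance under strictly monotone transforms
  x <- runif(20)
  expect_equal(accessibility_tertiles(x), accessibility_tertiles(exp(4 * x)))
  expect_warning(t <- accessibility_tertiles(rep(2, 5)), "all RPKM equal")
  expect_equal(as.character(t), rep("mid", 5))
  # boundary ties broken by id, deterministically
  expect_equal(accessibility_tertiles(c(1, 1, 1, 2, 2, 2), letters[1:6]),
               accessibility_tertiles(c(1, 1, 1, 2, 2, 2), letters[1:6]))
})

test_that("acr_related_genes uses the extended span with >= 1 bp overlap", {
  g <- gene("chr1", 10000, 12000, "+")
  expect_equal(nrow(acr_related_genes(g, iv("chr1", 13990, 14500))), 1L)
  expect_equal(nrow(acr_related_genes(g, iv("chr1", 14000, 14500))), 0L)
  three <- iv("chr1", c(8100, 10500, 13500), c(8400, 10900, 13900),
              name = c("a1", "a2", "a3"))
  rel <- acr_related_genes(g, three)
  expect_equal(rel$gene_id, rep("g1", 3))
  expect_setequal(rel$acr_id, c("a1", "a2", "a3"))
})

test_that("rpkm implements count * 1e9 / (length * total)", {
  expect_equal(rpkm(10, 500, 1e6), 20)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(10, 500, 2e6), rpkm(10, 500, 1e6) / 2)
  expect_error(rpkm(1, 0, 1e6), "length_bp")
})
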