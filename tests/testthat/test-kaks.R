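# NG86 divergence, the Ks/p filters, TSS peak status and subgroups.

test_that("identical sequences give zero divergence and undefined omega", {
  cds <- "ATGGCTAAATTTGGG"
  k <- ng86_kaks(cds, cds)
  expect_equal(k$Ka, 0)
  expect_equal(k$Ks, 0)
  expect_true(is.na(k$omega))
  expect_equal(k$S_d + k$N_d, 0)
})

test_that("a lone synonymous third-position change is counted as such", {
  # TTT <-> TTC, both Phe, in enough codon context for the JC correction
  k <- ng86_kaks("ATGTTTGGGCTACGA", "ATGTTCGGGCTACGA")
  expect_equal(k$S_d, 1)
  expect_equal(k$N_d, 0)
  expect_equal(k$Ka, 0)
  expect_gt(k$Ks, 0)
})

test_that("site counts satisfy S + N = 3 * codons and the sites oracle", {
  set.seed(150)
  for (rep in 1:5) {
    cds <- random_cds(12, seed = rep)
    k <- ng86_kaks(cds, cds)
    expect_equal(k$S + k$N, 3 * 12)
    want_S <- sum(vapply(teacr:::split_codons(cds), oracle_syn_sites,
                         numeric(1)))
    expect_equal(k$S, want_S)
  }
})

test_that("ng86 is symmetric in its two sequences", {
  set.seed(160)
  a <- random_cds(20, seed = 3)
  b <- mutate_cds_pair(a, 4, 3, seed = 9)$cds_b
  k1 <- ng86_kaks(a, b); k2 <- ng86_kaks(b, a)
  for (f in c("S", "N", "S_d", "N_d", "Ks", "Ka", "p_value"))
    expect_equal(k1[[f]], k2[[f]])
})

test_that("difference counting matches an independent pathway enumerator", {
  set.seed(170)
  for (rep in 1:15) {
    n <- sample(3:10, 1)
    a <- random_cds(n, seed = rep * 11)
    b <- mutate_cds_pair(a, sample(0:3, 1), sample(0:3, 1),
                         seed = rep * 13)$cds_b
    ca <- teacr:::split_codons(a); cb <- teacr:::split_codons(b)
    want <- c(0, 0)
    usable <- TRUE
    for (i in seq_len(n)) {
      d <- oracle_ng86_diffs(ca[i], cb[i])
      if (is.null(d)) { usable <- FALSE; break }  # all pathways blocked
      want <- want + d
    }
    if (!usable) next
    k <- ng86_kaks(a, b)
    expect_equal(k$S_d, want[1])
    expect_equal(k$N_d, want[2])
  }
})

test_that("stop codons in input are rejected", {
  expect_error(ng86_kaks("ATGTAAGGG", "ATGTAAGGG"), "stop codon")
  expect_error(ng86_kaks("ATGGGG", "ATGGGGAAA"), "equal length")
})

test_that("filters keep Ks <= 5 and p <= 0.05, both inclusive of the bound", {
  kaks <- data.frame(gene_a = letters[1:4], gene_b = LETTERS[1:4],
                     Ks = c(5.0, 5.01, 1, 1),
                     p_value = c(0.01, 0.01, 0.06, 0.05))
  kept <- filter_pairs(kaks)
  expect_setequal(kept$gene_a, c("a", "d"))
})

test_that("TSS peak status uses a closed +/- 500 bp window with TE priority", {
  g <- iv("chr1", 10000, 12000, strand = "+", gene_id = "g1")
  acr_at <- function(start, end) iv("chr1", start, end)
  # overlapping the window, TE-derived
  expect_equal(tss_acr_status(g, acr_at(9600, 9800), TRUE), "te_acr")
  # both a TE-derived and a regular peak: TE wins
  both <- rbind(acr_at(9600, 9800), acr_at(10100, 10300))
  expect_equal(tss_acr_status(g, both, c(FALSE, TRUE)), "te_acr")
  # +500 bp is inclusive; 501 bp away is not
  expect_equal(tss_acr_status(g, acr_at(10500, 10900), FALSE), "regular_acr")
  expect_equal(tss_acr_status(g, acr_at(10501, 10900), FALSE), "none")
})

test_that("subgroups implement the three TE/regular/none combinations", {
  a <- c("te_acr", "te_acr", "regular_acr", "regular_acr", "none")
  b <- c("te_acr", "regular_acr", "te_acr", "none", "te_acr")
  expect_equal(assign_subgroups(a, b), c("1", "2", "2", "unassigned", "3"))
  expect_equal(assign_subgroups("regular_acr", "none"), "unassigned")
})

test_that("divergence association splits at fold change 2 inclusively", {
  d <- divergence_association(fpkm_a = c(10, 10, 10), fpkm_b = c(10, 5, 1),
                              rpm_a = c(3, 3, 3), rpm_b = c(3, 2, 0.1),
                              eps = 1e-9)
  expect_equal(d$pairs$fc_expression[1], 0)
  expect_equal(d$pairs$fc_accessibility[1], 0)
  # ratio exactly 2 belongs to the "<= 2" group
  expect_equal(d$pairs$expression_group[2], "fc_le_2")
  expect_equal(d$pairs$expression_group[3], "fc_gt_2")
})
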