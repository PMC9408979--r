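# Generator contracts: controlled CDS divergence, config edge cases,
# bundle readability and determinism of the mini-genome.

test_that("mutate_cds_pair applies exactly the requested substitutions", {
  anc <- random_cds(30, seed = 5)
  id <- mutate_cds_pair(anc, 0, 0, seed = 1)
  expect_identical(id$cds_a, id$cds_b)

  m <- mutate_cds_pair(anc, 3, 0, seed = 2)
  tr <- function(x) as.character(Biostrings::translate(Biostrings::DNAString(x)))
  expect_identical(tr(m$cds_a), tr(m$cds_b))  # protein unchanged
  diffs <- sum(strsplit(m$cds_a, "")[[1]] != strsplit(m$cds_b, "")[[1]])
  expect_equal(diffs, 3)
  expect_equal(m$syn_applied, 3)

  m2 <- mutate_cds_pair(anc, 2, 4, seed = 3)
  expect_equal(m2$syn_applied, 2)
  expect_equal(m2$nonsyn_applied, 4)
  # no stop codons ever introduced
  expect_false(grepl("\\*", tr(m2$cds_b)))

  # ATG (Met) admits no synonymous change at all
  expect_error(mutate_cds_pair("ATG", 1, 0, seed = 1), "could not place")
})

test_that("a tiny config produces a readable, consistent bundle", {
  cfg <- sim_config(n_chroms = 2, chrom_len = 4e5, n_genes = 60,
                    n_tes = 80, n_acrs = 100, n_gene_pairs = 6,
                    n_sweeps = 1, n_codons = 60, seed = 42)
  dir <- withr::local_tempdir()
  b <- simulate_genome(cfg, dir)
  expect_no_warning({
    tes <- read_te_bed(b$files$tes)
    genes <- read_gff3_genes(b$files$genes)
    sites <- read_cgmap(b$files$methylation)
    cov <- read_bedgraph(b$files$coverage)
    peaks <- lapply(cfg$tissues, function(t)
      read_bed(b$files[[paste0("acrs_", t)]]))
    wild <- read_vcf_lite(b$files$wild_vcf)
    cds <- read_cds_pairs(b$files$cds)
  })
  expect_equal(nrow(tes), 80)
  expect_equal(nrow(genes), 60)
  expect_equal(nrow(cds), 6)
  expect_equal(nrow(merge_acrs(peaks)), 100)
  # truth table covers every simulated peak with its coordinates
  expect_equal(nrow(b$truth$acrs), 100)
  # the realised substitution counts match the recorded truth Ks
  expect_equal(b$truth$pairs$true_ks,
               b$truth$pairs$syn_subs / b$truth$pairs$S_ancestral)
})

test_that("frac_tissue_specific = 0 yields no tissue-specific truth labels", {
  cfg <- sim_config(n_chroms = 2, chrom_len = 4e5, n_genes = 60,
                    n_tes = 80, n_acrs = 100, n_gene_pairs = 6,
                    n_sweeps = 1, n_codons = 60,
                    frac_tissue_specific = 0, seed = 7)
  b <- simulate_genome(cfg, withr::local_tempdir())
  expect_true(all(b$truth$acrs$specific_tissue == "none"))
})

test_that("without a sweep effect the two panels' pi are indistinguishable", {
  # 200 windows at reduction 1: the wild and cultivated windowed-pi
  # distributions should pass a KS test comfortably
  cfg <- sim_config(n_chroms = 2, chrom_len = 1e7, n_genes = 60,
                    n_tes = 80, n_acrs = 100, n_gene_pairs = 6,
                    n_sweeps = 3, sweep_pi_reduction = 1, n_codons = 60,
                    meth_step = 200, seed = 11)
  b <- simulate_genome(cfg, withr::local_tempdir())
  pw <- windowed_pi(read_vcf_lite(b$files$wild_vcf), b$chrom_sizes)
  pc <- windowed_pi(read_vcf_lite(b$files$cult_vcf), b$chrom_sizes)
  expect_equal(nrow(pw), 200)
  expect_gt(suppressWarnings(ks.test(pw$pi, pc$pi)$p.value), 0.01)
})

test_that("identical seeds give byte-identical bundles", {
  cfg <- sim_config(n_chroms = 2, chrom_len = 4e5, n_genes = 60,
                    n_tes = 80, n_acrs = 100, n_gene_pairs = 6,
                    n_sweeps = 1, n_codons = 60, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_genome(cfg, d1)
  simulate_genome(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})
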