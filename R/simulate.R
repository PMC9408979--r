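# Synthetic mini-genome generator. Produces a bundle of plain-text files --
# gene models, TE annotation, per-tissue peaks, count and expression
# matrices, ATAC coverage, CGmap methylation, wild/cultivated genotype
# panels, and duplicate-gene CDS pairs -- whose ground truth is recorded in
# companion tables, so every analysis stage can be exercised end to end.
#
# Layout strategy: each chromosome is divided into fixed-width slots and
# each slot hosts at most one feature group (a gene with optional promoter/
# genic/downstream peak, a standalone TE, a standalone distal peak, or a
# TE + embedded-peak combination). Slot margins guarantee >2 kb clearance
# between groups, so positional classes and TE coverage fractions are known
# exactly from the placement arithmetic.

#' Simulation configuration
#'
#' Defaults describe a small but structured genome: four 1.5-Mb
#' chromosomes; six tissues; a quarter of peaks TE-derived with coverage
#' drawn across the >50% boundary; 15% of peaks restricted to one tissue
#' with strongly concentrated read mass; hypermethylated TE bodies with
#' hypomethylated embedded peaks; three 100-kb domestication sweeps with a
#' 10-fold diversity reduction in the cultivated panel; and duplicate CDS
#' pairs with synonymous divergence spanning Ks 0.05-0.6.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_genes,n_tes,n_acrs Feature counts for the whole genome.
#' @param frac_te_derived_acrs Fraction of peaks that are TE-derived.
#' @param frac_tissue_specific Fraction of peaks restricted to one tissue.
#' @param tissues Tissue labels.
#' @param te_body_methylation,acr_methylation,background_methylation Named
#'   per-context (CG/CHG/CHH) methylation probabilities for cytosines in TE
#'   bodies, inside peaks, and elsewhere.
#' @param meth_depth Mean read depth per cytosine (Poisson).
#' @param meth_step Spacing between simulated cytosines in bp.
#' @param n_sweeps Number of 100-kb sweep windows.
#' @param sweep_pi_reduction Fold reduction of cultivated diversity inside
#'   sweeps (1 = none).
#' @param snp_spacing Mean spacing between variant sites in bp.
#' @param n_wild,n_cult Diploid sample sizes of the two panels.
#' @param n_gene_pairs Number of duplicate gene pairs.
#' @param n_codons Codons per simulated CDS.
#' @param ks_range,omega_range Ranges for true synonymous divergence and
#'   Ka/Ks of simulated pairs.
#' @param seed Master seed; component seeds are derived at fixed offsets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 4, chrom_len = 1.5e6,
                       n_genes = 240, n_tes = 400, n_acrs = 400,
                       frac_te_derived_acrs = 0.25,
                       frac_tissue_specific = 0.15,
                       tissues = c("YL", "FL", "RT", "SP", "LP", "YP"),
                       te_body_methylation = c(CG = 0.85, CHG = 0.70, CHH = 0.15),
                       acr_methylation = c(CG = 0.05, CHG = 0.03, CHH = 0.02),
                       background_methylation = c(CG = 0.30, CHG = 0.15, CHH = 0.04),
                       meth_depth = 20, meth_step = 20,
                       n_sweeps = 3, sweep_pi_reduction = 10,
                       snp_spacing = 150, n_wild = 5, n_cult = 15,
                       n_gene_pairs = 40, n_codons = 500,
                       ks_range = c(0.05, 0.6), omega_range = c(0.1, 0.5),
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(frac_te_derived_acrs >= 0, frac_te_derived_acrs <= 1,
            frac_tissue_specific >= 0, frac_tissue_specific <= 1,
            sweep_pi_reduction >= 1, n_chroms >= 1, chrom_len > 2e5)
  class(cfg) <- "sim_config"
  cfg
}

# -- CDS machinery -----------------------------------------------------------

#' Random stop-free coding sequence
#'
#' @param n_codons Number of codons.
#' @param seed RNG seed.
#' @return A nucleotide string of length 3 * n_codons without stop codons.
#' @export
random_cds <- function(n_codons, seed) {
  aa_tab <- .codon_aa()
  ok <- names(aa_tab)[aa_tab != "*"]
  with_seed(seed, paste(sample(ok, n_codons, replace = TRUE), collapse = ""))
}

# classify a single-base change; returns "syn", "nonsyn" or "stop"
#' @noRd
change_type <- function(codon, pos, base, aa_tab) {
  mut <- codon
  substr(mut, pos, pos) <- base
  if (aa_tab[[mut]] == "*") return("stop")
  if (aa_tab[[mut]] == aa_tab[[codon]]) "syn" else "nonsyn"
}

#' Derive a diverged copy of a CDS with controlled substitution counts
#'
#' Applies exactly `target_syn_subs` synonymous and `target_nonsyn_subs`
#' nonsynonymous single-base substitutions (classified against the current
#' sequence state, so repeat hits are possible) to a copy of the ancestral
#' CDS. Proposals that would create a stop codon are resampled. Returns the
#' unchanged ancestor as copy A and the mutated sequence as copy B together
#' with the realised substitution counts.
#'
#' @param ancestral_cds Stop-free nucleotide string, length divisible by 3.
#' @param target_syn_subs,target_nonsyn_subs Substitution counts to apply.
#' @param seed RNG seed.
#' @return list with `cds_a`, `cds_b`, `syn_applied`, `nonsyn_applied`.
#' @export
mutate_cds_pair <- function(ancestral_cds, target_syn_subs,
                            target_nonsyn_subs, seed) {
  aa_tab <- .codon_aa()
  codons <- split_codons(ancestral_cds)
  if (any(aa_tab[codons] == "*"))
    stop("mutate_cds_pair: ancestral CDS contains a stop codon")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    cur <- codons
    need <- c(syn = target_syn_subs, nonsyn = target_nonsyn_subs)
    applied <- c(syn = 0L, nonsyn = 0L)
    max_attempts <- 1000L * (sum(need) + 1L)
    attempts <- 0L
    while (sum(need) > 0L) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("mutate_cds_pair: could not place the requested substitutions (",
             "remaining syn=", need["syn"], ", nonsyn=", need["nonsyn"], ")")
      ci <- sample.int(length(cur), 1)
      pos <- sample.int(3, 1)
      b <- sample(setdiff(bases, substr(cur[ci], pos, pos)), 1)
      ty <- change_type(cur[ci], pos, b, aa_tab)
      if (ty == "stop" || need[[ty]] == 0L) next
      substr(cur[ci], pos, pos) <- b
      need[[ty]] <- need[[ty]] - 1L
      applied[[ty]] <- applied[[ty]] + 1L
    }
    list(cds_a = ancestral_cds, cds_b = paste(cur, collapse = ""),
         syn_applied = applied[["syn"]], nonsyn_applied = applied[["nonsyn"]])
  })
}

# -- placement helpers -------------------------------------------------------

# draw per-slot feature groups; returns data.frames for genes, tes, acrs
# with truth labels; coordinates are exact by construction
#' @noRd
place_features <- function(cfg) {
  slot_bp <- 5000L
  slots_per_chrom <- as.integer(cfg$chrom_len %/% slot_bp)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  slot_tab <- data.frame(chrom = rep(chroms, each = slots_per_chrom),
                         slot = rep(seq_len(slots_per_chrom) - 1L,
                                    times = cfg$n_chroms))
  slot_tab$start <- slot_tab$slot * slot_bp

  n_prom <- round(0.40 * cfg$n_acrs)
  n_genic <- round(0.10 * cfg$n_acrs)
  n_dn <- round(0.10 * cfg$n_acrs)
  n_dist <- cfg$n_acrs - n_prom - n_genic - n_dn
  n_td <- round(cfg$frac_te_derived_acrs * cfg$n_acrs)
  td_prom <- min(round(n_td / 2), n_prom)
  td_dist <- n_td - td_prom
  if (td_dist > n_dist)
    stop("simulate_genome: infeasible TE-derived fraction for the peak mix")
  gene_hosts <- n_prom + n_genic + n_dn
  if (cfg$n_genes < gene_hosts)
    stop("simulate_genome: n_genes too small to host the requested peaks")
  n_te_standalone <- cfg$n_tes - td_prom - td_dist
  if (n_te_standalone < 0)
    stop("simulate_genome: n_tes too small for the TE-derived peaks")
  n_slots_needed <- cfg$n_genes + n_dist + n_te_standalone
  if (n_slots_needed > nrow(slot_tab))
    stop("simulate_genome: genome too small for the requested feature counts",
         " (need ", n_slots_needed, " slots, have ", nrow(slot_tab), ")")

  kinds <- c(rep("gene", cfg$n_genes), rep("dist_acr", n_dist),
             rep("te", n_te_standalone))
  picked <- sample(nrow(slot_tab), length(kinds))
  slot_tab$kind <- NA_character_
  slot_tab$kind[picked] <- sample(kinds)

  superfams <- c("hAT", "Mutator", "Helitron", "PIF_Harbinger", "Tc1_Mariner",
                 "CACTA", "Gypsy", "Copia", "LINE", "SINE")
  fam_class <- c(hAT = "DNA", Mutator = "DNA", Helitron = "DNA",
                 PIF_Harbinger = "DNA", Tc1_Mariner = "DNA", CACTA = "DNA",
                 Gypsy = "retrotransposon", Copia = "retrotransposon",
                 LINE = "retrotransposon", SINE = "retrotransposon")

  genes <- list(); tes <- list(); acrs <- list()
  gene_rows <- slot_tab[!is.na(slot_tab$kind) & slot_tab$kind == "gene", ]
  # assign peak roles to gene slots
  gene_role <- sample(c(rep("prom", n_prom), rep("genic", n_genic),
                        rep("dn", n_dn),
                        rep("none", cfg$n_genes - gene_hosts)))
  prom_td_flag <- rep(FALSE, n_prom)
  prom_td_flag[sample(n_prom, td_prom)] <- TRUE
  prom_seen <- 0L

  for (i in seq_len(nrow(gene_rows))) {
    s <- gene_rows$start[i]; ch <- gene_rows$chrom[i]
    strand <- sample(c("+", "-"), 1)
    lg <- sample(1000:2200, 1)
    gs <- s + 2500L; ge <- gs + lg
    gid <- sprintf("g%04d", i)
    genes[[i]] <- data.frame(chrom = ch, start = gs, end = ge,
                             strand = strand, gene_id = gid)
    role <- gene_role[i]
    if (role == "prom") {
      prom_seen <- prom_seen + 1L
      td <- prom_td_flag[prom_seen]
      L <- 400L
      if (strand == "+") { as_ <- gs - L } else { as_ <- ge }
      o <- 0L
      if (td) {
        f <- stats::runif(1, 0.55, 0.95)
        o <- as.integer(round(f * L))
        lte <- 800L
        fam <- sample(superfams, 1)
        te_start <- if (strand == "+") as_ - (lte - o) else as_ + L - o
        tes[[length(tes) + 1L]] <- data.frame(
          chrom = ch, start = te_start, end = te_start + lte,
          strand = ".", superfamily = fam, te_class = fam_class[[fam]],
          has_acr = TRUE)
      }
      acrs[[length(acrs) + 1L]] <- data.frame(
        chrom = ch, start = as_, end = as_ + L,
        te_derived = td, te_coverage = o / L, class = "pACR",
        host_gene = gid)
    } else if (role == "genic") {
      acrs[[length(acrs) + 1L]] <- data.frame(
        chrom = ch, start = gs + 200L, end = gs + 600L,
        te_derived = FALSE, te_coverage = 0, class = "gACR",
        host_gene = gid)
    } else if (role == "dn") {
      as_ <- if (strand == "+") ge + 300L else gs - 700L
      acrs[[length(acrs) + 1L]] <- data.frame(
        chrom = ch, start = as_, end = as_ + 400L,
        te_derived = FALSE, te_coverage = 0, class = "dnACR",
        host_gene = gid)
    }
  }

  dist_rows <- slot_tab[!is.na(slot_tab$kind) & slot_tab$kind == "dist_acr", ]
  dist_td_flag <- rep(FALSE, nrow(dist_rows))
  if (td_dist > 0) dist_td_flag[sample(nrow(dist_rows), td_dist)] <- TRUE
  for (i in seq_len(nrow(dist_rows))) {
    s <- dist_rows$start[i]; ch <- dist_rows$chrom[i]
    L <- sample(300:500, 1)
    if (dist_td_flag[i]) {
      lte <- sample(800:1500, 1)
      te_start <- s + 2000L
      fam <- sample(superfams, 1)
      tes[[length(tes) + 1L]] <- data.frame(
        chrom = ch, start = te_start, end = te_start + lte,
        strand = ".", superfamily = fam, te_class = fam_class[[fam]],
        has_acr = TRUE)
      f <- stats::runif(1, 0.55, 0.95)
      o <- as.integer(round(f * L))
      as_ <- te_start + lte - o
      acrs[[length(acrs) + 1L]] <- data.frame(
        chrom = ch, start = as_, end = as_ + L,
        te_derived = TRUE, te_coverage = o / L, class = "dACR",
        host_gene = NA_character_)
    } else {
      as_ <- s + 2200L
      acrs[[length(acrs) + 1L]] <- data.frame(
        chrom = ch, start = as_, end = as_ + L,
        te_derived = FALSE, te_coverage = 0, class = "dACR",
        host_gene = NA_character_)
    }
  }

  te_rows <- slot_tab[!is.na(slot_tab$kind) & slot_tab$kind == "te", ]
  for (i in seq_len(nrow(te_rows))) {
    s <- te_rows$start[i]; ch <- te_rows$chrom[i]
    lte <- sample(800:2000, 1)
    fam <- sample(superfams, 1)
    tes[[length(tes) + 1L]] <- data.frame(
      chrom = ch, start = s + 1000L, end = s + 1000L + lte,
      strand = ".", superfamily = fam, te_class = fam_class[[fam]],
      has_acr = FALSE)
  }

  genes <- do.call(rbind, genes)
  tes <- do.call(rbind, tes)
  acrs <- do.call(rbind, acrs)
  ord <- order(acrs$chrom, acrs$start)
  acrs <- acrs[ord, , drop = FALSE]
  acrs$acr_id <- sprintf("sim_acr_%04d", seq_len(nrow(acrs)))
  tes <- tes[order(tes$chrom, tes$start), , drop = FALSE]
  tes$name <- sprintf("te_%04d", seq_len(nrow(tes)))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- rownames(tes) <- rownames(acrs) <- NULL
  list(genes = genes, tes = tes, acrs = acrs)
}

# -- component generators ----------------------------------------------------

#' @noRd
sim_counts <- function(cfg, acrs, exclude_idx = integer(0)) {
  n <- nrow(acrs)
  tis <- cfg$tissues
  n_spec <- round(cfg$frac_tissue_specific * n)
  pool <- setdiff(seq_len(n), exclude_idx)
  if (n_spec > length(pool))
    stop("simulate_genome: too few peaks left to host tissue-specific calls")
  spec_idx <- if (n_spec > 0) sample(pool, n_spec) else integer(0)
  spec_tissue <- rep(NA_character_, n)
  if (n_spec > 0) spec_tissue[spec_idx] <- sample(tis, n_spec, replace = TRUE)
  counts <- matrix(stats::rnbinom(n * length(tis), mu = 60, size = 8),
                   nrow = n, dimnames = list(acrs$acr_id, tis))
  for (i in spec_idx) {
    counts[i, ] <- stats::rnbinom(length(tis), mu = 4, size = 5)
    counts[i, spec_tissue[i]] <- stats::rnbinom(1, mu = 250, size = 10)
  }
  list(counts = counts, specific_tissue = spec_tissue)
}

#' @noRd
sim_methylation <- function(cfg, tes, acrs) {
  regions <- merge_acrs(list(
    data.frame(chrom = tes$chrom, start = pmax(0L, tes$start - 2000L),
               end = tes$end + 2000L),
    acrs[, c("chrom", "start", "end")]))
  pos <- unlist(lapply(seq_len(nrow(regions)), function(i)
    seq(regions$start[i], regions$end[i] - 1L, by = cfg$meth_step)))
  chrom <- rep(regions$chrom, times = vapply(seq_len(nrow(regions)),
    function(i) length(seq(regions$start[i], regions$end[i] - 1L,
                           by = cfg$meth_step)), integer(1)))
  ctx <- sample(c("CG", "CHG", "CHH"), length(pos), replace = TRUE,
                prob = c(0.3, 0.3, 0.4))
  p <- cfg$background_methylation[ctx]
  pts <- data.frame(chrom = chrom, start = pos, end = pos + 1L)
  in_te <- coverage_fraction(pts, tes[, c("chrom", "start", "end")]) > 0
  in_acr <- coverage_fraction(pts, acrs[, c("chrom", "start", "end")]) > 0
  p[in_te] <- cfg$te_body_methylation[ctx[in_te]]
  p[in_acr] <- cfg$acr_methylation[ctx[in_acr]]  # embedded peaks stay hypomethylated
  depth <- stats::rpois(length(pos), cfg$meth_depth)
  mC <- stats::rbinom(length(pos), depth, p)
  dinuc <- ifelse(ctx == "CG", "CG", ifelse(ctx == "CHG", "CA", "CT"))
  df <- data.frame(chrom = chrom, pos = pos, nucleotide = "C",
                   context = ctx, dinucleotide = dinuc,
                   methylated = mC, total = depth, covered = depth > 0,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' @noRd
sim_genotypes <- function(cfg, sweep_windows) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  out <- list()
  for (panel in c("wild", "cult")) {
    n_dip <- if (panel == "wild") cfg$n_wild else cfg$n_cult
    rows <- list()
    for (ch in chroms) {
      n_sites <- round(cfg$chrom_len / cfg$snp_spacing)
      pos <- sort(sample.int(cfg$chrom_len, n_sites))
      if (panel == "cult" && cfg$sweep_pi_reduction > 1) {
        sw <- sweep_windows[sweep_windows$chrom == ch, , drop = FALSE]
        if (nrow(sw)) {
          in_sweep <- rep(FALSE, n_sites)
          for (j in seq_len(nrow(sw)))
            in_sweep <- in_sweep | (pos > sw$start[j] & pos <= sw$end[j])
          keep <- !in_sweep |
            stats::runif(n_sites) < 1 / cfg$sweep_pi_reduction
          pos <- pos[keep]
          n_sites <- length(pos)
        }
      }
      freq <- stats::runif(n_sites, 0.05, 0.95)
      hap <- matrix(stats::runif(n_sites * 2 * n_dip) < freq,
                    nrow = n_sites)
      gt <- matrix(paste(hap[, seq(1, ncol(hap), 2)] * 1L,
                         hap[, seq(2, ncol(hap), 2)] * 1L, sep = "/"),
                   nrow = n_sites)
      rows[[ch]] <- data.frame(chrom = ch, pos = pos,
                               gt = I(gt), stringsAsFactors = FALSE)
    }
    out[[panel]] <- rows
  }
  out
}

#' @noRd
write_vcf <- function(rows, samples, path) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (r in rows) {
    gt <- r$gt
    lines <- paste(r$chrom, r$pos + 1L, ".", "A", "T", ".", "PASS", ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  close(con)
}

#' @noRd
sim_pairs <- function(cfg, acrs, genes) {
  # pool genes by TSS peak status implied by placement
  prom <- acrs[acrs$class == "pACR", , drop = FALSE]
  te_genes <- prom$host_gene[prom$te_derived]
  reg_genes <- unique(c(prom$host_gene[!prom$te_derived],
                        acrs$host_gene[acrs$class == "gACR"]))
  none_genes <- setdiff(genes$gene_id, c(te_genes, reg_genes))
  np <- cfg$n_gene_pairs
  n1 <- max(1, round(0.10 * np)); n2 <- round(0.35 * np)
  n3 <- round(0.30 * np); n_un <- np - n1 - n2 - n3
  need_te <- 2 * n1 + n2 + n3
  need_reg <- n2 + 2 * n_un
  if (length(te_genes) < need_te || length(reg_genes) < need_reg ||
      length(none_genes) < n3)
    stop("simulate_genome: not enough genes of each TSS-peak status for ",
         "the requested pair design")
  te_pool <- sample(te_genes); reg_pool <- sample(reg_genes)
  none_pool <- sample(none_genes)
  idx_te <- 0; idx_reg <- 0; idx_none <- 0
  pairs <- data.frame(gene_a = character(np), gene_b = character(np),
                      subgroup = character(np), stringsAsFactors = FALSE)
  r <- 0L
  for (i in seq_len(n1)) {
    pairs[r + i, ] <- c(te_pool[idx_te + 1], te_pool[idx_te + 2], "1")
    idx_te <- idx_te + 2
  }
  r <- r + n1
  for (i in seq_len(n2)) {
    pairs[r + i, ] <- c(te_pool[idx_te + 1], reg_pool[idx_reg + 1], "2")
    idx_te <- idx_te + 1; idx_reg <- idx_reg + 1
  }
  r <- r + n2
  for (i in seq_len(n3)) {
    pairs[r + i, ] <- c(te_pool[idx_te + 1], none_pool[idx_none + 1], "3")
    idx_te <- idx_te + 1; idx_none <- idx_none + 1
  }
  r <- r + n3
  for (i in seq_len(n_un)) {
    pairs[r + i, ] <- c(reg_pool[idx_reg + 1], reg_pool[idx_reg + 2],
                        "unassigned")
    idx_reg <- idx_reg + 2
  }
  modes <- c("WGD", "tandem", "proximal", "transposed", "dispersed")
  pairs$mode <- sample(modes, np, replace = TRUE)
  # deeper Ks for subgroup 2, shallow for subgroup 1 (older vs younger pairs)
  base_ks <- stats::runif(np, cfg$ks_range[1], cfg$ks_range[2])
  base_ks[pairs$subgroup == "1"] <- stats::runif(sum(pairs$subgroup == "1"),
    cfg$ks_range[1], mean(cfg$ks_range))
  base_ks[pairs$subgroup == "2"] <- stats::runif(sum(pairs$subgroup == "2"),
    mean(cfg$ks_range), cfg$ks_range[2])
  omega <- stats::runif(np, cfg$omega_range[1], cfg$omega_range[2])
  pairs$pair_id <- sprintf("pair_%03d", seq_len(np))
  pairs$true_ks_target <- base_ks
  pairs$true_omega_target <- omega
  pairs
}

#' Generate the full synthetic bundle
#'
#' Writes every file the pipeline consumes plus truth tables, all derived
#' deterministically from the config seed (component seeds at fixed
#' offsets). See the package vignette for what each file emulates.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths (`$files`), the truth
#'   tables (`$truth`), and the chromosome sizes (`$chrom_sizes`).
#' @export
simulate_genome <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_len, cfg$n_chroms), chroms)

  placed <- with_seed(cfg$seed + 101, place_features(cfg))
  genes <- placed$genes; tes <- placed$tes; acrs <- placed$acrs

  pairs <- with_seed(cfg$seed + 606, sim_pairs(cfg, acrs, genes))
  # promoter peaks of pair genes are divergence-scaled later; keep them out
  # of the tissue-specific pool so truth labels stay exact
  pair_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  pair_prom_idx <- which(acrs$class == "pACR" & acrs$host_gene %in% pair_genes)
  cm <- with_seed(cfg$seed + 202, sim_counts(cfg, acrs, pair_prom_idx))
  counts <- cm$counts
  acrs$specific_tissue <- cm$specific_tissue

  # sweep windows: non-adjacent 100-kb tiles
  windows_per_chrom <- as.integer(cfg$chrom_len %/% 1e5)
  sweep_windows <- with_seed(cfg$seed + 303, {
    all_w <- data.frame(
      chrom = rep(chroms, each = windows_per_chrom),
      start = rep((seq_len(windows_per_chrom) - 1L) * 1e5, cfg$n_chroms))
    pick <- sort(sample(seq(1, nrow(all_w), by = 2), cfg$n_sweeps))
    w <- all_w[pick, , drop = FALSE]
    w$end <- w$start + 1e5
    rownames(w) <- NULL
    w
  })

  geno <- with_seed(cfg$seed + 404, sim_genotypes(cfg, sweep_windows))
  meth <- with_seed(cfg$seed + 505, sim_methylation(cfg, tes, acrs))

  aa_tab <- .codon_aa()
  cds <- with_seed(cfg$seed + 707, {
    lapply(seq_len(nrow(pairs)), function(i) {
      anc <- random_cds(cfg$n_codons,
                        seed = (cfg$seed * 131 + i) %% .Machine$integer.max)
      S_anc <- sum(vapply(split_codons(anc),
                          function(x) sum(codon_syn_fractions(x, aa_tab)),
                          numeric(1)))
      N_anc <- 3 * cfg$n_codons - S_anc
      n_syn <- as.integer(round(pairs$true_ks_target[i] * S_anc))
      n_non <- as.integer(round(pairs$true_omega_target[i] *
                                pairs$true_ks_target[i] * N_anc))
      mut <- mutate_cds_pair(anc, n_syn, n_non,
                             seed = (cfg$seed * 157 + i) %% .Machine$integer.max)
      list(cds_a = mut$cds_a, cds_b = mut$cds_b,
           S_anc = S_anc, N_anc = N_anc,
           syn = mut$syn_applied, nonsyn = mut$nonsyn_applied)
    })
  })
  pairs$syn_subs <- vapply(cds, `[[`, integer(1), "syn")
  pairs$nonsyn_subs <- vapply(cds, `[[`, integer(1), "nonsyn")
  pairs$S_ancestral <- vapply(cds, `[[`, numeric(1), "S_anc")
  pairs$N_ancestral <- vapply(cds, `[[`, numeric(1), "N_anc")
  pairs$true_ks <- pairs$syn_subs / pairs$S_ancestral
  pairs$true_ka <- pairs$nonsyn_subs / pairs$N_ancestral
  pairs$true_omega <- ifelse(pairs$true_ks > 0,
                             pairs$true_ka / pairs$true_ks, NA_real_)

  # accessibility / expression divergence for pairs whose copies both have
  # a promoter peak (subgroups 1 and 2 plus the unassigned regular pairs)
  fpkm <- with_seed(cfg$seed + 808, {
    base <- stats::rlnorm(nrow(genes), meanlog = 3, sdlog = 1)
    m <- matrix(base, nrow = nrow(genes), ncol = length(cfg$tissues)) *
      matrix(stats::rlnorm(nrow(genes) * length(cfg$tissues), 0, 0.2),
             nrow = nrow(genes))
    dimnames(m) <- list(genes$gene_id, cfg$tissues)
    m
  })
  div <- with_seed(cfg$seed + 909, {
    da <- stats::rnorm(nrow(pairs), 0, 1.5)
    de <- da + stats::rnorm(nrow(pairs), 0, 0.3)
    list(da = da, de = de)
  })
  pairs$log2_acc_divergence <- div$da
  pairs$log2_expr_divergence <- div$de
  prom_of <- function(gid) match(TRUE, acrs$host_gene == gid &
                                   acrs$class == "pACR")
  counts <- with_seed(cfg$seed + 1010, {
    for (i in seq_len(nrow(pairs))) {
      ia <- prom_of(pairs$gene_a[i]); ib <- prom_of(pairs$gene_b[i])
      if (!is.na(ia) && !is.na(ib)) {
        counts[ib, ] <- pmax(0L, as.integer(round(
          counts[ia, ] * 2^(-div$da[i]) *
            stats::rlnorm(ncol(counts), 0, 0.1))))
        fpkm[pairs$gene_b[i], ] <- fpkm[pairs$gene_a[i], ] * 2^(-div$de[i])
      }
    }
    counts
  })

  # ---- write the bundle ----
  fp <- function(x) file.path(out_dir, x)
  files <- list()

  gff <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                 genes$chrom, genes$start + 1L, genes$end, genes$strand,
                 genes$gene_id)
  writeLines(c("##gff-version 3", gff), fp("genes.gff3"))
  files$genes <- fp("genes.gff3")

  te_out <- data.frame(tes$chrom, tes$start, tes$end, tes$name, 0,
                       tes$strand, tes$te_class, tes$superfamily)
  utils::write.table(te_out, fp("tes.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files$tes <- fp("tes.bed")

  acr_len <- acrs$end - acrs$start
  for (t in cfg$tissues) {
    sel <- is.na(acrs$specific_tissue) | acrs$specific_tissue == t
    a <- acrs[sel, , drop = FALSE]
    np <- data.frame(a$chrom, a$start, a$end, a$acr_id, 0, ".",
                     counts[a$acr_id, t], -1, -1,
                     (a$end - a$start) %/% 2L)
    f <- fp(sprintf("acrs_%s.narrowPeak", t))
    utils::write.table(np, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files[[paste0("acrs_", t)]] <- f
  }

  counts_df <- data.frame(acr_id = rownames(counts), counts,
                          check.names = FALSE)
  write_tsv(counts_df, fp("acr_counts.tsv"))
  files$counts <- fp("acr_counts.tsv")
  totals <- colSums(counts) * 50
  write_tsv(data.frame(tissue = names(totals), total = as.numeric(totals)),
            fp("tissue_totals.tsv"))
  files$totals <- fp("tissue_totals.tsv")

  cov <- data.frame(chrom = acrs$chrom, start = acrs$start, end = acrs$end,
                    value = round(counts[acrs$acr_id, "SP"] / acr_len, 4))
  cov <- cov[order(cov$chrom, cov$start), ]
  utils::write.table(cov, fp("coverage_SP.bedGraph"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  files$coverage <- fp("coverage_SP.bedGraph")

  write_cgmap(meth, fp("methylation.cgmap"))
  files$methylation <- fp("methylation.cgmap")

  wild_samples <- sprintf("wild_%02d", seq_len(cfg$n_wild))
  cult_samples <- sprintf("cult_%02d", seq_len(cfg$n_cult))
  write_vcf(geno$wild, wild_samples, fp("wild.vcf"))
  write_vcf(geno$cult, cult_samples, fp("cult.vcf"))
  files$wild_vcf <- fp("wild.vcf")
  files$cult_vcf <- fp("cult.vcf")

  fa <- character(0)
  for (i in seq_len(nrow(pairs))) {
    fa <- c(fa, paste0(">", pairs$pair_id[i], "_a ", pairs$gene_a[i]),
            cds[[i]]$cds_a,
            paste0(">", pairs$pair_id[i], "_b ", pairs$gene_b[i]),
            cds[[i]]$cds_b)
  }
  writeLines(fa, fp("cds_pairs.fasta"))
  files$cds <- fp("cds_pairs.fasta")

  fpkm_df <- data.frame(gene_id = rownames(fpkm), round(fpkm, 4),
                        check.names = FALSE)
  write_tsv(fpkm_df, fp("fpkm.tsv"))
  files$fpkm <- fp("fpkm.tsv")

  truth_acrs <- data.frame(acr_id = acrs$acr_id, chrom = acrs$chrom,
                           start = acrs$start, end = acrs$end,
                           te_derived = acrs$te_derived,
                           te_coverage = round(acrs$te_coverage, 4),
                           class = acrs$class,
                           specific_tissue = ifelse(
                             is.na(acrs$specific_tissue), "none",
                             acrs$specific_tissue),
                           host_gene = ifelse(is.na(acrs$host_gene), "none",
                                              acrs$host_gene))
  write_tsv(truth_acrs, fp("truth_acrs.tsv"))
  write_tsv(sweep_windows, fp("truth_sweeps.tsv"))
  truth_pairs <- pairs[, c("pair_id", "gene_a", "gene_b", "mode", "subgroup",
                           "syn_subs", "nonsyn_subs", "S_ancestral",
                           "N_ancestral", "true_ks", "true_ka", "true_omega",
                           "log2_acc_divergence", "log2_expr_divergence")]
  write_tsv(truth_pairs, fp("truth_pairs.tsv"))
  files$truth_acrs <- fp("truth_acrs.tsv")
  files$truth_sweeps <- fp("truth_sweeps.tsv")
  files$truth_pairs <- fp("truth_pairs.tsv")

  invisible(list(files = files,
                 truth = list(acrs = truth_acrs, sweeps = sweep_windows,
                              pairs = truth_pairs),
                 chrom_sizes = chrom_sizes))
}

#' Read a TE annotation written as BED6 plus class/superfamily columns
#'
#' Columns 7 and 8 carry the TE class ("DNA"/"retrotransposon") and the
#' superfamily label.
#'
#' @param path Path to the TE BED file.
#' @return data.frame `chrom`, `start`, `end`, `name`, `strand`,
#'   `te_class`, `superfamily`.
#' @export
read_te_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = c(1, 4, 6, 7, 8)),
                          data.table = FALSE)
  if (ncol(dt) < 8) stop("TE BED parse error: expected 8 columns")
  out <- data.frame(chrom = dt[[1]], start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]), name = dt[[4]],
                    strand = dt[[6]], te_class = dt[[7]],
                    superfamily = dt[[8]], stringsAsFactors = FALSE)
  validate_intervals(out, what = "TE BED")
  if (!all(out$te_class %in% c("DNA", "retrotransposon")))
    stop("TE BED validation error: te_class must be DNA or retrotransposon")
  out
}
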