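# Independent brute-force oracles. These deliberately avoid the package's
# code paths: per-bp bitmaps for coverage, pairwise scans for distances,
# explicit haplotype-pair enumeration for diversity, subset enumeration for
# the hypergeometric tail, and a from-scratch pathway enumerator for NG86
# difference counting.

oracle_coverage <- function(q_start, q_end, subjects) {
  if (nrow(subjects) == 0) return(0)
  covered <- logical(q_end - q_start)
  for (i in seq_len(nrow(subjects))) {
    a <- max(subjects$start[i], q_start); b <- min(subjects$end[i], q_end)
    if (b > a) covered[(a - q_start + 1):(b - q_start)] <- TRUE
  }
  mean(covered)
}

oracle_nearest <- function(q_start, q_end, subjects) {
  if (nrow(subjects) == 0) return(Inf)
  d <- numeric(nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects$start[i]; e <- subjects$end[i]
    d[i] <- if (e > q_start && s < q_end) 0
            else if (s >= q_end) s - q_end else q_start - e
  }
  min(d)
}

# fraction of differing haplotype pairs at a biallelic site
oracle_site_pi <- function(k, n) {
  hap <- c(rep(1, k), rep(0, n - k))
  pairs <- utils::combn(n, 2)
  mean(hap[pairs[1, ]] != hap[pairs[2, ]])
}

# mean pairwise difference per bp over a window, from raw haplotypes with
# missing data (pairwise-complete per site)
oracle_window_pi <- function(geno, span_bp) {
  tot <- 0
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, !is.na(geno[i, ])]
    n <- length(g)
    if (n < 2) next
    pairs <- utils::combn(n, 2)
    tot <- tot + mean(g[pairs[1, ]] != g[pairs[2, ]])
  }
  tot / span_bp
}

# upper-tail hypergeometric by enumeration of all draw subsets
oracle_hyper_tail <- function(population, successes, draws, observed) {
  labels <- c(rep(1, successes), rep(0, population - successes))
  subsets <- utils::combn(population, draws)
  hits <- colSums(matrix(labels[subsets], nrow = draws))
  mean(hits >= observed)
}

# NG86 difference counting by explicit pathway enumeration, written
# independently of the package internals (iterative permutation builder,
# direct genetic-code lookups)
oracle_ng86_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  perms <- switch(as.character(length(pos)),
    "1" = matrix(1, 1, 1),
    "2" = rbind(c(1, 2), c(2, 1)),
    "3" = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1)))
  results <- NULL
  for (r in seq_len(nrow(perms))) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (j in perms[r, ]) {
      p <- pos[j]
      nxt <- paste0(substr(cur, 1, p - 1), substr(c2, p, p),
                    substr(cur, p + 1, 3))
      if (code[[nxt]] == "*") { blocked <- TRUE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) results <- rbind(results, c(sd, nd))
  }
  if (is.null(results)) return(NULL)  # caller decides about all-blocked
  colMeans(results)
}

# NG86 synonymous site count of one codon, independent implementation
oracle_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  s <- 0
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, p, p)) next
    mut <- paste0(substr(codon, 1, p - 1), b, substr(codon, p + 1, 3))
    if (code[[mut]] != "*" && code[[mut]] == code[[codon]]) s <- s + 1 / 3
  }
  s
}

random_intervals <- function(n, chrom = "chr1", max_pos = 10000,
                             max_len = 500) {
  if (n == 0) return(iv(character(0), integer(0), integer(0)))
  start <- sample.int(max_pos - max_len, n, replace = TRUE)
  iv(chrom, start, start + sample.int(max_len, n, replace = TRUE))
}
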