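# Nucleotide diversity (pi) from haplotype matrices, 100-kb windowed pi for
# wild and cultivated panels, and the top-5% pi-ratio domestication sweep
# scan.

#' Per-site nucleotide diversity
#'
#' pi at a biallelic site with k alternate alleles among n called
#' haplotypes is 2k(n-k)/(n(n-1)), the proportion of haplotype pairs that
#' differ. Sites with fewer than two called haplotypes are uninformative
#' and return 0 contribution (NA).
#'
#' @param alt_count Integer vector of alternate-allele counts k.
#' @param called_haplotypes Integer vector of called haplotypes n per site.
#' @return Numeric vector of per-site pi; NA where n < 2.
#' @export
site_pi <- function(alt_count, called_haplotypes) {
  k <- as.numeric(alt_count); n <- as.numeric(called_haplotypes)
  if (any(k < 0 | k > n)) stop("site_pi: require 0 <= k <= n")
  out <- 2 * k * (n - k) / (n * (n - 1))
  out[n < 2] <- NA_real_
  out
}

# Per-site k and n from a read_vcf_lite() result
#' @noRd
site_counts <- function(vcf) {
  g <- vcf$geno
  data.frame(chrom = vcf$sites$chrom, pos = vcf$sites$pos,
             k = rowSums(g == 1L, na.rm = TRUE),
             n = rowSums(!is.na(g)),
             stringsAsFactors = FALSE)
}

#' Windowed per-bp nucleotide diversity
#'
#' Tiles each chromosome with non-overlapping windows from position 0 and
#' reports, per window, the sum of per-site pi over variant sites divided
#' by the full window span in bp (invariant sites contribute zero). Missing
#' genotypes are handled pairwise-complete: each site uses its own called
#' haplotype count.
#'
#' @param vcf Result of [read_vcf_lite()], or a data.frame with `chrom`,
#'   `pos`, `k`, `n` per site.
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param window_bp Window size (default 1e5).
#' @return data.frame `chrom`, `start`, `end`, `pi` (per bp), `n_sites`.
#' @export
windowed_pi <- function(vcf, chrom_sizes, window_bp = 1e5) {
  stopifnot(window_bp > 0, !is.null(names(chrom_sizes)))
  sites <- if (is.data.frame(vcf)) vcf else site_counts(vcf)
  sp <- site_pi(sites$k, sites$n)
  sp[is.na(sp)] <- 0
  out <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    sel <- sites$chrom == ch
    idx <- findInterval(sites$pos[sel], starts)
    pisum <- tapply_full(sp[sel], idx, length(starts))
    nsite <- tapply_full(rep(1L, sum(sel)), idx, length(starts))
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            pi = pisum / (ends - starts),
                            n_sites = as.integer(nsite),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan for domestication sweeps by windowed pi ratio
#'
#' Joins the wild and cultivated windowed-pi tables, forms the ratio
#' pi_wild / pi_cult on eligible windows (both panels informative and
#' cultivated pi > 0), takes the empirical `1 - top_frac` quantile of the
#' ratios as the sweep threshold, flags windows at or above it, and merges
#' adjacent flagged windows into sweep regions. The threshold is always
#' recomputed from the data, never hard-coded.
#'
#' @param pi_wild,pi_cult Window tables from [windowed_pi()] on identical
#'   tilings.
#' @param top_frac Fraction of eligible windows flagged (default 0.05).
#' @param min_sites Minimum variant sites per window in each panel for
#'   eligibility (default 1).
#' @return list with `windows` (the joined table plus `ratio`, `eligible`,
#'   `is_sweep`), `sweeps` (merged sweep regions), and `threshold`.
#' @export
sweep_scan <- function(pi_wild, pi_cult, top_frac = 0.05, min_sites = 1) {
  if (nrow(pi_wild) != nrow(pi_cult) ||
      any(pi_wild$chrom != pi_cult$chrom) ||
      any(pi_wild$start != pi_cult$start))
    stop("sweep_scan: window tilings differ between panels")
  w <- data.frame(chrom = pi_wild$chrom, start = pi_wild$start,
                  end = pi_wild$end,
                  pi_wild = pi_wild$pi, pi_cult = pi_cult$pi,
                  n_sites_wild = pi_wild$n_sites,
                  n_sites_cult = pi_cult$n_sites,
                  stringsAsFactors = FALSE)
  w$eligible <- w$n_sites_wild >= min_sites & w$n_sites_cult >= min_sites &
    w$pi_cult > 0
  if (sum(w$eligible) < 20)
    stop("sweep_scan: fewer than 20 eligible windows; quantile threshold unstable")
  w$ratio <- ifelse(w$eligible, w$pi_wild / w$pi_cult, NA_real_)
  threshold <- stats::quantile(w$ratio[w$eligible], probs = 1 - top_frac,
                               names = FALSE, type = 7)
  w$is_sweep <- w$eligible & w$ratio >= threshold
  flagged <- w[w$is_sweep, c("chrom", "start", "end"), drop = FALSE]
  sweeps <- if (nrow(flagged)) {
    gr <- GenomicRanges::reduce(as_granges(flagged), ignore.strand = TRUE)
    s <- from_granges(gr); s$strand <- NULL
    s
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  }
  list(windows = w, sweeps = sweeps, threshold = threshold)
}

#' Mean nucleotide diversity around peak centers
#'
#' Per peak, pi over the `span_bp` window centered on the peak anchor
#' (summit when present, else midpoint): sum of per-site pi in the window
#' divided by the window span.
#'
#' @param acrs Peak data.frame.
#' @param vcf [read_vcf_lite()] result or a `chrom`/`pos`/`k`/`n` site
#'   table.
#' @param span_bp Total window size centered on the peak (default 2000).
#' @return Numeric vector of per-peak mean pi (per bp).
#' @export
acr_pi <- function(acrs, vcf, span_bp = 2000) {
  validate_intervals(acrs, what = "acrs")
  sites <- if (is.data.frame(vcf)) vcf else site_counts(vcf)
  sp <- site_pi(sites$k, sites$n)
  sp[is.na(sp)] <- 0
  centers <- anchor_positions(acrs)
  a <- pmax(centers - span_bp %/% 2, 0)
  b <- a + span_bp
  out <- numeric(nrow(acrs))
  if (!nrow(sites)) return(out)
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, width = 1L))
  wgr <- GenomicRanges::GRanges(acrs$chrom, IRanges::IRanges(a + 1L, b))
  h <- GenomicRanges::findOverlaps(wgr, sgr, ignore.strand = TRUE)
  if (length(h)) {
    agg <- tapply_full(sp[S4Vectors::subjectHits(h)],
                       S4Vectors::queryHits(h), nrow(acrs))
    out <- as.numeric(agg)
  }
  out / span_bp
}
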