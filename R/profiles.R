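# Binned metaprofiles around anchors (peak centers, TSSs) and over scaled
# feature bodies: TE counts per bin, mean ATAC/conservation signal, and
# read-weighted methylation levels.
#
# Signal is consumed as bedGraph-style interval/value tables. Per-chromosome
# piecewise-constant accumulators (prefix integrals over breakpoints) give
# exact sums over arbitrary [a,b) windows without building per-bp vectors.

# Build, per chromosome, a prefix-integral lookup for a bedGraph table.
# Returns a function(chrom, a, b) -> c(sum, covered_bp) vectorised over a/b.
#' @noRd
make_accumulator <- function(signal) {
  validate_intervals(signal, what = "signal")
  by_chrom <- split(signal, signal$chrom)
  tabs <- lapply(by_chrom, function(s) {
    s <- s[order(s$start), , drop = FALSE]
    if (any(s$start[-1] < s$end[-nrow(s)]))
      stop("signal: overlapping bedGraph intervals on ", s$chrom[1])
    p <- as.numeric(rbind(s$start, s$end))          # breakpoints
    rate <- as.numeric(rbind(s$value, 0))           # value on [p_i, p_{i+1})
    mask <- as.numeric(rbind(rep(1, nrow(s)), 0))   # scored-bp indicator
    cum <- c(0, cumsum(diff(p) * rate[-length(rate)]))
    cmask <- c(0, cumsum(diff(p) * mask[-length(mask)]))
    list(p = p, rate = rate, mask = mask, cum = cum, cmask = cmask)
  })
  eval_at <- function(tab, x, cumv, ratev) {
    i <- findInterval(x, tab$p)
    out <- numeric(length(x))
    ok <- i >= 1
    ii <- i[ok]
    r <- ifelse(ii < length(tab$p), ratev[ii], 0)
    out[ok] <- cumv[ii] + (x[ok] - tab$p[ii]) * r
    out
  }
  function(chrom, a, b) {
    sums <- numeric(length(a)); bp <- numeric(length(a))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      tab <- tabs[[ch]]
      if (is.null(tab)) next
      sums[sel] <- eval_at(tab, b[sel], tab$cum, tab$rate) -
        eval_at(tab, a[sel], tab$cum, tab$rate)
      bp[sel] <- eval_at(tab, b[sel], tab$cmask, tab$mask) -
        eval_at(tab, a[sel], tab$cmask, tab$mask)
    }
    list(sum = sums, scored_bp = bp)
  }
}

# Anchor-relative bin coordinates: matrix of starts/ends per anchor
#' @noRd
flank_bins <- function(centers, flank, bin) {
  nb <- as.integer(2 * flank / bin)
  offs <- seq(-flank, flank - bin, by = bin)
  list(nb = nb, offsets = offs,
       starts = outer(centers, offs, `+`),
       ends = outer(centers, offs + bin, `+`))
}

#' Count features per bin around anchor centers
#'
#' For each 50-bp (by default) bin in a +/- `flank` window around every
#' anchor center, counts the features whose span overlaps the bin, sums
#' over anchors and divides by the number of anchors ("normalised feature
#' number"). The anchor center is the peak summit when a `summit_offset`
#' column is present, otherwise the midpoint.
#'
#' @param anchors Interval data.frame (at least one row).
#' @param features Interval data.frame to count (e.g. TEs).
#' @param flank Half-window in bp (default 2000).
#' @param bin Bin width in bp; must divide `2 * flank` (default 50).
#' @param per_kb If TRUE, values are additionally divided by bin size in kb.
#' @return data.frame with `bin_start`, `bin_end` (bp offsets relative to
#'   the anchor center) and `value`; attribute `n_anchors`.
#' @export
feature_count_profile <- function(anchors, features, flank = 2000, bin = 50,
                                  per_kb = FALSE) {
  validate_intervals(anchors, what = "anchors")
  if (nrow(anchors) == 0) stop("feature_count_profile: no anchors")
  if ((2 * flank) %% bin != 0)
    stop("feature_count_profile: bin must divide 2*flank")
  centers <- anchor_positions(anchors)
  fb <- flank_bins(centers, flank, bin)
  n <- nrow(anchors)
  starts <- pmax(as.vector(fb$starts), 0)
  ends <- pmax(as.vector(fb$ends), 0)
  keep <- ends > starts
  counts <- numeric(length(starts))
  if (nrow(features) > 0 && any(keep)) {
    bgr <- GenomicRanges::GRanges(rep(anchors$chrom, times = fb$nb)[keep],
                                  IRanges::IRanges(starts[keep] + 1, ends[keep]))
    counts[keep] <- GenomicRanges::countOverlaps(bgr, as_granges(features),
                                                 ignore.strand = TRUE)
  }
  value <- colSums(matrix(counts, nrow = n)) / n
  if (per_kb) value <- value / (bin / 1000)
  out <- data.frame(bin_start = fb$offsets, bin_end = fb$offsets + bin,
                    value = value)
  attr(out, "n_anchors") <- n
  attr(out, "normalization") <- if (per_kb) "per_anchor_per_kb" else "per_anchor"
  out
}

#' Mean signal per bin around anchor centers
#'
#' Averages a bedGraph signal over all anchors in fixed bins around the
#' anchor centers. Positions absent from the track are counted as zero for
#' coverage-style signal (`missing = "zero"`) or excluded from the bin
#' denominator for sparse scores such as conservation tracks
#' (`missing = "skip"`, where a bin with no scored bp reports NaN). Bins
#' truncated at chromosome edges contribute only their in-genome bp.
#'
#' @param anchors Interval data.frame.
#' @param signal bedGraph data.frame (`chrom`, `start`, `end`, `value`).
#' @param flank Half-window in bp (default 2000).
#' @param bin Bin width in bp (default 50).
#' @param missing "zero" or "skip".
#' @param chrom_sizes Optional named vector for right-edge truncation.
#' @return data.frame `bin_start`, `bin_end`, `value`; attribute
#'   `n_anchors`.
#' @export
signal_profile <- function(anchors, signal, flank = 2000, bin = 50,
                           missing = c("zero", "skip"), chrom_sizes = NULL) {
  missing <- match.arg(missing)
  validate_intervals(anchors, what = "anchors")
  if (nrow(anchors) == 0) stop("signal_profile: no anchors")
  if ((2 * flank) %% bin != 0) stop("signal_profile: bin must divide 2*flank")
  centers <- anchor_positions(anchors)
  fb <- flank_bins(centers, flank, bin)
  n <- nrow(anchors)
  acc <- make_accumulator(signal)
  a <- pmax(as.vector(fb$starts), 0)
  b <- pmax(as.vector(fb$ends), 0)
  chrom <- rep(anchors$chrom, times = fb$nb)
  if (!is.null(chrom_sizes)) {
    lim <- as.numeric(chrom_sizes[chrom])
    a <- pmin(a, lim); b <- pmin(b, lim)
  }
  res <- acc(chrom, a, b)
  num <- colSums(matrix(res$sum, nrow = n))
  den <- if (missing == "skip") colSums(matrix(res$scored_bp, nrow = n))
         else colSums(matrix(b - a, nrow = n))
  value <- ifelse(den > 0, num / den, NaN)
  out <- data.frame(bin_start = fb$offsets, bin_end = fb$offsets + bin,
                    value = value)
  attr(out, "n_anchors") <- n
  attr(out, "normalization") <- "mean_per_bp"
  out
}

#' Scaled-body metaprofile over features with fixed flanks
#'
#' Rescales each feature body to `body_bins` equal-fraction bins and adds
#' fixed-width bins over the +/- `flank` regions, the standard metagene
#' layout for plotting methylation or signal over TE bodies. Minus-strand
#' features are reversed so upstream always reads left. Features shorter
#' than `body_bins` bp are excluded (their count is reported via the
#' `n_excluded` attribute).
#'
#' @param features Interval data.frame (strand column honoured when present).
#' @param signal bedGraph data.frame.
#' @param flank Flank size in bp (default 2000).
#' @param body_bins Number of body bins (default 40).
#' @param flank_bin Flank bin width in bp (default 50).
#' @param missing "zero" or "skip" (see [signal_profile()]).
#' @return data.frame with `bin` (1..total), `region`
#'   (upstream/body/downstream) and `value`; attributes `n_features`,
#'   `n_excluded`.
#' @export
scaled_body_profile <- function(features, signal, flank = 2000,
                                body_bins = 40, flank_bin = 50,
                                missing = c("zero", "skip")) {
  missing <- match.arg(missing)
  validate_intervals(features, what = "features")
  if (flank %% flank_bin != 0)
    stop("scaled_body_profile: flank_bin must divide flank")
  len <- features$end - features$start
  keep <- len >= body_bins
  n_excluded <- sum(!keep)
  if (n_excluded) message("scaled_body_profile: excluded ", n_excluded,
                          " feature(s) shorter than ", body_bins, " bp")
  features <- features[keep, , drop = FALSE]
  if (nrow(features) == 0) stop("scaled_body_profile: no usable features")
  n <- nrow(features)
  nf <- as.integer(flank / flank_bin)
  total <- 2L * nf + body_bins
  strand <- if (!is.null(features$strand)) features$strand else rep("+", n)

  # per-feature bin boundaries on the forward genome, as n x (total+1)
  up <- outer(features$start, seq(-flank, 0, by = flank_bin), `+`)
  body <- features$start +
    outer(features$end - features$start, (0:body_bins) / body_bins)
  body <- matrix(round(body), nrow = n)
  dn <- outer(features$end, seq(0, flank, by = flank_bin), `+`)
  bounds <- cbind(up[, -ncol(up), drop = FALSE], body, dn[, -1, drop = FALSE])
  a <- bounds[, -ncol(bounds), drop = FALSE]
  b <- bounds[, -1, drop = FALSE]
  a[] <- pmax(a, 0); b[] <- pmax(b, a)

  acc <- make_accumulator(signal)
  res <- acc(rep(features$chrom, times = total), as.vector(a), as.vector(b))
  summ <- matrix(res$sum, nrow = n)
  denm <- if (missing == "skip") matrix(res$scored_bp, nrow = n)
          else b - a
  rev_rows <- strand == "-"
  if (any(rev_rows)) {
    summ[rev_rows, ] <- summ[rev_rows, total:1, drop = FALSE]
    denm[rev_rows, ] <- denm[rev_rows, total:1, drop = FALSE]
  }
  num <- colSums(summ); den <- colSums(denm)
  value <- ifelse(den > 0, num / den, NaN)
  out <- data.frame(bin = seq_len(total),
                    region = rep(c("upstream", "body", "downstream"),
                                 times = c(nf, body_bins, nf)),
                    value = value)
  attr(out, "n_features") <- n
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Read-weighted methylation metaprofile over feature bodies
#'
#' Convenience wrapper building per-bp numerator (methylated reads) and
#' denominator (total reads) tracks from a CGmap site table for one
#' context, then forming the per-bin ratio of their scaled-body sums --
#' i.e. the bulk methylation level per bin.
#'
#' @param features Interval data.frame (e.g. TE bodies).
#' @param sites CGmap site table from [read_cgmap()] (pre-filtered).
#' @param context One of "CG", "CHG", "CHH".
#' @inheritParams scaled_body_profile
#' @return data.frame `bin`, `region`, `value` (methylation level, NaN for
#'   bins without covered cytosines).
#' @export
methylation_body_profile <- function(features, sites, context,
                                     flank = 2000, body_bins = 40,
                                     flank_bin = 50) {
  s <- sites[sites$context == context & sites$total > 0, , drop = FALSE]
  if (nrow(s) == 0) stop("methylation_body_profile: no covered sites for ",
                         context)
  meth <- data.frame(chrom = s$chrom, start = s$pos, end = s$pos + 1L,
                     value = s$methylated)
  tot <- data.frame(chrom = s$chrom, start = s$pos, end = s$pos + 1L,
                    value = s$total)
  pm <- scaled_body_profile(features, meth, flank, body_bins, flank_bin,
                            missing = "skip")
  pt <- scaled_body_profile(features, tot, flank, body_bins, flank_bin,
                            missing = "skip")
  # per-bin mean-per-scored-bp ratio == sum(mC)/sum(total) in the bin
  pm$value <- ifelse(is.finite(pt$value) & pt$value > 0,
                     pm$value / pt$value, NaN)
  pm
}
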