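# Region-level DNA methylation from per-cytosine CGmap calls, with the
# minimum-coverage filter applied before any level is computed.

#' Keep cytosine sites with sufficient read coverage
#'
#' @param sites CGmap site table from [read_cgmap()].
#' @param min_cov Minimum total reads per site; sites with `total >=
#'   min_cov` are retained (default 5).
#' @return Filtered site table.
#' @export
filter_sites <- function(sites, min_cov = 5) {
  sites[sites$total >= min_cov, , drop = FALSE]
}

#' Read-weighted methylation level of one region
#'
#' Bulk level = sum(methylated) / sum(total) over the in-region sites of
#' the requested context -- read-weighted rather than a mean of per-site
#' levels, so deeply covered cytosines carry proportionally more weight.
#'
#' @param region Single-row interval data.frame (or list with `chrom`,
#'   `start`, `end`).
#' @param sites Pre-filtered CGmap site table.
#' @param context One of "CG", "CHG", "CHH".
#' @return Level in \[0, 1\], or NA when the region holds no covered site
#'   of that context.
#' @export
region_methylation <- function(region, sites, context) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  sel <- sites$context == context &
    sites$chrom == region$chrom[1] &
    sites$pos >= region$start[1] & sites$pos < region$end[1]
  tot <- sum(sites$total[sel])
  if (tot == 0) return(NA_real_)
  sum(sites$methylated[sel]) / tot
}

#' Methylation levels for many regions, all contexts
#'
#' Vectorised version of [region_methylation()]: one row per region and
#' context with the read-weighted level and the number of contributing
#' sites. Level is NA (and `n_sites` 0) when no covered site of that
#' context falls in the region.
#'
#' @param regions Interval data.frame; `name` used as region id when
#'   present.
#' @param sites Pre-filtered CGmap site table.
#' @param contexts Contexts to report (default all three).
#' @return data.frame `region_id`, `context`, `level`, `n_sites`.
#' @export
region_methylation_table <- function(regions, sites,
                                     contexts = c("CG", "CHG", "CHH")) {
  validate_intervals(regions, what = "regions")
  id <- if (!is.null(regions$name)) regions$name
        else sprintf("region_%d", seq_len(nrow(regions)))
  rgr <- as_granges(regions)
  out <- list()
  for (ctx in contexts) {
    s <- sites[sites$context == ctx, , drop = FALSE]
    meth <- numeric(nrow(regions)); tot <- numeric(nrow(regions))
    nsite <- integer(nrow(regions))
    if (nrow(s)) {
      sgr <- GenomicRanges::GRanges(s$chrom,
                                    IRanges::IRanges(s$pos + 1L, width = 1L))
      h <- GenomicRanges::findOverlaps(rgr, sgr, ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
      if (length(h)) {
        meth <- as.numeric(tapply_full(s$methylated[sh], qh, nrow(regions)))
        tot <- as.numeric(tapply_full(s$total[sh], qh, nrow(regions)))
        nsite <- as.integer(tapply_full(rep(1L, length(sh)), qh, nrow(regions)))
      }
    }
    out[[ctx]] <- data.frame(region_id = id, context = ctx,
                             level = ifelse(tot > 0, meth / tot, NA_real_),
                             n_sites = nsite, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# sum values by integer group over 1..n, zero-filled
#' @noRd
tapply_full <- function(values, group, n) {
  out <- numeric(n)
  agg <- rowsum(values, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
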