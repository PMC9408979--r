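# Relating TE-derived peaks near transcription start sites to duplicated
# gene pairs: per-gene TSS peak status, the three pair subgroups, and the
# accessibility-vs-expression divergence comparison.

#' Peak status in the +/- 500 bp TSS neighbourhood of each gene
#'
#' For every gene, looks at the closed window \[TSS - window, TSS + window\]
#' and reports "te_acr" when any TE-derived peak overlaps it by at least
#' 1 bp, else "regular_acr" when any peak does, else "none". TE-derived
#' peaks dominate when both kinds overlap.
#'
#' @param genes Gene data.frame (strand required).
#' @param acrs Peak data.frame.
#' @param te_derived Logical vector parallel to `acrs` (e.g. from
#'   [is_te_derived()]).
#' @param window Half-window around the TSS in bp (default 500; both ends
#'   inclusive).
#' @return Character vector per gene: "te_acr", "regular_acr" or "none".
#' @export
tss_acr_status <- function(genes, acrs, te_derived, window = 500) {
  validate_intervals(genes, require_strand = TRUE, what = "genes")
  validate_intervals(acrs, what = "acrs")
  stopifnot(length(te_derived) == nrow(acrs))
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0L, tss - window),
                    end = tss + window + 1L)  # closed window, half-open coords
  h <- GenomicRanges::findOverlaps(as_granges(win), as_granges(acrs),
                                   ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
  out <- rep("none", nrow(genes))
  has_any <- unique(qh)
  out[has_any] <- "regular_acr"
  has_te <- unique(qh[te_derived[sh]])
  out[has_te] <- "te_acr"
  out
}

#' Assign duplicate gene pairs to TSS-peak subgroups
#'
#' Subgroup 1: both copies have a TE-derived peak at the TSS; subgroup 2:
#' one copy TE-derived, the other a regular peak; subgroup 3: one copy
#' TE-derived, the other none. Pairs where neither copy has a TE-derived
#' peak are "unassigned" and excluded from subgroup contrasts.
#'
#' @param status_a,status_b Character vectors of per-copy statuses from
#'   [tss_acr_status()].
#' @return Character vector: "1", "2", "3" or "unassigned".
#' @export
assign_subgroups <- function(status_a, status_b) {
  stopifnot(length(status_a) == length(status_b))
  te_a <- status_a == "te_acr"; te_b <- status_b == "te_acr"
  other <- ifelse(te_a, status_b, status_a)
  ifelse(te_a & te_b, "1",
  ifelse((te_a | te_b) & other == "regular_acr", "2",
  ifelse((te_a | te_b) & other == "none", "3", "unassigned")))
}

#' Accessibility change of pairs split by expression divergence
#'
#' Computes per-pair absolute log2 fold changes of expression (FPKM) and
#' TSS-peak accessibility (RPM), splits pairs at expression fold change 2
#' (|log2 FC| > 1; a ratio of exactly 2 falls in the "<= 2" group), and
#' compares the accessibility changes of the two groups with a Wilcoxon
#' rank-sum test.
#'
#' @param fpkm_a,fpkm_b Per-pair expression of the two copies.
#' @param rpm_a,rpm_b Per-pair TSS-peak accessibility of the two copies.
#' @param eps Pseudocount added before the log ratio (default 0.01).
#' @return list with `pairs` (data.frame `fc_expression`,
#'   `fc_accessibility`, `expression_group`), per-group medians, and
#'   `p_value` of the rank-sum comparison (NA when a group is empty).
#' @export
divergence_association <- function(fpkm_a, fpkm_b, rpm_a, rpm_b, eps = 0.01) {
  stopifnot(eps > 0)
  fc_expr <- abs(log2((fpkm_a + eps) / (fpkm_b + eps)))
  fc_acc <- abs(log2((rpm_a + eps) / (rpm_b + eps)))
  grp <- ifelse(fc_expr > 1, "fc_gt_2", "fc_le_2")
  pairs <- data.frame(fc_expression = fc_expr, fc_accessibility = fc_acc,
                      expression_group = grp, stringsAsFactors = FALSE)
  hi <- fc_acc[grp == "fc_gt_2"]; lo <- fc_acc[grp == "fc_le_2"]
  p <- if (length(hi) && length(lo))
    stats::wilcox.test(hi, lo, alternative = "greater", exact = FALSE)$p.value
  else NA_real_
  list(pairs = pairs,
       median_fc_gt_2 = stats::median(hi),
       median_fc_le_2 = stats::median(lo),
       p_value = p)
}
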