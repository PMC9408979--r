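# Positional classification of merged peaks relative to gene models:
# promoter (pACR), genic (gACR), downstream (dnACR) and distal (dACR)
# classes, accessibility tertiles, and the gene <-> peak association map.

#' Classify peaks by position relative to genes
#'
#' Strand-aware windows per gene: promoter = 2 kb upstream of the TSS,
#' downstream = 2 kb past the TTS, genic = the gene body. A peak touching
#' several windows takes the highest-precedence class
#' (pACR > gACR > dnACR > dACR); distal (dACR) is assigned only when the
#' peak is more than `promoter_bp` from every gene body, so the four
#' classes partition the peak set. With no genes at all, every peak is
#' distal.
#'
#' @param acrs Peak data.frame; `name` used as id when present.
#' @param genes Gene data.frame from [read_gff3_genes()] (strand required).
#' @param promoter_bp Upstream window size in bp (default 2000).
#' @param downstream_bp Downstream window size in bp (default 2000).
#' @return data.frame with `acr_id`, `class` (factor pACR/gACR/dnACR/dACR),
#'   `anchor_gene`, `tss_distance` (signed bp; negative = upstream of the
#'   anchor gene's TSS).
#' @export
classify_position <- function(acrs, genes, promoter_bp = 2000,
                              downstream_bp = 2000) {
  validate_intervals(acrs, what = "acrs")
  id <- if (!is.null(acrs$name)) acrs$name else sprintf("acr_%d", seq_len(nrow(acrs)))
  lv <- c("pACR", "gACR", "dnACR", "dACR")
  n <- nrow(acrs)
  out <- data.frame(acr_id = id,
                    class = factor(rep("dACR", n), levels = lv),
                    anchor_gene = NA_character_,
                    tss_distance = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(genes) == 0) return(out)
  validate_intervals(genes, require_strand = TRUE, what = "genes")

  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end - 1L)  # 0-based TSS base
  # windows are widened by 1 bp on the outer edge so that a peak exactly
  # promoter_bp away (not ">2 kb from the gene", hence not distal) still
  # lands in the adjacent class and the four classes partition the peaks
  prom <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, pmax(0L, genes$start - promoter_bp - 1L), genes$end),
    end = ifelse(plus, genes$start, genes$end + promoter_bp + 1L))
  down <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, genes$end, pmax(0L, genes$start - downstream_bp - 1L)),
    end = ifelse(plus, genes$end + downstream_bp + 1L, genes$start))
  body <- genes[, c("chrom", "start", "end")]

  agr <- as_granges(acrs)
  # signed distance from a peak to a gene's TSS: 0 when the peak covers the
  # TSS base; otherwise edge distance, negative on the gene's upstream side
  signed_tss <- function(ai, gi) {
    as <- acrs$start[ai]; ae <- acrs$end[ai]
    t <- tss[gi]
    d <- ifelse(t >= as & t < ae, 0,
         ifelse(ae <= t, t - (ae - 1L), as - t))
    upstream <- ifelse(plus[gi], ae <= t, as > t)
    ifelse(upstream, -abs(d), abs(d))
  }
  hit_table <- function(win) {
    keep <- win$end > win$start
    wgr <- as_granges(win[keep, , drop = FALSE])
    h <- GenomicRanges::findOverlaps(agr, wgr, ignore.strand = TRUE)
    data.frame(ai = S4Vectors::queryHits(h),
               gi = which(keep)[S4Vectors::subjectHits(h)])
  }
  assign_class <- function(hits, cls) {
    if (!nrow(hits)) return()
    open <- out$class == "dACR" & is.na(out$anchor_gene)
    hits <- hits[open[hits$ai], , drop = FALSE]
    if (!nrow(hits)) return()
    d <- signed_tss(hits$ai, hits$gi)
    ord <- order(hits$ai, abs(d), genes$gene_id[hits$gi])
    first <- !duplicated(hits$ai[ord])
    ai <- hits$ai[ord][first]; gi <- hits$gi[ord][first]
    out$class[ai] <<- cls
    out$anchor_gene[ai] <<- genes$gene_id[gi]
    out$tss_distance[ai] <<- d[ord][first]
  }
  assign_class(hit_table(prom), "pACR")
  assign_class(hit_table(body), "gACR")
  assign_class(hit_table(down), "dnACR")

  # remaining peaks are distal; report the nearest gene for context
  rest <- which(out$class == "dACR")
  if (length(rest)) {
    ggr <- as_granges(genes)
    dn <- GenomicRanges::distanceToNearest(agr[rest], ggr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(dn); gi <- S4Vectors::subjectHits(dn)
    out$anchor_gene[rest[qh]] <- genes$gene_id[gi]
    out$tss_distance[rest[qh]] <- signed_tss(rest[qh], gi)
  }
  out
}

#' Split peaks into accessibility tertiles
#'
#' Ranks peaks by normalised read density (RPKM) and splits at the 1/3 and
#' 2/3 empirical quantiles into low/mid/high groups whose sizes differ by
#' at most one. Ties are broken by peak id so the split is deterministic.
#'
#' @param rpkm Numeric vector of non-negative, finite RPKM values.
#' @param ids Character ids used for deterministic tie-breaking (defaults
#'   to the element index).
#' @return Factor with levels low/mid/high, parallel to `rpkm`.
#' @export
accessibility_tertiles <- function(rpkm, ids = NULL) {
  stopifnot(all(is.finite(rpkm)), all(rpkm >= 0))
  n <- length(rpkm)
  if (is.null(ids)) ids <- sprintf("acr_%d", seq_len(n))
  lv <- c("low", "mid", "high")
  if (n == 0) return(factor(character(0), levels = lv))
  if (length(unique(rpkm)) == 1L) {
    warning("accessibility_tertiles: all RPKM equal; every peak labelled 'mid'")
    return(factor(rep("mid", n), levels = lv))
  }
  ord <- order(rpkm, ids)
  b <- n %/% 3L; r <- n %% 3L
  sizes <- c(low = b + (r >= 1), mid = b + (r >= 2), high = b)
  lab <- rep(lv, times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(out, levels = lv)
}

#' Map genes to the peaks overlapping their extended span
#'
#' A gene is ACR-related when its extended span (gene body plus `flank_bp`
#' on both sides, i.e. 2 kb upstream of the TSS through 2 kb downstream of
#' the TTS) overlaps at least one peak by at least 1 bp.
#'
#' @param genes Gene data.frame.
#' @param acrs Peak data.frame.
#' @param flank_bp Flank size in bp (default 2000).
#' @return Long data.frame with one row per (gene_id, acr_id) association.
#' @export
acr_related_genes <- function(genes, acrs, flank_bp = 2000) {
  validate_intervals(genes, require_strand = TRUE, what = "genes")
  validate_intervals(acrs, what = "acrs")
  id <- if (!is.null(acrs$name)) acrs$name else sprintf("acr_%d", seq_len(nrow(acrs)))
  span <- data.frame(chrom = genes$chrom,
                     start = pmax(0L, genes$start - flank_bp),
                     end = genes$end + flank_bp)
  h <- GenomicRanges::findOverlaps(as_granges(span), as_granges(acrs),
                                   ignore.strand = TRUE)
  data.frame(gene_id = genes$gene_id[S4Vectors::queryHits(h)],
             acr_id = id[S4Vectors::subjectHits(h)],
             stringsAsFactors = FALSE)
}

#' Reads per kilobase per million mapped reads
#'
#' @param count Read count(s) within the region.
#' @param length_bp Region length(s) in bp (> 0).
#' @param total_mapped Library size in mapped reads (> 0).
#' @return Numeric RPKM: count * 1e9 / (length_bp * total_mapped).
#' @export
rpkm <- function(count, length_bp, total_mapped) {
  if (any(length_bp <= 0)) stop("rpkm: length_bp must be > 0")
  if (any(total_mapped <= 0)) stop("rpkm: total_mapped must be > 0")
  count * 1e9 / (length_bp * total_mapped)
}
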