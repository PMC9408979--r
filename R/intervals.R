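# Deterministic interval computations underpinning every classification:
# TE coverage of peaks, summit overlap, nearest-TE distances, tissue merging,
# matched random controls, and simple sequence features.
#
# Overlap machinery is delegated to IRanges/GenomicRanges; this module owns
# the field-specific rules layered on top (the strict >50% coverage rule,
# the distance binning, class roll-up, etc.).

#' Fraction of a query interval covered by the union of subject intervals
#'
#' Overlapping subjects are unioned first so shared bp are not double
#' counted. Vectorised over queries.
#'
#' @param query Interval data.frame (0-based half-open).
#' @param subjects Interval data.frame.
#' @return Numeric vector in \[0, 1\], one value per query row; 0 when no
#'   subject overlaps.
#' @export
coverage_fraction <- function(query, subjects) {
  validate_intervals(query, what = "query")
  if (nrow(subjects) == 0) return(rep(0, nrow(query)))
  validate_intervals(subjects, what = "subjects")
  qgr <- as_granges(query)
  sgr <- GenomicRanges::reduce(as_granges(subjects), ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(qgr, sgr, ignore.strand = TRUE)
  ov <- IRanges::pintersect(qgr[S4Vectors::queryHits(hits)],
                            sgr[S4Vectors::subjectHits(hits)])
  covered <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
  out <- rep(0, nrow(query))
  idx <- as.integer(names(covered))
  out[idx] <- as.numeric(covered) / (query$end[idx] - query$start[idx])
  out
}

#' Is a peak TE-derived? (strictly more than half covered by TE sequence)
#'
#' A peak counts as TE-derived only when the union of overlapping TEs covers
#' strictly more than 50% of its length, so a peak exactly half covered is
#' not TE-derived.
#'
#' @param acrs Peak data.frame.
#' @param tes TE data.frame.
#' @param threshold Coverage threshold, exceeded strictly (default 0.5).
#' @return Logical vector, one per peak.
#' @export
is_te_derived <- function(acrs, tes, threshold = 0.5) {
  coverage_fraction(acrs, tes) > threshold
}

#' Does the peak summit fall inside any TE?
#'
#' The summit is the single-bp position `start + summit_offset` (midpoint
#' when no summit is recorded). Membership uses the half-open convention:
#' a TE \[s, e) contains the summit iff s <= summit < e.
#'
#' @param acrs Peak data.frame (optionally with `summit_offset`).
#' @param tes TE data.frame.
#' @return Logical vector, one per peak.
#' @export
summit_covered <- function(acrs, tes) {
  validate_intervals(acrs, what = "acrs")
  if (nrow(tes) == 0) return(rep(FALSE, nrow(acrs)))
  pos <- anchor_positions(acrs)
  pts <- data.frame(chrom = acrs$chrom, start = pos, end = pos + 1L)
  coverage_fraction(pts, tes) > 0
}

#' TE attribution for summit-covered peaks
#'
#' For each peak whose summit lies inside one or more TEs, reports the
#' superfamily and class of the innermost (shortest) covering TE, so nested
#' TEs attribute each peak exactly once.
#'
#' @param acrs Peak data.frame.
#' @param tes TE data.frame with `superfamily` and `te_class` columns.
#' @return data.frame with `covered` (logical), `superfamily`, `te_class`
#'   (NA when the summit is outside all TEs).
#' @export
summit_te_attribution <- function(acrs, tes) {
  validate_intervals(acrs, what = "acrs")
  pos <- anchor_positions(acrs)
  out <- data.frame(covered = rep(FALSE, nrow(acrs)),
                    superfamily = NA_character_,
                    te_class = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(tes) == 0) return(out)
  pts <- GenomicRanges::GRanges(acrs$chrom,
                                IRanges::IRanges(pos + 1L, width = 1L))
  tgr <- as_granges(tes)
  hits <- GenomicRanges::findOverlaps(pts, tgr, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- tes$end[sh] - tes$start[sh]
  ord <- order(qh, w)  # shortest covering TE first within each peak
  first <- !duplicated(qh[ord])
  qi <- qh[ord][first]; si <- sh[ord][first]
  out$covered[qi] <- TRUE
  out$superfamily[qi] <- tes$superfamily[si]
  out$te_class[qi] <- tes$te_class[si]
  out
}

#' Edge-to-edge distance from each query to its nearest subject
#'
#' Returns 0 for any overlap of at least 1 bp; otherwise the gap in bp
#' between the closest edges. Queries on chromosomes with no subject get
#' `Inf`.
#'
#' @param query,subjects Interval data.frames.
#' @return Numeric vector of distances (bp), `Inf` when no subject shares
#'   the chromosome.
#' @export
nearest_distance <- function(query, subjects) {
  validate_intervals(query, what = "query")
  out <- rep(Inf, nrow(query))
  if (nrow(subjects) == 0) return(out)
  validate_intervals(subjects, what = "subjects")
  qgr <- as_granges(query)
  sgr <- as_granges(subjects)
  # queries on chromosomes absent from the subject set are a legitimate
  # input (Inf sentinel); silence the disjoint-seqlevels notice
  d <- suppressWarnings(
    GenomicRanges::distanceToNearest(qgr, sgr, ignore.strand = TRUE))
  out[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  out
}

#' Bin nearest-TE distances into the reporting categories
#'
#' Categories: "0" (>= 1 bp overlap), "1-170", "171-500", "501-1000",
#' ">1000". Infinite distances (no TE on the chromosome) fall in ">1000".
#'
#' @param d Numeric distances from [nearest_distance()].
#' @return Factor with the five distance bins.
#' @export
bin_distance <- function(d) {
  lv <- c("0", "1-170", "171-500", "501-1000", ">1000")
  b <- ifelse(d == 0, lv[1],
       ifelse(d <= 170, lv[2],
       ifelse(d <= 500, lv[3],
       ifelse(d <= 1000, lv[4], lv[5]))))
  factor(b, levels = lv)
}

#' Roll up the TE class overlapping each peak
#'
#' A peak overlapping both DNA transposons and retrotransposons is assigned
#' the class contributing more covered bp; ties go to the DNA class.
#'
#' @param acrs Peak data.frame.
#' @param tes TE data.frame with `te_class` in {"DNA", "retrotransposon"}.
#' @return Character vector: "DNA", "retrotransposon" or NA for peaks with
#'   no TE overlap.
#' @export
te_class_rollup <- function(acrs, tes) {
  dna <- tes[tes$te_class == "DNA", , drop = FALSE]
  retro <- tes[tes$te_class == "retrotransposon", , drop = FALSE]
  len <- acrs$end - acrs$start
  cov_dna <- coverage_fraction(acrs, dna) * len
  cov_retro <- coverage_fraction(acrs, retro) * len
  out <- rep(NA_character_, nrow(acrs))
  any_cov <- (cov_dna + cov_retro) > 0
  out[any_cov] <- ifelse(cov_dna[any_cov] >= cov_retro[any_cov],
                         "DNA", "retrotransposon")
  out
}

#' Merge per-tissue peak sets into a union set
#'
#' Any two intervals sharing at least 1 bp are merged transitively;
#' half-open abutting intervals (\[a,b) and \[b,c)) are kept separate.
#' Output is sorted by (chrom, start) and named `macr_<i>`.
#'
#' @param collections A list of peak data.frames (one per tissue) or a
#'   single data.frame.
#' @return data.frame of merged intervals with a `name` column.
#' @export
merge_acrs <- function(collections) {
  if (is.data.frame(collections)) collections <- list(collections)
  all <- do.call(rbind, lapply(collections, function(x) {
    validate_intervals(x, what = "merge_acrs input")
    x[, c("chrom", "start", "end")]
  }))
  if (nrow(all) == 0) return(data.frame(chrom = character(0),
                                        start = integer(0), end = integer(0),
                                        name = character(0)))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(as_granges(all)),
                              ignore.strand = TRUE, min.gapwidth = 0L)
  out <- from_granges(gr)
  out$strand <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$name <- sprintf("macr_%d", seq_len(nrow(out)))
  out
}

#' Random control regions matched in number and length
#'
#' Draws one control per template with the template's exact length: the
#' chromosome is chosen with probability proportional to its length (among
#' chromosomes long enough to hold the template, redrawing rather than
#' clipping at ends) and the start uniformly within the allowed range.
#'
#' @param templates Interval data.frame whose lengths are copied.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param n_sets Number of independent control sets.
#' @param seed Integer RNG seed.
#' @return A list of `n_sets` interval data.frames.
#' @export
random_matched_regions <- function(templates, chrom_sizes, n_sets = 1, seed) {
  validate_intervals(templates, what = "templates")
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  lens <- templates$end - templates$start
  if (any(lens > max(chrom_sizes)))
    stop("random_matched_regions: template longer than every chromosome")
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      chroms <- character(length(lens))
      starts <- integer(length(lens))
      for (i in seq_along(lens)) {
        ok <- chrom_sizes >= lens[i]
        cs <- chrom_sizes[ok]
        ch <- sample(names(cs), 1, prob = cs)
        chroms[i] <- ch
        starts[i] <- floor(stats::runif(1, 0, chrom_sizes[[ch]] - lens[i] + 1))
      }
      data.frame(chrom = chroms, start = starts, end = starts + lens,
                 stringsAsFactors = FALSE)
    })
  })
}

#' GC content of nucleotide sequences
#'
#' (G+C)/(A+C+G+T); N bases are excluded from the denominator. An all-N
#' sequence yields NA.
#'
#' @param sequence Character vector of ACGTN sequences (case-insensitive).
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(sequence) {
  seqs <- Biostrings::DNAStringSet(toupper(sequence))
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  out <- (freq[, "G"] + freq[, "C"]) / denom
  out[denom == 0] <- NA_real_
  as.numeric(out)
}

#' Per-peak TE classification table
#'
#' One-stop annotation combining the TE-coverage rule, summit coverage,
#' nearest-TE distance and class roll-up, matching the columns a
#' peak-annotation report needs.
#'
#' @param acrs Peak data.frame (name column used as id when present).
#' @param tes TE data.frame with `te_class`, `superfamily`.
#' @return data.frame with `acr_id`, `te_coverage`, `te_derived`,
#'   `summit_covered`, `summit_superfamily`, `nearest_te_bp`,
#'   `distance_bin`, `te_class`.
#' @export
classify_te_acrs <- function(acrs, tes) {
  id <- if (!is.null(acrs$name)) acrs$name else sprintf("acr_%d", seq_len(nrow(acrs)))
  cov <- coverage_fraction(acrs, tes)
  att <- summit_te_attribution(acrs, tes)
  d <- nearest_distance(acrs, tes)
  data.frame(acr_id = id,
             te_coverage = cov,
             te_derived = cov > 0.5,
             summit_covered = att$covered,
             summit_superfamily = att$superfamily,
             nearest_te_bp = d,
             distance_bin = bin_distance(d),
             te_class = te_class_rollup(acrs, tes),
             stringsAsFactors = FALSE)
}
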