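# Readers and writers for the plain-text formats the pipeline touches.
# Every reader emits 0-based half-open coordinates regardless of the source
# dialect; 1-based formats (GFF3, CGmap, VCF) are converted on ingest.

#' Read a BED / BED6 / narrowPeak file
#'
#' Accepts 3+ tab-separated columns. Column 4 is taken as the feature name,
#' column 5 as the score, column 6 as the strand and, for 10-column
#' narrowPeak input, column 10 as the summit offset from the feature start.
#' A narrowPeak summit of -1 (absent) defaults to the feature midpoint so
#' that every peak has a usable center.
#'
#' @param path Path to a BED-like file.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) plus `name`, `score`, `strand`, `summit_offset` when the
#'   corresponding columns are present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = 1), fill = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 3) stop("BED parse error: fewer than 3 columns in ", path)
  bad <- which(is.na(dt[[2]]) | is.na(dt[[3]]))
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": non-numeric coordinates")
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]),
                    stringsAsFactors = FALSE)
  bad <- which(out$end <= out$start | out$start < 0)
  if (length(bad))
    stop("BED validation error at line ", bad[1],
         ": end must be > start and start >= 0")
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) out$score <- as.numeric(dt[[5]])
  if (ncol(dt) >= 6) {
    s <- as.character(dt[[6]])
    if (!all(s %in% c("+", "-", ".")))
      stop("BED validation error: strand must be '+', '-' or '.'")
    out$strand <- s
  }
  if (ncol(dt) >= 10) {
    su <- as.integer(dt[[10]])
    len <- out$end - out$start
    su[is.na(su) | su < 0] <- (len %/% 2L)[is.na(su) | su < 0]
    if (any(su >= len))
      stop("BED validation error: summit offset outside the peak")
    out$summit_offset <- su
  }
  out
}

#' Write intervals as BED / narrowPeak
#'
#' Emits 10-column narrowPeak when `summit_offset` is present, BED6 when
#' `name`/`score`/`strand` are present, otherwise BED3. Inverse of
#' [read_bed()] for the columns it writes.
#'
#' @param x Interval data.frame as returned by [read_bed()].
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, what = "write_bed input")
  n <- nrow(x)
  name <- if (!is.null(x$name)) x$name else paste0("region_", seq_len(n))
  score <- if (!is.null(x$score)) x$score else rep(0, n)
  strand <- if (!is.null(x$strand)) x$strand else rep(".", n)
  if (!is.null(x$summit_offset)) {
    out <- data.frame(x$chrom, x$start, x$end, name, score, strand,
                      0, -1, -1, x$summit_offset)
  } else if (!is.null(x$name) || !is.null(x$score) || !is.null(x$strand)) {
    out <- data.frame(x$chrom, x$start, x$end, name, score, strand)
  } else {
    out <- data.frame(x$chrom, x$start, x$end)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps rows whose feature type is `gene`, converts the 1-based closed GFF
#' coordinates to 0-based half-open, and extracts the `ID` attribute as
#' `gene_id`. Strand is mandatory for genes because the transcription start
#' site (TSS) is strand-dependent.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   in file order.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(data.frame(chrom = character(0),
                                        start = integer(0), end = integer(0),
                                        strand = character(0),
                                        gene_id = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 9))
    stop("GFF3 parse error at line ", which(nf < 9)[1], ": expected 9 columns")
  m <- do.call(rbind, f)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) return(data.frame(chrom = character(0),
                                  start = integer(0), end = integer(0),
                                  strand = character(0),
                                  gene_id = character(0)))
  strand <- m[, 7]
  if (!all(strand %in% c("+", "-")))
    stop("GFF3 validation error: gene rows must have strand '+' or '-'")
  gid <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  gid[!grepl("ID=", m[, 9])] <- paste0("gene_", which(!grepl("ID=", m[, 9])))
  out <- data.frame(chrom = m[, 1],
                    start = as.integer(m[, 4]) - 1L,
                    end = as.integer(m[, 5]),
                    strand = strand,
                    gene_id = gid,
                    stringsAsFactors = FALSE)
  validate_intervals(out, require_strand = TRUE, what = "GFF3 genes")
  out
}

#' Read per-cytosine methylation calls in CGmap format
#'
#' CGmap columns: chrom, nucleotide (C or G), 1-based position, context
#' (CG/CHG/CHH), dinucleotide, methylation level, methylated read count,
#' total read count. Positions are converted to 0-based. Sites with zero
#' total reads are retained and flagged via the `covered` column.
#'
#' @param path Path to a CGmap file.
#' @return data.frame with `chrom`, `pos` (0-based), `nucleotide`,
#'   `context`, `dinucleotide`, `methylated`, `total`, `covered`.
#' @export
read_cgmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = c(1, 2, 4, 5)),
                          data.table = FALSE)
  if (ncol(dt) != 8) stop("CGmap parse error: expected 8 columns")
  ctx <- dt[[4]]
  bad <- which(!ctx %in% c("CG", "CHG", "CHH"))
  if (length(bad))
    stop("CGmap validation error at line ", bad[1], ": unknown context '",
         ctx[bad[1]], "'")
  mC <- as.integer(dt[[7]]); tot <- as.integer(dt[[8]])
  bad <- which(mC > tot)
  if (length(bad))
    stop("CGmap validation error at line ", bad[1],
         ": methylated count exceeds total count")
  data.frame(chrom = dt[[1]], pos = as.integer(dt[[3]]) - 1L,
             nucleotide = dt[[2]], context = ctx, dinucleotide = dt[[5]],
             methylated = mC, total = tot, covered = tot > 0L,
             stringsAsFactors = FALSE)
}

#' Write methylation sites in CGmap format
#'
#' Inverse of [read_cgmap()]; the level column is recomputed as
#' methylated/total (0 for uncovered sites).
#' @param x Site table as returned by [read_cgmap()].
#' @param path Output path.
#' @export
write_cgmap <- function(x, path) {
  lev <- ifelse(x$total > 0, x$methylated / x$total, 0)
  out <- data.frame(x$chrom, x$nucleotide, x$pos + 1L, x$context,
                    x$dinucleotide, formatC(lev, format = "g", digits = 6),
                    x$methylated, x$total)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a 4-column bedGraph file (track lines are skipped).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 5)
  skip <- sum(startsWith(lines, "track") | startsWith(lines, "#"))
  dt <- data.table::fread(path, sep = "\t", header = FALSE, skip = skip,
                          colClasses = list(character = 1),
                          data.table = FALSE)
  if (ncol(dt) != 4) stop("bedGraph parse error: expected 4 columns")
  out <- data.frame(chrom = dt[[1]], start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]), value = as.numeric(dt[[4]]),
                    stringsAsFactors = FALSE)
  validate_intervals(out, what = "bedGraph")
  out
}

#' Read a genotype matrix from a minimal (GT-only) VCF
#'
#' Parses biallelic SNP records into a site table plus a haplotype matrix:
#' each diploid sample contributes two columns, values are alternate-allele
#' indicators (0/1) or NA. Half-missing genotypes ("./1") are treated as
#' fully missing, a conservative choice for diversity estimation.
#' Multi-allelic records are skipped; their count is attached as the
#' `n_skipped` attribute and reported in one warning.
#'
#' @param path Path to a VCF file with GT fields.
#' @return list with `sites` (data.frame `chrom`, `pos` 0-based, `ref`,
#'   `alt`) and `geno` (sites x haplotypes integer matrix), plus attribute
#'   `n_skipped` on the list.
#' @export
read_vcf_lite <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("VCF parse error: missing #CHROM header line")
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  if (!length(body)) {
    res <- list(sites = data.frame(chrom = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0)),
                geno = matrix(NA_integer_, 0, 2 * length(samples)))
    attr(res, "n_skipped") <- 0L
    return(res)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  m <- do.call(rbind, f)
  multi <- grepl(",", m[, 5], fixed = TRUE)
  n_skipped <- sum(multi)
  if (n_skipped)
    warning("read_vcf_lite: skipped ", n_skipped, " multi-allelic record(s)")
  m <- m[!multi, , drop = FALSE]
  sites <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]) - 1L,
                      ref = m[, 4], alt = m[, 5], stringsAsFactors = FALSE)
  gt <- m[, -(1:9), drop = FALSE]
  # keep the GT subfield only
  gt <- sub(":.*", "", gt)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  half_missing <- (a1 == ".") != (a2 == ".")
  a1[half_missing] <- "."; a2[half_missing] <- "."
  to_int <- function(a) {
    v <- suppressWarnings(as.integer(a))
    if (any(!is.na(v) & !v %in% c(0L, 1L)))
      stop("VCF validation error: non-biallelic allele index in GT")
    v
  }
  g1 <- matrix(to_int(a1), nrow = nrow(m))
  g2 <- matrix(to_int(a2), nrow = nrow(m))
  geno <- matrix(NA_integer_, nrow = nrow(m), ncol = 2 * length(samples))
  geno[, seq(1, ncol(geno), by = 2)] <- g1
  geno[, seq(2, ncol(geno), by = 2)] <- g2
  colnames(geno) <- paste0(rep(samples, each = 2), c("_1", "_2"))
  res <- list(sites = sites, geno = geno)
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Down-sample per-region read counts to a fixed total
#'
#' Draws a multivariate hypergeometric subsample of reads without
#' replacement, emulating depth equalisation across libraries before
#' comparing accessibility. The draw is reproducible for a fixed seed and
#' conserves the target total exactly.
#'
#' @param counts Non-negative integer vector of per-region read counts.
#' @param target_total Desired total after down-sampling; must not exceed
#'   `sum(counts)`.
#' @param seed Integer RNG seed.
#' @return Integer vector of the same length summing to `target_total`.
#' @export
downsample_counts <- function(counts, target_total, seed) {
  stopifnot(all(counts >= 0), target_total >= 0)
  total <- sum(counts)
  if (target_total > total)
    stop("downsample_counts: target_total (", target_total,
         ") exceeds available total (", total, ")")
  if (target_total == total) return(as.integer(counts))
  with_seed(seed, {
    out <- integer(length(counts))
    remaining <- total
    need <- target_total
    for (i in seq_along(counts)) {
      if (need == 0L) break
      remaining <- remaining - counts[i]
      # draw how many of the needed reads come from bin i, given the rest
      k <- stats::rhyper(1, counts[i], remaining, need)
      out[i] <- k
      need <- need - k
    }
    out
  })
}
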