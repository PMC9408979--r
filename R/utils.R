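# Internal helpers shared across modules.

#' Run code with a temporarily-seeded RNG, restoring global state afterwards
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Validate a data.frame of 0-based half-open intervals
#'
#' Columns required: chrom, start, end; optional strand (one of "+", "-", ".").
#' @noRd
validate_intervals <- function(x, require_strand = FALSE, what = "intervals") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  if (any(x$start < 0))
    stop(what, ": negative start coordinate")
  if (any(x$end <= x$start))
    stop(what, ": end must be strictly greater than start (0-based half-open)")
  if (require_strand) {
    if (is.null(x$strand))
      stop(what, ": strand column required")
    if (!all(x$strand %in% c("+", "-")))
      stop(what, ": strand must be '+' or '-'")
  } else if (!is.null(x$strand) &&
             !all(x$strand %in% c("+", "-", "."))) {
    stop(what, ": strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

#' Convert a 0-based half-open interval data.frame to a GRanges
#' @noRd
as_granges <- function(x, keep = character(0)) {
  strand <- if (!is.null(x$strand)) {
    s <- x$strand
    s[s == "."] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- x[[k]]
  gr
}

#' Convert a GRanges back to the package's 0-based half-open data.frame
#' @noRd
from_granges <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = s,
    stringsAsFactors = FALSE
  )
}

#' Interval midpoint / anchor position (0-based bp of the single anchor base)
#'
#' Uses the summit when a `summit_offset` column is present and non-NA,
#' otherwise the midpoint floor(start + length/2).
#' @noRd
anchor_positions <- function(x) {
  mid <- x$start + (x$end - x$start) %/% 2L
  if (!is.null(x$summit_offset)) {
    use <- !is.na(x$summit_offset)
    mid[use] <- x$start[use] + x$summit_offset[use]
  }
  mid
}

#' Write a data.frame as a plain TSV with a header line
#' @noRd
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
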