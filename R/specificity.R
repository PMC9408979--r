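# Tissue specificity of merged peaks: RPM quantification, Shannon entropy
# over the per-tissue accessibility distribution, the ascending-entropy
# top-15% rule, fold changes, and TE-superfamily enrichment among the
# tissue-specific peaks.

#' Reads-per-million matrix for merged peaks
#'
#' @param counts Matrix or data.frame of per-peak, per-tissue read counts
#'   (rows = peaks, columns = tissues).
#' @param totals Named vector of per-tissue mapped-read totals (> 0),
#'   covering every column of `counts`.
#' @return Numeric matrix of RPM values: count * 1e6 / total.
#' @export
rpm_matrix <- function(counts, totals) {
  m <- as.matrix(counts)
  miss <- setdiff(colnames(m), names(totals))
  if (length(miss))
    stop("rpm_matrix: no mapped-read total for tissue(s): ",
         paste(miss, collapse = ", "))
  tot <- as.numeric(totals[colnames(m)])
  if (any(tot <= 0)) stop("rpm_matrix: totals must be > 0")
  sweep(m, 2, tot, `/`) * 1e6
}

#' Shannon entropy of a peak's accessibility across tissues
#'
#' Normalises each row to a probability vector p and returns
#' H = -sum(p * log2 p) with 0*log(0) = 0. Low entropy means accessibility
#' is concentrated in few tissues. Rows summing to zero are unquantifiable
#' and return NA (they carry no entropy and are excluded from ranking).
#'
#' @param rpm Numeric matrix (peaks x tissues) or a single row vector.
#' @return Numeric vector of entropies in bits, in \[0, log2(T)\].
#' @export
shannon_entropy <- function(rpm) {
  if (is.null(dim(rpm))) rpm <- matrix(rpm, nrow = 1)
  if (any(rpm < 0)) stop("shannon_entropy: negative accessibility value")
  tot <- rowSums(rpm)
  p <- rpm / ifelse(tot > 0, tot, 1)
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  h[tot == 0] <- NA_real_
  h
}

#' Call tissue-specific peaks by the ascending-entropy top-fraction rule
#'
#' Quantifiable peaks (non-NA entropy) are sorted by ascending entropy and
#' the first floor(top_frac * N) are called tissue-specific; each specific
#' peak is assigned the tissue with maximal RPM. Ties in entropy are broken
#' in favour of the higher maximal RPM, then by peak id, so the call set is
#' deterministic.
#'
#' @param rpm Numeric matrix (peaks x tissues) with tissue column names.
#' @param ids Character peak ids (default row index).
#' @param top_frac Fraction called specific (default 0.15).
#' @return data.frame `acr_id`, per-input-order: `entropy_bits`, `rank`
#'   (NA for unquantifiable peaks), `is_specific`, `specific_tissue`,
#'   `fold_change`.
#' @export
call_specific <- function(rpm, ids = NULL, top_frac = 0.15) {
  if (is.null(dim(rpm))) rpm <- matrix(rpm, nrow = 1)
  n_all <- nrow(rpm)
  if (n_all == 0) stop("call_specific: empty input")
  if (is.null(ids)) ids <- sprintf("acr_%d", seq_len(n_all))
  tissues <- colnames(rpm)
  if (is.null(tissues)) tissues <- sprintf("tissue_%d", seq_len(ncol(rpm)))
  h <- shannon_entropy(rpm)
  maxrpm <- apply(rpm, 1, max)
  quant <- which(!is.na(h))
  n <- length(quant)
  if (n == 0) stop("call_specific: no quantifiable peaks (all rows zero)")
  k <- floor(top_frac * n)
  ord <- quant[order(h[quant], -maxrpm[quant], ids[quant])]
  rank <- rep(NA_integer_, n_all)
  rank[ord] <- seq_len(n)
  is_spec <- !is.na(rank) & rank <= k
  top_tissue <- tissues[max.col(rpm, ties.method = "first")]
  data.frame(acr_id = ids,
             entropy_bits = h,
             rank = rank,
             is_specific = is_spec,
             specific_tissue = ifelse(is_spec, top_tissue, NA_character_),
             fold_change = fold_change(rpm),
             stringsAsFactors = FALSE)
}

#' Accessibility fold change of the top tissue over the rest
#'
#' (max RPM + eps) / (mean RPM of the remaining tissues + eps); the
#' pseudocount keeps the ratio finite for peaks silent outside one tissue.
#'
#' @param rpm Numeric matrix (peaks x tissues) or single row.
#' @param eps Pseudocount (default 0.01).
#' @return Numeric vector of fold changes.
#' @export
fold_change <- function(rpm, eps = 0.01) {
  if (is.null(dim(rpm))) rpm <- matrix(rpm, nrow = 1)
  stopifnot(eps > 0, ncol(rpm) >= 2)
  mx <- apply(rpm, 1, max)
  rest <- (rowSums(rpm) - mx) / (ncol(rpm) - 1)
  (mx + eps) / (rest + eps)
}

#' Hypergeometric enrichment of TE superfamilies in a peak subset
#'
#' Upper-tail hypergeometric test P(X >= observed) per superfamily:
#' population = all annotated TEs, successes = TEs of the superfamily,
#' draws = TEs associated with the peak subset (e.g. tissue-specific
#' peaks). Benjamini-Hochberg q-values are reported alongside raw p.
#'
#' @param subset_counts Named vector: TEs of each superfamily associated
#'   with the subset.
#' @param genome_counts Named vector: genome-wide TE count per superfamily
#'   (must cover the names of `subset_counts`).
#' @return data.frame `superfamily`, `observed`, `draws`, `successes`,
#'   `population`, `p_value`, `q_value`, ordered by ascending p.
#' @export
superfamily_enrichment <- function(subset_counts, genome_counts) {
  fams <- names(genome_counts)
  obs <- ifelse(fams %in% names(subset_counts),
                as.numeric(subset_counts[fams]), 0)
  names(obs) <- fams
  pop <- sum(genome_counts)
  draws <- sum(obs)
  if (any(obs > draws)) stop("superfamily_enrichment: observed > draws")
  if (any(genome_counts > pop)) stop("superfamily_enrichment: successes > population")
  p <- stats::phyper(obs - 1, genome_counts, pop - genome_counts, draws,
                     lower.tail = FALSE)
  out <- data.frame(superfamily = fams,
                    observed = as.integer(obs),
                    draws = as.integer(draws),
                    successes = as.integer(genome_counts),
                    population = as.integer(pop),
                    p_value = as.numeric(p),
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$p_value), , drop = FALSE]
}
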