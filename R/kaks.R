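# Nei-Gojobori (1986) synonymous/nonsynonymous divergence for codon-aligned
# duplicate gene pairs: per-codon site counting averaged over the two
# sequences, difference counting averaged over all minimal substitution
# pathways, Jukes-Cantor multiple-hit correction, and a Fisher exact test
# on the difference/site table.

# cached codon translation table (includes "*" for stops)
.codon_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' @noRd
split_codons <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# fraction of the 3 possible changes at each codon position that are
# synonymous; changes creating a stop codon count as nonsynonymous
#' @noRd
codon_syn_fractions <- function(codon, aa_tab) {
  bases <- c("A", "C", "G", "T")
  ref_aa <- aa_tab[[codon]]
  if (is.null(ref_aa) || is.na(ref_aa)) stop("invalid codon: ", codon)
  vapply(1:3, function(i) {
    alt <- setdiff(bases, substr(codon, i, i))
    syn <- vapply(alt, function(b) {
      mut <- codon
      substr(mut, i, i) <- b
      identical(aa_tab[[mut]], ref_aa) && aa_tab[[mut]] != "*"
    }, logical(1))
    sum(syn) / 3
  }, numeric(1))
}

# all orderings of the differing positions
#' @noRd
position_orders <- function(pos) {
  if (length(pos) == 1) return(list(pos))
  if (length(pos) == 2) return(list(pos, rev(pos)))
  out <- list()
  for (i in seq_along(pos)) {
    rest <- position_orders(pos[-i])
    for (r in rest) out[[length(out) + 1L]] <- c(pos[i], r)
  }
  out
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal pathways; pathways through stop codons are excluded unless every
# pathway is blocked
#' @noRd
codon_diffs <- function(c1, c2, aa_tab) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- position_orders(pos)
  walk <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (aa_tab[[nxt]] == "*") return(NULL)  # pathway hits a stop
      if (aa_tab[[nxt]] == aa_tab[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, walk))
  if (!length(res)) {
    # endpoints are valid codons but every route passes a stop: fall back
    # to counting through stops, classifying stop transitions nonsynonymous
    walk2 <- function(order) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (aa_tab[[nxt]] == aa_tab[[cur]] && aa_tab[[nxt]] != "*")
          sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(paths, walk2)
  }
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

#' Nei-Gojobori Ka/Ks for one codon-aligned pair
#'
#' Computes synonymous (S) and nonsynonymous (N) site counts per sequence
#' (averaged between the two), classifies observed differences by averaging
#' over all minimal substitution pathways (routes through stop codons are
#' excluded when avoidable), converts the proportions p_S = S_d/S and
#' p_N = N_d/N to distances with the Jukes-Cantor correction
#' d = -3/4 ln(1 - 4/3 p), and tests S_d/N_d against S/N with a two-sided
#' Fisher exact test on the rounded 2x2 table.
#'
#' @param cds_a,cds_b Codon-aligned nucleotide strings of equal length,
#'   divisible by 3, without internal stop codons.
#' @return list with `S`, `N`, `S_d`, `N_d`, `ps`, `pn`, `Ks`, `Ka`,
#'   `omega`, `p_value`. `Ks`/`Ka` are NA when the corrected distance is
#'   undefined (p >= 0.75); `omega` is NA when Ks is 0 or undefined.
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("ng86_kaks: sequences must be codon-aligned to equal length")
  aa_tab <- .codon_aa()
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  if (any(aa_tab[ca] == "*") || any(aa_tab[cb] == "*"))
    stop("ng86_kaks: internal stop codon in input")
  s_a <- sum(vapply(ca, function(x) sum(codon_syn_fractions(x, aa_tab)),
                    numeric(1)))
  s_b <- sum(vapply(cb, function(x) sum(codon_syn_fractions(x, aa_tab)),
                    numeric(1)))
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(function(x, y) codon_diffs(x, y, aa_tab), ca, cb)
  S_d <- sum(diffs["sd", ])
  N_d <- sum(diffs["nd", ])
  ps <- if (S > 0) S_d / S else NA_real_
  pn <- if (N > 0) N_d / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(ps); Ka <- jc(pn)
  omega <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  tab <- round(matrix(c(S_d, S - S_d, N_d, N - N_d), nrow = 2, byrow = TRUE))
  tab[tab < 0] <- 0
  p_value <- stats::fisher.test(tab)$p.value
  list(S = S, N = N, S_d = S_d, N_d = N_d, ps = ps, pn = pn,
       Ks = Ks, Ka = Ka, omega = omega, p_value = p_value)
}

#' NG86 Ka/Ks for a table of pairs
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `cds_a`, `cds_b`.
#' @return data.frame with the pair ids and all [ng86_kaks()] fields.
#' @export
ng86_kaks_table <- function(pairs) {
  res <- lapply(seq_len(nrow(pairs)), function(i)
    ng86_kaks(pairs$cds_a[i], pairs$cds_b[i]))
  cbind(pairs[, c("gene_a", "gene_b"), drop = FALSE],
        do.call(rbind, lapply(res, as.data.frame)))
}

#' Read paired coding sequences from a FASTA file
#'
#' Records are consumed two at a time (copy A then copy B of each pair).
#' When a record description carries a second whitespace-separated token it
#' is taken as the gene id, otherwise the record name is used.
#'
#' @param path Path to a FASTA file with an even number of records.
#' @return data.frame `gene_a`, `gene_b`, `cds_a`, `cds_b`.
#' @export
read_cds_pairs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) %% 2 != 0)
    stop("read_cds_pairs: expected an even number of records")
  nm <- names(seqs)
  gene <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+(\\S+).*$", "\\1", nm),
                 sub("\\s.*", "", nm))
  a <- seq(1, length(seqs), by = 2)
  data.frame(gene_a = gene[a], gene_b = gene[a + 1],
             cds_a = as.character(seqs[a]),
             cds_b = as.character(seqs[a + 1]),
             stringsAsFactors = FALSE)
}

#' Apply the saturation and significance filters to Ka/Ks results
#'
#' Retains pairs with defined Ks <= 5 (synonymous sites not saturated) and
#' Fisher p-value <= 0.05; the Ks bound is inclusive because only values
#' strictly greater than 5 are excluded.
#'
#' @param kaks data.frame from [ng86_kaks_table()].
#' @param max_ks Ks ceiling (default 5).
#' @param max_p p-value ceiling (default 0.05).
#' @return Filtered data.frame.
#' @export
filter_pairs <- function(kaks, max_ks = 5, max_p = 0.05) {
  keep <- !is.na(kaks$Ks) & kaks$Ks <= max_ks &
    !is.na(kaks$p_value) & kaks$p_value <= max_p
  kaks[keep, , drop = FALSE]
}
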