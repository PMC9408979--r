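---
title: "Models and conventions behind teacr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind teacr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`teacr` characterises accessible chromatin regions (ACRs, ATAC-seq peaks)
that arise from transposable elements (TEs). This vignette documents the
statistical models, coordinate conventions and numerical choices each stage
relies on, the knobs that matter, and what the synthetic genome does and
does not emulate.

## Coordinates

Everything internal is 0-based, half-open `[start, end)`, the BED
convention. GFF3, CGmap and VCF inputs (1-based) are converted on ingest and
never afterwards. Two consequences worth remembering: abutting intervals
(`[a,b)`, `[b,c)`) share no base and are *not* merged by `merge_acrs()`, and
a TE `[s,e)` contains a peak summit at position `p` iff `s <= p < e`.

## TE-derived classification

A peak is TE-derived when the union of overlapping TEs covers **strictly
more** than half its length; a peak exactly half covered is not TE-derived.
Union coverage means two overlapping TEs never double-count shared bases.
Nearest-TE distances are edge gaps (0 for any ≥1 bp overlap) binned as 0,
1–170, 171–500, 501–1000 and >1000 bp. Two reporting rules are deliberate
choices where several readings are defensible:

- a peak overlapping both a DNA transposon and a retrotransposon is
  assigned the class contributing more covered bp, ties to the DNA class;
- a summit covered by nested TEs is attributed once, to the innermost
  (shortest) covering TE.

## Positional classes

Per gene, three strand-aware windows are formed: promoter (2 kb upstream of
the TSS), gene body, and downstream (2 kb past the TTS). A peak takes the
highest-precedence class among the windows it touches —
pACR > gACR > dnACR > dACR — and is distal (dACR) only when it is more than
2 kb from *every* gene body. One numerical subtlety: a peak whose gap to a
gene body is exactly 2 kb touches no 2-kb window under half-open
arithmetic, yet is by definition not distal. The classification windows are
therefore widened by a single base on their outer edge, which makes the
four classes an exact partition with the distal boundary at "strictly more
than 2000 bp". Assignment uses any-overlap (≥1 bp) rather than the summit;
with the default window sizes the two differ only for peaks straddling a
window edge.

Accessibility tertiles rank peaks by RPKM
(`count × 10^9 / (length × library size)`) and split at the empirical 1/3
and 2/3 quantiles into groups whose sizes differ by at most one; ties are
broken by peak id so repeated runs agree. All-equal inputs have no
meaningful tertiles and collapse to "mid" with a warning.

## Tissue specificity

Counts are RPM-normalised (`count × 10^6 / library size`) per tissue. Each
peak's row is renormalised to a probability vector p over the T tissues and
scored by Shannon entropy `H = −Σ p_i log2 p_i` (0·log 0 = 0), so H ranges
from 0 (all accessibility in one tissue) to log2 T. Rows with zero total
RPM carry no information and are excluded before ranking, so the "top 15%"
rule — sort ascending by entropy, call the first `floor(0.15 N)` peaks
tissue-specific — counts only quantifiable peaks. Ties in entropy are
resolved in favour of the larger maximal RPM, then lexicographic id. RPM
rows are not quantile-normalised first; the entropy is already invariant to
per-peak scale, and cross-tissue depth differences are handled by the RPM
totals (or by explicit down-sampling with `downsample_counts()`, a
multivariate-hypergeometric draw without replacement).

The specific tissue is the argmax-RPM tissue; the reported fold change is
`(max + ε) / (mean of others + ε)` with ε = 0.01 RPM, a pseudocount that
keeps the ratio finite for peaks silent outside one tissue. Superfamily
enrichment among TEs linked to specific peaks is an upper-tail
hypergeometric test `P(X ≥ observed)` with the whole TE annotation as the
population; Benjamini–Hochberg q-values are reported alongside raw p.

## Methylation

Region levels are read-weighted: `Σ methylated / Σ total` over covered
cytosines of one context in the region, not a mean of per-site levels, so a
10-read cytosine outweighs a 1-read one. This matches the bulk-level
convention of common bisulfite pipelines and makes levels additive across
any partition of a region. Sites need ≥5 reads (configurable) to enter any
level. Symmetric CG positions are kept as separate per-strand records, as
the CGmap extraction emits them. Scaled-body metaprofiles rescale each
feature body to 40 bins with 50-bp flank bins over ±2 kb; bin widths are
conventional metagene resolution, not biologically meaningful constants,
and are arguments. For sparse tracks (methylation, conservation scores)
bins without any scored base report NaN, distinguishing "unscored" from
"score 0"; coverage-style tracks treat absent positions as 0.

## Nucleotide diversity and sweeps

Per biallelic site with k alternate alleles among n called haplotypes,
`π = 2k(n−k)/(n(n−1))` — the fraction of haplotype pairs that differ. n is
per-site (pairwise-complete): missing genotypes reduce n at that site only,
and half-missing diploid calls ("./1") are treated as fully missing, a
conservative choice. Windowed π sums site values over non-overlapping
100-kb tiles anchored at position 0 and divides by the *full* window span,
the convention of the standard windowed-π tools (a callable-bp denominator
would need a mask the pipeline does not consume). The sweep scan forms
π_wild/π_cult on eligible windows (≥1 variant in each panel, cultivated
π > 0), takes the empirical 95th percentile (R quantile type 7) as the
threshold — always recomputed, never hard-coded — flags windows at or above
it, and merges adjacent flagged windows. Fewer than 20 eligible windows is
an error: a 95th percentile of fewer points is noise.

## NG86 Ka/Ks

For codon-aligned pairs the package implements Nei–Gojobori (1986):

1. **Sites.** Per codon position, the fraction of the three possible
   single-base changes that are synonymous; changes creating a stop codon
   count as nonsynonymous. S is averaged between the two sequences;
   N = 3·codons − S.
2. **Differences.** Codons differing at d positions are scored by averaging
   the synonymous/nonsynonymous step counts over all d! minimal pathways.
   Pathways passing through a stop codon are excluded; in the rare case
   every pathway is blocked, all are counted with stop transitions treated
   as nonsynonymous rather than leaving the codon unscored.
3. **Correction.** p_S = S_d/S and p_N = N_d/N are Jukes–Cantor corrected,
   `d = −(3/4)·ln(1 − (4/3)p)`, undefined for p ≥ 0.75 (returned as NA, as
   is ω when Ks = 0).
4. **Significance.** A two-sided Fisher exact test on the rounded 2×2 table
   (S_d, S−S_d; N_d, N−N_d). Downstream filters retain pairs with Ks ≤ 5
   (synonymous saturation bound, inclusive) and p ≤ 0.05.

NG86 with equal-weight pathways was chosen over ML or γ-corrected
estimators because it is fully specifiable and testable against exhaustive
pathway enumeration; the estimator name is part of the output contract.
Codon alignment is an input contract of the Ka/Ks core.

TSS peak status uses a closed ±500 bp window around the TSS: `te_acr` when
a TE-derived peak overlaps it by ≥1 bp (TE-derived dominates a co-occurring
regular peak), else `regular_acr`, else `none`. Pair subgroups follow: 1 =
both copies te_acr, 2 = te_acr + regular_acr, 3 = te_acr + none; anything
else is unassigned. The expression/accessibility divergence contrast uses
absolute log2 fold changes with an ε = 0.01 pseudocount and splits at
expression fold change 2, the ratio exactly 2 falling in the "≤ 2" group;
groups are compared with a one-sided Wilcoxon rank-sum test.

## The synthetic genome

`simulate_genome()` lays features into fixed 5-kb slots so that every truth
label is exact placement arithmetic rather than a post-hoc measurement:
slot margins guarantee >2 kb clearance between feature groups, TE-derived
peaks are embedded in their TE with a coverage fraction drawn uniformly
from (0.55, 0.95), and promoter/genic/downstream/distal peaks are placed so
the positional classifier's answer is known by construction. Defaults
describe four 1.5-Mb chromosomes, 240 genes, 400 TEs and 400 peaks across
six tissues — large enough for 60 100-kb diversity windows and stable
quantiles, small enough that the full bundle generates in seconds.

Other components:

- **Counts.** Common peaks draw NB(μ=60, size=8) in every tissue;
  tissue-specific peaks draw NB(μ=250) in their tissue and NB(μ=4)
  elsewhere, concentrating RPM mass as the entropy model assumes.
- **Methylation.** Cytosines every 20 bp over TEs ±2 kb and peaks, depth
  Poisson(20), methylated reads binomial with per-context means: TE bodies
  CG/CHG/CHH = 0.85/0.70/0.15, peaks 0.05/0.03/0.02, background
  0.30/0.15/0.04 — the hypermethylated-TE / hypomethylated-peak structure
  of plant genomes, with peak cytosines staying hypomethylated even inside
  TE bodies.
- **Genotypes.** 5 wild and 15 cultivated diploids; variant sites every
  ~150 bp with allele frequencies uniform on (0.05, 0.95) in both panels.
  Inside the three sweep windows, cultivated sites are thinned with
  probability 1 − 1/reduction (default reduction 10), which divides the
  expected windowed π by exactly the reduction factor while leaving its
  per-site distribution untouched; at reduction 1 the panels are
  statistically identical.
- **CDS pairs.** 40 pairs of 500 codons. An ancestral stop-free CDS is
  mutated with exactly the requested numbers of synonymous and
  nonsynonymous substitutions, classified against the current sequence
  state (repeat hits allowed, stop-creating proposals resampled); truth Ks
  is applied synonymous substitutions per ancestral synonymous site. The
  500-codon default comes from calibrating the NG86 estimator against this
  truth: its relative error is unbiased with standard deviation ≈0.05–0.07
  at 500 codons over the simulated Ks range (0.05–0.6), comfortably inside
  a 20% recovery tolerance, whereas at 300 codons the error spread makes
  individual pairs unreliable. Subgroup-1 pairs draw lower Ks targets than
  subgroup-2 pairs (younger versus older duplicates).
- **Divergence coupling.** For pairs whose copies both have promoter
  peaks, copy B's peak counts and expression are scaled by correlated
  log2 offsets, so accessibility change predicts expression change.

What the generator does **not** emulate: read-level noise and mapping
artefacts, overlapping or nested genes, TE fragments and nested insertions,
real TE sequence models, linkage disequilibrium between variant sites,
indels in coding sequence, and peak-boundary jitter between tissues.
Passing the recovery tests therefore shows the estimators are correct on
clean, structured input — not that they are robust to alignment or
peak-calling noise, which is upstream of this package's scope.

## Determinism

Every stochastic component takes an explicit seed; `simulate_genome()`
derives per-component child seeds from the master seed at fixed offsets, so
a bundle is byte-identical across runs and components can be regenerated
independently. RNG state of the calling session is saved and restored
around every seeded operation.

## Known limitations

- `classify_position()` reports gene-level classes only; exon/intron
  sub-classification would require exon rows, which the gene reader does
  not consume.
- The sweep scan flags a fixed top fraction of windows; with no true
  sweeps it will still flag ~5% of windows, by construction. Interpreting
  flagged windows requires the companion π values, which are reported.
- NG86 saturates above Ks ≈ 1–2; the Ks ≤ 5 filter keeps conventionally
  reportable pairs but values that large are already unreliable.
- The Fisher test on rounded fractional NG86 counts is the convention of
  widely used Ka/Ks pipelines, not an exact test of the underlying model.
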