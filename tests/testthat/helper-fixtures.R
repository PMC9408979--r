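# Shared fixtures: tiny interval builders and a cached default simulation
# bundle so the full-pipeline tests pay the generation cost once.

iv <- function(chrom, start, end, ...) {
  data.frame(chrom = chrom, start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

te <- function(chrom, start, end, superfamily = "hAT", te_class = "DNA") {
  iv(chrom, start, end, superfamily = superfamily, te_class = te_class)
}

.fixture_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    cfg <- sim_config()
    dir <- file.path(tempdir(), "teacr_default_bundle")
    .fixture_cache$cfg <- cfg
    .fixture_cache$bundle <- simulate_genome(cfg, dir)
  }
  list(cfg = .fixture_cache$cfg, bundle = .fixture_cache$bundle)
}

# merged peaks of the default bundle with truth columns joined by coordinates
merged_with_truth <- function() {
  if (is.null(.fixture_cache$merged)) {
    x <- default_bundle()
    peaks <- lapply(x$cfg$tissues, function(t)
      read_bed(x$bundle$files[[paste0("acrs_", t)]]))
    merged <- merge_acrs(peaks)
    truth <- x$bundle$truth$acrs
    m <- match(paste(merged$chrom, merged$start, merged$end),
               paste(truth$chrom, truth$start, truth$end))
    stopifnot(!anyNA(m))
    merged$te_derived_truth <- truth$te_derived[m]
    merged$class_truth <- truth$class[m]
    merged$specific_truth <- truth$specific_tissue[m]
    merged$truth_id <- truth$acr_id[m]
    .fixture_cache$merged <- merged
  }
  .fixture_cache$merged
}
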