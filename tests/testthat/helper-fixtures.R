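## Shared fixtures, built in code at test time.

options(mrdtrace.quiet = TRUE)

## Small two-gene panel + reference for read-level end-to-end tests.
small_refpanel <- function(seed = 42, n_genes = 2, territory_bp = 800) {
  simulate_reference_and_panel(seed, n_genes = n_genes,
                               territory_bp = territory_bp)
}

## Hand-built family of reads at one locus.
make_family <- function(seqs, chrom = "c1", start = 0L, umi = "ACGTACGTAC") {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)), chrom = chrom,
             start = start, seq = seqs, umi = umi, stringsAsFactors = FALSE)
}

## A one-row pileup with explicit base counts.
make_pileup <- function(chrom, pos, ref, counts) {
  n <- length(pos)
  out <- data.frame(chrom = chrom, pos = pos, ref = ref,
                    A = 0L, C = 0L, G = 0L, T = 0L, depth = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (b in names(counts[[i]])) out[i, b] <- counts[[i]][[b]]
    out$depth[i] <- sum(unlist(counts[[i]]))
  }
  class(out) <- unique(c("locus_pileup", class(out)))
  out
}

## Reporter set straight from a variant table (bypasses tissue genotyping).
make_reporter_set <- function(variants, patient_id = "P01") {
  n <- nrow(variants)
  select_reporters(
    variant_calls(variants$chrom, variants$pos, variants$ref, variants$alt,
                  rep(5000L, n), rep(10000L, n)),
    genotyping_af_threshold = 18, patient_id = patient_id)
}
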