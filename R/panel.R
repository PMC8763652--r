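## Capture panel handling. Internal coordinates are 0-based half-open
## everywhere in the package; conversion to 1-based happens only at the
## VCF/SAM text boundary.

#' Construct a panel definition
#'
#' @param regions data.frame with columns `gene`, `region_label`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return A `panel_def`: list with `regions` (sorted by chrom, start) and
#'   `territory_bp`, the total bases covered after merging overlaps.
#' @export
panel_def <- function(regions) {
  req <- c("gene", "region_label", "chrom", "start", "end")
  assert_that(is.data.frame(regions) && all(req %in% names(regions)),
              "regions must have columns: %s", paste(req, collapse = ", "))
  regions <- as.data.frame(regions)[, req]
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  bad <- which(regions$start >= regions$end)
  assert_that(length(bad) == 0L,
              "region %d: start (%s) must be < end (%s)",
              bad[1], regions$start[bad[1]], regions$end[bad[1]])
  assert_that(all(nzchar(regions$chrom)), "chrom names must be non-empty")
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions, territory_bp = merged_territory(regions)),
            class = "panel_def")
}

## Merged footprint in bp via GenomicRanges::reduce (handles overlaps).
merged_territory <- function(regions) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  sum(GenomicRanges::width(GenomicRanges::reduce(gr)))
}

#' @export
print.panel_def <- function(x, ...) {
  cat(sprintf("Capture panel: %d regions, %d genes, %d bp merged territory\n",
              nrow(x$regions), length(unique(x$regions$gene)), x$territory_bp))
  invisible(x)
}

#' Load a capture panel from a BED file
#'
#' Expects a 4+ column BED (0-based half-open); column 4 carries
#' `GENE|label` (a bare gene symbol is also accepted). Lines are validated
#' before parsing so malformed input fails with the offending line number.
#'
#' @param path Path to a BED file.
#' @return A [panel_def()].
#' @examples
#' bed <- system.file("extdata", "default_panel.bed", package = "mrdtrace")
#' panel <- load_panel(bed)
#' panel$territory_bp
#' @export
load_panel <- function(path) {
  assert_that(file.exists(path), "BED file not found: %s", path)
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t| +")[[1]]
    if (length(f) < 4L)
      stop_mrd("BED parse error at line %d: expected >= 4 columns, got %d", i, length(f))
    if (is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))))
      stop_mrd("BED parse error at line %d: non-integer coordinates", i)
    if (as.integer(f[2]) >= as.integer(f[3]))
      stop_mrd("BED validation error at line %d: start >= end", i)
  }
  gr <- rtracklayer::import(path, format = "BED")
  nm <- as.character(gr$name)
  gene <- sub("\\|.*$", "", nm)
  label <- ifelse(grepl("\\|", nm), sub("^[^|]*\\|", "", nm), "")
  panel_def(data.frame(
    gene = gene, region_label = label,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  ))
}

#' Write a panel definition to BED
#'
#' @param panel A [panel_def()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  assert_that(inherits(panel, "panel_def"), "panel must be a panel_def")
  r <- panel$regions
  gr <- GenomicRanges::GRanges(
    seqnames = r$chrom,
    ranges = IRanges::IRanges(start = r$start + 1L, end = r$end),
    name = ifelse(nzchar(r$region_label), paste0(r$gene, "|", r$region_label), r$gene)
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' The bundled default 18-gene panel
#'
#' A synthetic stand-in capture design over 18 genes recurrently mutated in
#' NSCLC (BRAF, CDKN2A, CTNNB1, EGFR, ERBB2, HRAS, KEAP1, KIT, KRAS, MET,
#' NFE2L2, NRAS, PDGFRA, PIK3CA, PTEN, SDHA, SMAD4, TP53), laid out on one
#' synthetic contig per gene with a merged territory of exactly 17,000 bp.
#' Exon labels follow the genes' commonly targeted exons; genomic
#' coordinates are synthetic.
#'
#' @return A [panel_def()] with 18 genes and 17,000 bp territory.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "default_panel.bed", package = "mrdtrace"))
}

## Gene -> targeted exon labels for the default design.
panel_gene_table <- function() {
  list(
    BRAF   = c(11, 15),
    CDKN2A = c(1, 2),
    CTNNB1 = 3,
    EGFR   = c(18, 19, 20, 21),
    ERBB2  = 20,
    HRAS   = c(2, 3),
    KEAP1  = 2:6,
    KIT    = c(9, 11, 13, 14, 17),
    KRAS   = c(2, 3, 4),
    MET    = 14,
    NFE2L2 = 2,
    NRAS   = c(2, 3),
    PDGFRA = 18,
    PIK3CA = c(10, 21),
    PTEN   = c(1, 3, 6, 7, 8),
    SDHA   = c(2, 7, 13),
    SMAD4  = c(1, 2, 8, 9, 10, 11),
    TP53   = 4:10
  )
}

## Deterministic region layout: n regions split a territory as evenly as
## integer lengths allow; one contig per gene, exons separated by `gap` bp.
panel_layout <- function(n_genes = 18L, territory_bp = 17000L,
                         gap = 200L, margin = 100L) {
  assert_that(is_count(n_genes), "n_genes must be a positive integer")
  assert_that(territory_bp >= n_genes,
              "territory_bp (%d) smaller than n_genes (%d)", territory_bp, n_genes)
  if (n_genes == 18L) {
    tab <- panel_gene_table()
    genes <- rep(names(tab), lengths(tab))
    labels <- paste0("ex", unlist(tab, use.names = FALSE))
  } else {
    genes <- sprintf("GENE%02d", seq_len(n_genes))
    labels <- rep("ex1", n_genes)
  }
  n <- length(genes)
  len <- rep(territory_bp %/% n, n)
  extra <- territory_bp %% n
  if (extra > 0) len[seq_len(extra)] <- len[seq_len(extra)] + 1L
  out <- data.frame(gene = genes, region_label = labels,
                    chrom = paste0("chr_", genes),
                    start = NA_integer_, end = NA_integer_)
  for (g in unique(genes)) {
    idx <- which(genes == g)
    pos <- margin
    for (i in idx) {
      out$start[i] <- pos
      out$end[i] <- pos + len[i]
      pos <- pos + len[i] + gap
    }
  }
  out
}

## Is every read interval [start, start+len) inside a single panel region?
positions_in_panel <- function(panel, chrom, start, end) {
  r <- panel$regions
  ok <- logical(length(chrom))
  for (i in seq_along(chrom)) {
    ok[i] <- any(r$chrom == chrom[i] & r$start <= start[i] & r$end >= end[i])
  }
  ok
}
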