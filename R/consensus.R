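## UMI consensus deduplication. Reads sharing (chrom, leftmost aligned
## position, exact UMI string) are presumed copies of one original cfDNA
## molecule; each family collapses to a single consensus read. Strand is
## ignored (single-strand UMIs, no soft-clipping in this package's inputs).

#' Group UMI-tagged reads into families
#'
#' Partitions reads by the family key (chrom, start, umi). Every read lands
#' in exactly one family.
#'
#' @param reads data.frame with `chrom`, `start`, `umi`, `seq` columns.
#' @return data.table of the same reads with an integer `family_id` column;
#'   attribute `families` holds the per-family key/size table.
#' @export
group_families <- function(reads) {
  dt <- data.table::as.data.table(reads)
  assert_that(all(c("chrom", "start", "umi", "seq") %in% names(dt)),
              "reads must have chrom/start/umi/seq columns")
  if (nrow(dt) == 0L) {
    dt[, family_id := integer(0)]
    data.table::setattr(dt, "families",
                        data.table::data.table(family_id = integer(),
                                               chrom = character(),
                                               start = integer(),
                                               umi = character(), n = integer()))
    return(dt[])
  }
  dt[, family_id := .GRP, by = .(chrom, start, umi)]
  bad <- dt[, data.table::uniqueN(nchar(seq)), by = family_id][V1 > 1L]
  assert_that(nrow(bad) == 0L,
              "family %d contains reads of unequal length", bad$family_id[1])
  fam <- dt[, .(chrom = chrom[1], start = start[1], umi = umi[1], n = .N),
            by = family_id]
  data.table::setattr(dt, "families", fam)
  dt[]
}

#' Collapse one read family to a consensus read
#'
#' Reference single-family implementation of the consensus rule: families
#' below the size threshold are rejected; per column, the modal base is
#' taken when its fraction of the family (N bases never counted as modal
#' candidates, denominator = family size) reaches `consensus_freq`,
#' otherwise the column becomes `N`. Ties for the modal base resolve to `N`
#' (only reachable when `consensus_freq <= 0.5`).
#'
#' @param family data.frame of one family's reads (equal-length `seq`).
#' @param consensus_freq Column agreement threshold, default 0.90.
#' @param min_family_size Family size threshold, default 10.
#' @return A one-row data.frame (`chrom`, `start`, `umi`, `family_size`,
#'   `seq`) or `NULL` when the family is rejected.
#' @examples
#' fam <- data.frame(chrom = "c", start = 0, umi = "AC",
#'                   seq = rep(c("AAAA", "AACA"), c(11, 1)))
#' call_consensus(fam)$seq  # 11/12 >= 0.90 at every column
#' @export
call_consensus <- function(family, consensus_freq = 0.90, min_family_size = 10) {
  n <- nrow(family)
  if (n < min_family_size) return(NULL)
  L <- nchar(family$seq[1])
  assert_that(all(nchar(family$seq) == L), "family reads of unequal length")
  mat <- matrix(unlist(strsplit(family$seq, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  cons <- character(L)
  for (j in seq_len(L)) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    top <- max(tab)
    modal <- names(tab)[tab == top]
    cons[j] <- if (length(modal) == 1L && top / n >= consensus_freq) modal else "N"
  }
  data.frame(chrom = family$chrom[1], start = family$start[1],
             umi = family$umi[1], family_size = n,
             seq = paste0(cons, collapse = ""), stringsAsFactors = FALSE)
}

#' Deduplicate a sample's UMI-tagged reads
#'
#' Groups reads into families and collapses each family passing the size
#' threshold with the consensus rule of [call_consensus()] (vectorized; the
#' two paths are equivalent and tested against each other). Returns the
#' consensus reads and bookkeeping statistics, including the
#' deduplication rate `1 - consensus_out / reads_in`.
#'
#' @param reads data.frame of tagged reads (`chrom`, `start`, `umi`, `seq`).
#' @param config An [run_config()]; `consensus_freq` and `min_family_size`
#'   are taken from it.
#' @return list with `consensus` (data.frame: `read_id`, `chrom`, `start`,
#'   `umi`, `family_size`, `seq`) and `stats` (class `dedup_stats`).
#' @export
deduplicate <- function(reads, config = run_config()) {
  dt <- group_families(reads)
  fam <- attr(dt, "families")
  n_in <- nrow(dt)
  keep <- fam[n >= config$min_family_size]
  cons_dt <- if (nrow(keep) == 0L) {
    data.table::data.table(chrom = character(), start = integer(),
                           umi = character(), family_size = integer(),
                           seq = character())
  } else {
    consensus_vectorized(dt[family_id %in% keep$family_id],
                         config$consensus_freq)
  }
  stats <- structure(list(
    reads_in = n_in,
    families_total = nrow(fam),
    families_kept = nrow(keep),
    consensus_out = nrow(cons_dt),
    dedup_rate = if (n_in > 0) 1 - nrow(cons_dt) / n_in else NA_real_
  ), class = "dedup_stats")
  cons <- as.data.frame(cons_dt)
  if (nrow(cons)) cons$read_id <- sprintf("cons%06d", seq_len(nrow(cons)))
  log_msg("dedup", "%d reads -> %d/%d families kept -> %d consensus (rate %.3f)",
          stats$reads_in, stats$families_kept, stats$families_total,
          stats$consensus_out, stats$dedup_rate)
  list(consensus = cons, stats = stats)
}

#' @export
print.dedup_stats <- function(x, ...) {
  cat(sprintf(
    "Dedup: %d reads in, %d families (%d kept), %d consensus out, rate %.3f\n",
    x$reads_in, x$families_total, x$families_kept, x$consensus_out,
    x$dedup_rate))
  invisible(x)
}

## Vectorized consensus over many families. Fast path: families whose reads
## are all identical take that sequence verbatim. Only discordant families
## go through per-column counting.
consensus_vectorized <- function(dt, consensus_freq) {
  fam_summary <- dt[, .(n = .N, n_distinct_seq = data.table::uniqueN(seq),
                        chrom = chrom[1], start = start[1], umi = umi[1],
                        rep_seq = seq[1]),
                    by = family_id]
  fast <- fam_summary[n_distinct_seq == 1L]
  out_fast <- fast[, .(family_id, chrom, start, umi, family_size = n,
                       seq = rep_seq)]
  slow_ids <- fam_summary[n_distinct_seq > 1L, family_id]
  if (length(slow_ids) == 0L) {
    res <- out_fast
  } else {
    sub <- dt[family_id %in% slow_ids]
    L <- nchar(sub$seq[1])
    mat <- matrix(unlist(strsplit(sub$seq, "", fixed = TRUE), use.names = FALSE),
                  nrow = nrow(sub), byrow = TRUE)
    long <- data.table::data.table(
      family_id = rep(sub$family_id, times = L),
      pos = rep(seq_len(L), each = nrow(sub)),
      base = as.vector(mat)
    )
    cnt <- long[base %in% c("A", "C", "G", "T"), .N, by = .(family_id, pos, base)]
    sizes <- sub[, .(fam_n = .N), by = family_id]
    top <- cnt[, {
      m <- max(N)
      .(base = base[N == m][1], n_top = sum(N == m), top_n = m)
    }, by = .(family_id, pos)]
    top <- sizes[top, on = "family_id"]
    top[, cons := data.table::fifelse(n_top == 1L & top_n / fam_n >= consensus_freq,
                                      base, "N")]
    ## columns can be absent from `top` only if every read had N there
    grid <- data.table::CJ(family_id = slow_ids, pos = seq_len(L))
    top <- top[grid, on = .(family_id, pos)]
    top[is.na(cons), cons := "N"]
    data.table::setorder(top, family_id, pos)
    slow_seq <- top[, .(seq = paste0(cons, collapse = "")), by = family_id]
    meta <- fam_summary[n_distinct_seq > 1L,
                        .(family_id, chrom, start, umi, family_size = n)]
    out_slow <- slow_seq[meta, on = "family_id"]
    res <- data.table::rbindlist(list(out_fast, out_slow), use.names = TRUE)
  }
  data.table::setorder(res, chrom, start, umi)
  res[, family_id := NULL]
  res[]
}
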