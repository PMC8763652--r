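## Minimal SAM text codec for the simulator's pre-aligned, indel-free,
## single-end reads. The UMI travels in a string tag (default RX) and the
## consensus family size in an integer tag (fs). The test suite
## cross-checks this codec against Rsamtools on BAM conversions.

#' Write tagged reads to a SAM file
#'
#' @param reads data.frame with `read_id`, `chrom`, `start` (0-based), `seq`
#'   and either `umi` (raw reads) or `family_size` (consensus reads).
#' @param path Output path.
#' @param reference Named sequence vector used for the `@SQ` header lines.
#' @param umi_tag Two-letter tag carrying the UMI (default "RX").
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, reference, umi_tag = "RX") {
  reads <- as.data.frame(reads)
  assert_that(all(c("read_id", "chrom", "start", "seq") %in% names(reads)),
              "reads must have read_id/chrom/start/seq columns")
  sq <- sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", sq,
           "@PG\tID:mrdtrace\tPN:mrdtrace")
  L <- nchar(reads$seq)
  tags <- character(nrow(reads))
  if ("umi" %in% names(reads)) {
    tags <- paste0(umi_tag, ":Z:", reads$umi)
  }
  if ("family_size" %in% names(reads)) {
    fs <- paste0("fs:i:", reads$family_size)
    tags <- ifelse(nzchar(tags), paste(tags, fs, sep = "\t"), fs)
  }
  body <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\t%s",
                  reads$read_id, reads$chrom, reads$start + 1L, L,
                  reads$seq, strrep("I", L), tags)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read tagged reads from a SAM file
#'
#' Parses the minimal single-end SAM this package writes: unmapped and
#' secondary records are rejected, positions are converted back to 0-based.
#'
#' @param path Path to a SAM file.
#' @param umi_tag Tag holding the UMI (default "RX").
#' @return data.frame with `read_id`, `chrom`, `start`, `seq` and, when
#'   present in the file, `umi` and `family_size` columns.
#' @export
read_sam <- function(path, umi_tag = "RX") {
  assert_that(file.exists(path), "SAM file not found: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) {
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), seq = character(),
                      umi = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  assert_that(all(nf >= 11L), "SAM parse error at record %d: < 11 fields",
              which(nf < 11L)[1])
  get <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(get(2))
  assert_that(all(bitwAnd(flag, 4L) == 0L), "unmapped records not supported")
  out <- data.frame(
    read_id = get(1), chrom = get(3),
    start = as.integer(get(4)) - 1L, seq = toupper(get(10)),
    stringsAsFactors = FALSE
  )
  tagv <- function(tag, type) {
    rx <- paste0("^", tag, ":", type, ":")
    vapply(f, function(x) {
      hit <- grep(rx, x[-(1:11)], value = TRUE)
      if (length(hit)) sub(rx, "", hit[1]) else NA_character_
    }, "")
  }
  umi <- tagv(umi_tag, "Z")
  if (!all(is.na(umi))) out$umi <- umi
  fs <- tagv("fs", "i")
  if (!all(is.na(fs))) out$family_size <- as.integer(fs)
  out
}
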