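# Minimal text-level VCF 4.x reader/writer.  The annotation contracts
# require byte-for-byte preservation of untouched records and byte-identical
# re-serialization, so records are kept as their original tab-separated
# fields rather than re-encoded through a richer container.

#' Read a VCF file
#'
#' @param path VCF path (uncompressed text).
#' @return List of class `vcf`: `meta` (the `##` header lines), `header`
#'   (the `#CHROM` column line), and `records` — a data frame with the
#'   eight fixed columns parsed (`chrom`, `pos`, `id`, `ref`, `alt`,
#'   `qual`, `filter`, `info`) plus a list column `extra` carrying any
#'   FORMAT/sample fields verbatim.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_idx <- grep("^##", lines)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (length(hdr_idx) != 1L) {
    stop("VCF parse error: expected exactly one #CHROM header line",
         call. = FALSE)
  }
  if (any(meta_idx > hdr_idx)) {
    stop("VCF parse error: '##' meta line after the #CHROM header",
         call. = FALSE)
  }
  rec_lines <- lines[seq_along(lines) > hdr_idx & nzchar(lines)]
  fields <- strsplit(rec_lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 8L)
  if (length(short)) {
    stop("VCF parse error: record with fewer than 8 columns at data line ",
         short[1], call. = FALSE)
  }
  records <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    pos = as.integer(vapply(fields, `[[`, "", 2L)),
    id = vapply(fields, `[[`, "", 3L),
    ref = vapply(fields, `[[`, "", 4L),
    alt = vapply(fields, `[[`, "", 5L),
    qual = vapply(fields, `[[`, "", 6L),
    filter = vapply(fields, `[[`, "", 7L),
    info = vapply(fields, `[[`, "", 8L),
    stringsAsFactors = FALSE)
  records$extra <- lapply(fields, function(f) {
    if (length(f) > 8L) f[-(1:8)] else character(0)
  })
  if (any(!nzchar(records$ref))) {
    stop("VCF parse error: empty REF allele", call. = FALSE)
  }
  structure(list(meta = lines[meta_idx], header = lines[hdr_idx],
                 records = records), class = "vcf")
}

#' Write a VCF object
#'
#' Serializes exactly the stored fields; reading and re-writing a file is a
#' byte-identical round trip.
#'
#' @param vcf A `vcf` object.
#' @param path Output path.
#' @export
write_vcf <- function(vcf, path) {
  rec <- vcf$records
  body <- vapply(seq_len(nrow(rec)), function(i) {
    paste(c(rec$chrom[i], rec$pos[i], rec$id[i], rec$ref[i], rec$alt[i],
            rec$qual[i], rec$filter[i], rec$info[i], rec$extra[[i]]),
          collapse = "\t")
  }, "")
  writeLines(c(vcf$meta, vcf$header, body), path)
  invisible(path)
}
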