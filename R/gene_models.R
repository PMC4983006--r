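#' Read transcript models from a genePred file
#'
#' Parses a UCSC-style genePred table (tab-delimited, no header) into a
#' `transcript_models` data frame.  Columns: name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds, gene_symbol.
#' Exon block lists are comma-terminated as in UCSC dumps.  All coordinates
#' are 0-based half-open and stay that way throughout the package; the only
#' 1-based conversion happens at VCF ingestion.
#'
#' A transcript whose CDS is empty (`cdsStart == cdsEnd`) is classified as
#' `non_coding`, otherwise `protein_coding`.
#'
#' @param path Path to a genePred TSV.
#' @return A data frame of class `transcript_models` with one row per
#'   transcript and list columns `exon_starts` / `exon_ends`.
#' @export
read_genepred <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(fields, lineno) {
    if (length(fields) != 11L) {
      stop(sprintf("genePred parse error at line %d: expected 11 fields, got %d",
                   lineno, length(fields)), call. = FALSE)
    }
    n_exon <- suppressWarnings(as.integer(fields[8]))
    starts <- parse_blocklist(fields[9])
    ends   <- parse_blocklist(fields[10])
    if (is.na(n_exon) || length(starts) != n_exon || length(ends) != n_exon) {
      stop(sprintf(
        "genePred parse error at line %d: exonCount %s does not match block lists (%d starts, %d ends)",
        lineno, fields[8], length(starts), length(ends)), call. = FALSE)
    }
    list(transcript_id = fields[1], chrom = fields[2], strand = fields[3],
         tx_start = as.numeric(fields[4]), tx_end = as.numeric(fields[5]),
         cds_start = as.numeric(fields[6]), cds_end = as.numeric(fields[7]),
         exon_starts = starts, exon_ends = ends, gene_symbol = fields[11],
         lineno = lineno)
  }
  parsed <- Map(parse_row, rows, seq_along(rows))
  models <- data.frame(
    transcript_id = vapply(parsed, `[[`, "", "transcript_id"),
    gene_symbol   = vapply(parsed, `[[`, "", "gene_symbol"),
    chrom         = vapply(parsed, `[[`, "", "chrom"),
    strand        = vapply(parsed, `[[`, "", "strand"),
    tx_start      = vapply(parsed, `[[`, 0, "tx_start"),
    tx_end        = vapply(parsed, `[[`, 0, "tx_end"),
    cds_start     = vapply(parsed, `[[`, 0, "cds_start"),
    cds_end       = vapply(parsed, `[[`, 0, "cds_end"),
    stringsAsFactors = FALSE
  )
  models$exon_starts <- lapply(parsed, `[[`, "exon_starts")
  models$exon_ends   <- lapply(parsed, `[[`, "exon_ends")
  models$biotype <- ifelse(models$cds_start == models$cds_end,
                           "non_coding", "protein_coding")
  for (i in seq_len(nrow(models))) {
    msg <- check_model_row(models[i, ])
    if (!is.null(msg)) {
      stop(sprintf("genePred parse error at line %d (%s): %s",
                   parsed[[i]]$lineno, models$transcript_id[i], msg),
           call. = FALSE)
    }
  }
  class(models) <- c("transcript_models", class(models))
  models
}

parse_blocklist <- function(s) {
  s <- sub(",+$", "", s)
  if (!nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
}

# Returns NULL if the row satisfies every transcript-model invariant,
# otherwise a message describing the first violation.
check_model_row <- function(m) {
  es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
  if (!m$strand %in% c("+", "-")) return(sprintf("bad strand '%s'", m$strand))
  if (length(es) == 0L) return("transcript has no exons")
  if (any(ee <= es)) return("empty or inverted exon interval")
  if (is.unsorted(es, strictly = TRUE)) return("exon starts not strictly ascending")
  if (length(es) > 1L && any(es[-1] < ee[-length(ee)])) return("overlapping exons")
  if (es[1] < m$tx_start || ee[length(ee)] > m$tx_end) return("exons outside [txStart, txEnd)")
  if (m$cds_start > m$cds_end) return("cdsStart > cdsEnd")
  if (m$cds_start < m$tx_start || m$cds_end > m$tx_end) return("CDS outside transcript span")
  NULL
}

#' Write transcript models back to genePred
#'
#' Inverse of [read_genepred()]; a load/write round trip reproduces the
#' input file byte-identically (modulo trailing whitespace).
#'
#' @param models A `transcript_models` data frame.
#' @param path Output path.
#' @export
write_genepred <- function(models, path) {
  fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- vapply(seq_len(nrow(models)), function(i) {
    paste(
      models$transcript_id[i], models$chrom[i], models$strand[i],
      fmt_coord(models$tx_start[i]), fmt_coord(models$tx_end[i]),
      fmt_coord(models$cds_start[i]), fmt_coord(models$cds_end[i]),
      length(models$exon_starts[[i]]),
      paste0(paste(fmt_coord(models$exon_starts[[i]]), collapse = ","), ","),
      paste0(paste(fmt_coord(models$exon_ends[[i]]), collapse = ","), ","),
      models$gene_symbol[i],
      sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Fetch one transcript model by id
#'
#' @param models A `transcript_models` data frame.
#' @param id Transcript identifier.
#' @return A single-row `transcript_models` data frame.
#' @export
get_model <- function(models, id) {
  i <- match(id, models$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", id, call. = FALSE)
  models[i, ]
}

#' Load a genome FASTA as a chromosome lookup
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences, one per chromosome.
#' @export
load_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a genome to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

genome_slice <- function(genome, chrom, start0, end0) {
  if (!chrom %in% names(genome)) {
    stop("chromosome absent from genome: ", chrom, call. = FALSE)
  }
  substr(genome[[chrom]], start0 + 1L, end0)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Exon ordinal in transcription order
#'
#' Exons are stored in ascending genomic order; biologically they are
#' numbered from the transcription start site.  On the plus strand the two
#' orders coincide; on the minus strand the genomically last exon is exon 1.
#'
#' @param model Single transcript model row.
#' @param genomic_index 1-based index of the exon block in ascending genomic
#'   order (may be a vector).
#' @return 1-based exon ordinal(s) in transcription order.
#' @export
exon_ordinal <- function(model, genomic_index) {
  n <- length(model$exon_starts[[1]])
  if (any(genomic_index < 1L | genomic_index > n)) {
    stop(sprintf("exon index out of range [1, %d]", n), call. = FALSE)
  }
  if (model$strand == "+") genomic_index else n - genomic_index + 1L
}

# Genomic intervals (ascending order) making up the CDS of a coding model.
cds_segments <- function(model) {
  es <- model$exon_starts[[1]]; ee <- model$exon_ends[[1]]
  s <- pmax(es, model$cds_start); e <- pmin(ee, model$cds_end)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the exon-CDS intersections in genomic order and reverse
#' complements on the minus strand, yielding the CDS in transcription
#' orientation.  If the CDS length is not a multiple of three the trailing
#' partial codon is dropped with a warning.
#'
#' @param model Single coding transcript model row.
#' @param genome Named character vector from [load_genome()].
#' @param trim_partial Drop a trailing partial codon (default `TRUE`).
#' @return Nucleotide string in transcription orientation.
#' @export
spliced_cds <- function(model, genome, trim_partial = TRUE) {
  if (model$biotype != "protein_coding") {
    stop("transcript is non-coding: ", model$transcript_id, call. = FALSE)
  }
  segs <- cds_segments(model)
  parts <- vapply(seq_len(nrow(segs)), function(i) {
    genome_slice(genome, model$chrom, segs$start[i], segs$end[i])
  }, "")
  seq <- paste(parts, collapse = "")
  if (model$strand == "-") seq <- revcomp(seq)
  if (trim_partial && nchar(seq) %% 3L != 0L) {
    warning(sprintf("CDS length %d of %s is not a multiple of 3; trailing partial codon dropped",
                    nchar(seq), model$transcript_id), call. = FALSE)
    seq <- substr(seq, 1L, 3L * (nchar(seq) %/% 3L))
  }
  seq
}

# 1-based CDS coordinate (transcription orientation) of a genomic position,
# or NA if the position is not inside the CDS.
cds_index <- function(model, pos0) {
  segs <- cds_segments(model)
  if (nrow(segs) == 0L) return(NA_integer_)
  widths <- segs$end - segs$start
  offs <- cumsum(c(0, widths))[seq_len(nrow(segs))]
  hit <- which(pos0 >= segs$start & pos0 < segs$end)
  if (length(hit) == 0L) return(NA_integer_)
  g <- offs[hit] + (pos0 - segs$start[hit])  # 0-based along genomic-order CDS
  total <- sum(widths)
  if (model$strand == "+") as.integer(g + 1L) else as.integer(total - g)
}

#' Decide whether a transcript is protein-coding
#'
#' The cross-reference table's peptide-availability flag is authoritative
#' when a row exists for the transcript; otherwise a non-empty CDS implies
#' protein-coding.
#'
#' @param model Single transcript model row.
#' @param xrefs Optional isoform cross-reference data frame
#'   (see [read_isoform_xrefs()]).
#' @return Logical.
#' @export
is_protein_coding <- function(model, xrefs = NULL) {
  if (!is.null(xrefs)) {
    i <- match(model$transcript_id, xrefs$transcript_id)
    if (!is.na(i)) return(isTRUE(as.logical(xrefs$peptide_available[i])))
  }
  model$cds_start < model$cds_end
}

#' Read the isoform cross-reference table
#'
#' Header-bearing TSV: transcript_id, uniprot_id, refseq_id, ensembl_tx_id,
#' ccds_id, peptide_available.  Missing identifiers are `.` in the file and
#' `NA` in memory.
#' @param path TSV path.
#' @export
read_isoform_xrefs <- function(path) {
  x <- read_tsv_strict(path)
  need <- c("transcript_id", "uniprot_id", "refseq_id", "ensembl_tx_id",
            "ccds_id", "peptide_available")
  if (!all(need %in% names(x))) {
    stop("xref table missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  x$peptide_available <- as.logical(x$peptide_available)
  x
}

#' Read canonical/principal isoform assignments
#'
#' Header-bearing TSV: gene_symbol, uniprot_canonical, ucsc_canonical,
#' appris_principal (missing as `.`).
#' @param path TSV path.
#' @param models Optional `transcript_models`; when given, every named
#'   transcript is checked to be an isoform of its gene.
#' @export
read_canonical <- function(path, models = NULL) {
  x <- read_tsv_strict(path)
  need <- c("gene_symbol", "uniprot_canonical", "ucsc_canonical", "appris_principal")
  if (!all(need %in% names(x))) {
    stop("canonical table missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  if (!is.null(models)) {
    for (col in need[-1]) {
      tx <- x[[col]]
      ok <- is.na(tx) |
        models$gene_symbol[match(tx, models$transcript_id)] == x$gene_symbol
      if (any(!ok, na.rm = TRUE) || anyNA(ok[!is.na(tx)])) {
        bad <- tx[!is.na(tx)][which(!ok[!is.na(tx)] | is.na(ok[!is.na(tx)]))]
        stop("canonical transcript not an isoform of its gene: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  x
}

#' Read the gene-information table
#'
#' Header-bearing TSV: symbol, full_name, refseq_id, uniprot_id,
#' ensembl_gene_id.
#' @param path TSV path.
#' @export
read_gene_info <- function(path) read_tsv_strict(path)

#' Build the gene registry
#'
#' Groups transcripts by gene symbol into one entry per gene with its locus
#' (0-based half-open union of transcript spans), isoform list, and
#' gene-level cross references.  A symbol occurring on more than one
#' chromosome is split into distinct genes with a `_<chrom>` suffix.
#'
#' @param models `transcript_models` data frame.
#' @param gene_info Optional gene-information table (see [read_gene_info()]).
#' @return Data frame of class `gene_registry`, one row per gene, with a
#'   list column `isoform_ids`.
#' @export
build_gene_registry <- function(models, gene_info = NULL) {
  key <- paste(models$gene_symbol, models$chrom, sep = "\r")
  multi <- tapply(models$chrom, models$gene_symbol,
                  function(ch) length(unique(ch)) > 1L)
  rows <- lapply(split(seq_len(nrow(models)), key), function(idx) {
    sym <- models$gene_symbol[idx[1]]
    chrom <- models$chrom[idx[1]]
    display <- if (isTRUE(multi[[sym]])) paste0(sym, "_", chrom) else sym
    data.frame(symbol = display, base_symbol = sym, chrom = chrom,
               start = min(models$tx_start[idx]),
               end = max(models$tx_end[idx]),
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  reg$isoform_ids <- lapply(split(seq_len(nrow(models)), key),
                            function(idx) models$transcript_id[idx])
  reg$full_name <- NA_character_
  reg$refseq_id <- NA_character_
  reg$uniprot_id <- NA_character_
  reg$ensembl_gene_id <- NA_character_
  if (!is.null(gene_info)) {
    i <- match(reg$base_symbol, gene_info$symbol)
    for (col in c("full_name", "refseq_id", "uniprot_id", "ensembl_gene_id")) {
      if (col %in% names(gene_info)) reg[[col]] <- gene_info[[col]][i]
    }
  }
  rownames(reg) <- NULL
  class(reg) <- c("gene_registry", class(reg))
  reg
}

#' Resolve a gene query
#'
#' Exact mode matches the gene symbol, any of the gene-level RefSeq /
#' UniProt / Ensembl identifiers, or a `chr:start-end` locus (1-based
#' inclusive, as printed in genome browsers) overlapping the gene span.
#' Keyword mode substring-matches the symbol and full name,
#' case-insensitively.  No match yields an empty result, not an error.
#'
#' @param registry A `gene_registry`.
#' @param q Query string (non-empty).
#' @param mode `"exact"` or `"keyword"`.
#' @return The matching registry rows.
#' @export
resolve_query <- function(registry, q, mode = c("exact", "keyword")) {
  mode <- match.arg(mode)
  if (!is.character(q) || length(q) != 1L || !nzchar(trimws(q))) {
    stop("query must be a non-empty string", call. = FALSE)
  }
  q <- trimws(q)
  if (mode == "exact") {
    hit <- registry$symbol == q | registry$base_symbol == q
    for (col in c("refseq_id", "uniprot_id", "ensembl_gene_id")) {
      hit <- hit | (!is.na(registry[[col]]) & registry[[col]] == q)
    }
    loc <- regmatches(q, regexec("^([^:]+):([0-9]+)-([0-9]+)$", q))[[1]]
    if (length(loc) == 4L) {
      qs <- as.numeric(loc[3]) - 1  # to 0-based half-open
      qe <- as.numeric(loc[4])
      hit <- hit | (registry$chrom == loc[2] & registry$start < qe & registry$end > qs)
    }
  } else {
    ql <- tolower(q)
    hit <- grepl(ql, tolower(registry$symbol), fixed = TRUE) |
      (!is.na(registry$full_name) &
         grepl(ql, tolower(registry$full_name), fixed = TRUE))
  }
  registry[which(hit), , drop = FALSE]
}
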