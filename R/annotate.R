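#' Locate a genomic position on a transcript
#'
#' Classifies a 0-based genomic position against one transcript model into
#' the element vocabulary `E#` (coding exon, or any exon of a non-coding
#' transcript), `I#` (intron), `5U`/`3U` (untranslated exonic sequence), or
#' `OTR` (outside the transcription region).  Exon and intron ordinals
#' count from the transcription start site; an intron takes the ordinal of
#' the exon preceding it in transcription order.  For UTR positions the
#' containing exon's ordinal is retained in the `ordinal` field (used by
#' backbone comparison) but the rendered label is plain `5U`/`3U`.
#'
#' @param model Single transcript model row.
#' @param pos0 0-based genomic position.
#' @param chrom Optional chromosome; an explicit mismatch with the model is
#'   an error.
#' @return List of class `element_location`: `category` (one of
#'   `"E"`, `"I"`, `"5U"`, `"3U"`, `"OTR"`), `ordinal`, `label`.
#' @export
locate_element <- function(model, pos0, chrom = NULL) {
  if (!is.null(chrom) && chrom != model$chrom) {
    stop(sprintf("chromosome mismatch: variant on %s, transcript %s on %s",
                 chrom, model$transcript_id, model$chrom), call. = FALSE)
  }
  es <- model$exon_starts[[1]]; ee <- model$exon_ends[[1]]
  n <- length(es)
  if (pos0 < model$tx_start || pos0 >= model$tx_end) {
    return(element_location("OTR", NA_integer_))
  }
  ex <- which(es <= pos0 & pos0 < ee)
  if (length(ex) == 0L) {
    left <- max(which(ee <= pos0))  # genomic index of the exon 5' (genomic) of the gap
    ord <- if (model$strand == "+") left else n - left
    return(element_location("I", ord))
  }
  ord <- exon_ordinal(model, ex)
  coding <- model$cds_start < model$cds_end
  if (!coding) return(element_location("E", ord))
  if (pos0 >= model$cds_start && pos0 < model$cds_end) {
    return(element_location("E", ord))
  }
  upstream <- if (model$strand == "+") pos0 < model$cds_start
              else pos0 >= model$cds_end
  element_location(if (upstream) "5U" else "3U", ord)
}

element_location <- function(category, ordinal) {
  label <- switch(category,
                  E = paste0("E", ordinal),
                  I = paste0("I", ordinal),
                  category)
  structure(list(category = category, ordinal = ordinal, label = label),
            class = "element_location")
}

# Standard nuclear genetic code on a codon string; stop is "*".
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Predict the protein-level consequence of an SNV on one transcript
#'
#' Builds the reference and alternate codons from the spliced CDS
#' (strand-aware: the alternate base is complemented on minus-strand
#' transcripts), translates both with the standard genetic code, and
#' classifies the change as synonymous, missense, nonsense, or stop_lost.
#' Non-SNV alleles get kind `unsupported_allele`; positions outside the CDS
#' (or in a trailing partial codon) get `noncoding_position`.  A REF allele
#' disagreeing with the genome is an error naming the position.
#'
#' @param model Single coding transcript model row.
#' @param genome Named character vector from [load_genome()].
#' @param variant List/row with `chrom`, `pos` (1-based VCF coordinate),
#'   `ref`, `alt`.
#' @return List of class `consequence`: `kind`, `ref_aa`, `alt_aa`,
#'   `aa_pos`, `codon_change`.
#' @export
predict_consequence <- function(model, genome, variant) {
  none <- function(kind) {
    structure(list(kind = kind, ref_aa = NA_character_,
                   alt_aa = NA_character_, aa_pos = NA_integer_,
                   codon_change = NA_character_), class = "consequence")
  }
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L ||
      !grepl("^[ACGT]$", toupper(variant$alt))) {
    return(none("unsupported_allele"))
  }
  pos0 <- variant$pos - 1L
  gbase <- genome_slice(genome, variant$chrom, pos0, pos0 + 1L)
  if (toupper(gbase) != toupper(variant$ref)) {
    stop(sprintf("reference mismatch at %s:%d — VCF says %s, genome has %s",
                 variant$chrom, variant$pos, variant$ref, gbase),
         call. = FALSE)
  }
  if (model$biotype != "protein_coding") return(none("noncoding_position"))
  idx <- cds_index(model, pos0)
  if (is.na(idx)) return(none("noncoding_position"))
  cds <- suppressWarnings(spliced_cds(model, genome, trim_partial = FALSE))
  codon_i <- (idx - 1L) %/% 3L + 1L
  if (3L * codon_i > nchar(cds)) return(none("noncoding_position"))
  ref_codon <- substr(cds, 3L * codon_i - 2L, 3L * codon_i)
  alt_base <- toupper(variant$alt)
  if (model$strand == "-") alt_base <- revcomp(alt_base)
  within <- (idx - 1L) %% 3L + 1L
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  kind <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "nonsense"
  else if (ref_aa == "*") "stop_lost"
  else "missense"
  structure(list(kind = kind, ref_aa = ref_aa, alt_aa = alt_aa,
                 aa_pos = codon_i,
                 codon_change = paste0(ref_codon, ">", alt_codon)),
            class = "consequence")
}

#' Rank a gene's isoforms by group expression
#'
#' Descending median TPM; ties broken by descending Q3 (the same
#' convention as the all-zero major call), then ascending transcript id.
#' Zero-expression isoforms come last.
#'
#' @inheritParams expression_percentage
#' @return Character vector of transcript ids.
#' @export
rank_isoforms <- function(summaries, gene, cohort, sample_class) {
  sub <- summaries_for(summaries, gene, cohort, sample_class)
  ord <- order(-sub$median_tpm, -sub$q3, sub$isoform_id)
  sub$isoform_id[ord]
}

fmt_tpm <- function(x) as.character(signif(x, 6))

xref_block <- function(xrefs, transcript_id) {
  i <- if (is.null(xrefs)) NA_integer_ else match(transcript_id, xrefs$transcript_id)
  gv <- function(col) {
    if (is.na(i)) "." else {
      v <- xrefs[[col]][i]
      if (is.na(v) || !nzchar(v)) "." else v
    }
  }
  paste0("UniProt:", gv("uniprot_id"), "&RefSeq:", gv("refseq_id"),
         "&Ensembl:", gv("ensembl_tx_id"), "&CCDS:", gv("ccds_id"))
}

#' Annotate a VCF with expression-prioritized isoform information
#'
#' Adds four header meta fields — sample tissue (`IE_TS`), cohort used for
#' expression (`IE_CA`), sample class (`IE_SA`), and that group's patient
#' count (`IE_SN`) — and five per-record INFO keys: the overlapped gene
#' symbol (`IE_GE`), the UniProt/UCSC canonical and APPRIS principal
#' isoform ids (`IE_UP`, `IE_UC`, `IE_AP`), and an isoform list sorted by
#' median TPM descending (`IE_IS`).  Each `IE_IS` entry is
#' `transcriptID|biotype|elementLabel|medianTPM|UniProt:x&RefSeq:x&Ensembl:x&CCDS:x`
#' with missing ids rendered `.` and median TPM at 6 significant digits.
#' Variants overlapping several genes get one block per gene joined by
#' `&`; intergenic variants get `.` in the gene and canonical keys and no
#' isoform list.  Original records are otherwise preserved byte for byte.
#'
#' @param vcf A `vcf` object from [read_vcf()].
#' @param models `transcript_models` data frame.
#' @param canon Canonical-assignment table.
#' @param xrefs Isoform cross-reference table (or `NULL`).
#' @param summaries A `group_summaries` data frame.
#' @param cohort,sample_class Expression group used for ranking.
#' @param tissue Free-text tissue label for `IE_TS` (defaults to the
#'   cohort).
#' @return The annotated `vcf` object.
#' @export
annotate_vcf <- function(vcf, models, canon, xrefs, summaries,
                         cohort, sample_class, tissue = cohort) {
  grp <- summaries[summaries$cohort == cohort &
                     summaries$sample_class == sample_class, , drop = FALSE]
  if (nrow(grp) == 0L) {
    stop(sprintf("no expression group (%s, %s) in summaries",
                 cohort, sample_class), call. = FALSE)
  }
  n_samples <- max(grp$n_patients)
  info_meta <- c(
    sprintf("##IE_TS=%s", tissue),
    sprintf("##IE_CA=%s", cohort),
    sprintf("##IE_SA=%s", sample_class),
    sprintf("##IE_SN=%d", n_samples),
    "##INFO=<ID=IE_GE,Number=.,Type=String,Description=\"Gene symbol at the variant position\">",
    "##INFO=<ID=IE_UP,Number=.,Type=String,Description=\"UniProt-based canonical isoform\">",
    "##INFO=<ID=IE_UC,Number=.,Type=String,Description=\"UCSC-based canonical isoform\">",
    "##INFO=<ID=IE_AP,Number=.,Type=String,Description=\"APPRIS-based principal isoform\">",
    "##INFO=<ID=IE_IS,Number=.,Type=String,Description=\"Isoforms sorted by median TPM: id|biotype|element|medianTPM|xrefs\">")
  vcf$meta <- c(vcf$meta, info_meta)
  # gene spans per (symbol, chrom)
  gkey <- paste(models$gene_symbol, models$chrom, sep = "\r")
  spans <- do.call(rbind, lapply(split(seq_len(nrow(models)), gkey), function(idx) {
    data.frame(gene = models$gene_symbol[idx[1]], chrom = models$chrom[idx[1]],
               start = min(models$tx_start[idx]), end = max(models$tx_end[idx]),
               stringsAsFactors = FALSE)
  }))
  canon_of <- function(gene, col) {
    i <- match(gene, canon$gene_symbol)
    if (is.na(i) || is.na(canon[[col]][i])) "." else canon[[col]][i]
  }
  rec <- vcf$records
  for (r in seq_len(nrow(rec))) {
    pos0 <- rec$pos[r] - 1L  # single 1-based -> 0-based conversion point
    hits <- spans[spans$chrom == rec$chrom[r] &
                    spans$start <= pos0 & pos0 < spans$end, , drop = FALSE]
    if (nrow(hits) == 0L) {
      add <- "IE_GE=.;IE_UP=.;IE_UC=.;IE_AP=."
    } else {
      genes <- hits$gene
      is_blocks <- vapply(genes, function(g) {
        ranked <- rank_isoforms(summaries, g, cohort, sample_class)
        gsub_rows <- grp[grp$gene_id == g, , drop = FALSE]
        entries <- vapply(ranked, function(tx) {
          m <- get_model(models, tx)
          loc <- locate_element(m, pos0, chrom = rec$chrom[r])
          mtpm <- gsub_rows$median_tpm[match(tx, gsub_rows$isoform_id)]
          paste(tx, m$biotype, loc$label, fmt_tpm(mtpm),
                xref_block(xrefs, tx), sep = "|")
        }, "")
        paste(entries, collapse = ",")
      }, "")
      add <- paste0(
        "IE_GE=", paste(genes, collapse = "&"),
        ";IE_UP=", paste(vapply(genes, canon_of, "", col = "uniprot_canonical"), collapse = "&"),
        ";IE_UC=", paste(vapply(genes, canon_of, "", col = "ucsc_canonical"), collapse = "&"),
        ";IE_AP=", paste(vapply(genes, canon_of, "", col = "appris_principal"), collapse = "&"),
        ";IE_IS=", paste(is_blocks, collapse = "&"))
    }
    rec$info[r] <- if (rec$info[r] == "." || !nzchar(rec$info[r])) add
                   else paste(rec$info[r], add, sep = ";")
  }
  vcf$records <- rec
  vcf
}

#' Compare a variant's interpretation on two transcript backbones
#'
#' Locates the variant on the expression-chosen major isoform and on the
#' canonical/principal isoform, predicts the protein consequence where the
#' position is coding, and assigns one of the discordance case labels:
#' `concordant_coding` (coding on both backbones, same amino-acid
#' interpretation), `coding_coding_aa_changed` (coding on both, different
#' interpretation — a synonymous vs non-synonymous flip counts as
#' different), or `coding_vs_intron` / `coding_vs_5U` / `coding_vs_3U` /
#' `coding_vs_OTR` when a canonically coding position relocates.  Variants
#' that are non-coding on the canonical backbone are labelled
#' `canonical_noncoding` and excluded from the relocation partition.
#'
#' @param variant List/row with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param major_model,canonical_model Transcript model rows for the same
#'   gene.
#' @param genome Named character vector from [load_genome()].
#' @return One-row data frame of class `backbone_comparison`.
#' @export
compare_backbones <- function(variant, major_model, canonical_model, genome) {
  is_coding <- function(model, loc) {
    loc$category == "E" && model$cds_start < model$cds_end &&
      !is.na(cds_index(model, variant$pos - 1L))
  }
  loc_m <- locate_element(major_model, variant$pos - 1L, chrom = variant$chrom)
  loc_c <- locate_element(canonical_model, variant$pos - 1L, chrom = variant$chrom)
  coding_m <- is_coding(major_model, loc_m)
  coding_c <- is_coding(canonical_model, loc_c)
  cons_m <- if (coding_m) predict_consequence(major_model, genome, variant) else NULL
  cons_c <- if (coding_c) predict_consequence(canonical_model, genome, variant) else NULL
  exon_changed <- NA
  aa_changed <- NA
  if (!coding_c) {
    case <- "canonical_noncoding"
  } else if (coding_m) {
    exon_changed <- loc_m$ordinal != loc_c$ordinal
    syn_m <- cons_m$kind == "synonymous"
    syn_c <- cons_c$kind == "synonymous"
    aa_changed <- if (syn_m != syn_c) TRUE
    else if (!syn_m) !identical(c(cons_m$ref_aa, cons_m$alt_aa),
                                c(cons_c$ref_aa, cons_c$alt_aa))
    else FALSE
    case <- if (aa_changed) "coding_coding_aa_changed" else "concordant_coding"
  } else {
    case <- switch(loc_m$category,
                   I = "coding_vs_intron",
                   `5U` = "coding_vs_5U",
                   `3U` = "coding_vs_3U",
                   E = "coding_vs_3U",  # exonic but outside CDS never reaches here
                   "coding_vs_OTR")
  }
  res <- data.frame(
    chrom = variant$chrom, pos = variant$pos, ref = variant$ref,
    alt = variant$alt,
    major_id = major_model$transcript_id,
    canonical_id = canonical_model$transcript_id,
    major_label = loc_m$label, canonical_label = loc_c$label,
    case = case, exon_number_changed = exon_changed, aa_changed = aa_changed,
    major_kind = if (coding_m) cons_m$kind else NA_character_,
    canonical_kind = if (coding_c) cons_c$kind else NA_character_,
    major_aa = if (coding_m) paste0(cons_m$ref_aa, ">", cons_m$alt_aa) else NA_character_,
    canonical_aa = if (coding_c) paste0(cons_c$ref_aa, ">", cons_c$alt_aa) else NA_character_,
    stringsAsFactors = FALSE)
  class(res) <- c("backbone_comparison", class(res))
  res
}

#' Summarize backbone discordance over many variants
#'
#' Counts, over the comparisons whose major isoform differs from the
#' canonical one: how many positions are coding on the canonical backbone;
#' of those, how many remain coding on the major backbone versus relocate
#' to intron / 5'UTR / 3'UTR / outside the transcript; of the
#' still-coding ones, how many keep or change their exon ordinal; and how
#' many change their amino-acid interpretation.  Percentages (one decimal,
#' half away from zero) use the denominators of the published layout:
#' coding-in-canonical over non-canonical-major; each relocation bucket
#' over coding-in-canonical; exon-number splits over still-coding; and
#' amino-acid changes over exon-number-changed.
#'
#' @param comparisons Data frame of [compare_backbones()] rows.
#' @param canonical_definition Which canonical definition produced the
#'   comparisons: `"ucsc"`, `"uniprot"`, or `"appris"` (recorded, not used
#'   in arithmetic).
#' @return List of class `discordance_summary` with `counts` and `pct`.
#' @export
summarize_discordance <- function(comparisons,
                                  canonical_definition = c("ucsc", "uniprot", "appris")) {
  canonical_definition <- match.arg(canonical_definition)
  n_total <- nrow(comparisons)
  if (n_total == 0L) {
    comparisons <- comparisons[0, , drop = FALSE]
  }
  mism <- comparisons[comparisons$major_id != comparisons$canonical_id, ,
                      drop = FALSE]
  counts <- list(
    n_total = n_total,
    n_noncanonical_major = nrow(mism),
    n_coding_in_canonical = sum(mism$case != "canonical_noncoding"),
    n_still_coding_in_major =
      sum(mism$case %in% c("concordant_coding", "coding_coding_aa_changed")),
    n_intron = sum(mism$case == "coding_vs_intron"),
    n_5U = sum(mism$case == "coding_vs_5U"),
    n_3U = sum(mism$case == "coding_vs_3U"),
    n_OTR = sum(mism$case == "coding_vs_OTR"),
    n_same_exon_number = sum(!is.na(mism$exon_number_changed) &
                               !mism$exon_number_changed),
    n_exon_number_changed = sum(mism$exon_number_changed, na.rm = TRUE),
    n_aa_interpretation_changed = sum(mism$aa_changed, na.rm = TRUE))
  pct_of <- function(x, denom) {
    if (denom > 0) round_half_away(100 * x / denom, 1) else NA_real_
  }
  pct <- list(
    coding_in_canonical = pct_of(counts$n_coding_in_canonical,
                                 counts$n_noncanonical_major),
    still_coding_in_major = pct_of(counts$n_still_coding_in_major,
                                   counts$n_coding_in_canonical),
    intron = pct_of(counts$n_intron, counts$n_coding_in_canonical),
    `5U` = pct_of(counts$n_5U, counts$n_coding_in_canonical),
    `3U` = pct_of(counts$n_3U, counts$n_coding_in_canonical),
    OTR = pct_of(counts$n_OTR, counts$n_coding_in_canonical),
    same_exon_number = pct_of(counts$n_same_exon_number,
                              counts$n_still_coding_in_major),
    exon_number_changed = pct_of(counts$n_exon_number_changed,
                                 counts$n_still_coding_in_major),
    aa_interpretation_changed = pct_of(counts$n_aa_interpretation_changed,
                                       counts$n_exon_number_changed))
  structure(list(canonical_definition = canonical_definition,
                 counts = counts, pct = pct),
            class = "discordance_summary")
}
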