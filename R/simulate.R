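# Deterministic synthetic fixtures.  The gene architecture is fixed by
# design (engineered to contain each discordance case analogue and each
# consistency bucket); the seed only controls genome sequence and the
# jitter around designed expression medians.

#' Describe a synthetic fixture
#'
#' The default design states the world the tests assume: a five-isoform
#' gene with a tumor-only isoform at a designed 0.40 TPM and a major-
#' isoform switch at a designed 29.3-fold change; a two-isoform gene whose
#' shared position sits in different exon ordinals with a shifted reading
#' frame; a gene where a canonically coding position is 3'UTR on the major
#' isoform; plus- and minus-strand genes; a non-coding isoform; a silent
#' gene; and an expressed gene with no canonical assignment.  Patient
#' counts are odd so sample medians hit the designed values exactly; the
#' eligible cohort has 11 matched normals (above the 10-patient floor) and
#' the second cohort 5 (below it).
#'
#' @param seed Integer seed driving every random draw.
#' @param n_tumor,n_normal Patients per group in the eligible cohort
#'   (odd; defaults 11/11).
#' @param n_tumor2,n_normal2 Patients per group in the ineligible cohort
#'   (odd; defaults 5/5).
#' @param chrom_lengths Named lengths of the synthetic chromosomes.
#' @param jitter Relative spread of non-median values around the designed
#'   median (default 0.2, i.e. within +/-20 percent).
#' @return List of class `fixture_design`.
#' @export
fixture_design <- function(seed = 1L, n_tumor = 11L, n_normal = 11L,
                           n_tumor2 = 5L, n_normal2 = 5L,
                           chrom_lengths = c(chr1 = 9000L, chr2 = 6000L),
                           jitter = 0.2) {
  if (any(chrom_lengths <= 0)) {
    stop("fixture_design: chromosome lengths must be positive", call. = FALSE)
  }
  for (n in c(n_tumor, n_normal, n_tumor2, n_normal2)) {
    if (n %% 2L == 0L) {
      stop("fixture_design: patient counts must be odd so designed medians are exact",
           call. = FALSE)
    }
  }
  # designed group medians in TPM (fractions are these times 1e-6)
  med <- rbind(
    data.frame(isoform_id = paste0("FXA.iso", 1:5), gene_id = "FXA",
               tumor = c(0.40, 29.3, 0.3, 14.0, 0.1),
               normal = c(0, 1.0, 0.4, 10.0, 1.4866)),
    data.frame(isoform_id = paste0("BTF.iso", 1:2), gene_id = "BTF",
               tumor = c(5, 20), normal = c(5, 20)),
    data.frame(isoform_id = paste0("AMH.iso", 1:2), gene_id = "AMH",
               tumor = c(2, 8), normal = c(2, 8)),
    data.frame(isoform_id = paste0("MND.iso", 1:2), gene_id = "MND",
               tumor = c(6, 1), normal = c(6, 1)),
    data.frame(isoform_id = "SIL.iso1", gene_id = "SIL",
               tumor = 0, normal = 0),
    data.frame(isoform_id = paste0("NOC.iso", 1:2), gene_id = "NOC",
               tumor = c(3, 1), normal = c(3, 1)))
  structure(list(seed = as.integer(seed), n_tumor = n_tumor,
                 n_normal = n_normal, n_tumor2 = n_tumor2,
                 n_normal2 = n_normal2, chrom_lengths = chrom_lengths,
                 jitter = jitter, medians = med,
                 cohorts = c("LUAD", "BRCA")),
            class = "fixture_design")
}

#' Generate the synthetic genome
#'
#' @param design A [fixture_design()].
#' @return Named character vector of random ACGT sequences, deterministic
#'   per seed.
#' @export
make_genome <- function(design) {
  with_seed(design$seed, {
    vapply(names(design$chrom_lengths), function(ch) {
      paste(sample(c("A", "C", "G", "T"), design$chrom_lengths[[ch]],
                   replace = TRUE), collapse = "")
    }, "")
  })
}

# Hard-coded transcript architecture (0-based half-open coordinates).
fixture_architecture <- function() {
  tx <- function(id, sym, chrom, strand, es, ee, cs, ce) {
    list(transcript_id = id, gene_symbol = sym, chrom = chrom,
         strand = strand, exon_starts = es, exon_ends = ee,
         cds_start = cs, cds_end = ce)
  }
  list(
    tx("FXA.iso1", "FXA", "chr1", "+", c(1000, 1500, 2000, 2600),
       c(1200, 1700, 2200, 2800), 1100, 2700),
    tx("FXA.iso2", "FXA", "chr1", "+", c(1000, 1500, 2000, 2600),
       c(1200, 1700, 2200, 2900), 1105, 2705),
    tx("FXA.iso3", "FXA", "chr1", "+", c(1000, 2000), c(1200, 2200),
       1101, 2150),
    tx("FXA.iso4", "FXA", "chr1", "+", c(1000, 1500, 2600),
       c(1200, 1700, 2800), 1100, 2699),
    tx("FXA.iso5", "FXA", "chr1", "+", 2500, 3000, 2550, 2850),
    tx("BTF.iso1", "BTF", "chr1", "+", c(4000, 4020, 4040, 4070),
       c(4010, 4030, 4060, 4090), 4003, 4087),
    tx("BTF.iso2", "BTF", "chr1", "+", c(3900, 4000, 4020, 4040, 4070),
       c(3920, 4010, 4030, 4060, 4090), 4004, 4088),
    tx("AMH.iso1", "AMH", "chr1", "+", 5000, 5100, 5010, 5070),
    tx("AMH.iso2", "AMH", "chr1", "+", 5000, 5100, 5010, 5040),
    tx("SIL.iso1", "SIL", "chr1", "+", c(6000, 6300), c(6200, 6400),
       6050, 6351),
    tx("NOC.iso1", "NOC", "chr1", "+", 7000, 7300, 7050, 7200),
    tx("NOC.iso2", "NOC", "chr1", "+", c(7000, 7200), c(7100, 7500),
       7050, 7351),
    tx("MND.iso1", "MND", "chr2", "-", c(1000, 1500, 1900),
       c(1300, 1700, 2000), 1100, 1950),
    tx("MND.iso2", "MND", "chr2", "-", c(1000, 1900), c(1300, 2000),
       1000, 1000))
}

#' Generate synthetic transcript models and annotation tables
#'
#' @param design A [fixture_design()].
#' @param genome Genome from [make_genome()] (used to check that every
#'   transcript fits on its chromosome).
#' @return List: `models` (`transcript_models`), `canonical`, `xrefs`,
#'   `gene_info` data frames.
#' @export
make_gene_models <- function(design, genome) {
  arch <- fixture_architecture()
  for (t in arch) {
    len <- nchar(genome[[t$chrom]] %||% "")
    if (max(t$exon_ends) > len) {
      stop(sprintf("fixture generation error: %s extends to %d beyond %s length %d",
                   t$transcript_id, max(t$exon_ends), t$chrom, len),
           call. = FALSE)
    }
  }
  models <- data.frame(
    transcript_id = vapply(arch, `[[`, "", "transcript_id"),
    gene_symbol = vapply(arch, `[[`, "", "gene_symbol"),
    chrom = vapply(arch, `[[`, "", "chrom"),
    strand = vapply(arch, `[[`, "", "strand"),
    tx_start = vapply(arch, function(t) min(t$exon_starts), 0),
    tx_end = vapply(arch, function(t) max(t$exon_ends), 0),
    cds_start = vapply(arch, `[[`, 0, "cds_start"),
    cds_end = vapply(arch, `[[`, 0, "cds_end"),
    stringsAsFactors = FALSE)
  models$exon_starts <- lapply(arch, `[[`, "exon_starts")
  models$exon_ends <- lapply(arch, `[[`, "exon_ends")
  models$biotype <- ifelse(models$cds_start == models$cds_end,
                           "non_coding", "protein_coding")
  for (i in seq_len(nrow(models))) {
    msg <- check_model_row(models[i, ])
    if (!is.null(msg)) {
      stop("fixture generation error in ", models$transcript_id[i], ": ", msg,
           call. = FALSE)
    }
  }
  class(models) <- c("transcript_models", class(models))
  canonical <- data.frame(
    gene_symbol = c("FXA", "BTF", "AMH", "MND", "SIL"),
    uniprot_canonical = c("FXA.iso2", NA, "AMH.iso1", NA, NA),
    ucsc_canonical = c("FXA.iso2", "BTF.iso1", "AMH.iso1", "MND.iso1",
                       "SIL.iso1"),
    appris_principal = c("FXA.iso2", "BTF.iso1", NA, "MND.iso1", NA),
    stringsAsFactors = FALSE)
  xrefs <- data.frame(
    transcript_id = models$transcript_id,
    uniprot_id = ifelse(models$biotype == "protein_coding",
                        paste0("Q9", sprintf("%04d", seq_len(nrow(models)))), NA),
    refseq_id = paste0("NM_", sprintf("%06d", 900000 + seq_len(nrow(models)))),
    ensembl_tx_id = paste0("ENST", sprintf("%011d", seq_len(nrow(models)))),
    ccds_id = ifelse(seq_len(nrow(models)) %% 2L == 0L,
                     paste0("CCDS", 7000 + seq_len(nrow(models))), NA),
    peptide_available = models$biotype == "protein_coding",
    stringsAsFactors = FALSE)
  gene_info <- data.frame(
    symbol = c("FXA", "BTF", "AMH", "MND", "SIL", "NOC"),
    full_name = c("forkhead box fixture A", "basic transcription fixture",
                  "anti-Mullerian-like fixture", "minus-strand demo gene",
                  "silent fixture gene", "no-canonical fixture gene"),
    refseq_id = c("NM_202900", "NM_202901", "NM_202902", "NM_202903",
                  "NM_202904", "NM_202905"),
    uniprot_id = c("Q08900", "Q08901", "Q08902", "Q08903", "Q08904",
                   "Q08905"),
    ensembl_gene_id = paste0("ENSG", sprintf("%011d", 900001:900006)),
    stringsAsFactors = FALSE)
  list(models = models, canonical = canonical, xrefs = xrefs,
       gene_info = gene_info)
}

#' Generate a synthetic expression table and sample sheet
#'
#' Per (isoform, group), one patient carries exactly the designed median
#' fraction; the patients below/above it draw uniformly within the design's
#' jitter band, so group medians equal the design exactly (patient counts
#' are odd).  The first tumor patient of the eligible cohort contributes
#' two replicate samples whose mean is the patient's value, exercising
#' replicate collapsing.
#'
#' @param design A [fixture_design()].
#' @return List: `expr` (`expression_table`), `sheet` (sample sheet).
#' @export
make_expression <- function(design) {
  med <- design$medians
  groups <- list(
    list(cohort = "LUAD", class = "tumor", n = design$n_tumor, col = "tumor"),
    list(cohort = "LUAD", class = "normal", n = design$n_normal, col = "normal"),
    list(cohort = "BRCA", class = "tumor", n = design$n_tumor2, col = "tumor"),
    list(cohort = "BRCA", class = "normal", n = design$n_normal2, col = "normal"))
  with_seed(design$seed + 1L, {
    expr <- med[, c("isoform_id", "gene_id")]
    sheet <- NULL
    for (g in groups) {
      patients <- sprintf("%s-%s-P%02d", g$cohort, toupper(substr(g$class, 1, 1)),
                          seq_len(g$n))
      sample_ids <- paste0("S_", patients)
      vals <- matrix(0, nrow(med), g$n)
      half <- (g$n - 1L) %/% 2L
      mid <- half + 1L
      for (r in seq_len(nrow(med))) {
        m <- med[[g$col]][r] * 1e-6  # designed median as a fraction
        if (m > 0) {
          lo <- sort(stats::runif(half, m * (1 - design$jitter), m))
          hi <- sort(stats::runif(half, m, m * (1 + design$jitter)))
          vals[r, ] <- pmin(c(lo, m, hi), 1)
        }
      }
      df <- as.data.frame(vals)
      names(df) <- sample_ids
      gsheet <- data.frame(sample_id = sample_ids, patient_id = patients,
                           cohort = g$cohort, sample_class = g$class,
                           stringsAsFactors = FALSE)
      # replicate pair for the first eligible-cohort tumor patient
      if (g$cohort == "LUAD" && g$class == "tumor") {
        v <- df[[1]]
        rep_a <- paste0(sample_ids[1], "a"); rep_b <- paste0(sample_ids[1], "b")
        df[[1]] <- NULL
        df[[rep_a]] <- v * 0.9
        df[[rep_b]] <- v * 1.1
        gsheet <- rbind(gsheet[-1, ],
                        data.frame(sample_id = c(rep_a, rep_b),
                                   patient_id = patients[1],
                                   cohort = g$cohort, sample_class = g$class,
                                   stringsAsFactors = FALSE))
      }
      expr <- cbind(expr, df)
      sheet <- rbind(sheet, gsheet)
    }
    class(expr) <- c("expression_table", "data.frame")
    list(expr = expr, sheet = sheet)
  })
}

# Designed variant placements: position plus the element category expected
# on the named target transcript.
fixture_variant_plan <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr1"),
    pos0 = c(4075, 5050, 1600, 1850, 1050, 2750, 1600, 8500),
    target = c("BTF.iso1", "AMH.iso1", "FXA.iso2", "FXA.iso2", "FXA.iso2",
               "FXA.iso2", "MND.iso1", NA),
    category = c("E", "E", "E", "I", "5U", "3U", "E", "OTR"),
    note = c("case2: E4 on BTF.iso1 vs E5 on BTF.iso2, frame shifted",
             "case3: coding on AMH.iso1, 3U on AMH.iso2",
             "coding exon 2 of the FXA major isoform",
             "intron 2 of the FXA major isoform",
             "5'UTR of the FXA major isoform",
             "3'UTR of the FXA major isoform",
             "minus-strand coding exon",
             "intergenic"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic VCF hitting each designed element category
#'
#' REF alleles are read from the genome; ALT is the next base in ACGT
#' order, so the file is deterministic per seed and annotates with zero
#' reference mismatches.
#'
#' @param design A [fixture_design()].
#' @param models Models from [make_gene_models()].
#' @param genome Genome from [make_genome()].
#' @return A `vcf` object (see [read_vcf()]).
#' @export
make_vcf <- function(design, models, genome) {
  plan <- fixture_variant_plan()
  for (i in seq_len(nrow(plan))) {
    if (!is.na(plan$target[i])) {
      m <- get_model(models, plan$target[i])
      loc <- locate_element(m, plan$pos0[i])
      if (loc$category != plan$category[i]) {
        stop(sprintf(
          "fixture generation error: variant %d lands in %s on %s, designed %s",
          i, loc$category, plan$target[i], plan$category[i]), call. = FALSE)
      }
    }
  }
  bases <- c("A", "C", "G", "T")
  ref <- vapply(seq_len(nrow(plan)), function(i) {
    genome_slice(genome, plan$chrom[i], plan$pos0[i], plan$pos0[i] + 1L)
  }, "")
  alt <- bases[(match(ref, bases)) %% 4L + 1L]
  records <- data.frame(
    chrom = plan$chrom, pos = plan$pos0 + 1L,
    id = sprintf("var%02d", seq_len(nrow(plan))),
    ref = ref, alt = alt, qual = ".", filter = "PASS", info = ".",
    stringsAsFactors = FALSE)
  records$extra <- rep(list(character(0)), nrow(records))
  structure(list(
    meta = c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(design$chrom_lengths),
                     design$chrom_lengths),
             "##source=isomajor_fixture"),
    header = paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"),
    records = records), class = "vcf")
}

#' Generate and write a complete fixture set
#'
#' Writes genome.fa, models.genepred, expression.tsv, samples.tsv,
#' canonical.tsv, xrefs.tsv, gene_info.tsv, and variants.vcf under `dir`.
#'
#' @param design A [fixture_design()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_fixture <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(design)
  ann <- make_gene_models(design, genome)
  ex <- make_expression(design)
  vcf <- make_vcf(design, ann$models, genome)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    models = file.path(dir, "models.genepred"),
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    canonical = file.path(dir, "canonical.tsv"),
    xrefs = file.path(dir, "xrefs.tsv"),
    gene_info = file.path(dir, "gene_info.tsv"),
    vcf = file.path(dir, "variants.vcf"))
  write_genome(genome, paths$genome)
  write_genepred(ann$models, paths$models)
  write_tsv(ex$expr, paths$expression)
  write_tsv(ex$sheet, paths$samples)
  write_tsv(ann$canonical, paths$canonical)
  write_tsv(ann$xrefs, paths$xrefs)
  write_tsv(ann$gene_info, paths$gene_info)
  write_vcf(vcf, paths$vcf)
  invisible(paths)
}
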