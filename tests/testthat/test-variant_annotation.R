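test_that("locate_element matches the per-base oracle on every fixture base", {
  fx <- default_fixture()
  for (i in seq_len(nrow(fx$models))) {
    m <- fx$models[i, ]
    for (pos in (m$tx_start - 2):(m$tx_end + 1)) {
      got <- locate_element(m, pos)
      expect_identical(got$label, oracle_locate_label(m, pos),
                       label = sprintf("%s pos %d", m$transcript_id, pos))
    }
  }
})

test_that("locate_element matches the oracle on random structures (both strands)", {
  set.seed(21)
  for (i in 1:40) {
    m <- random_model(i)
    for (pos in (m$tx_start - 1):m$tx_end) {
      expect_identical(locate_element(m, pos)$label,
                       oracle_locate_label(m, pos),
                       label = sprintf("random %d (%s) pos %d", i, m$strand, pos))
    }
  }
})

test_that("locate_element frozen examples and errors", {
  m <- toy_model(es = c(100, 200, 300, 400, 500, 600, 700, 800),
                 ee = c(150, 250, 350, 450, 550, 650, 750, 850),
                 cs = 120, ce = 820)
  expect_equal(locate_element(m, 50)$label, "OTR")
  expect_equal(locate_element(m, 210)$label, "E2")
  expect_equal(locate_element(m, 760)$label, "I7")  # between exons 7 and 8
  expect_equal(locate_element(m, 105)$label, "5U")
  expect_equal(locate_element(m, 830)$label, "3U")
  # minus strand: genomically last exon upstream of CDS in transcription order
  mm <- toy_model(strand = "-", es = c(100, 300), ee = c(200, 400),
                  cs = 120, ce = 350)
  expect_equal(locate_element(mm, 380)$label, "5U")
  expect_equal(locate_element(mm, 110)$label, "3U")
  expect_equal(locate_element(mm, 250)$label, "I1")
  # non-coding transcripts: every exonic position is an exon
  nc <- toy_model(strand = "-", es = c(100, 300), ee = c(200, 400))
  expect_equal(locate_element(nc, 110)$label, "E2")
  expect_equal(locate_element(nc, 380)$label, "E1")
  expect_error(locate_element(m, 210, chrom = "chrOther"), "mismatch")
})

test_that("predict_consequence classifies toy codon changes", {
  genome <- c(chrT = paste0(strrep("A", 50), "ATGTTGTAA", strrep("A", 41)))
  m <- toy_model(es = 50, ee = 59, cs = 50, ce = 59)
  v <- function(pos1, ref, alt) list(chrom = "chrT", pos = pos1, ref = ref,
                                     alt = alt)
  mis <- predict_consequence(m, genome, v(55, "T", "C"))  # TTG -> TCG
  expect_equal(mis$kind, "missense")
  expect_equal(c(mis$ref_aa, mis$alt_aa), c("L", "S"))
  expect_equal(mis$aa_pos, 2L)
  syn <- predict_consequence(m, genome, v(54, "T", "C"))  # TTG -> CTG
  expect_equal(syn$kind, "synonymous")
  expect_equal(syn$ref_aa, syn$alt_aa)
  non <- predict_consequence(m, genome, v(55, "T", "A"))  # TTG -> TAG
  expect_equal(non$kind, "nonsense")
  lost <- predict_consequence(m, genome, v(58, "A", "C")) # TAA -> TCA
  expect_equal(lost$kind, "stop_lost")
  # non-SNV and reference mismatch
  expect_equal(predict_consequence(m, genome, v(55, "TT", "T"))$kind,
               "unsupported_allele")
  expect_error(predict_consequence(m, genome, v(55, "G", "C")),
               "reference mismatch")
  # UTR position on a longer transcript
  m2 <- toy_model(es = 40, ee = 70, cs = 50, ce = 59)
  expect_equal(predict_consequence(m2, genome, v(45, "A", "G"))$kind,
               "noncoding_position")
})

test_that("consequence is strand-symmetric under a mirrored world", {
  set.seed(31)
  genome <- random_genome(300, "chrT")
  m <- toy_model(es = c(40, 120, 200), ee = c(90, 160, 260), cs = 55,
                 ce = 240)
  mir <- mirror_world(m, genome)
  expect_identical(spliced_cds(m, genome, trim_partial = FALSE),
                   spliced_cds(mir$model, mir$genome, trim_partial = FALSE))
  exonic <- unlist(mapply(function(s, e) s:(e - 1), m$exon_starts[[1]],
                          m$exon_ends[[1]], SIMPLIFY = FALSE))
  coding <- exonic[exonic >= m$cds_start & exonic < m$cds_end]
  for (pos in sample(coding, 40)) {
    ref <- substr(genome[["chrT"]], pos + 1, pos + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a <- predict_consequence(m, genome,
                               list(chrom = "chrT", pos = pos + 1,
                                    ref = ref, alt = alt))
      mp <- mir$flip_pos(pos)
      b <- predict_consequence(mir$model, mir$genome,
                               list(chrom = "chrM", pos = mp + 1,
                                    ref = unname(mir$comp[ref]),
                                    alt = unname(mir$comp[alt])))
      expect_identical(a[c("kind", "ref_aa", "alt_aa", "aa_pos")],
                       b[c("kind", "ref_aa", "alt_aa", "aa_pos")])
    }
  }
})

test_that("rank_isoforms sorts by median TPM, then Q3, then id", {
  mk <- function(iso, med, q3) {
    df <- data.frame(isoform_id = iso, gene_id = "G1", cohort = "C",
                     sample_class = "tumor", n_patients = 5, whisker_min = 0,
                     q1 = 0, median = med, q3 = q3, whisker_max = q3,
                     median_tpm = med * 1e6)
    df$lower_outliers <- rep(list(numeric(0)), length(iso))
    df$upper_outliers <- rep(list(numeric(0)), length(iso))
    class(df) <- c("group_summaries", "data.frame")
    df
  }
  s <- mk(c("A", "B", "C"), c(1e-5, 1e-4, 0), c(1e-5, 1e-4, 0))
  expect_equal(rank_isoforms(s, "G1", "C", "tumor"), c("B", "A", "C"))
  s2 <- mk(c("A", "B"), c(0, 0), c(0, 1e-6))
  expect_equal(rank_isoforms(s2, "G1", "C", "tumor"), c("B", "A"))
  s3 <- mk("A", 1e-6, 1e-6)
  expect_equal(rank_isoforms(s3, "G1", "C", "tumor"), "A")
})

test_that("annotate_vcf emits all nine IE_* fields and preserves records", {
  fx <- default_fixture()
  ann <- annotate_vcf(fx$vcf, fx$models, fx$canonical, fx$xrefs,
                      fx$summaries, "LUAD", "tumor")
  # header declares the nine fields
  for (k in c("##IE_TS=", "##IE_CA=LUAD", "##IE_SA=tumor", "##IE_SN=11")) {
    expect_true(any(startsWith(ann$meta, k)), label = k)
  }
  for (k in c("IE_GE", "IE_UP", "IE_UC", "IE_AP", "IE_IS")) {
    expect_true(any(grepl(sprintf("##INFO=<ID=%s,", k), ann$meta)), label = k)
  }
  # genic records carry the five per-variant keys
  genic <- ann$records$info[ann$records$chrom == "chr1" &
                              ann$records$pos == 1601]
  for (k in c("IE_GE=FXA", "IE_UP=", "IE_UC=", "IE_AP=", "IE_IS=")) {
    expect_match(genic, k, fixed = TRUE)
  }
  # IE_IS sorted by median TPM descending, all isoforms present
  is_field <- sub("^.*IE_IS=", "", genic)
  ids <- vapply(strsplit(strsplit(is_field, ",", fixed = TRUE)[[1]], "|",
                         fixed = TRUE), `[[`, "", 1L)
  expect_equal(ids, rank_isoforms(fx$summaries, "FXA", "LUAD", "tumor"))
  # no forbidden characters inside IE_IS values
  expect_false(grepl("[ ;=]", is_field))
  # intergenic record: '.' gene and no isoform list
  inter <- ann$records$info[ann$records$pos == 8501]
  expect_match(inter, "IE_GE=\\.")
  expect_false(grepl("IE_IS=", inter))
  # element label of the minus-strand coding variant
  mnd <- ann$records$info[ann$records$chrom == "chr2"]
  expect_match(mnd, "MND.iso1|protein_coding|E2|", fixed = TRUE)
  # original fields untouched; stripping IE_* keys recovers the input
  stripped <- sub(";?IE_GE=.*$", "", ann$records$info)
  stripped[stripped == ""] <- "."
  expect_identical(stripped, fx$vcf$records$info)
  expect_identical(ann$records[, c("chrom", "pos", "id", "ref", "alt")],
                   fx$vcf$records[, c("chrom", "pos", "id", "ref", "alt")])
})

test_that("VCF read/write round trip is byte-identical and idempotent", {
  fx <- default_fixture()
  p1 <- tempfile(fileext = ".vcf")
  write_vcf(fx$vcf, p1)
  v2 <- read_vcf(p1)
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(v2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # annotated VCF re-parses and re-serializes identically
  ann <- annotate_vcf(fx$vcf, fx$models, fx$canonical, fx$xrefs,
                      fx$summaries, "LUAD", "tumor")
  p3 <- tempfile(fileext = ".vcf"); p4 <- tempfile(fileext = ".vcf")
  write_vcf(ann, p3)
  write_vcf(read_vcf(p3), p4)
  expect_identical(readLines(p3), readLines(p4))
  unlink(c(p1, p2, p3, p4))
})

test_that("compare_backbones reproduces the discordance case taxonomy", {
  fx <- default_fixture()
  vr <- fx$vcf$records
  mkvar <- function(i) list(chrom = vr$chrom[i], pos = vr$pos[i],
                            ref = vr$ref[i], alt = vr$alt[i])
  # case-2 analogue: both coding, different exon ordinal, shifted frame
  b2 <- compare_backbones(mkvar(1), get_model(fx$models, "BTF.iso2"),
                          get_model(fx$models, "BTF.iso1"), fx$genome)
  expect_true(b2$case %in% c("concordant_coding", "coding_coding_aa_changed"))
  expect_true(b2$exon_number_changed)
  expect_equal(c(b2$canonical_label, b2$major_label), c("E4", "E5"))
  # case-3 analogue: coding in canonical, 3'UTR in major
  b3 <- compare_backbones(mkvar(2), get_model(fx$models, "AMH.iso2"),
                          get_model(fx$models, "AMH.iso1"), fx$genome)
  expect_equal(b3$case, "coding_vs_3U")
  # concordant: same backbone structure around the variant
  b1 <- compare_backbones(mkvar(3), get_model(fx$models, "FXA.iso1"),
                          get_model(fx$models, "FXA.iso2"), fx$genome)
  expect_true(b1$case %in% c("concordant_coding", "coding_coding_aa_changed"))
  # intron relocation: FXA.iso3 skips exon 2
  vint <- list(chrom = "chr1", pos = 1601,
               ref = substr(fx$genome[["chr1"]], 1601, 1601), alt = "A")
  if (vint$ref == "A") vint$alt <- "C"
  bi <- compare_backbones(vint, get_model(fx$models, "FXA.iso3"),
                          get_model(fx$models, "FXA.iso2"), fx$genome)
  expect_equal(bi$case, "coding_vs_intron")
})

test_that("shared-CDS transcripts differing only in UTR exons stay concordant", {
  set.seed(41)
  genome <- random_genome(1000, "chrT")
  canonical <- toy_model(id = "c1", es = c(100, 300, 500),
                         ee = c(200, 400, 600), cs = 150, ce = 548)
  # major adds a 5'UTR exon upstream: CDS identical, exon ordinals shift by 1
  major <- toy_model(id = "m1", es = c(20, 100, 300, 500),
                     ee = c(60, 200, 400, 600), cs = 150, ce = 548)
  coding <- unlist(mapply(function(s, e) s:(e - 1),
                          canonical$exon_starts[[1]],
                          canonical$exon_ends[[1]], SIMPLIFY = FALSE))
  coding <- coding[coding >= 150 & coding < 548]
  for (pos in sample(coding, 30)) {
    ref <- substr(genome[["chrT"]], pos + 1, pos + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    cmp <- compare_backbones(list(chrom = "chrT", pos = pos + 1, ref = ref,
                                  alt = alt), major, canonical, genome)
    expect_equal(cmp$case, "concordant_coding")
    expect_true(cmp$exon_number_changed)
  }
})

test_that("summarize_discordance counts obey the partition identities", {
  fx <- default_fixture()
  vr <- fx$vcf$records
  ucsc <- fx$canonical$ucsc_canonical
  names(ucsc) <- fx$canonical$gene_symbol
  rows <- list()
  for (i in seq_len(nrow(vr))) {
    pos0 <- vr$pos[i] - 1L
    hits <- fx$models[fx$models$chrom == vr$chrom[i] &
                        fx$models$tx_start <= pos0 &
                        pos0 < fx$models$tx_end, ]
    genes <- unique(hits$gene_symbol)
    for (g in genes) {
      can_id <- ucsc[g]
      if (is.na(can_id)) next
      major_id <- call_major(fx$summaries, g, "LUAD", "tumor")$isoform_id
      rows[[length(rows) + 1L]] <- compare_backbones(
        list(chrom = vr$chrom[i], pos = vr$pos[i], ref = vr$ref[i],
             alt = vr$alt[i]),
        get_model(fx$models, major_id), get_model(fx$models, can_id),
        fx$genome)
    }
  }
  comparisons <- do.call(rbind, rows)
  s <- summarize_discordance(comparisons, "ucsc")
  with(s$counts, {
    expect_equal(n_still_coding_in_major + n_intron + n_5U + n_3U + n_OTR,
                 n_coding_in_canonical)
    expect_equal(n_same_exon_number + n_exon_number_changed,
                 n_still_coding_in_major)
    expect_lte(n_coding_in_canonical, n_noncanonical_major)
  })
  # brute-force recount of one bucket
  mism <- comparisons[comparisons$major_id != comparisons$canonical_id, ]
  expect_equal(s$counts$n_3U, sum(mism$case == "coding_vs_3U"))
  # empty input: all-zero summary, percentages omitted
  z <- summarize_discordance(comparisons[0, ], "ucsc")
  expect_equal(z$counts$n_total, 0L)
  expect_true(is.na(z$pct$coding_in_canonical))
})
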