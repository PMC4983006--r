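# Shared fixtures and independent brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

# Full default synthetic fixture, built once per test run.
default_fixture <- function(seed = 42L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    d <- fixture_design(seed = seed)
    genome <- make_genome(d)
    ann <- make_gene_models(d, genome)
    ex <- make_expression(d)
    .fixture_cache[[key]] <- list(
      design = d, genome = genome, models = ann$models,
      canonical = ann$canonical, xrefs = ann$xrefs,
      gene_info = ann$gene_info, expr = ex$expr, sheet = ex$sheet,
      summaries = summarize_expression(ex$expr, ex$sheet),
      vcf = make_vcf(d, ann$models, genome))
  }
  .fixture_cache[[key]]
}

# One-row transcript model constructed directly (bypasses file parsing).
toy_model <- function(id = "tx1", sym = "G1", chrom = "chrT", strand = "+",
                      es, ee, cs = min(es), ce = min(es)) {
  m <- data.frame(transcript_id = id, gene_symbol = sym, chrom = chrom,
                  strand = strand, tx_start = min(es), tx_end = max(ee),
                  cds_start = cs, cds_end = ce, stringsAsFactors = FALSE)
  m$exon_starts <- list(es)
  m$exon_ends <- list(ee)
  m$biotype <- if (cs == ce) "non_coding" else "protein_coding"
  class(m) <- c("transcript_models", "data.frame")
  m
}

# Brute-force linear-interpolation quantile: sort, h = (n-1)p, interpolate.
oracle_quantile <- function(values, p) {
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# Per-base element classifier: paints every base of the transcript span in
# transcription order, independent of locate_element's interval arithmetic.
oracle_locate_label <- function(m, pos0) {
  if (pos0 < m$tx_start || pos0 >= m$tx_end) return("OTR")
  es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]; n <- length(es)
  lab <- rep(NA_character_, m$tx_end - m$tx_start)
  at <- function(g) g - m$tx_start + 1
  ord_exons <- if (m$strand == "+") seq_len(n) else rev(seq_len(n))
  for (k in seq_len(n)) {
    gi <- ord_exons[k]
    lab[at(es[gi]:(ee[gi] - 1))] <- paste0("E", k)
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      gap <- ee[i]:(es[i + 1] - 1)
      prev_genomic <- if (m$strand == "+") i else i + 1
      lab[at(gap)] <- paste0("I", match(prev_genomic, ord_exons))
    }
  }
  if (m$cds_start < m$cds_end) {
    exonic <- unlist(mapply(function(s, e) s:(e - 1), es, ee,
                            SIMPLIFY = FALSE))
    tx_order <- if (m$strand == "+") exonic else rev(exonic)
    in_cds <- tx_order >= m$cds_start & tx_order < m$cds_end
    hit <- which(in_cds)
    if (length(hit)) {
      if (hit[1] > 1) lab[at(tx_order[1:(hit[1] - 1)])] <- "5U"
      last <- hit[length(hit)]
      if (last < length(tx_order)) {
        lab[at(tx_order[(last + 1):length(tx_order)])] <- "3U"
      }
    }
  }
  lab[at(pos0)]
}

# Per-base spliced-CDS builder with an explicit complement table.
oracle_spliced_cds <- function(m, genome) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seq <- genome[[m$chrom]]
  es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
  bases <- character(0)
  for (i in seq_along(es)) {
    s <- max(es[i], m$cds_start); e <- min(ee[i], m$cds_end)
    if (e > s) {
      bases <- c(bases, vapply((s + 1):e, function(p) substr(seq, p, p), ""))
    }
  }
  if (m$strand == "-") bases <- rev(unname(comp[bases]))
  paste(bases, collapse = "")
}

# Random but always-valid transcript structure for property tests.
random_model <- function(i, chrom_len = 600L) {
  n_exon <- sample(1:5, 1)
  gaps <- sample(5:30, n_exon)      # leading gap + introns
  widths <- sample(10:60, n_exon, replace = TRUE)
  es <- cumsum(gaps + c(0, widths[-n_exon]))
  ee <- es + widths
  strand <- sample(c("+", "-"), 1)
  exonic <- unlist(mapply(function(s, e) s:(e - 1), es, ee, SIMPLIFY = FALSE))
  if (runif(1) < 0.15) {            # non-coding
    cs <- ce <- es[1]
  } else {
    b <- sort(sample(exonic, 2))
    cs <- b[1]; ce <- b[2] + 1
  }
  toy_model(id = sprintf("rnd%03d", i), sym = sprintf("R%03d", i),
            chrom = "chrR", strand = strand, es = es, ee = ee,
            cs = cs, ce = ce)
}

random_genome <- function(len = 800L, chrom = "chrR") {
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), chrom)
}

# Mirror a plus-strand world onto the minus strand: reverse-complemented
# genome, coordinates flipped.  Used for strand-symmetry checks.
mirror_world <- function(model, genome) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seq <- genome[[model$chrom]]
  L <- nchar(seq)
  rc <- paste(rev(unname(comp[strsplit(seq, "")[[1]]])), collapse = "")
  flip <- function(x) L - x  # half-open flip: [s,e) -> [L-e, L-s)
  es <- rev(flip(model$exon_ends[[1]]))
  ee <- rev(flip(model$exon_starts[[1]]))
  m2 <- toy_model(id = paste0(model$transcript_id, "_rc"),
                  sym = model$gene_symbol, chrom = "chrM",
                  strand = if (model$strand == "+") "-" else "+",
                  es = es, ee = ee,
                  cs = flip(model$cds_end), ce = flip(model$cds_start))
  list(model = m2, genome = stats::setNames(rc, "chrM"),
       flip_pos = function(p) L - 1 - p, comp = comp)
}
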