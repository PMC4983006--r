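#' Inference thresholds for tumor-specific isoform calling
#'
#' Defaults follow the published procedure: an isoform counts as expressed
#' when its group median TPM exceeds 1e-6; a Type I candidate is "strong"
#' when its tumor median TPM is at least 1.0 TPM *and* at least 10 percent
#' of the gene's expression; a Type II (major-isoform switch) call requires
#' a median-TPM fold change strictly greater than 2; the normal group must
#' contain at least 10 patients for a cohort to be eligible.
#'
#' @param expressed_min_tpm Expression floor in TPM (default 1e-6).
#' @param strong_min_tpm Strong Type I TPM gate (default 1.0).
#' @param strong_min_pct Strong Type I expression-percentage gate (default 10).
#' @param type2_min_fold Type II fold-change gate, strict (default 2).
#' @param min_normal_samples Minimum matched-normal patients (default 10).
#' @return List of class `thresholds`.
#' @export
thresholds <- function(expressed_min_tpm = 1e-6, strong_min_tpm = 1.0,
                       strong_min_pct = 10, type2_min_fold = 2,
                       min_normal_samples = 10) {
  th <- list(expressed_min_tpm = expressed_min_tpm,
             strong_min_tpm = strong_min_tpm,
             strong_min_pct = strong_min_pct,
             type2_min_fold = type2_min_fold,
             min_normal_samples = min_normal_samples)
  if (any(vapply(th, function(x) !is.numeric(x) || length(x) != 1L || x <= 0,
                 TRUE))) {
    stop("all thresholds must be strictly positive scalars", call. = FALSE)
  }
  structure(th, class = "thresholds")
}

#' Median-TPM fold change, tumor over normal
#'
#' Tumor expression with no normal expression gives `Inf`; a silent isoform
#' in both groups gives `NaN` (undefined).
#'
#' @param tumor_mtpm,normal_mtpm Non-negative median TPM values.
#' @return Ratio, possibly `Inf` or `NaN`.
#' @export
fold_change <- function(tumor_mtpm, normal_mtpm) {
  if (tumor_mtpm < 0 || normal_mtpm < 0) {
    stop("fold_change: median TPM values must be non-negative", call. = FALSE)
  }
  if (normal_mtpm == 0) {
    if (tumor_mtpm > 0) Inf else NaN
  } else {
    tumor_mtpm / normal_mtpm
  }
}

#' Type I classification (tumor-only expression)
#'
#' Type I: expressed in tumor (median TPM above the 1e-6 floor) and absent
#' in the matched normal.  Strong when the tumor median TPM and tumor
#' expression percentage are at least 1.0 and 10 (both inclusive),
#' otherwise weak.
#'
#' @param tumor_mtpm,normal_mtpm Median TPM in each group.
#' @param tumor_pct Isoform's percentage of the gene's tumor expression.
#' @param th A [thresholds()] object.
#' @return List `is_type1` (logical), `subclass`
#'   (`"strong"`, `"weak"`, or `"not_applicable"`).
#' @export
classify_type1 <- function(tumor_mtpm, normal_mtpm, tumor_pct,
                           th = thresholds()) {
  is_t1 <- tumor_mtpm > th$expressed_min_tpm &&
    normal_mtpm <= th$expressed_min_tpm
  subclass <- if (!is_t1) {
    "not_applicable"
  } else if (tumor_mtpm >= th$strong_min_tpm && tumor_pct >= th$strong_min_pct) {
    "strong"
  } else {
    "weak"
  }
  list(is_type1 = is_t1, subclass = subclass)
}

#' Type II classification (major-isoform switch)
#'
#' True when the isoform is the tumor-group major but not the normal-group
#' major and its fold change strictly exceeds the gate (an infinite fold
#' change passes).
#'
#' @param isoform_id Candidate transcript id.
#' @param tumor_major,normal_major [call_major()] results for the same gene
#'   and cohort.
#' @param fc Fold change from [fold_change()].
#' @param th A [thresholds()] object.
#' @return Logical.
#' @export
classify_type2 <- function(isoform_id, tumor_major, normal_major, fc,
                           th = thresholds()) {
  if (tumor_major$gene_symbol != normal_major$gene_symbol ||
      tumor_major$cohort != normal_major$cohort) {
    stop("classify_type2: major calls refer to different genes/cohorts",
         call. = FALSE)
  }
  isoform_id == tumor_major$isoform_id &&
    isoform_id != normal_major$isoform_id &&
    !is.nan(fc) && fc > th$type2_min_fold
}

#' Screen one gene for tumor-specific isoforms
#'
#' Produces one row per isoform with tumor/normal median TPM, expression
#' percentages, fold change, and the Type I / Type II decision.  An isoform
#' satisfying both definitions is reported as Type I (Type II's fold change
#' is infinite or undefined when normal expression is absent).
#'
#' @param summaries A `group_summaries` data frame covering tumor and
#'   normal groups of `cohort`.
#' @param gene Gene identifier.
#' @param cohort Cohort (cancer type) to screen.
#' @param th A [thresholds()] object.
#' @return Data frame of class `tumor_specific_calls`.
#' @export
screen_gene <- function(summaries, gene, cohort, th = thresholds()) {
  norm <- summaries_for(summaries, gene, cohort, "normal")
  tum <- summaries_for(summaries, gene, cohort, "tumor")
  n_normal <- max(norm$n_patients)
  if (n_normal < th$min_normal_samples) {
    stop(sprintf(
      "cohort %s is not eligible: %d matched normal patients (minimum %d)",
      cohort, n_normal, th$min_normal_samples), call. = FALSE)
  }
  isoforms <- sort(unique(c(tum$isoform_id, norm$isoform_id)))
  if (!setequal(tum$isoform_id, norm$isoform_id)) {
    stop("tumor and normal groups summarize different isoform sets for gene ",
         gene, call. = FALSE)
  }
  t_pct <- expression_percentage(summaries, gene, cohort, "tumor")
  n_pct <- expression_percentage(summaries, gene, cohort, "normal")
  t_major <- call_major(summaries, gene, cohort, "tumor")
  n_major <- call_major(summaries, gene, cohort, "normal")
  rows <- lapply(isoforms, function(iso) {
    tm <- tum$median_tpm[match(iso, tum$isoform_id)]
    nm <- norm$median_tpm[match(iso, norm$isoform_id)]
    fc <- fold_change(tm, nm)
    t1 <- classify_type1(tm, nm, unname(t_pct[iso]), th)
    t2 <- classify_type2(iso, t_major, n_major, fc, th)
    call <- if (t1$is_type1) "type1" else if (t2) "type2" else "none"
    data.frame(
      isoform_id = iso, gene_symbol = gene, cohort = cohort,
      call = call,
      subclass = if (call == "type1") t1$subclass else "not_applicable",
      tumor_mtpm = tm, normal_mtpm = nm, fold_change = fc,
      tumor_pct = unname(t_pct[iso]), normal_pct = unname(n_pct[iso]),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("tumor_specific_calls", class(res))
  res
}

#' Consistency census between major and canonical/principal isoforms
#'
#' Partitions all genes of one group into: silent (no isoform with median
#' TPM above zero), expressed with no canonical/principal isoform defined
#' (`nokcanon`), expressed with the major isoform matching at least one of
#' the UniProt canonical, UCSC canonical, or APPRIS principal isoforms
#' (`matched`), or expressed with a defined canonical that the major
#' isoform misses (`notmatched_kcanon`).  Parallel `*_ge1` counts restrict
#' the three expressed buckets to genes whose major isoform has median TPM
#' of at least 1.
#'
#' @param summaries A `group_summaries` data frame.
#' @param genes Character vector of all gene identifiers to census (every
#'   one must be summarized in the group).
#' @param canon Canonical-assignment table (see [read_canonical()]).
#' @param cohort,sample_class Group selector.
#' @return One-row data frame of class `consistency_counts`.
#' @export
consistency_check <- function(summaries, genes, canon, cohort, sample_class) {
  grp <- summaries[summaries$cohort == cohort &
                     summaries$sample_class == sample_class, , drop = FALSE]
  missing <- setdiff(genes, grp$gene_id)
  if (length(missing)) {
    stop("genes lacking summaries in group: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  buckets <- c(mtpm_zero = 0L, matched = 0L, notmatched_kcanon = 0L,
               nokcanon = 0L)
  ge1 <- c(matched = 0L, notmatched_kcanon = 0L, nokcanon = 0L)
  for (g in genes) {
    sub <- grp[grp$gene_id == g, , drop = FALSE]
    if (max(sub$median_tpm) <= 0) {
      buckets["mtpm_zero"] <- buckets["mtpm_zero"] + 1L
      next
    }
    ci <- match(g, canon$gene_symbol)
    canon_set <- if (is.na(ci)) character(0) else {
      v <- c(canon$uniprot_canonical[ci], canon$ucsc_canonical[ci],
             canon$appris_principal[ci])
      v[!is.na(v)]
    }
    major <- call_major(summaries, g, cohort, sample_class)
    major_mtpm <- sub$median_tpm[match(major$isoform_id, sub$isoform_id)]
    bucket <- if (length(canon_set) == 0L) {
      "nokcanon"
    } else if (major$isoform_id %in% canon_set) {
      "matched"
    } else {
      "notmatched_kcanon"
    }
    buckets[bucket] <- buckets[bucket] + 1L
    if (major_mtpm >= 1) ge1[bucket] <- ge1[bucket] + 1L
  }
  res <- data.frame(
    cohort = cohort, sample_class = sample_class,
    n_total_genes = length(genes),
    n_mtpm_zero = unname(buckets["mtpm_zero"]),
    n_matched = unname(buckets["matched"]),
    n_notmatched_kcanon = unname(buckets["notmatched_kcanon"]),
    n_nokcanon = unname(buckets["nokcanon"]),
    n_matched_ge1 = unname(ge1["matched"]),
    n_notmatched_kcanon_ge1 = unname(ge1["notmatched_kcanon"]),
    n_nokcanon_ge1 = unname(ge1["nokcanon"]),
    stringsAsFactors = FALSE)
  class(res) <- c("consistency_counts", class(res))
  res
}

#' Percent increase between two gene counts
#'
#' `100 * (tumor_count - normal_count) / normal_count`, rounded
#' half-away-from-zero to one decimal — the display convention of the
#' consistency census.
#'
#' @param normal_count Baseline count (> 0).
#' @param tumor_count Comparison count.
#' @return Percentage at one decimal.
#' @export
percent_increase <- function(normal_count, tumor_count) {
  if (normal_count <= 0) {
    stop("percent_increase: normal_count must be positive", call. = FALSE)
  }
  round_half_away(100 * (tumor_count - normal_count) / normal_count, 1)
}
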