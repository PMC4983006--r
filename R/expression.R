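#' Read an RSEM-style isoform expression table
#'
#' Header-bearing TSV whose first two columns are `isoform_id` and
#' `gene_id`, followed by one column per sample.  Values are RSEM
#' fraction-of-transcripts estimates, unitless in \[0, 1\].
#'
#' @param path TSV path.
#' @return Data frame of class `expression_table`.
#' @export
read_expression <- function(path) {
  x <- read_tsv_strict(path)
  if (!all(c("isoform_id", "gene_id") %in% names(x)[1:2])) {
    stop("expression table must start with columns isoform_id, gene_id",
         call. = FALSE)
  }
  samp <- setdiff(names(x), c("isoform_id", "gene_id"))
  vals <- as.matrix(x[, samp, drop = FALSE])
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("expression values must be fractions in [0, 1]", call. = FALSE)
  }
  class(x) <- c("expression_table", class(x))
  x
}

#' Read the sample sheet
#'
#' Header-bearing TSV: sample_id, patient_id, cohort, sample_class
#' (`tumor` or `normal`).  Metastatic or otherwise excluded samples are an
#' upstream filter and simply never appear in the sheet.
#'
#' @param path TSV path.
#' @export
read_sample_sheet <- function(path) {
  x <- read_tsv_strict(path)
  need <- c("sample_id", "patient_id", "cohort", "sample_class")
  if (!all(need %in% names(x))) {
    stop("sample sheet missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(x$sample_class), c("tumor", "normal"))
  if (length(bad)) {
    stop("unknown sample_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Average replicate samples per patient
#'
#' When a patient contributed two or more samples to the same
#' (cohort, sample class) group, their expression estimates are replaced by
#' the per-isoform arithmetic mean, so that each patient counts once in all
#' downstream statistics.
#'
#' @param expr An `expression_table`.
#' @param sheet A sample sheet covering every expression column.
#' @return List with `expr` (one column per patient-group, named
#'   `patient|cohort|class`) and `sheet` (one row per collapsed column).
#' @export
collapse_replicates <- function(expr, sheet) {
  samp <- setdiff(names(expr), c("isoform_id", "gene_id"))
  unmapped <- setdiff(samp, sheet$sample_id)
  if (length(unmapped)) {
    stop("expression columns missing from sample sheet: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  i <- match(samp, sheet$sample_id)
  key <- paste(sheet$patient_id[i], sheet$cohort[i], sheet$sample_class[i],
               sep = "|")
  groups <- split(samp, key)
  keys <- names(groups)
  vals <- as.matrix(expr[, samp, drop = FALSE])
  out <- do.call(cbind, lapply(groups, function(cols) {
    rowMeans(vals[, cols, drop = FALSE])
  }))
  colnames(out) <- keys
  collapsed <- cbind(expr[, c("isoform_id", "gene_id")],
                     as.data.frame(out, check.names = FALSE))
  parts <- strsplit(keys, "|", fixed = TRUE)
  sheet2 <- data.frame(
    sample_id = keys,
    patient_id = vapply(parts, `[[`, "", 1L),
    cohort = vapply(parts, `[[`, "", 2L),
    sample_class = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  class(collapsed) <- c("expression_table", "data.frame")
  list(expr = collapsed, sheet = sheet2)
}

#' Boxplot statistics for one group of expression fractions
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).  Outliers are points strictly outside the
#' Tukey fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR); the whiskers are the extreme
#' non-outlier points, so raw min/max are recoverable from the outlier
#' lists.  `median_tpm` is the group median scaled by 1e6.
#'
#' @param values Non-empty numeric vector of fractions.
#' @return List with `n`, `lower_outliers`, `whisker_min`, `q1`, `median`,
#'   `q3`, `whisker_max`, `upper_outliers`, `median_tpm`.
#' @export
group_summary <- function(values) {
  if (length(values) == 0L) stop("group_summary: empty value list", call. = FALSE)
  qs <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  lower <- sort(values[values < lo_fence])
  upper <- sort(values[values > hi_fence])
  inliers <- values[values >= lo_fence & values <= hi_fence]
  list(
    n = length(values),
    lower_outliers = lower,
    whisker_min = min(inliers),
    q1 = qs[1],
    median = qs[2],
    q3 = qs[3],
    whisker_max = max(inliers),
    upper_outliers = upper,
    median_tpm = qs[2] * 1e6
  )
}

#' Median TPM of a group
#'
#' The group median of the fraction-of-transcripts estimates multiplied by
#' one million.
#'
#' @param values Non-empty numeric vector of fractions.
#' @return Median TPM.
#' @export
median_tpm <- function(values) {
  if (length(values) == 0L) stop("median_tpm: empty value list", call. = FALSE)
  stats::median(values) * 1e6
}

#' Summarize every isoform in every (cohort, sample class) group
#'
#' Collapses replicates, then computes [group_summary()] per isoform per
#' group.
#'
#' @param expr An `expression_table` (raw, sample-level).
#' @param sheet Matching sample sheet.
#' @return Data frame of class `group_summaries`: one row per isoform x
#'   group with boxplot statistics, `median_tpm`, `n_patients`, and list
#'   columns of outliers.
#' @export
summarize_expression <- function(expr, sheet) {
  coll <- collapse_replicates(expr, sheet)
  cexpr <- coll$expr; csheet <- coll$sheet
  gkey <- paste(csheet$cohort, csheet$sample_class, sep = "|")
  out <- list()
  for (g in unique(gkey)) {
    cols <- csheet$sample_id[gkey == g]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    vals <- as.matrix(cexpr[, cols, drop = FALSE])
    for (r in seq_len(nrow(cexpr))) {
      s <- group_summary(vals[r, ])
      out[[length(out) + 1L]] <- data.frame(
        isoform_id = cexpr$isoform_id[r], gene_id = cexpr$gene_id[r],
        cohort = parts[1], sample_class = parts[2],
        n_patients = s$n, whisker_min = s$whisker_min, q1 = s$q1,
        median = s$median, q3 = s$q3, whisker_max = s$whisker_max,
        median_tpm = s$median_tpm,
        lower_outliers = I(list(s$lower_outliers)),
        upper_outliers = I(list(s$upper_outliers)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("group_summaries", class(res))
  res
}

summaries_for <- function(summaries, gene, cohort, sample_class) {
  sub <- summaries[summaries$gene_id == gene &
                     summaries$cohort == cohort &
                     summaries$sample_class == sample_class, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no summaries for gene %s in group (%s, %s)",
                 gene, cohort, sample_class), call. = FALSE)
  }
  sub
}

#' Per-isoform share of a gene's expression
#'
#' Each isoform's percentage of the gene's total median TPM within one
#' group.  When the gene is entirely silent (total median TPM of zero) all
#' percentages are 0.
#'
#' @param summaries A `group_summaries` data frame.
#' @param gene Gene identifier (as in the expression table's `gene_id`).
#' @param cohort,sample_class Group selector.
#' @return Named numeric vector of percentages (names are isoform ids).
#' @export
expression_percentage <- function(summaries, gene, cohort, sample_class) {
  sub <- summaries_for(summaries, gene, cohort, sample_class)
  tot <- sum(sub$median_tpm)
  pct <- if (tot > 0) 100 * sub$median_tpm / tot else rep(0, nrow(sub))
  stats::setNames(pct, sub$isoform_id)
}

#' Call the major isoform of a gene in a group
#'
#' The major isoform is the one with the highest median TPM.  If every
#' isoform's median TPM is zero, Q3 values are compared instead (basis
#' `q3_tiebreak`); any remaining exact tie is broken by the
#' lexicographically smallest transcript id (basis `lexicographic`).
#'
#' @inheritParams expression_percentage
#' @return List of class `major_isoform_call`: `gene_symbol`, `cohort`,
#'   `sample_class`, `isoform_id`, `basis`, `expression_percentage`.
#' @export
call_major <- function(summaries, gene, cohort, sample_class) {
  sub <- summaries_for(summaries, gene, cohort, sample_class)
  m <- sub$median_tpm
  if (any(m > 0)) {
    cand <- which(m == max(m))
    basis <- "median"
  } else {
    q <- sub$q3
    cand <- which(q == max(q))
    basis <- "q3_tiebreak"
  }
  if (length(cand) > 1L) {
    cand <- cand[order(sub$isoform_id[cand])][1]
    basis <- "lexicographic"
  }
  pct <- expression_percentage(summaries, gene, cohort, sample_class)
  structure(list(
    gene_symbol = gene, cohort = cohort, sample_class = sample_class,
    isoform_id = sub$isoform_id[cand], basis = basis,
    expression_percentage = unname(pct[sub$isoform_id[cand]])
  ), class = "major_isoform_call")
}

#' Write group summaries as tidy TSV
#'
#' One row per isoform x group; outlier lists are comma-joined.  This is
#' the downloadable expression-view surrogate.
#'
#' @param summaries A `group_summaries` data frame.
#' @param path Output path.
#' @export
write_group_summaries <- function(summaries, path) {
  write_tsv(as.data.frame(summaries), path)
}
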