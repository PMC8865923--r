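#' Post-ASV-table filtering and normalization
#'
#' Tools reproducing the final processing chain applied to a raw ASV count
#' table before community statistics: removal of negative-control
#' contaminants, of rare ASVs, and of non-target lineages, followed by a
#' fourth-root transformation and conversion to relative abundances.
#'
#' @name preprocessing
NULL

new_filter_report <- function(stage, removed_asv_ids, reads_removed) {
  structure(list(stages = list(list(stage = stage,
                                    removed_asv_ids = removed_asv_ids,
                                    reads_removed = reads_removed)),
                 per_sample_fraction_removed = NULL,
                 mean_fraction_removed = NULL),
            class = "filter_report")
}

combine_reports <- function(...) {
  reps <- list(...)
  structure(list(stages = do.call(c, lapply(reps, `[[`, "stages")),
                 per_sample_fraction_removed = NULL,
                 mean_fraction_removed = NULL),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (s in x$stages) {
    cat(sprintf("  %-18s removed %4d ASVs, %12.0f reads\n",
                s$stage, length(s$removed_asv_ids), s$reads_removed))
  }
  if (!is.null(x$mean_fraction_removed)) {
    cat(sprintf("  mean per-sample read fraction removed: %.3f\n",
                x$mean_fraction_removed))
  }
  invisible(x)
}

#' Turn a filter report into a per-stage data frame
#' @param x a `filter_report`.
#' @param ... unused.
#' @return data frame with one row per stage.
#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(stage = vapply(x$stages, `[[`, "", "stage"),
             n_asvs_removed = vapply(x$stages, function(s) length(s$removed_asv_ids), 0L),
             reads_removed = vapply(x$stages, `[[`, 0, "reads_removed"),
             stringsAsFactors = FALSE)
}

#' Remove ASVs prevalent in extraction negatives
#'
#' An ASV detected (count > 0) in at least `min_negatives` negative-control
#' samples is treated as a reagent/lab contaminant and its column is deleted
#' from the whole table; the negative-control samples themselves are dropped
#' from the output. With no negatives present the table passes through
#' unchanged (with a warning).
#'
#' @param table raw-count [asv_table()] (samples including negatives).
#' @param meta validated metadata with `is_negative_control`.
#' @param min_negatives detection threshold among negatives (default 10).
#' @return list(table, report).
#' @export
filter_negative_contaminants <- function(table, meta, min_negatives = 10) {
  assert_count(min_negatives, "min_negatives")
  stopifnot(table$value_kind == "raw_counts")
  neg_ids <- intersect(meta$sample_id[meta$is_negative_control], sample_ids(table))
  keep_samples <- setdiff(sample_ids(table), neg_ids)
  if (length(neg_ids) == 0L) {
    warning("no negative controls present; contaminant filter is a no-op",
            call. = FALSE)
    return(list(table = table,
                report = new_filter_report("negative_control", character(0), 0)))
  }
  det_in_neg <- colSums(table$values[neg_ids, , drop = FALSE] > 0)
  contaminants <- asv_ids(table)[det_in_neg >= min_negatives]
  out <- subset_asv_table(table, samples = keep_samples,
                          asvs = setdiff(asv_ids(table), contaminants))
  reads_removed <- sum(table$values[keep_samples, contaminants, drop = FALSE])
  list(table = out,
       report = new_filter_report("negative_control", contaminants, reads_removed))
}

#' Remove rare ASVs
#'
#' Drops ASVs detected in fewer than `min_samples` samples, a guard against
#' residual sequencing contaminants and index bleed-through.
#'
#' @param table raw-count [asv_table()].
#' @param min_samples minimum number of samples an ASV must be detected in
#'   to be retained (default 5; an ASV in exactly 5 samples is kept).
#' @return list(table, report).
#' @export
filter_rare_asvs <- function(table, min_samples = 5) {
  assert_count(min_samples, "min_samples")
  stopifnot(table$value_kind == "raw_counts")
  prev <- colSums(table$values > 0)
  removed <- asv_ids(table)[prev < min_samples]
  out <- subset_asv_table(table, asvs = setdiff(asv_ids(table), removed))
  list(table = out,
       report = new_filter_report("prevalence",
                                  removed,
                                  sum(table$values[, removed, drop = FALSE])))
}

#' Remove non-target lineages
#'
#' Keeps ASVs whose domain is Bacteria or Archaea and whose lineage contains
#' neither "Mitochondria" nor "Chloroplast" at any rank (case-insensitive).
#'
#' @param table raw-count [asv_table()].
#' @param tax taxonomy data frame ([read_taxonomy()] layout); every ASV in
#'   the table must have an entry.
#' @return list(table, report).
#' @export
filter_taxonomy <- function(table, tax) {
  stopifnot(table$value_kind == "raw_counts")
  idx <- match(asv_ids(table), tax$asv_id)
  if (anyNA(idx)) {
    stop("taxonomy missing for ASV(s): ",
         paste(utils::head(asv_ids(table)[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  tx <- tax[idx, , drop = FALSE]
  dom_ok <- tolower(tx$domain) %in% c("bacteria", "archaea")
  dom_ok[is.na(tx$domain)] <- FALSE
  lineage <- apply(tx[, .tax_ranks, drop = FALSE], 1, function(r) {
    paste(r[!is.na(r)], collapse = ";")
  })
  organelle <- grepl("mitochondria|chloroplast", lineage, ignore.case = TRUE)
  keep <- dom_ok & !organelle
  removed <- asv_ids(table)[!keep]
  out <- subset_asv_table(table, asvs = asv_ids(table)[keep])
  list(table = out,
       report = new_filter_report("taxonomy",
                                  removed,
                                  sum(table$values[, removed, drop = FALSE])))
}

#' Fourth-root transformation and relative-abundance normalization
#'
#' Replaces each count x by x^(1/4) (damping PCR amplification bias), then
#' rescales every sample row to sum to 1. All-zero samples stay all-zero and
#' are flagged in the `empty_samples` attribute.
#'
#' @param table raw-count [asv_table()].
#' @return an [asv_table()] with `value_kind = "transformed_relabund"`.
#' @export
fourth_root_relabund <- function(table) {
  stopifnot(table$value_kind == "raw_counts")
  v <- table$values^0.25
  rs <- rowSums(v)
  empty <- rs == 0
  v[!empty, ] <- v[!empty, , drop = FALSE] / rs[!empty]
  out <- asv_table(v, "transformed_relabund")
  attr(out, "empty_samples") <- sample_ids(table)[empty]
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: negative-control contaminant filter, prevalence filter,
#' taxonomy filter, then (optionally) fourth-root normalization. The filter
#' order follows the narrative of the protocol it reproduces; it is recorded
#' in the report so alternative orders remain auditable (the final ASV set is
#' order-invariant, only stage attribution changes).
#'
#' @param table raw-count [asv_table()] including negative controls.
#' @param meta validated metadata.
#' @param tax taxonomy data frame.
#' @param min_negatives passed to [filter_negative_contaminants()].
#' @param min_samples passed to [filter_rare_asvs()].
#' @param normalize apply [fourth_root_relabund()] at the end (default TRUE).
#' @return list with `counts` (filtered raw counts, negatives removed),
#'   `table` (normalized abundances, or the counts when `normalize = FALSE`)
#'   and `report` (a `filter_report` with per-stage losses and the mean
#'   per-sample read fraction removed, computed over non-control samples).
#' @export
run_preprocessing <- function(table, meta, tax, min_negatives = 10,
                              min_samples = 5, normalize = TRUE) {
  stopifnot(table$value_kind == "raw_counts")
  real_ids <- intersect(sample_ids(table),
                        meta$sample_id[!meta$is_negative_control])
  before <- rowSums(table$values[real_ids, , drop = FALSE])

  s1 <- filter_negative_contaminants(table, meta, min_negatives = min_negatives)
  s2 <- filter_rare_asvs(s1$table, min_samples = min_samples)
  s3 <- filter_taxonomy(s2$table, tax)

  report <- combine_reports(s1$report, s2$report, s3$report)
  after <- rowSums(s3$table$values[real_ids, , drop = FALSE])
  frac <- ifelse(before > 0, (before - after) / before, 0)
  names(frac) <- real_ids
  report$per_sample_fraction_removed <- frac
  report$mean_fraction_removed <- mean(frac)

  list(counts = s3$table,
       table = if (normalize) fourth_root_relabund(s3$table) else s3$table,
       report = report)
}
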