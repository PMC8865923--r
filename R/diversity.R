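#' Alpha diversity: ASV richness
#'
#' Number of ASVs detected (count > 0) in each sample. Richness is invariant
#' under monotone transforms that preserve zeros, so it may be computed on
#' either the raw or the fourth-root table; by convention it is taken on the
#' pre-normalization counts.
#'
#' @param x an [asv_table()] or a single abundance vector.
#' @return named integer vector (per sample), or a single integer.
#' @export
asv_richness <- function(x) {
  if (inherits(x, "asv_table")) {
    rowSums(x$values > 0)
  } else {
    sum(x > 0)
  }
}

#' Alpha diversity: Shannon index
#'
#' H = -sum p_i log p_i over the non-zero entries, natural log, after
#' rescaling the vector to sum to 1. An all-zero vector has no defined
#' composition and returns NA with a warning.
#'
#' @param x an [asv_table()] (per-row H) or a single abundance vector.
#' @return named numeric vector, or a single number.
#' @export
shannon <- function(x) {
  one <- function(v) {
    if (any(v < 0)) stop("negative abundance", call. = FALSE)
    s <- sum(v)
    if (s == 0) {
      warning("Shannon undefined for an all-zero sample", call. = FALSE)
      return(NA_real_)
    }
    p <- v[v > 0] / s
    -sum(p * log(p))
  }
  if (inherits(x, "asv_table")) {
    apply(x$values, 1, one)
  } else {
    one(x)
  }
}

#' Per-sample alpha-diversity table
#'
#' Richness on the raw counts; Shannon on the fourth-root-transformed
#' relative abundances by default (`shannon_on = "transformed"`), matching
#' the normalization applied for all downstream statistics, or on the raw
#' relative abundances with `shannon_on = "raw"`.
#'
#' @param counts raw-count [asv_table()].
#' @param shannon_on `"transformed"` or `"raw"`.
#' @return data frame (sample_id, richness, shannon).
#' @export
alpha_diversity <- function(counts, shannon_on = c("transformed", "raw")) {
  shannon_on <- match.arg(shannon_on)
  stopifnot(counts$value_kind == "raw_counts")
  tab <- if (shannon_on == "transformed") fourth_root_relabund(counts) else counts
  data.frame(sample_id = sample_ids(counts),
             richness = as.integer(asv_richness(counts)),
             shannon = as.numeric(shannon(tab)),
             stringsAsFactors = FALSE)
}

#' Beta diversity: richness difference between two samples
#'
#' @param a,b abundance vectors over the same ASV universe.
#' @return |richness(a) - richness(b)|, a non-negative integer.
#' @export
beta_asv_difference <- function(a, b) {
  stopifnot(length(a) == length(b))
  abs(asv_richness(a) - asv_richness(b))
}

#' Beta diversity: Jaccard membership similarity
#'
#' Proportion of shared ASVs: |A intersect B| / |A union B| on detection
#' sets. Two empty samples share everything vacuously; the convention here
#' is 1 with a warning.
#'
#' @param a,b abundance vectors over the same ASV universe.
#' @return similarity in \[0, 1\].
#' @export
jaccard_membership <- function(a, b) {
  stopifnot(length(a) == length(b))
  da <- a > 0; db <- b > 0
  uni <- sum(da | db)
  if (uni == 0) {
    warning("both samples empty; Jaccard defined as 1", call. = FALSE)
    return(1)
  }
  sum(da & db) / uni
}

#' Beta diversity: Yue-Clayton similarity
#'
#' theta = sum(p*q) / (sum((p-q)^2) + sum(p*q)), an abundance-weighted
#' similarity in \[0, 1\]: 1 iff the compositions are identical, 0 iff their
#' supports are disjoint.
#'
#' @param p,q relative-abundance vectors summing to 1 (tolerance 1e-9).
#' @return similarity in \[0, 1\], or NA (with a warning) if both empty.
#' @export
yue_clayton <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (sum(p) == 0 && sum(q) == 0) {
    warning("both compositions empty; Yue-Clayton undefined", call. = FALSE)
    return(NA_real_)
  }
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("inputs must be relative abundances summing to 1", call. = FALSE)
  }
  cross <- sum(p * q)
  denom <- sum((p - q)^2) + cross
  cross / denom
}

#' Within-participant temporal beta diversity
#'
#' For every participant, forms all unordered pairs of that participant's
#' samples across time points while holding skin depth and skin status
#' fixed (so each pair differs only in visit), and computes the three
#' pairwise metrics: richness difference and Jaccard on the raw counts,
#' Yue-Clayton on the normalized abundances. `pairing = "consecutive"`
#' restricts to visits (t, t+1).
#'
#' @param counts raw-count [asv_table()] (post-filtering).
#' @param normalized matching transformed-relabund [asv_table()].
#' @param meta validated metadata aligned with the tables.
#' @param pairing `"all"` (every temporal pair) or `"consecutive"`.
#' @return data frame of `BetaPair` rows: participant_id, depth,
#'   skin_status, sample_id_a/b, timepoint_a/b, asv_difference, jaccard,
#'   yue_clayton, pairing_context.
#' @export
within_participant_beta <- function(counts, normalized, meta,
                                    pairing = c("all", "consecutive")) {
  pairing <- match.arg(pairing)
  meta <- meta[!meta$is_negative_control, , drop = FALSE]
  meta <- meta[meta$sample_id %in% sample_ids(counts), , drop = FALSE]
  key <- interaction(meta$participant_id, meta$depth, meta$skin_status,
                     drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    rows <- meta[key == g, , drop = FALSE]
    rows <- rows[order(rows$timepoint), , drop = FALSE]
    n <- nrow(rows)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (pairing == "consecutive" &&
            rows$timepoint[j] != rows$timepoint[i] + 1L) next
        a <- rows$sample_id[i]; b <- rows$sample_id[j]
        ca <- counts$values[a, ]; cb <- counts$values[b, ]
        out[[length(out) + 1L]] <- data.frame(
          participant_id = rows$participant_id[i],
          depth = rows$depth[i],
          skin_status = rows$skin_status[i],
          sample_id_a = a, sample_id_b = b,
          timepoint_a = rows$timepoint[i], timepoint_b = rows$timepoint[j],
          asv_difference = beta_asv_difference(ca, cb),
          jaccard = jaccard_membership(ca, cb),
          yue_clayton = yue_clayton(normalized$values[a, ],
                                    normalized$values[b, ]),
          pairing_context = if (pairing == "all") "within_participant_temporal"
                            else "custom",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    stop("no participant has >= 2 temporal samples within any stratum",
         call. = FALSE)
  }
  do.call(rbind, out)
}

#' Genus-level aggregation
#'
#' Sums relative abundance and counts detected ASVs per sample and genus.
#' ASVs without a genus assignment are pooled under "unassigned".
#'
#' @param table an [asv_table()] (normalized for abundance shares).
#' @param tax taxonomy data frame covering every ASV in the table.
#' @return data frame (sample_id, genus, abundance, richness).
#' @export
aggregate_by_genus <- function(table, tax) {
  idx <- match(asv_ids(table), tax$asv_id)
  if (anyNA(idx)) stop("taxonomy missing for some ASVs", call. = FALSE)
  genus <- tax$genus[idx]
  genus[is.na(genus) | !nzchar(genus)] <- "unassigned"
  genus <- factor(genus)
  ab <- t(rowsum(t(table$values), genus))            # samples x genera
  rich <- t(rowsum(t(table$values > 0) * 1L, genus))
  data.frame(sample_id = rep(sample_ids(table), times = nlevels(genus)),
             genus = rep(levels(genus), each = nrow(ab)),
             abundance = as.vector(ab),
             richness = as.integer(rich),
             stringsAsFactors = FALSE)
}
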