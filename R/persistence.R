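#' Within-participant persistence profiles
#'
#' Persistence of an ASV over a set of samples is the exact fraction of
#' those samples in which it is detected (raw count > 0). Profiles are
#' computed per participant, within every combination of the design axes
#' that are *not* pooled: pooling `c("time", "depth")` (the default for
#' core-community work) yields one stratum per participant; pooling only
#' `"time"` yields one stratum per depth.
#'
#' @param counts raw-count [asv_table()] (post-filtering, negatives removed).
#' @param meta aligned metadata.
#' @param pool design axes to pool over, subset of `c("time", "depth",
#'   "status")`.
#' @param exclude_lesional drop lesional (LS) samples first (default TRUE).
#' @return a `persistence_profile`: list with `persistence` (matrix, rows =
#'   participant/stratum keys, columns = ASVs), `n_samples`, `detections`,
#'   `keys` (data frame participant_id, stratum), and the pooling used.
#' @export
persistence_profile <- function(counts, meta, pool = c("time", "depth"),
                                exclude_lesional = TRUE) {
  stopifnot(all(pool %in% c("time", "depth", "status")))
  meta <- meta[!meta$is_negative_control, , drop = FALSE]
  if (exclude_lesional) meta <- meta[meta$skin_status != "LS", , drop = FALSE]
  meta <- meta[meta$sample_id %in% sample_ids(counts), , drop = FALSE]
  if (nrow(meta) == 0L) stop("no samples left for persistence", call. = FALSE)
  strat_parts <- list()
  if (!"depth" %in% pool) strat_parts$depth <- meta$depth
  if (!"status" %in% pool) strat_parts$status <- meta$skin_status
  if (!"time" %in% pool) strat_parts$time <- paste0("t", meta$timepoint)
  stratum <- if (length(strat_parts)) {
    do.call(paste, c(strat_parts, sep = "|"))
  } else {
    rep("all", nrow(meta))
  }
  key <- paste(meta$participant_id, stratum, sep = "\r")
  det <- (counts$values[meta$sample_id, , drop = FALSE] > 0) * 1L
  detections <- rowsum(det, key)
  n <- as.vector(table(key)[rownames(detections)])
  pers <- detections / n
  split_keys <- do.call(rbind, strsplit(rownames(pers), "\r", fixed = TRUE))
  structure(list(persistence = pers,
                 detections = detections,
                 n_samples = stats::setNames(n, rownames(pers)),
                 keys = data.frame(participant_id = split_keys[, 1],
                                   stratum = split_keys[, 2],
                                   stringsAsFactors = FALSE),
                 pool = pool, exclude_lesional = exclude_lesional),
            class = "persistence_profile")
}

#' @export
print.persistence_profile <- function(x, ...) {
  cat(sprintf("<persistence_profile> %d participant/stratum keys x %d ASVs (pooled: %s)\n",
              nrow(x$persistence), ncol(x$persistence),
              paste(x$pool, collapse = ", ")))
  invisible(x)
}

#' Long-format view of a persistence profile
#' @param x a `persistence_profile`.
#' @param ... unused.
#' @return data frame (participant_id, stratum, asv_id, detections,
#'   n_samples, persistence).
#' @export
as.data.frame.persistence_profile <- function(x, ...) {
  nr <- nrow(x$persistence); nc <- ncol(x$persistence)
  data.frame(participant_id = rep(x$keys$participant_id, nc),
             stratum = rep(x$keys$stratum, nc),
             asv_id = rep(colnames(x$persistence), each = nr),
             detections = as.integer(x$detections),
             n_samples = rep(unname(x$n_samples), nc),
             persistence = as.vector(x$persistence),
             stringsAsFactors = FALSE)
}

# Persistence matrix (participants x ASVs) for rows whose (possibly
# compound, "|"-separated) stratum label contains `stratum` as a component.
profile_matrix <- function(profile, stratum) {
  sel <- vapply(strsplit(profile$keys$stratum, "|", fixed = TRUE),
                function(p) stratum %in% p || identical(p, stratum), TRUE)
  if (!any(sel)) stop("no stratum '", stratum, "' in profile", call. = FALSE)
  m <- profile$persistence[sel, , drop = FALSE]
  rownames(m) <- profile$keys$participant_id[sel]
  m
}

#' Paired test of persistence between skin depths
#'
#' For every common ASV (detected in more than `min_samples` samples
#' overall), a paired t test across participants of surface-minus-within
#' persistence, Benjamini-Hochberg corrected. Participants lacking either
#' depth are dropped from the pairing. ASVs with fewer than 3 paired
#' participants or zero variance of differences get NA statistics with a
#' reason code.
#'
#' @param profile a `persistence_profile` pooled over time only (strata =
#'   depths; see [persistence_profile()] with `pool = "time"`).
#' @param counts raw-count table used for the overall-detection filter.
#' @param min_samples overall-detection inclusion threshold: an ASV enters
#'   the test iff detected in **more than** this many samples (default 5).
#' @return data frame (asv_id, n_pairs, mean_difference, statistic, p, q,
#'   flag), sorted as the table's ASV order.
#' @export
depth_persistence_test <- function(profile, counts, min_samples = 5) {
  surface <- profile_matrix(profile, "surface")
  within <- profile_matrix(profile, "within")
  common_participants <- intersect(rownames(surface), rownames(within))
  surface <- surface[common_participants, , drop = FALSE]
  within <- within[common_participants, , drop = FALSE]
  overall_det <- colSums(counts$values > 0)
  asvs <- colnames(surface)[overall_det[colnames(surface)] > min_samples]
  res <- lapply(asvs, function(a) {
    d <- surface[, a] - within[, a]
    d <- d[!is.na(d)]
    if (length(d) < 3L) {
      return(data.frame(asv_id = a, n_pairs = length(d),
                        mean_difference = NA_real_, statistic = NA_real_,
                        p = NA_real_, flag = "too_few_pairs",
                        stringsAsFactors = FALSE))
    }
    tt <- paired_t(surface[names(d), a], within[names(d), a])
    data.frame(asv_id = a, n_pairs = length(d), mean_difference = mean(d),
               statistic = tt$statistic, p = tt$p_value,
               flag = if (length(tt$flags)) paste(tt$flags, collapse = ";") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[, c("asv_id", "n_pairs", "mean_difference", "statistic", "p", "q", "flag")]
}

#' Per-ASV test of persistence against disease status
#'
#' Fixed effect of cohort (AD nonlesional vs healthy control) on
#' per-participant persistence at one skin depth, with a participant-level
#' random intercept. With the standard design there is exactly one
#' persistence value per participant per ASV, so the random intercept is
#' unidentifiable; this degeneracy is detected and the operation reports the
#' equivalent two-sample linear-model test, flagged `degenerate_random_effect`.
#' ASVs enter only with non-zero persistence in more than `min_patients`
#' participants. p-values are Benjamini-Hochberg corrected.
#'
#' @param profile `persistence_profile` with depth strata (`pool = "time"`).
#' @param meta metadata (maps participant to cohort).
#' @param depth `"surface"` or `"within"`.
#' @param min_patients inclusion threshold (strictly more than; default 5).
#' @return data frame (asv_id, n_patients, effect, statistic, p, q, flag);
#'   effect is the AD-minus-HC difference in mean persistence.
#' @export
status_persistence_test <- function(profile, meta, depth = c("surface", "within"),
                                    min_patients = 5) {
  depth <- match.arg(depth)
  m <- profile_matrix(profile, depth)
  participants <- rownames(m)
  cohort <- meta$cohort[match(participants, meta$participant_id)]
  if (length(unique(cohort)) < 2L) stop("need both cohorts", call. = FALSE)
  keep <- colSums(m > 0) > min_patients
  res <- lapply(colnames(m)[keep], function(a) {
    y <- m[, a]
    n_per_part <- table(participants)
    flag <- character(0)
    if (all(n_per_part == 1L)) {
      # one observation per participant: random intercept unidentifiable
      flag <- "degenerate_random_effect"
      fit <- stats::lm(y ~ cohort)
      # perfect separation (e.g. an ASV in every AD, no HC) is legitimate
      # here; summary() warns about it but the Wald row is still what we
      # report
      cf <- suppressWarnings(summary(fit)$coefficients)
      row <- cf[grep("^cohort", rownames(cf))[1], ]
      est <- row[1]; stat <- row[3]; p <- row[4]
      if (rownames(cf)[grep("^cohort", rownames(cf))[1]] == "cohortHC") {
        est <- -est; stat <- -stat   # report AD (NLS) minus HC
      }
    } else {
      fit <- lme4::lmer(y ~ cohort + (1 | participants), REML = FALSE)
      if (lme4::isSingular(fit)) flag <- "singular_fit"
      cf <- stats::coef(summary(fit))
      i <- grep("^cohort", rownames(cf))[1]
      est <- cf[i, "Estimate"]; stat <- cf[i, "t value"]
      p <- 2 * stats::pnorm(-abs(stat))   # Wald, normal reference
      if (rownames(cf)[i] == "cohortHC") { est <- -est; stat <- -stat }
    }
    data.frame(asv_id = a, n_patients = sum(y > 0), effect = unname(est),
               statistic = unname(stat), p = unname(p),
               flag = paste(flag, collapse = ";"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no ASV passes the inclusion threshold", call. = FALSE)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[, c("asv_id", "n_patients", "effect", "statistic", "p", "q", "flag")]
}

#' Identify per-participant core communities
#'
#' The core of a participant is the set of ASVs with within-participant
#' persistence at or above `threshold`, persistence being pooled over time
#' points and skin depths with lesional samples excluded. Membership is
#' inclusive (>= threshold); an ASV at exactly the threshold is in the core.
#' Per-participant core abundance share is the mean over that participant's
#' samples of the summed relative abundance of their core ASVs.
#'
#' @param counts raw-count [asv_table()] (detection basis).
#' @param normalized matching relative-abundance table (share basis).
#' @param meta aligned metadata.
#' @param threshold persistence cutoff (default 0.7).
#' @param exclude_lesional default TRUE.
#' @return a `core_community_result`: list with `cores` (named list of ASV
#'   sets), `union_core`, `share`, `richness` (named per participant),
#'   `threshold`, and the profile used.
#' @export
identify_core <- function(counts, normalized, meta, threshold = 0.7,
                          exclude_lesional = TRUE) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]",
                                            call. = FALSE)
  profile <- persistence_profile(counts, meta, pool = c("time", "depth"),
                                 exclude_lesional = exclude_lesional)
  m <- profile$persistence
  participants <- profile$keys$participant_id
  cores <- lapply(seq_len(nrow(m)), function(i) colnames(m)[m[i, ] >= threshold])
  names(cores) <- participants
  meta_use <- meta[!meta$is_negative_control, , drop = FALSE]
  if (exclude_lesional) meta_use <- meta_use[meta_use$skin_status != "LS", , drop = FALSE]
  meta_use <- meta_use[meta_use$sample_id %in% sample_ids(normalized), , drop = FALSE]
  share <- vapply(participants, function(p) {
    ids <- meta_use$sample_id[meta_use$participant_id == p]
    core <- cores[[p]]
    if (length(core) == 0L || length(ids) == 0L) return(0)
    mean(rowSums(normalized$values[ids, core, drop = FALSE]))
  }, 0)
  structure(list(cores = cores,
                 union_core = sort(unique(unlist(cores))),
                 share = share,
                 richness = vapply(cores, length, 0L),
                 threshold = threshold,
                 profile = profile),
            class = "core_community_result")
}

#' @export
print.core_community_result <- function(x, ...) {
  cat(sprintf("<core_community_result> %d participants, union core %d ASVs (threshold %.2f)\n",
              length(x$cores), length(x$union_core), x$threshold))
  cat(sprintf("  mean core richness %.1f, mean abundance share %.3f\n",
              mean(x$richness), mean(x$share)))
  invisible(x)
}

#' Identify ubiquitous ASVs
#'
#' ASVs detected in at least `threshold` of all retained samples, study-wide.
#' Lesional samples are excluded by default, mirroring the core-community
#' definition; set `include_lesional = TRUE` to keep them.
#'
#' @param counts raw-count [asv_table()].
#' @param meta aligned metadata.
#' @param threshold fraction of samples (default 0.7).
#' @param include_lesional default FALSE.
#' @return character vector of ASV identifiers.
#' @export
identify_ubiquitous <- function(counts, meta, threshold = 0.7,
                                include_lesional = FALSE) {
  meta <- meta[!meta$is_negative_control, , drop = FALSE]
  if (!include_lesional) meta <- meta[meta$skin_status != "LS", , drop = FALSE]
  ids <- intersect(meta$sample_id, sample_ids(counts))
  frac <- colMeans(counts$values[ids, , drop = FALSE] > 0)
  asv_ids(counts)[frac >= threshold]
}

#' Compare core communities between disease statuses
#'
#' Kruskal-Wallis tests of per-participant core abundance share and core
#' richness between AD (nonlesional) and healthy-control participants, plus
#' a PERMANOVA on the core-subset composition (union core ASVs,
#' renormalized fourth-root abundances, cohort term with participant
#' strata).
#'
#' @param core a `core_community_result`.
#' @param counts raw-count table (for the core-subset composition).
#' @param meta aligned metadata.
#' @param n_perm permutations for the PERMANOVA (default 999).
#' @param seed RNG seed.
#' @return list with `share_test`, `richness_test` (TestResult) and
#'   `composition` (`permanova_result`).
#' @export
compare_core_by_status <- function(core, counts, meta, n_perm = 999,
                                   seed = NULL) {
  parts <- names(core$cores)
  cohort <- meta$cohort[match(parts, meta$participant_id)]
  if (length(unique(cohort)) < 2L) stop("need two statuses", call. = FALSE)
  groups_share <- split(unname(core$share), cohort)
  groups_rich <- split(as.numeric(core$richness), cohort)
  meta_use <- meta[!meta$is_negative_control & meta$skin_status != "LS", ,
                   drop = FALSE]
  ids <- intersect(meta_use$sample_id, sample_ids(counts))
  sub <- subset_asv_table(counts, samples = ids, asvs = core$union_core)
  sub_norm <- fourth_root_relabund(sub)
  nonempty <- rowSums(sub_norm$values) > 0
  d <- compute_distance(subset_asv_table(sub_norm,
                                         samples = ids[nonempty]),
                        "bray_curtis")
  list(share_test = kruskal_wallis(groups_share),
       richness_test = kruskal_wallis(groups_rich),
       composition = permanova(d, meta_use, "cohort",
                               n_perm = n_perm, strata = "participant_id",
                               seed = seed))
}
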