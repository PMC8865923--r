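# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Random raw-count table with simple metadata (one participant per
# `samples_per_participant` block, alternating depths, HC cohort).
rand_study <- function(n_participants = 4, n_timepoints = 2, n_asvs = 30,
                       seed = 1, reads = 500) {
  withr::with_seed(seed, {
    ids <- c()
    meta <- list()
    for (p in seq_len(n_participants)) {
      for (t in seq_len(n_timepoints)) {
        for (dp in c("surface", "within")) {
          id <- sprintf("P%02d_T%d_%s", p, t, dp)
          ids <- c(ids, id)
          meta[[id]] <- data.frame(
            sample_id = id, participant_id = sprintf("P%02d", p),
            cohort = if (p <= n_participants / 2) "AD" else "HC",
            skin_status = if (p <= n_participants / 2) "NLS" else "HC",
            depth = dp, timepoint = t, body_location = "volar_forearm",
            oscorad = NA_real_, filaggrin_mutation = NA,
            is_negative_control = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    m <- t(vapply(ids, function(i) {
      stats::rmultinom(1, reads, stats::rlnorm(n_asvs, 0, 1))[, 1]
    }, numeric(n_asvs)))
    colnames(m) <- sprintf("ASV%03d", seq_len(n_asvs))
    list(table = asv_table(m, "raw_counts"),
         meta = validate_metadata(do.call(rbind, meta)))
  })
}

# Hand-built preprocessing fixture: 20 real samples + 12 negatives,
# 10 ASVs with planted removals: contaminants C1 (10/12 negatives) and
# C2 (12/12), rare ASV R1 (4 real samples), chloroplast lineage X1.
toy_preprocess_fixture <- function() {
  real_ids <- sprintf("S%02d", 1:20)
  neg_ids <- sprintf("NEG%02d", 1:12)
  asvs <- c(paste0("A", 1:6), "C1", "C2", "R1", "X1")
  m <- matrix(0, 32, 10, dimnames = list(c(real_ids, neg_ids), asvs))
  m[real_ids, paste0("A", 1:6)] <- 10          # clean ASVs everywhere
  m[real_ids, "C1"] <- 3                        # contaminants also in samples
  m[real_ids, "C2"] <- 2
  m[real_ids[1:4], "R1"] <- 7                   # rare: 4 real samples
  m[real_ids, "X1"] <- 5                        # chloroplast, prevalent
  m[neg_ids[1:10], "C1"] <- 5                   # exactly 10 of 12 negatives
  m[neg_ids, "C2"] <- 4                         # all 12 negatives
  m[neg_ids[1:9], "A1"] <- 1                    # 9 of 12: below threshold
  meta <- do.call(rbind, c(
    lapply(seq_along(real_ids), function(i) data.frame(
      sample_id = real_ids[i], participant_id = sprintf("P%02d", (i - 1) %/% 4 + 1),
      cohort = "HC", skin_status = "HC",
      depth = c("surface", "within")[(i %% 2) + 1],
      timepoint = ((i - 1) %% 4) + 1, body_location = "volar_forearm",
      oscorad = NA_real_, filaggrin_mutation = NA,
      is_negative_control = FALSE, stringsAsFactors = FALSE)),
    lapply(neg_ids, function(id) data.frame(
      sample_id = id, participant_id = NA_character_, cohort = NA_character_,
      skin_status = NA_character_, depth = NA_character_,
      timepoint = NA_integer_, body_location = NA_character_,
      oscorad = NA_real_, filaggrin_mutation = NA,
      is_negative_control = TRUE, stringsAsFactors = FALSE))))
  tax <- data.frame(
    asv_id = asvs,
    domain = "Bacteria",
    phylum = "Firmicutes", class = "Bacilli", order = "Bacillales",
    family = "Staphylococcaceae", genus = "Staphylococcus",
    species = NA_character_, stringsAsFactors = FALSE)
  tax$family[tax$asv_id == "X1"] <- "Chloroplast"
  list(table = asv_table(m, "raw_counts"), meta = validate_metadata(meta),
       tax = tax,
       planted = list(contaminants = c("C1", "C2"), rare = "R1",
                      organelle = "X1"))
}

# Random symmetric distance matrix on n points (valid metric not required
# for the algebraic identities).
rand_distance <- function(n, seed = 1, dim = 3) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * dim), n)
    d <- as.matrix(stats::dist(x))
    dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
    as_distance_matrix(d)
  })
}

# Independent one-factor PERMANOVA oracle from the pairwise-distance
# group-sum formulas (no projections), with exact p by enumerating all
# distinct labelings.
oracle_oneway_permanova <- function(d, groups) {
  f_of <- function(g) {
    n <- nrow(d)
    ss_tot <- sum(d[upper.tri(d)]^2) / n
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        sub <- d[idx, idx]
        ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(idx)
      }
    }
    a <- length(unique(g))
    ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_of(groups)
  perms <- dermadiv:::all_permutations(nrow(d))
  labelings <- unique(apply(perms, 1, function(p) paste(groups[p], collapse = "")))
  fs <- vapply(strsplit(labelings, ""), f_of, 0)
  list(f = f_obs, p_exact = mean(fs >= f_obs - 1e-12))
}
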