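small_cfg <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_participants_ad = 3, n_participants_hc = 3,
                   n_asvs_global = 120, reads_mean = 1500, n_negatives = 12,
                   n_contaminant_asvs = 8, n_core_asvs_per_participant = 8,
                   n_pathobiont_asvs = 4, ...)
}

test_that("config validation rejects impossible worlds", {
  expect_error(synthetic_config(depth_retention_fraction = 0), "in \\(0, 1\\]")
  expect_error(synthetic_config(participant_effect_sd = -1), ">= 0")
  expect_error(synthetic_config(reads_mean = 0), "positive")
  expect_error(synthetic_config(n_timepoints = 0), "integer >= 1")
  expect_s3_class(preset_paper_like(), "synthetic_config")
  null_cfg <- preset_null()
  expect_equal(null_cfg$participant_effect_sd, 0)
  expect_equal(null_cfg$depth_retention_fraction, 1)
  expect_equal(null_cfg$n_core_asvs_per_participant, 0L)
})

test_that("sample bookkeeping and determinism hold", {
  st <- generate_study(small_cfg(seed = 7))
  # 6 participants x 4 visits x 2 depths non-control samples
  expect_equal(sum(!st$meta$is_negative_control), 6 * 4 * 2)
  expect_equal(sum(st$meta$is_negative_control), 12)
  expect_equal(nrow(st$table$values), nrow(st$meta))
  # same seed -> bit-identical
  st2 <- generate_study(small_cfg(seed = 7))
  expect_identical(st$table$values, st2$table$values)
  expect_identical(st$meta, st2$meta)
  expect_identical(st$truth, st2$truth)
  # different seed -> different draws
  st3 <- generate_study(small_cfg(seed = 8))
  expect_false(identical(st$table$values, st3$table$values))
  # lesional samples double the AD sample count when enabled
  stl <- generate_study(small_cfg(seed = 7, include_lesional = TRUE))
  expect_equal(sum(stl$meta$skin_status == "LS", na.rm = TRUE), 3 * 4 * 2)
  expect_true(all(stl$meta$body_location[which(stl$meta$skin_status == "LS")] %in%
                    dermadiv:::.location_levels))
})

test_that("within-epidermis support is nested in surface support", {
  st <- generate_study(small_cfg(seed = 3))
  for (p in names(st$truth$support)) {
    expect_true(all(st$truth$within_support[[p]] %in% st$truth$support[[p]]))
    expect_setequal(st$truth$depth_restricted[[p]],
                    setdiff(st$truth$support[[p]], st$truth$within_support[[p]]))
    # realized counts respect the support sets
    ids_w <- st$meta$sample_id[!st$meta$is_negative_control &
                                 st$meta$participant_id == p &
                                 st$meta$depth == "within"]
    detected_w <- colnames(st$table$values)[colSums(st$table$values[ids_w, ]) > 0]
    expect_true(all(setdiff(detected_w, st$truth$contaminants) %in%
                      st$truth$within_support[[p]]))
  }
})

test_that("planted structure is disjoint where required and taxonomy tracks it", {
  st <- generate_study(small_cfg(seed = 11))
  for (p in names(st$truth$core)) {
    expect_length(intersect(st$truth$core[[p]], st$truth$contaminants), 0)
    expect_length(intersect(st$truth$core[[p]], st$truth$pathobionts), 0)
  }
  tax <- st$taxonomy
  expect_true(all(tax$genus[tax$asv_id %in% st$truth$pathobionts] ==
                    "Staphylococcus"))
  expect_true(all(tax$domain == "Bacteria"))
  expect_true(all(st$truth$contaminants %in% tax$asv_id))
})

test_that("counts sum to the drawn depth and negatives carry contaminants", {
  st <- generate_study(small_cfg(seed = 5))
  # every sample's counts sum to its multinomial size (> 0)
  expect_true(all(rowSums(st$table$values) > 0))
  neg_ids <- st$meta$sample_id[st$meta$is_negative_control]
  neg <- st$table$values[neg_ids, , drop = FALSE]
  # negatives contain only contaminant-pool ASVs
  bio_cols <- setdiff(colnames(neg), st$truth$contaminants)
  expect_equal(sum(neg[, bio_cols]), 0)
  # default-world invariant: each contaminant detected in >= 10 of the
  # negatives. This needs the *default* negative model (30 negatives at
  # realistic sequencing depth); sparse low-read negatives miss rare
  # contaminants.
  for (seed in 1:3) {
    stn <- generate_study(synthetic_config(
      seed = seed, n_participants_ad = 2, n_participants_hc = 2,
      n_asvs_global = 120, n_core_asvs_per_participant = 8,
      n_pathobiont_asvs = 4))
    det <- colSums(stn$table$values[stn$meta$sample_id[stn$meta$is_negative_control],
                                    stn$truth$contaminants] > 0)
    expect_true(all(det >= 10))
  }
})

test_that("AD participants carry elevated pathobiont signal", {
  st <- generate_study(small_cfg(seed = 13, status_effect = 2))
  meta <- st$meta[!st$meta$is_negative_control, ]
  rel <- st$table$values / rowSums(st$table$values)
  patho <- rowSums(rel[meta$sample_id, st$truth$pathobionts, drop = FALSE])
  expect_gt(mean(patho[meta$cohort == "AD"]), mean(patho[meta$cohort == "HC"]))
})
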