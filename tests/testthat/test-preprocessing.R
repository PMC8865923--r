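test_that("negative-control filter applies the >= threshold and drops negatives", {
  fx <- toy_preprocess_fixture()
  out <- filter_negative_contaminants(fx$table, fx$meta, min_negatives = 10)
  # C1 in exactly 10 negatives -> removed; C2 in 12 -> removed; A1 in 9 -> kept
  expect_setequal(out$report$stages[[1]]$removed_asv_ids, c("C1", "C2"))
  expect_true("A1" %in% asv_ids(out$table))
  expect_false(any(fx$meta$sample_id[fx$meta$is_negative_control] %in%
                     sample_ids(out$table)))
  # reads accounting: contaminant reads in real samples only
  expect_equal(out$report$stages[[1]]$reads_removed, 20 * 3 + 20 * 2)
  expect_error(filter_negative_contaminants(fx$table, fx$meta, 0),
               "min_negatives")
  # zero negatives: warning + no-op
  no_neg <- fx$meta[!fx$meta$is_negative_control, ]
  tab_real <- dermadiv:::subset_asv_table(fx$table, samples = no_neg$sample_id)
  expect_warning(out2 <- filter_negative_contaminants(tab_real, no_neg),
                 "no negative controls")
  expect_equal(out2$table$values, tab_real$values)
})

test_that("rare and taxonomy filters apply their boundary rules", {
  fx <- toy_preprocess_fixture()
  out <- filter_rare_asvs(fx$table, min_samples = 5)
  expect_equal(out$report$stages[[1]]$removed_asv_ids, "R1")   # 4 samples < 5
  # exactly 5 detections retained
  m <- matrix(0, 6, 2, dimnames = list(paste0("s", 1:6), c("five", "one")))
  m[1:5, "five"] <- 1; m[1, "one"] <- 1
  keep5 <- filter_rare_asvs(asv_table(m), 5)
  expect_equal(asv_ids(keep5$table), "five")
  # min_samples = 1 removes nothing detected
  expect_equal(asv_ids(filter_rare_asvs(asv_table(m), 1)$table), c("five", "one"))

  tax <- fx$tax
  tax$domain[tax$asv_id == "A2"] <- "Eukaryota"
  tax$domain[tax$asv_id == "A3"] <- "Archaea"
  out2 <- filter_taxonomy(fx$table, tax)
  removed <- out2$report$stages[[1]]$removed_asv_ids
  expect_true("A2" %in% removed)      # non-target domain
  expect_true("X1" %in% removed)      # chloroplast lineage under Bacteria
  expect_false("A3" %in% removed)     # clean Archaea retained
  expect_error(filter_taxonomy(fx$table, tax[-1, ]), "taxonomy missing")
})

test_that("fourth-root normalization matches the worked example", {
  m <- rbind(s1 = c(16, 81, 0), s2 = c(1, 1, 0), s3 = c(0, 0, 0))
  colnames(m) <- paste0("a", 1:3)
  norm <- fourth_root_relabund(asv_table(m))
  expect_equal(unname(norm$values["s1", ]), c(0.4, 0.6, 0))   # (2,3,0)/5
  expect_equal(unname(norm$values["s2", ]), c(0.5, 0.5, 0))
  expect_equal(unname(norm$values["s3", ]), c(0, 0, 0))
  expect_equal(attr(norm, "empty_samples"), "s3")
  expect_equal(norm$value_kind, "transformed_relabund")
})

test_that("run_preprocessing removes exactly the planted ASVs, in stage order", {
  fx <- toy_preprocess_fixture()
  pre <- run_preprocessing(fx$table, fx$meta, fx$tax)
  stages <- pre$report$stages
  expect_setequal(stages[[1]]$removed_asv_ids, fx$planted$contaminants)
  expect_equal(stages[[2]]$removed_asv_ids, fx$planted$rare)
  expect_equal(stages[[3]]$removed_asv_ids, fx$planted$organelle)
  expect_setequal(asv_ids(pre$counts), paste0("A", 1:6))
  # retained counts unchanged (filters are monotone column drops)
  expect_equal(pre$counts$values,
               fx$table$values[sample_ids(pre$counts), asv_ids(pre$counts)])
  # row sums of normalized table are 1
  expect_true(all(abs(rowSums(pre$table$values) - 1) < 1e-9))
  # mean per-sample fraction removed, by hand: sample S01 has 60+3+2+7+5 = 77
  # reads of which 3+2+7+5 = 17 removed; S05..S20 have 70 with 10 removed
  frac <- pre$report$per_sample_fraction_removed
  expect_equal(unname(frac["S01"]), 17 / 77)
  expect_equal(unname(frac["S05"]), 10 / 70)
  expect_equal(pre$report$mean_fraction_removed, mean(frac))
})

test_that("filter order changes attribution but not the final ASV set", {
  fx <- toy_preprocess_fixture()
  pre <- run_preprocessing(fx$table, fx$meta, fx$tax)
  # alternative order: prevalence -> taxonomy -> negatives
  s1 <- filter_rare_asvs(fx$table, 5)
  s2 <- filter_taxonomy(s1$table, fx$tax)
  s3 <- filter_negative_contaminants(s2$table, fx$meta, 10)
  expect_setequal(asv_ids(s3$table), asv_ids(pre$counts))
})

test_that("preprocessing is idempotent and monotone", {
  st <- rand_study(n_participants = 4, n_asvs = 40, seed = 11)
  fx <- toy_preprocess_fixture()
  tax <- data.frame(asv_id = asv_ids(st$table), domain = "Bacteria",
                    phylum = NA, class = NA, order = NA, family = NA,
                    genus = NA, species = NA, stringsAsFactors = FALSE)
  pre <- suppressWarnings(run_preprocessing(st$table, st$meta, tax))
  expect_true(all(asv_ids(pre$counts) %in% asv_ids(st$table)))
  # second pass: negatives are already gone, so the contaminant stage warns
  # and no stage removes anything
  again <- suppressWarnings(run_preprocessing(pre$counts, st$meta, tax))
  expect_equal(asv_ids(again$counts), asv_ids(pre$counts))
  expect_equal(sum(vapply(again$report$stages,
                          function(s) length(s$removed_asv_ids), 0L)), 0L)
})
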