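test_that("distance metrics match worked examples and vegan", {
  m <- rbind(s1 = c(0.5, 0.5), s2 = c(0.25, 0.75))
  colnames(m) <- c("a", "b")
  tab <- asv_table(m, "transformed_relabund")
  d <- bray_curtis(tab)
  expect_equal(d["s1", "s2"], 0.25)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
  # disjoint supports -> 1
  m2 <- rbind(s1 = c(1, 0), s2 = c(0, 1)); colnames(m2) <- c("a", "b")
  expect_equal(compute_distance(asv_table(m2), "bray_curtis")["s1", "s2"], 1)
  # vegan oracle on random tables, all three metrics
  st <- rand_study(n_participants = 3, n_asvs = 25, seed = 13)
  norm <- fourth_root_relabund(st$table)
  expect_equal(unclass(compute_distance(norm, "bray_curtis")),
               as.matrix(vegan::vegdist(norm$values, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(compute_distance(st$table, "jaccard_binary")),
               as.matrix(vegan::vegdist(st$table$values > 0, "jaccard")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(compute_distance(st$table, "euclidean")),
               as.matrix(stats::dist(st$table$values)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("gower centering satisfies its algebraic identities", {
  z <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_equal(gower_center(z), z)
  for (seed in 1:5) {
    d <- rand_distance(8, seed = seed)
    g <- gower_center(d)
    expect_equal(sum(diag(g)), sum(d[upper.tri(d)]^2) / nrow(d),
                 tolerance = 1e-10)
    expect_equal(max(abs(rowSums(g))), 0, tolerance = 1e-9)
    expect_equal(g, t(g), tolerance = 1e-12)
  }
})

test_that("sequential SS, R2 and F match the vegan oracle", {
  st <- rand_study(n_participants = 4, n_timepoints = 2, n_asvs = 40, seed = 21)
  norm <- fourth_root_relabund(st$table)
  d <- bray_curtis(norm)
  meta <- st$meta
  meta$timepoint <- factor(meta$timepoint)
  res <- permanova(d, meta, c("cohort", "depth", "timepoint", "participant_id"),
                   n_perm = 19, seed = 1)
  vg <- vegan::adonis2(stats::as.dist(d) ~ cohort + depth + timepoint + participant_id,
                       data = meta[match(rownames(d), meta$sample_id), ],
                       permutations = 19, by = "terms")
  expect_equal(res$SS, vg$SumOfSqs, tolerance = 1e-9)
  expect_equal(res$R2, vg$R2, tolerance = 1e-9)
  expect_equal(res$F[1:4], vg$F[1:4], tolerance = 1e-9)
  expect_equal(res$df, vg$Df)
})

test_that("partition identities hold and results are order-invariant", {
  st <- rand_study(n_participants = 3, n_asvs = 30, seed = 8)
  norm <- fourth_root_relabund(st$table)
  d <- bray_curtis(norm)
  res <- permanova(d, st$meta, c("depth", "participant_id"), n_perm = 9, seed = 1)
  k <- nrow(res) - 2
  expect_equal(sum(res$SS[1:(k + 1)]), res$SS[k + 2], tolerance = 1e-9)
  expect_equal(sum(res$R2[1:(k + 1)]), 1, tolerance = 1e-9)
  # shuffling input sample order leaves the partition unchanged
  perm <- withr::with_seed(4, sample(nrow(d)))
  d2 <- as_distance_matrix(unclass(d)[perm, perm])
  res2 <- permanova(d2, st$meta, c("depth", "participant_id"), n_perm = 9, seed = 1)
  expect_equal(res2$SS, res$SS, tolerance = 1e-9)
  expect_equal(res2$R2, res$R2, tolerance = 1e-9)
})

test_that("degenerate designs error clearly", {
  d <- rand_distance(6, seed = 2)
  meta <- data.frame(sample_id = rownames(d), g = rep("x", 6),
                     h = rep(c("a", "b"), 3))
  expect_error(permanova(d, meta, "g"), "no variation in term")
  meta$g2 <- meta$h
  expect_error(permanova(d, meta, c("h", "g2"), n_perm = 9), "singular design")
  expect_error(permanova(as_distance_matrix(unclass(d)[1:2, 1:2]),
                         meta[1:2, ], "h"), "at least 3")
})

test_that("identical seeds give identical p-values; p respects its bounds", {
  st <- rand_study(n_participants = 3, n_asvs = 20, seed = 30)
  d <- bray_curtis(fourth_root_relabund(st$table))
  r1 <- permanova(d, st$meta, c("depth", "timepoint"), n_perm = 99, seed = 42)
  r2 <- permanova(d, st$meta, c("depth", "timepoint"), n_perm = 99, seed = 42)
  expect_identical(r1$p, r2$p)
  k <- 2
  expect_true(all(r1$p[1:k] >= 1 / 100 & r1$p[1:k] <= 1))
})

test_that("strata restrict permutations; block-constant terms fall back", {
  st <- rand_study(n_participants = 4, n_timepoints = 2, n_asvs = 25, seed = 17)
  d <- bray_curtis(fourth_root_relabund(st$table))
  # cohort is constant within participant: fallback must engage and be noted
  res <- permanova(d, st$meta, "cohort", n_perm = 99,
                   strata = "participant_id", seed = 3)
  expect_match(attr(res, "notes"), "block-level exchange")
  expect_true(res$p[1] > 0 && res$p[1] <= 1)
  # depth varies within participant: within-block shuffling, no note
  res2 <- permanova(d, st$meta, "depth", n_perm = 99,
                    strata = "participant_id", seed = 3)
  expect_length(attr(res2, "notes"), 0)
})

test_that("continuous covariates match a direct projection oracle", {
  d <- rand_distance(6, seed = 5)
  meta <- data.frame(sample_id = rownames(d),
                     oscorad = c(1.2, 3.4, 2.2, 5.1, 0.7, 4.4))
  res <- permanova(d, meta, "oscorad", n_perm = 9, seed = 1)
  g <- gower_center(d)
  x <- cbind(1, meta$oscorad)
  h <- x %*% solve(crossprod(x), t(x))
  ss_term <- sum(diag(h %*% g))        # intercept part contributes 0
  expect_equal(res$SS[1], ss_term, tolerance = 1e-9)
  expect_equal(res$df[1], 1)
})
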