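#' Pairwise community distance matrix
#'
#' Computes a symmetric sample-by-sample dissimilarity matrix from an
#' [asv_table()]. Metrics:
#' * `bray_curtis` — sum|x_i - x_j| / sum(x_i + x_j), the default for
#'   abundance-weighted community comparison (applied to the fourth-root
#'   relative abundances);
#' * `jaccard_binary` — 1 - shared/union on detection sets;
#' * `euclidean` — ordinary Euclidean distance.
#'
#' @param table an [asv_table()].
#' @param metric one of `"bray_curtis"`, `"jaccard_binary"`, `"euclidean"`.
#' @return a `distance_matrix`: symmetric numeric matrix, zero diagonal,
#'   sample identifiers as dimnames.
#' @export
compute_distance <- function(table,
                             metric = c("bray_curtis", "jaccard_binary",
                                        "euclidean")) {
  metric <- match.arg(metric)
  v <- table$values
  d <- switch(metric,
    bray_curtis = {
      num <- as.matrix(stats::dist(v, method = "manhattan"))
      rs <- rowSums(v)
      den <- outer(rs, rs, "+")
      out <- num / den
      out[den == 0] <- 0   # two empty samples: no information, distance 0
      out
    },
    jaccard_binary = {
      b <- (v > 0) * 1
      shared <- tcrossprod(b)
      sz <- diag(shared)
      uni <- outer(sz, sz, "+") - shared
      out <- 1 - shared / uni
      out[uni == 0] <- 0
      out
    },
    euclidean = as.matrix(stats::dist(v))
  )
  diag(d) <- 0
  as_distance_matrix(d)
}

#' Validate/construct a distance matrix
#' @param d symmetric numeric matrix with zero diagonal and dimnames.
#' @return the matrix, classed `distance_matrix`.
#' @export
as_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs sample identifiers",
                                 call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stop("distance matrix must be symmetric (tolerance 1e-12)", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' Bray-Curtis dissimilarity
#' @param table an [asv_table()] (normally fourth-root relative abundances).
#' @return a `distance_matrix`.
#' @export
bray_curtis <- function(table) compute_distance(table, "bray_curtis")

#' Gower-centered inner-product matrix
#'
#' G = -1/2 J A J with A the matrix of squared distances and
#' J = I - 11'/n. The trace of G is the total sum of squares of the
#' partitioning; its rows and columns sum to zero.
#'
#' @param d a `distance_matrix` (or plain symmetric matrix).
#' @return centered n x n matrix.
#' @export
gower_center <- function(d) {
  d <- as.matrix(d)
  a <- -0.5 * d^2
  n <- nrow(a)
  rm_ <- rowMeans(a); cm <- colMeans(a); gm <- mean(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), cm) + gm
  dimnames(g) <- dimnames(d)
  g
}

# Orthonormal bases for the nested sequence of design spaces
# (intercept, +term1, +term1+term2, ...). Returns list of Q matrices and
# cumulative ranks.
design_chain <- function(df, terms) {
  qs <- vector("list", length(terms) + 1L)
  ranks <- integer(length(terms) + 1L)
  for (k in 0:length(terms)) {
    fml <- if (k == 0) ~1 else
      stats::as.formula(paste("~", paste(terms[1:k], collapse = " + ")))
    x <- stats::model.matrix(fml, df)
    if (nrow(x) != nrow(df)) {
      stop("missing values in model terms are not allowed", call. = FALSE)
    }
    qr_ <- qr(x)
    ranks[k + 1L] <- qr_$rank
    qs[[k + 1L]] <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  }
  list(q = qs, rank = ranks)
}

# Sequential trace statistics tr(Q_k' G Q_k) for a chain of bases; `idx`
# optionally permutes the rows of each Q (equivalent to permuting G).
chain_traces <- function(g, chain, idx = NULL) {
  vapply(chain$q, function(q) {
    if (!is.null(idx)) q <- q[idx, , drop = FALSE]
    sum((g %*% q) * q)
  }, 0)
}

seq_stats <- function(tr, ranks, total_ss, n) {
  k <- length(tr) - 1L
  ss <- diff(tr)
  df <- diff(ranks)
  ss_res <- total_ss - (tr[k + 1L] - tr[1L]) - tr[1L]  # tr[1] ~ 0 (centered G)
  df_res <- n - ranks[k + 1L]
  f <- (ss / df) / (ss_res / df_res)
  list(ss = ss, df = df, ss_res = ss_res, df_res = df_res, f = f)
}

# Draw one permutation of 1..n, optionally restricted within strata blocks.
draw_perm <- function(n, blocks = NULL) {
  if (is.null(blocks)) return(sample.int(n))
  idx <- seq_len(n)
  for (b in split(seq_len(n), blocks)) {
    if (length(b) > 1L) idx[b] <- b[sample.int(length(b))]
  }
  idx
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Sequential (Type I) partitioning of the variance of a distance matrix
#' among ordered model terms, with permutation p-values. Each term's sum of
#' squares is the increase in tr(H G H) between nested design projections;
#' pseudo-F is (SS_term/df_term)/(SS_res/df_res).
#'
#' Permutation schemes:
#' * no `strata` — free shuffling of samples;
#' * `strata` given, tested term varies within blocks — labels are shuffled
#'   only within strata blocks;
#' * `strata` given, tested term constant within blocks (e.g. disease status
#'   within participant) — within-block shuffles cannot test it, so the
#'   term's block-level values are exchanged across blocks instead; this
#'   fallback is recorded in the result's `notes`.
#'
#' `n_perm = "exact"` enumerates all distinct rearrangements (error above
#' 1e6) and reports p as the exact fraction of arrangements with permuted
#' F >= observed F (the identity included). Monte-Carlo p uses the add-one
#' estimator (1 + #exceedances) / (1 + n_perm), so p is never zero.
#'
#' @param d a `distance_matrix`.
#' @param meta data frame with one row per sample of `d` (matched by
#'   `sample_id`).
#' @param terms character vector of metadata columns, in model order.
#' @param n_perm number of permutations (default 999) or `"exact"`.
#' @param strata optional metadata column restricting permutations.
#' @param seed RNG seed for the permutation stream (identical seed, identical
#'   p-values); the caller's RNG state is untouched.
#' @return a `permanova_result`: data frame with one row per term plus
#'   Residual and Total (columns term, df, SS, R2, F, p), with attributes
#'   `n_perm`, `strata`, `seed`, `notes`.
#' @export
permanova <- function(d, meta, terms, n_perm = 999, strata = NULL,
                      seed = NULL) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (!"sample_id" %in% names(meta)) stop("meta needs sample_id", call. = FALSE)
  idx <- match(rownames(d), meta$sample_id)
  if (anyNA(idx)) stop("metadata missing for some samples of d", call. = FALSE)
  df <- meta[idx, , drop = FALSE]
  for (tm in c(terms, strata)) {
    if (!tm %in% names(df)) stop("unknown term: ", tm, call. = FALSE)
    if (anyNA(df[[tm]])) stop("missing values in term '", tm, "'", call. = FALSE)
    v <- df[[tm]]
    if (length(unique(v)) < 2L) stop("no variation in term '", tm, "'", call. = FALSE)
    if (is.character(v) || is.logical(v)) df[[tm]] <- factor(v)
  }

  g <- gower_center(d)
  total_ss <- sum(diag(g))
  chain <- design_chain(df, terms)
  if (any(diff(chain$rank) == 0L)) {
    stop("singular design: term '",
         terms[which(diff(chain$rank) == 0L)[1]],
         "' adds no estimable contrasts", call. = FALSE)
  }
  obs <- seq_stats(chain_traces(g, chain), chain$rank, total_ss, n)
  if (obs$df_res <= 0) stop("singular design: no residual degrees of freedom",
                            call. = FALSE)

  notes <- character(0)
  blocks <- if (!is.null(strata)) factor(df[[strata]]) else NULL
  block_constant <- function(tm) {
    !is.null(blocks) &&
      all(tapply(as.character(df[[tm]]), blocks,
                 function(z) length(unique(z)) == 1L))
  }

  k <- length(terms)
  p <- rep(NA_real_, k)
  exact <- identical(n_perm, "exact")

  # Terms testable by shuffling sample labels (freely or within blocks).
  shuffle_terms <- if (is.null(blocks)) seq_len(k) else
    which(!vapply(terms, block_constant, TRUE))
  exch_terms <- setdiff(seq_len(k), shuffle_terms)
  for (i in exch_terms) {
    notes <- c(notes,
               sprintf(paste0("term '%s' is constant within strata '%s' ",
                              "blocks; p-value from block-level exchange of ",
                              "its values"), terms[i], strata))
  }

  with_seed(seed, {
    if (length(shuffle_terms)) {
      if (exact) {
        perms <- enumerate_perms(n, blocks)
        exc <- integer(k)
        for (r in seq_len(nrow(perms))) {
          fp <- seq_stats(chain_traces(g, chain, perms[r, ]),
                          chain$rank, total_ss, n)$f
          exc <- exc + (fp >= obs$f - 1e-12)
        }
        p[shuffle_terms] <- exc[shuffle_terms] / nrow(perms)
      } else {
        assert_count(n_perm, "n_perm")
        exc <- integer(k)
        for (r in seq_len(n_perm)) {
          fp <- seq_stats(chain_traces(g, chain, draw_perm(n, blocks)),
                          chain$rank, total_ss, n)$f
          exc <- exc + (fp >= obs$f - 1e-12)
        }
        p[shuffle_terms] <- (1 + exc[shuffle_terms]) / (1 + n_perm)
      }
    }
    for (i in exch_terms) {
      p[i] <- block_exchange_p(g, df, terms, i, blocks, total_ss, n,
                               n_perm, obs$f[i])
    }
  })

  res <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(obs$df, obs$df_res, n - 1L),
    SS = c(obs$ss, obs$ss_res, total_ss),
    R2 = c(obs$ss, obs$ss_res, total_ss) / total_ss,
    F = c(obs$f, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  structure(res,
            class = c("permanova_result", "data.frame"),
            n_perm = n_perm, strata = strata, seed = seed, notes = notes)
}

# Exhaustive permutation set, free or within blocks (products of per-block
# permutations). Guard: at most 1e6 arrangements.
enumerate_perms <- function(n, blocks = NULL, limit = 1e6) {
  if (is.null(blocks)) return(all_permutations(n, limit))
  parts <- split(seq_len(n), blocks)
  total <- prod(vapply(parts, function(b) factorial(length(b)), 0))
  if (total > limit) {
    stop("exact enumeration would need ", format(total),
         " arrangements (limit ", format(limit), ")", call. = FALSE)
  }
  out <- matrix(seq_len(n), nrow = 1L)
  for (b in parts) {
    sub <- all_permutations(length(b), Inf)
    grown <- matrix(0L, nrow(out) * nrow(sub), n)
    r <- 0L
    for (i in seq_len(nrow(out))) for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- out[i, ]
      row[b] <- b[sub[j, ]]
      grown[r, ] <- row
    }
    out <- grown
  }
  out
}

# p-value for a block-constant term: exchange the term's block-level values
# across blocks, rebuild the sequential chain with the permuted term, and
# compare the term's pseudo-F. Monte-Carlo only (block-level exact
# enumeration available when the number of blocks is small).
block_exchange_p <- function(g, df, terms, i, blocks, total_ss, n, n_perm,
                             f_obs) {
  tm <- terms[i]
  block_ids <- levels(blocks)
  block_val <- vapply(block_ids,
                      function(b) as.character(df[[tm]][blocks == b][1]), "")
  perm_f <- function(vals) {
    df2 <- df
    df2[[tm]] <- factor(vals[as.character(blocks)],
                        levels = levels(factor(block_val)))
    if (length(unique(df2[[tm]])) < 2L) return(NA_real_)
    ch <- design_chain(df2, terms)
    if (any(diff(ch$rank) == 0L)) return(NA_real_)
    seq_stats(chain_traces(g, ch), ch$rank, total_ss, n)$f[i]
  }
  if (identical(n_perm, "exact")) {
    pm <- all_permutations(length(block_ids))
    fs <- apply(pm, 1, function(ord) {
      v <- block_val[ord]; names(v) <- block_ids; perm_f(v)
    })
    fs <- fs[!is.na(fs)]
    sum(fs >= f_obs - 1e-12) / length(fs)
  } else {
    exc <- 0L; used <- 0L
    for (r in seq_len(n_perm)) {
      v <- block_val[sample.int(length(block_ids))]
      names(v) <- block_ids
      f <- perm_f(v)
      if (!is.na(f)) {
        used <- used + 1L
        if (f >= f_obs - 1e-12) exc <- exc + 1L
      }
    }
    (1 + exc) / (1 + used)
  }
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (sequential SS)")
  if (!is.null(attr(x, "strata"))) cat(", strata:", attr(x, "strata"))
  cat(", permutations:", format(attr(x, "n_perm")), "\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  for (nt in attr(x, "notes")) cat("note:", nt, "\n")
  invisible(x)
}

#' Paper-style variance-partition suites
#'
#' Runs the standard analysis models on a preprocessed study:
#' * `pooled` — healthy-control + nonlesional samples, terms in the order
#'   status, depth, time, participant. Disease status is constant within a
#'   participant, so it must precede the participant term in a sequential
#'   partition (after participant it spans no new contrasts and the design
#'   is singular); interindividual variation, entered last, absorbs the
#'   remaining between-participant variance;
#' * `status_by_depth` — for each depth separately, status with participant
#'   strata;
#' * optional severity models on nonlesional samples per depth: `oscorad`
#'   and `filaggrin` (participant strata), and `location` on lesional
#'   samples.
#' Sample subsets are taken before distance computation.
#'
#' @param table normalized [asv_table()].
#' @param meta aligned metadata.
#' @param n_perm permutations per model.
#' @param seed RNG seed.
#' @param metric distance metric (see [compute_distance()]).
#' @param severity_models also fit the oscorad/filaggrin/location models
#'   where the relevant covariates are present (default FALSE).
#' @return named list of `permanova_result` objects.
#' @export
run_variance_partition <- function(table, meta, n_perm = 999, seed = NULL,
                                   metric = "bray_curtis",
                                   severity_models = FALSE) {
  meta <- meta[!meta$is_negative_control, , drop = FALSE]
  meta$timepoint <- factor(meta$timepoint)   # visits are categories, not a trend
  fit <- function(ids, terms, strata = NULL, sub_seed_off = 0L) {
    sub <- subset_asv_table(table, samples = ids)
    d <- compute_distance(sub, metric)
    permanova(d, meta, terms, n_perm = n_perm, strata = strata,
              seed = if (is.null(seed)) NULL else seed + sub_seed_off)
  }
  out <- list()
  pooled_ids <- meta$sample_id[meta$skin_status %in% c("HC", "NLS")]
  out$pooled <- fit(pooled_ids,
                    c("cohort", "depth", "timepoint", "participant_id"))
  for (dp in unique(meta$depth[meta$sample_id %in% pooled_ids])) {
    ids <- meta$sample_id[meta$skin_status %in% c("HC", "NLS") &
                          meta$depth == dp]
    out[[paste0("status_", dp)]] <-
      fit(ids, "cohort", strata = "participant_id",
          sub_seed_off = match(dp, .depth_levels))
  }
  if (severity_models) {
    nls <- meta[meta$skin_status == "NLS" & !is.na(meta$oscorad), , drop = FALSE]
    for (dp in unique(nls$depth)) {
      ids <- nls$sample_id[nls$depth == dp]
      if (length(ids) >= 3L) {
        out[[paste0("oscorad_nls_", dp)]] <-
          fit(ids, "oscorad", strata = "participant_id", sub_seed_off = 10L)
      }
    }
    fil <- meta[meta$skin_status == "NLS" & !is.na(meta$filaggrin_mutation), ,
                drop = FALSE]
    for (dp in unique(fil$depth)) {
      ids <- fil$sample_id[fil$depth == dp]
      if (length(ids) >= 3L &&
          length(unique(fil$filaggrin_mutation[fil$depth == dp])) > 1L) {
        out[[paste0("filaggrin_nls_", dp)]] <-
          fit(ids, "filaggrin_mutation", strata = "participant_id",
              sub_seed_off = 20L)
      }
    }
    les <- meta[meta$skin_status == "LS", , drop = FALSE]
    for (dp in unique(les$depth)) {
      ids <- les$sample_id[les$depth == dp]
      if (length(ids) >= 3L &&
          length(unique(les$body_location[les$depth == dp])) > 1L) {
        out[[paste0("location_ls_", dp)]] <-
          fit(ids, "body_location", strata = "participant_id",
              sub_seed_off = 30L)
      }
    }
  }
  out
}
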