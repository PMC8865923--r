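#' Statistical primitives
#'
#' Self-contained implementations of the rank test, FDR correction, paired
#' t test and (mixed) linear models used across the pipeline. Each returns
#' a light `dd_test` record (statistic, p, n, flags) so callers can carry
#' degeneracy information (ties, zero variance, singular fits) alongside
#' the numbers.
#'
#' @name inference
NULL

new_test <- function(statistic, statistic_name, p_value, n,
                     flags = character(0), q_value = NA_real_) {
  structure(list(statistic = statistic, statistic_name = statistic_name,
                 p_value = p_value, q_value = q_value, n = n, flags = flags),
            class = "dd_test")
}

#' @export
print.dd_test <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (n = %d%s)\n", x$statistic_name,
              x$statistic, x$p_value, x$n,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' H = 12/(N(N+1)) * sum R_j^2/n_j - 3(N+1), corrected for ties by dividing
#' by 1 - sum(t^3 - t)/(N^3 - N); p from the chi-square approximation with
#' k - 1 degrees of freedom.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return a `dd_test` (statistic H).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("each group must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 3L) stop("need total n >= 3", call. = FALSE)
  g <- rep(seq_along(groups), sizes)
  r <- rank(x)
  rsum <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  flags <- character(0)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) {            # all observations identical
    h <- 0
    flags <- "zero_variance"
  } else {
    if (any(ties > 1)) flags <- "ties"
    h <- h / tie_corr
  }
  p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  new_test(h, "H", p, n, flags)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up q-values: q_i = min over j with p_(j) >= p_(i) of m * p_(j) /
#' rank(j), capped at 1. Input order is preserved; NAs stay NA and do not
#' count toward m.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must be in [0, 1]",
                                             call. = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(q)
  ord <- ok[order(p[ok])]
  qs <- p[ord] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  q[ord] <- pmin(qs, 1)
  q
}

#' Paired t test
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on d = x - y, two-sided p from the t
#' distribution with n - 1 degrees of freedom. Zero-variance differences
#' give a `zero_variance` flag and a missing p.
#'
#' @param x,y equal-length numeric vectors (n >= 3), paired by position.
#' @return a `dd_test` (statistic t).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  d <- x - y
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) {
    return(new_test(NA_real_, "t", NA_real_, n, "zero_variance"))
  }
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  new_test(t, "t", p, n)
}

#' Linear / random-intercept model for diversity responses
#'
#' Gaussian least-squares fit of a per-sample response (e.g. ASV richness
#' or Shannon diversity) on design factors, optionally with a
#' participant-level random intercept (maximum likelihood). Aliased design
#' columns are dropped and reported; a singular random-intercept fit (e.g.
#' one observation per group) is flagged and refit by plain least squares.
#'
#' @param response numeric vector, one value per row of `data`.
#' @param data data frame of covariates.
#' @param fixed character vector of fixed-effect columns.
#' @param random_intercept optional grouping column (e.g. participant_id).
#' @param family `"gaussian"` (default) or `"poisson"` — a count family for
#'   richness responses; the Gaussian fit is the default used throughout
#'   the pipeline.
#' @return list with `coefficients` (data frame term, estimate, se,
#'   statistic, p), `model` (`"lm"`, `"glm"`, `"lmer"` or `"glmer"`),
#'   `flags`, and `aliased` (dropped columns).
#' @export
diversity_model <- function(response, data, fixed, random_intercept = NULL,
                            family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  stopifnot(length(response) == nrow(data))
  df <- data[, intersect(names(data), c(fixed, random_intercept)), drop = FALSE]
  df$.y <- response
  flags <- character(0)
  fixed_part <- paste(fixed, collapse = " + ")
  use_lmer <- !is.null(random_intercept)
  if (use_lmer) {
    nobs <- table(df[[random_intercept]])
    if (all(nobs <= 1L)) {
      flags <- c(flags, "singular_fit")
      use_lmer <- FALSE
    }
  }
  if (use_lmer) {
    fml <- stats::as.formula(paste(".y ~", fixed_part,
                                   "+ (1 |", random_intercept, ")"))
    if (family == "gaussian") {
      fit <- lme4::lmer(fml, data = df, REML = FALSE)
      model <- "lmer"
    } else {
      fit <- lme4::glmer(fml, data = df, family = stats::poisson())
      model <- "glmer"
    }
    if (lme4::isSingular(fit)) flags <- c(flags, "singular_fit")
    cf <- stats::coef(summary(fit))
    stat <- cf[, 3]
    coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                        se = cf[, 2], statistic = stat,
                        p = 2 * stats::pnorm(-abs(stat)),
                        stringsAsFactors = FALSE)
    aliased <- character(0)
  } else {
    fml <- stats::as.formula(paste(".y ~", fixed_part))
    if (family == "gaussian") {
      fit <- stats::lm(fml, data = df)
      model <- "lm"
    } else {
      fit <- stats::glm(fml, data = df, family = stats::poisson())
      model <- "glm"
    }
    al <- is.na(stats::coef(fit))
    aliased <- names(al)[al]
    if (length(aliased)) flags <- c(flags, "aliased_columns_dropped")
    cf <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                        statistic = cf[, 3], p = cf[, 4],
                        stringsAsFactors = FALSE)
  }
  rownames(coefs) <- NULL
  list(coefficients = coefs, model = model, flags = unique(flags),
       aliased = aliased)
}
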