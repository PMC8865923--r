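# Internal helpers shared across modules.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so package functions never clobber the user's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a named pipeline stage, kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, preprocess = 211L, diversity = 307L,
               permanova = 401L, persistence = 503L, core = 601L,
               report = 701L)
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 7919 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..n as a matrix (n! rows); guard against blow-up.
all_permutations <- function(n, limit = 1e6) {
  if (factorial(n) > limit) {
    stop("exact enumeration would need ", format(factorial(n)),
         " arrangements (limit ", format(limit), ")", call. = FALSE)
  }
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L, limit = Inf)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  res <- do.call(rbind, out)
  storage.mode(res) <- "integer"
  res
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}
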