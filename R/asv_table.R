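#' ASV count/abundance table
#'
#' The central container of the pipeline: a samples-by-ASVs numeric matrix
#' with unique identifiers on both margins. Samples are always rows and ASVs
#' always columns. `value_kind` records whether the table holds raw sequence
#' counts or fourth-root-transformed relative abundances (in which case every
#' non-empty row must sum to 1).
#'
#' @param values numeric matrix, samples in rows (named), ASVs in columns
#'   (named); all entries must be non-negative and finite.
#' @param value_kind `"raw_counts"` or `"transformed_relabund"`.
#' @return an object of class `asv_table` wrapping the validated matrix.
#' @export
asv_table <- function(values, value_kind = c("raw_counts", "transformed_relabund")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L) stop("no samples", call. = FALSE)
  if (ncol(values) == 0L) stop("no ASVs", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("sample and ASV identifiers are required as dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate ASV identifiers", call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative or non-numeric value at sample '%s', ASV '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  }
  if (value_kind == "transformed_relabund") {
    rs <- rowSums(values)
    nz <- rs > 0
    if (any(abs(rs[nz] - 1) > 1e-9)) {
      stop("transformed_relabund rows must sum to 1 (tolerance 1e-9)", call. = FALSE)
    }
  }
  structure(list(values = values, value_kind = value_kind), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d samples x %d ASVs [%s]\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$values)

#' Sample and ASV identifiers of an [asv_table()]
#' @param x an `asv_table`.
#' @return character vector of identifiers, in table order.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
asv_ids <- function(x) colnames(x$values)

# Subset while preserving the class and value_kind; renormalization is the
# caller's business (dropping ASV columns from a relabund table invalidates
# row sums, so subsetting columns of a transformed table downgrades kind).
subset_asv_table <- function(x, samples = NULL, asvs = NULL) {
  v <- x$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(asvs)) v <- v[, asvs, drop = FALSE]
  kind <- x$value_kind
  if (!is.null(asvs) && kind == "transformed_relabund" &&
      ncol(v) != ncol(x$values)) {
    kind <- "raw_counts"   # no longer sums to 1; treat as plain non-negative
  }
  out <- asv_table(v, "raw_counts")
  out$value_kind <- kind
  out
}

#' Read an ASV table from disk
#'
#' TSV layout: first column `sample_id`, remaining columns one per ASV.
#' The BIOM variant reads the JSON (format 1.0) observation-by-sample matrix
#' and transposes it into the package's sample-major orientation.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom"`.
#' @return an [asv_table()] with `value_kind = "raw_counts"`.
#' @export
read_asv_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("no samples", call. = FALSE)
    if (ncol(df) < 2L) stop("no ASVs: need sample_id plus at least one ASV column",
                            call. = FALSE)
    if (names(df)[1] != "sample_id") {
      stop("malformed header: first column must be 'sample_id'", call. = FALSE)
    }
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      num <- suppressWarnings(array(as.numeric(m), dim(m)))
      bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
    }
    rownames(m) <- ids
    asv_table(m, "raw_counts")
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    need <- c("rows", "columns", "data", "matrix_type", "shape")
    if (!all(need %in% names(b))) stop("malformed BIOM file: missing fields", call. = FALSE)
    n_obs <- b$shape[1]; n_samp <- b$shape[2]
    if (n_samp == 0L) stop("no samples", call. = FALSE)
    m <- matrix(0, n_obs, n_samp)
    if (identical(b$matrix_type, "dense")) {
      m[] <- do.call(rbind, if (is.list(b$data)) b$data else list(b$data))
    } else {
      d <- if (is.list(b$data)) do.call(rbind, b$data) else b$data
      m[cbind(d[, 1] + 1, d[, 2] + 1)] <- d[, 3]
    }
    rownames(m) <- b$rows$id
    colnames(m) <- b$columns$id
    asv_table(t(m), "raw_counts")
  }
}

#' Write an ASV table to disk
#'
#' @param x an [asv_table()].
#' @param path output file.
#' @param format `"tsv"` (sample-major) or `"biom"` (JSON, format 1.0,
#'   sparse observation-major).
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(x, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "asv_table"))
  if (format == "tsv") {
    df <- data.frame(sample_id = sample_ids(x), x$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    m <- t(x$values)  # BIOM is observation-major
    idx <- which(m != 0, arr.ind = TRUE)
    data <- lapply(seq_len(nrow(idx)), function(i) {
      c(idx[i, 1] - 1, idx[i, 2] - 1, m[idx[i, 1], idx[i, 2]])
    })
    b <- list(
      id = "dermadiv", format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table", generated_by = "dermadiv",
      date = "1970-01-01T00:00:00",
      matrix_type = "sparse", matrix_element_type = "float",
      shape = dim(m),
      rows = data.frame(id = rownames(m), metadata = NA),
      columns = data.frame(id = colnames(m), metadata = NA),
      data = data
    )
    jsonlite::write_json(b, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

.metadata_cols <- c("sample_id", "participant_id", "cohort", "skin_status",
                    "depth", "timepoint", "body_location", "oscorad",
                    "filaggrin_mutation", "is_negative_control")
.depth_levels <- c("surface", "within")
.status_levels <- c("HC", "NLS", "LS")
.location_levels <- c("volar_forearm", "back", "elbow_crease", "inguinal",
                      "leg", "neck", "wrist")

#' Validate a sample-metadata data frame
#'
#' Checks the design-variable contract: categorical levels, timepoint range,
#' the cohort/skin-status consistency rule (`skin_status == "HC"` iff
#' `cohort == "HC"`), and that negative controls carry no participant-level
#' fields. Missing clinical covariates (oscorad, filaggrin) are allowed and
#' must be encoded as `NA`, never a sentinel number.
#'
#' @param meta data frame with the columns listed in [read_metadata()].
#' @param max_timepoint largest admissible visit number (default 4).
#' @return the validated data frame (types coerced), invisibly classed.
#' @export
validate_metadata <- function(meta, max_timepoint = 4) {
  missing_cols <- setdiff(.metadata_cols, names(meta))
  if (length(missing_cols)) {
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id", call. = FALSE)
  meta$is_negative_control <- as.logical(meta$is_negative_control)
  if (anyNA(meta$is_negative_control)) stop("is_negative_control must be TRUE/FALSE",
                                            call. = FALSE)
  real <- !meta$is_negative_control
  chk_levels <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) stop("unknown ", what, " level: ", x[bad][1], call. = FALSE)
  }
  chk_levels(meta$depth[real], .depth_levels, "depth")
  chk_levels(meta$cohort[real], c("AD", "HC"), "cohort")
  chk_levels(meta$skin_status[real], .status_levels, "skin_status")
  chk_levels(meta$body_location[real], .location_levels, "body_location")
  tp <- suppressWarnings(as.integer(meta$timepoint))
  if (any(real & (is.na(tp) | tp < 1 | tp > max_timepoint))) {
    stop("timepoint out of range (1-", max_timepoint, ")", call. = FALSE)
  }
  meta$timepoint <- tp
  hc_mismatch <- real & ((meta$skin_status == "HC") != (meta$cohort == "HC"))
  if (any(hc_mismatch)) {
    stop("skin_status 'HC' must coincide with cohort 'HC' (sample ",
         meta$sample_id[hc_mismatch][1], ")", call. = FALSE)
  }
  meta$oscorad <- suppressWarnings(as.numeric(meta$oscorad))
  if (any(!is.na(meta$oscorad) & meta$oscorad < 0)) {
    stop("oscorad must be non-negative", call. = FALSE)
  }
  meta$filaggrin_mutation <- as.logical(meta$filaggrin_mutation)
  ctrl <- meta$is_negative_control
  has_participant <- !is.na(meta$participant_id) & nzchar(as.character(meta$participant_id))
  if (any(ctrl & has_participant)) {
    stop("negative controls must not carry participant-level fields", call. = FALSE)
  }
  meta
}

#' Read sample metadata from a TSV file
#'
#' Required columns: sample_id, participant_id, cohort (AD/HC), skin_status
#' (HC/NLS/LS), depth (surface/within, i.e. tape 1 / tape 5), timepoint
#' (1-4), body_location, oscorad, filaggrin_mutation, is_negative_control.
#' Empty fields are read as missing.
#'
#' @inheritParams validate_metadata
#' @param path TSV file.
#' @return validated data frame of per-sample design variables.
#' @export
read_metadata <- function(path, max_timepoint = 4) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_metadata(meta, max_timepoint = max_timepoint)
}

#' Write sample metadata to TSV
#' @param meta validated metadata data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Read a taxonomy table
#'
#' Accepts either seven rank columns (domain..species; species optional) or a
#' single semicolon-delimited `lineage` column. Unassigned ranks may be empty.
#'
#' @param path TSV with first column `asv_id`.
#' @return data frame with columns asv_id plus the seven ranks (NA where
#'   unassigned).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"asv_id" %in% names(df)) stop("taxonomy needs an 'asv_id' column", call. = FALSE)
  if ("lineage" %in% names(df)) {
    parts <- strsplit(ifelse(is.na(df$lineage), "", df$lineage), ";", fixed = TRUE)
    m <- t(vapply(parts, function(p) {
      p <- trimws(p)
      c(p, rep(NA_character_, 7 - length(p)))[1:7]
    }, character(7)))
    colnames(m) <- .tax_ranks
    df <- data.frame(asv_id = df$asv_id, m, stringsAsFactors = FALSE)
  }
  need <- setdiff(.tax_ranks[1:6], names(df))
  if (length(need)) stop("taxonomy missing ranks: ", paste(need, collapse = ", "),
                         call. = FALSE)
  if (!"species" %in% names(df)) df$species <- NA_character_
  if (anyDuplicated(df$asv_id)) stop("duplicate asv_id in taxonomy", call. = FALSE)
  df <- df[, c("asv_id", .tax_ranks)]
  df[] <- lapply(df, as.character)
  df
}

#' Write a taxonomy table to TSV
#' @param tax taxonomy data frame as returned by [read_taxonomy()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Align an ASV table with its sample metadata
#'
#' Harmonizes sample order (table order wins), drops and reports samples
#' present in only one input, and drops all-zero samples with a warning
#' (samples that failed sequencing carry no information).
#'
#' @param table an [asv_table()].
#' @param meta validated metadata.
#' @param drop_empty drop all-zero samples (default TRUE).
#' @return list with elements `table`, `meta` (aligned, same order) and
#'   `dropped` (identifiers removed from either side).
#' @export
align_samples <- function(table, meta, drop_empty = TRUE) {
  common <- intersect(sample_ids(table), meta$sample_id)
  if (length(common) == 0L) stop("zero overlapping samples", call. = FALSE)
  dropped <- union(setdiff(sample_ids(table), common),
                   setdiff(meta$sample_id, common))
  if (length(dropped)) {
    message("align_samples: dropped ", length(dropped),
            " unmatched sample(s): ", paste(dropped, collapse = ", "))
  }
  keep <- sample_ids(table)[sample_ids(table) %in% common]
  tab <- subset_asv_table(table, samples = keep)
  if (drop_empty) {
    empty <- rowSums(tab$values) == 0
    if (any(empty)) {
      warning("dropping ", sum(empty), " all-zero sample(s): ",
              paste(keep[empty], collapse = ", "), call. = FALSE)
      dropped <- union(dropped, keep[empty])
      keep <- keep[!empty]
      tab <- subset_asv_table(tab, samples = keep)
    }
  }
  meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(table = tab, meta = meta, dropped = dropped)
}
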