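# Internal helpers shared across modules.
#
# Feature tables travel through the package as tibbles: one `sample_id`
# character column plus one numeric column per feature. These helpers move
# between that representation and the plain matrix the numerics want.

# Convert a feature tibble to a numeric matrix with sample_id rownames.
ft_matrix <- function(table) {
  stopifnot(is.data.frame(table))
  if (!"sample_id" %in% names(table)) {
    abort("feature table must have a 'sample_id' column")
  }
  ids <- as.character(table$sample_id)
  if (anyDuplicated(ids)) abort("duplicate sample_id in feature table")
  feats <- setdiff(names(table), "sample_id")
  if (length(feats) == 0L) abort("feature table has no feature columns")
  m <- as.matrix(table[, feats, drop = FALSE])
  if (!is.numeric(m)) abort("feature columns must be numeric")
  rownames(m) <- ids
  m
}

# Convert a matrix (samples x features, rownames = sample ids) back.
ft_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
}

feature_ids <- function(table) setdiff(names(table), "sample_id")

# Check that a metadata tibble carries the handling columns we rely on.
check_meta <- function(meta, require_time = TRUE) {
  need <- c("sample_id", "subject_id", "temperature_c")
  if (require_time) need <- c(need, "time_h")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    abort(paste0("metadata missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  if (require_time && any(!is.finite(meta$time_h) | meta$time_h <= 0)) {
    abort("time_h must be finite and > 0")
  }
  invisible(meta)
}

# Align a metadata tibble to a feature table; error on unmatched samples.
align_meta <- function(table, meta, require_time = TRUE) {
  check_meta(meta, require_time = require_time)
  rep <- match_samples(table, meta)
  if (length(rep$only_table) || length(rep$only_meta)) {
    abort(paste0(
      "feature table and metadata sample ids do not match; ",
      length(rep$only_table), " only in table, ",
      length(rep$only_meta), " only in metadata"
    ))
  }
  meta[match(table$sample_id, meta$sample_id), , drop = FALSE]
}

# Deterministic sub-seed derivation, kept inside 32-bit range.
sub_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed)
  for (k in ks) s <- (s * 69069 + k) %% 2147483629
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
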