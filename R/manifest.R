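MANIFEST_COLUMNS <- c("image_id", "annotation_path", "spacing_source",
                      "true_code", "split")
SPLIT_TAGS <- c("train", "validation", "test", "unassigned")

validate_manifest <- function(manifest) {
  if (!is.data.frame(manifest) || !all(MANIFEST_COLUMNS %in% names(manifest))) {
    isz_error(sprintf("manifest must be a data frame with columns %s",
                      paste(MANIFEST_COLUMNS, collapse = ", ")),
              "implant_format_error")
  }
  if (anyDuplicated(manifest$image_id)) {
    isz_error("manifest image_ids must be unique", "implant_format_error")
  }
  bad <- !manifest$split %in% SPLIT_TAGS
  if (any(bad)) {
    isz_error(sprintf("invalid split tag(s): %s",
                      paste(unique(manifest$split[bad]), collapse = ", ")),
              "implant_format_error")
  }
  invisible(manifest)
}

#' Read a dataset manifest CSV
#'
#' A manifest lists one implant image per row with columns
#' `image_id,annotation_path,spacing_source,true_code,split`. Lines starting
#' with `#` are treated as comments. Missing split tags default to
#' `"unassigned"`.
#'
#' @param path Manifest CSV path.
#' @return Manifest data frame (all columns character).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    isz_error(sprintf("manifest not found: %s", path), "implant_format_error")
  }
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if ("split" %in% missing_cols) {
    df$split <- "unassigned"
    missing_cols <- setdiff(missing_cols, "split")
  }
  if (length(missing_cols)) {
    isz_error(sprintf("manifest '%s' lacks column(s): %s", path,
                      paste(missing_cols, collapse = ", ")),
              "implant_format_error")
  }
  df$split[!nzchar(df$split)] <- "unassigned"
  df$true_code[!nzchar(df$true_code)] <- NA_character_
  validate_manifest(df[MANIFEST_COLUMNS])
}

#' Write a dataset manifest CSV
#'
#' Deterministic CSV dialect: header row, comma separated, no quoting, LF
#' line endings; reading then writing a manifest is byte-stable. Optional
#' `meta` lines are emitted as leading `#` comments.
#'
#' @param manifest Manifest data frame.
#' @param path Destination path.
#' @param meta Optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, meta = NULL) {
  validate_manifest(manifest)
  out <- manifest[MANIFEST_COLUMNS]
  out$true_code[is.na(out$true_code)] <- ""
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  writeLines(paste(MANIFEST_COLUMNS, collapse = ","), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Stratified validation/test split of a manifest
#'
#' Tags `n_val_per_class` records of every size class as `validation` and
#' `n_test_per_class` as `test`, sampling without replacement under `seed`;
#' all remaining records become `train`. Equal per-class counts in the
#' held-out sets prevent class imbalance in evaluation (the study design
#' uses 20 + 20 per class on a 1320-image dataset, giving 960/180/180).
#'
#' @param manifest Manifest data frame with `true_code` set on every row.
#' @param n_val_per_class,n_test_per_class Held-out records per class.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return The manifest with its `split` column filled.
#' @export
stratified_split <- function(manifest, n_val_per_class = 20,
                             n_test_per_class = 20, seed = 1) {
  validate_manifest(manifest)
  n_val <- stopifnot_scalar_count(n_val_per_class, "n_val_per_class")
  n_test <- stopifnot_scalar_count(n_test_per_class, "n_test_per_class")
  if (anyNA(manifest$true_code)) {
    isz_error("stratified_split requires true_code on every record",
              "implant_config_error")
  }
  classes <- sort(unique(manifest$true_code))
  need <- n_val + n_test
  manifest$split <- "train"
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(manifest$true_code == cl)
      if (length(idx) < need) {
        isz_error(sprintf(
          "class %s has %d records; %d needed for validation + test",
          cl, length(idx), need), "implant_insufficiency_error")
      }
      take <- if (length(idx) == 1L) idx else sample(idx, need)
      manifest$split[take[seq_len(n_val)]] <- "validation"
      if (n_test > 0) {
        manifest$split[take[n_val + seq_len(n_test)]] <- "test"
      }
    }
  })
  manifest
}
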