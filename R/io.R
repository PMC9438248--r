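#' Read a per-batch feature table
#'
#' Expects delimited text (TSV by default; CSV accepted by extension or
#' `delim`), one header row of feature names, and sample ids in the first
#' column. Within a measured column, an empty cell or the censoring sentinel
#' (default `"NA"`) marks a left-censored entry; features the file does not
#' contain are simply unmeasured in the batch. Negative values, duplicate
#' names and non-numeric cells are rejected with their location.
#'
#' @param path File path.
#' @param batch_id Batch label; defaults to the file name without extension.
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @param sentinel String marking a censored entry (besides an empty cell).
#' @return A [raw_dataset()].
#' @export
read_dataset <- function(path, batch_id = NULL, delim = NULL, sentinel = "NA") {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  batch_id <- batch_id %||% sub("\\.[^.]*$", "", basename(path))
  tb <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE,
                          show_col_types = FALSE, name_repair = "minimal")
  if (ncol(tb) < 2) abort("file must have a sample-id column and at least one feature")
  samples <- as.character(tb[[1]])
  feats <- colnames(tb)[-1]
  if (anyDuplicated(feats)) {
    abort(sprintf("duplicate feature name(s) in header: %s",
                  paste(unique(feats[duplicated(feats)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  raw <- as.matrix(tb[, -1, drop = FALSE])
  cens <- raw == "" | raw == sentinel
  vals <- suppressWarnings(array(as.numeric(raw), dim(raw)))
  bad <- which(is.na(vals) & !cens, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell '%s' at sample '%s', feature '%s'",
                  raw[bad[1, 1], bad[1, 2]], samples[bad[1, 1]], feats[bad[1, 2]]))
  }
  neg <- which(!is.na(vals) & vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("negative value at sample '%s', feature '%s'",
                  samples[neg[1, 1]], feats[neg[1, 2]]))
  }
  vals[cens] <- NA_real_
  dimnames(vals) <- list(samples, feats)
  dimnames(cens) <- dimnames(vals)
  raw_dataset(vals, batch_id = batch_id, censored = cens)
}

#' Harmonize feature names against a mapping table
#'
#' Renames a batch's features to canonical metabolite names via a
#' source-to-canonical table (many sources may share one canonical name
#' across batches). Two features of the *same* batch mapping to one canonical
#' name is a collision and an error.
#'
#' @param ds A [raw_dataset()].
#' @param table Data frame with columns `source` and `canonical` (first two
#'   columns used), or a named character vector `c(source = canonical)`.
#' @param unmapped `"keep"` passes unmapped features through unchanged;
#'   `"error"` rejects them.
#' @return The dataset with canonical feature names.
#' @export
harmonize <- function(ds, table, unmapped = c("keep", "error")) {
  unmapped <- match.arg(unmapped)
  if (is.data.frame(table)) {
    map <- setNames(as.character(table[[2]]), as.character(table[[1]]))
  } else {
    map <- table
  }
  if (anyDuplicated(names(map))) {
    abort("harmonization table maps a source name more than once")
  }
  old <- colnames(ds$values)
  hit <- old %in% names(map)
  if (unmapped == "error" && !all(hit)) {
    abort(sprintf("unmapped feature(s): %s", paste(old[!hit], collapse = ", ")))
  }
  new <- ifelse(hit, unname(map[old]), old)
  if (anyDuplicated(new)) {
    clash <- new[duplicated(new)][1]
    abort(sprintf("harmonization collision in batch '%s': features {%s} all map to '%s'",
                  ds$batch_id, paste(old[new == clash], collapse = ", "), clash))
  }
  colnames(ds$values) <- new
  colnames(ds$censored) <- new
  ds
}

#' Read a two-column harmonization (or annotation) table
#'
#' @param path TSV/CSV with two columns: source name, canonical name (or
#'   feature, pathway).
#' @return A tibble with the file's two columns.
#' @export
read_mapping <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
}

#' Write a matrix (aggregate, imputed, or factor) as delimited text
#'
#' Samples in rows with ids in the first column, feature names in the header;
#' unobserved entries are written as the missing sentinel so that
#' `read_matrix(write_matrix(x))` round-trips values, mask and labels.
#'
#' @param x An `aggregate_matrix`, `mirth_imputed`, or plain matrix.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param sentinel String written for unobserved entries.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delim = "\t", sentinel = "NA") {
  v <- if (is.matrix(x)) x else x$values
  tb <- tibble::as_tibble(v, rownames = "sample_id")
  readr::write_delim(tb, path, delim = delim, na = sentinel)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, delim = "\t") {
  tb <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- as.character(tb[[1]])
  m
}
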