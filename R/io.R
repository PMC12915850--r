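#' Read a merged taxonomic profile table
#'
#' Reads a tab-separated relative-abundance table in the merged-table dialect
#' produced by MetaPhlAn-style profilers: an optional block of comment lines
#' starting with `#`, a header row, a leading clade-name column, and one
#' column per sample (or the transpose). When clade strings with rank
#' prefixes (`k__ ... s__`) are detected, only species-level rows — those
#' whose deepest rank prefix is `s__` — are retained.
#'
#' @param path Path to a TSV file.
#' @param orientation `"taxa_in_rows"` (the merged-table default: one row per
#'   taxon, one column per sample) or `"samples_in_rows"`.
#' @param unit `"percent"` (MetaPhlAn convention, values 0–100; converted to
#'   fractions on ingest) or `"fraction"` (values already in `[0, 1]`).
#' @return A tibble with `sample_id` first and one column per taxon, values
#'   as fractions — the `profiles` slot of an [mgba_dataset()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("clade_name\ts1\ts2",
#'              "k__Bacteria|s__Alpha\t60\t20",
#'              "k__Bacteria|s__Beta\t40\t80"), tf)
#' read_profile_table(tf)
#' @export
read_profile_table <- function(path,
                               orientation = c("taxa_in_rows", "samples_in_rows"),
                               unit = c("percent", "fraction")) {
  orientation <- match.arg(orientation)
  unit <- match.arg(unit)
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) stop("profile table needs a name column plus data", call. = FALSE)
  row_names <- as.character(raw[[1]])
  col_names <- names(raw)[-1]
  if (anyDuplicated(row_names)) {
    stop("duplicate names in first column: ",
         paste(unique(row_names[duplicated(row_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(col_names)) {
    stop("duplicate column names: ",
         paste(unique(col_names[duplicated(col_names)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) stop("non-numeric abundance cells", call. = FALSE)
  rownames(m) <- row_names
  if (orientation == "taxa_in_rows") m <- t(m)
  # now samples x taxa
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  taxa <- colnames(m)
  if (any(grepl("__", taxa))) {
    m <- m[, species_level(taxa), drop = FALSE]
    if (ncol(m) == 0) stop("no species-level ('s__') rows found", call. = FALSE)
  }
  if (unit == "percent") m <- m / 100
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}

## TRUE for clade strings whose deepest rank prefix is species level.
## Plain names without rank prefixes are kept (assumed already species).
species_level <- function(taxa) {
  has_rank <- grepl("[a-z]__", taxa)
  deepest <- vapply(strsplit(taxa, "|", fixed = TRUE), function(parts) {
    last <- parts[length(parts)]
    sub("^([a-z])__.*$", "\\1", last)
  }, character(1))
  # subspecies markers ("t__") are below species; exclude them too
  !has_rank | (has_rank & deepest == "s")
}

#' Write a profile table
#'
#' Inverse of [read_profile_table()]; writes the same TSV dialect.
#'
#' @param profiles A profiles tibble (or an `mgba_dataset`, whose profiles
#'   are used).
#' @inheritParams read_profile_table
#' @param name_column Header of the leading clade/taxon column when writing
#'   taxa in rows.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path,
                                orientation = c("taxa_in_rows", "samples_in_rows"),
                                unit = c("percent", "fraction"),
                                name_column = "clade_name") {
  orientation <- match.arg(orientation)
  unit <- match.arg(unit)
  if (inherits(profiles, "mgba_dataset")) profiles <- profiles$profiles
  m <- as.matrix(profiles[setdiff(names(profiles), "sample_id")])
  rownames(m) <- profiles$sample_id
  if (unit == "percent") m <- m * 100
  if (orientation == "taxa_in_rows") {
    out <- dplyr::bind_cols(tibble::tibble(!!name_column := colnames(m)),
                            tibble::as_tibble(t(m)))
  } else {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                            tibble::as_tibble(m))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a TSV of per-sample metadata. Missingness is preserved: cells equal
#' to `na_token` become `NA` and no record is dropped at read time — each
#' downstream analysis removes only the records missing a field it needs.
#'
#' @param path Path to a TSV with required columns `sample_id`, `study_id`,
#'   `disease` and `is_case`; recognised optional columns are `age`, `sex`,
#'   `bmi`, `read_count` and `unclassified_fraction`, and any additional
#'   columns are carried along as phenotype scores.
#' @param na_token String encoding missing values. Default `"NA"`.
#' @return A metadata tibble suitable for [mgba_dataset()].
#' @export
read_metadata <- function(path, na_token = "NA") {
  md <- readr::read_tsv(path, na = na_token, show_col_types = FALSE,
                        progress = FALSE)
  required <- c("sample_id", "study_id", "disease", "is_case")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  md$sample_id <- as.character(md$sample_id)
  md$study_id <- as.character(md$study_id)
  md$disease <- as.character(md$disease)
  md$is_case <- as.logical(md$is_case)
  for (col in intersect(c("age", "bmi", "read_count", "unclassified_fraction"),
                        names(md))) {
    md[[col]] <- as.numeric(md[[col]])
  }
  md
}

#' Write a sample metadata table
#'
#' @param samples A metadata tibble (or an `mgba_dataset`).
#' @param path Output TSV path.
#' @param na_token String used to encode missing values.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(samples, path, na_token = "NA") {
  if (inherits(samples, "mgba_dataset")) samples <- samples$samples
  readr::write_tsv(samples, path, na = na_token, progress = FALSE)
  invisible(path)
}
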