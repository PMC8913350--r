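# Validated delimited-table I/O. All pipeline tables are plain
# tab-separated text with a header row; reading validates the schema and
# reports coercion failures with row and column.

table_schemas <- function() {
  list(
    peak = list(
      numeric = c("concentration", "snr", "pq"),
      character = c("species_id", "class", "adduct", "sample_id", "genotype"),
      integer = "replicate"
    ),
    echo = list(
      numeric = c("heart_rate", "lvid_s", "lvid_d", "lvpw_s", "lvpw_d",
                  "lvaw_s", "lvaw_d", "lv_vol_s", "lv_vol_d"),
      character = c("animal_id", "genotype"),
      integer = character(0)
    ),
    grid = list(
      numeric = "grid_spacing",
      character = "field_id",
      integer = c("points_mito", "points_total")
    ),
    ct = list(
      numeric = c("ct_target", "ct_reference"),
      character = c("sample_id", "genotype"),
      integer = character(0)
    )
  )
}

read_checked <- function(path, schema, what) {
  if (!file.exists(path)) {
    abort_config(sprintf("input file does not exist: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- unlist(schema, use.names = FALSE)
  assert_columns(raw, required, what)
  extra <- setdiff(names(raw), required)
  if (length(extra) > 0) {
    rlang::warn(sprintf("extra column(s) preserved: %s",
                        paste(extra, collapse = ", ")))
  }
  for (col in c(schema$numeric, schema$integer)) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort_schema(sprintf(
        "malformed numeric value '%s' in column '%s', row %d of %s",
        raw[[col]][bad[1]], col, bad[1], path))
    }
    raw[[col]] <- if (col %in% schema$integer) as.integer(parsed) else parsed
  }
  attr(raw, "spec") <- NULL
  attr(raw, "problems") <- NULL
  class(raw) <- c("tbl_df", "tbl", "data.frame")
  raw
}

#' Read and write pipeline tables
#'
#' Typed, schema-validated readers and writers for the four pipeline table
#' kinds (lipid peaks, per-animal echo records, stereology grid counts,
#' qPCR Ct records). Files are tab-separated text with a header row;
#' write-then-read round-trips are lossless to full double precision.
#' Unknown extra columns are preserved with a warning; malformed numeric
#' cells raise an error naming the row and column.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a validated tibble; writers return `x` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_peak_table <- function(path) {
  read_checked(path, table_schemas()$peak, "peak table")
}

#' @rdname table_io
#' @export
read_echo_table <- function(path) {
  read_checked(path, table_schemas()$echo, "echo table")
}

#' @rdname table_io
#' @export
read_grid_counts <- function(path) {
  read_checked(path, table_schemas()$grid, "grid-count table")
}

#' @rdname table_io
#' @export
read_ct_table <- function(path) {
  read_checked(path, table_schemas()$ct, "Ct table")
}

#' @rdname table_io
#' @export
write_pipeline_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Write a class-level fold-change report
#'
#' Writes the wide report of [build_class_report()] as tab-separated text
#' with p-values printed to four decimal places.
#'
#' @param report Output of [build_class_report()].
#' @param path File path.
#' @return `report`, invisibly.
#' @export
write_class_report <- function(report, path) {
  out <- report
  for (col in grep("^p_", names(out), value = TRUE)) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         sprintf("%.4f", out[[col]]))
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(report)
}

#' Read back a class-level fold-change report
#'
#' @param path File path written by [write_class_report()].
#' @return A tibble with numeric fold-change and p-value columns.
#' @export
read_class_report <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("input file does not exist: %s", path))
  }
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  for (col in grep("^(p|fc)_", names(out), value = TRUE)) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out
}
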