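# On-disk formats: FASTA consensus sets, probe tables, intensity matrices
# with array metadata, and results tables. All writers emit deterministic
# row and column order so outputs are diffable.

PROBE_TABLE_COLUMNS <- c("probeset_id", "probe_id", "order_index", "sequence", "design_id")

validate_probe_table <- function(probes, arg = "probes") {
  assert_data_frame(probes, arg, PROBE_TABLE_COLUMNS)
  probes <- as_tibble(probes)
  probes$order_index <- as.integer(probes$order_index)
  if (nrow(probes) == 0L) {
    return(probes)
  }
  bad_len <- nchar(probes$sequence) != PROBE_LENGTH
  if (any(bad_len)) {
    first <- which(bad_len)[1L]
    abort_validation(sprintf(
      "probe %s has sequence length %d (expected %d)",
      probes$probe_id[first], nchar(probes$sequence[first]), PROBE_LENGTH
    ))
  }
  bad_alpha <- grepl("[^ACGT]", probes$sequence)
  if (any(bad_alpha)) {
    first <- which(bad_alpha)[1L]
    abort_validation(sprintf(
      "probe %s has characters outside the strict ACGT alphabet: %s",
      probes$probe_id[first], probes$sequence[first]
    ))
  }
  dup <- duplicated(probes$probe_id)
  if (any(dup)) {
    abort_validation(sprintf(
      "duplicate probe_id: %s", probes$probe_id[which(dup)[1L]]
    ))
  }
  if (any(is.na(probes$order_index) | probes$order_index < 1L)) {
    abort_validation("`order_index` must be integers >= 1")
  }
  probes
}

#' Read and write probe tables
#'
#' Probe tables are tab-separated with header columns `probeset_id`,
#' `probe_id`, `order_index`, `sequence`, `design_id`. Sequences must be
#' 25-mers over the strict ACGT alphabet; `order_index` gives the probe's
#' position within its probeset along the consensus. Writing then reading a
#' table is the identity; rows are written sorted by (probeset_id,
#' order_index, probe_id).
#'
#' @param path File path.
#' @return `read_probe_table()` returns a tibble of validated probe records
#'   (possibly empty). `write_probe_table()` returns `path` invisibly.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("probe table not found: %s", path))
  }
  probes <- readr::read_tsv(path,
    col_types = readr::cols(
      probeset_id = readr::col_character(),
      probe_id = readr::col_character(),
      order_index = readr::col_integer(),
      sequence = readr::col_character(),
      design_id = readr::col_character()
    )
  )
  validate_probe_table(probes, path)
}

#' @rdname read_probe_table
#' @param probes Data frame of probe records.
#' @export
write_probe_table <- function(probes, path) {
  probes <- validate_probe_table(probes)
  probes <- dplyr::arrange(probes, .data$probeset_id, .data$order_index, .data$probe_id)
  readr::write_tsv(probes[, PROBE_TABLE_COLUMNS], path)
  invisible(path)
}

#' Read and write consensus sequence sets (FASTA)
#'
#' Sequence ids are taken from the header token up to the first whitespace;
#' sequences are uppercased. Duplicate ids and empty sequences are rejected.
#' Round-tripping preserves (id, sequence).
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a tibble with columns `id` and `sequence`.
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("FASTA file not found: %s", path))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  dup <- duplicated(ids)
  if (any(dup)) {
    abort_validation(sprintf("duplicate FASTA id: %s", ids[which(dup)[1L]]))
  }
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    abort_validation(sprintf(
      "FASTA record %s has an empty sequence", ids[which(empty)[1L]]
    ))
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' @rdname read_fasta
#' @param consensus Data frame with columns `id` and `sequence`.
#' @export
write_fasta <- function(consensus, path) {
  assert_data_frame(consensus, "consensus", c("id", "sequence"))
  consensus <- dplyr::arrange(as_tibble(consensus), .data$id)
  set <- Biostrings::DNAStringSet(setNames(consensus$sequence, consensus$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

validate_intensity <- function(values, metadata) {
  assert_data_frame(values, "values", "probe_id")
  assert_data_frame(metadata, "metadata", c("array_id", "platform", "tissue", "replicate"))
  values <- as_tibble(values)
  metadata <- as_tibble(metadata)
  metadata$replicate <- as.integer(metadata$replicate)
  array_cols <- setdiff(names(values), "probe_id")
  if (length(array_cols) == 0L) {
    abort_validation("intensity table has no array columns")
  }
  if (anyDuplicated(values$probe_id)) {
    abort_validation("duplicate probe_id in intensity table")
  }
  if (!setequal(metadata$array_id, array_cols) ||
    nrow(metadata) != length(array_cols)) {
    abort_validation(
      "metadata rows must match intensity columns one-to-one by array_id"
    )
  }
  triple <- paste(metadata$platform, metadata$tissue, metadata$replicate)
  if (anyDuplicated(triple)) {
    abort_validation("(platform, tissue, replicate) triples must be unique")
  }
  for (col in array_cols) {
    bad <- which(!is.finite(values[[col]]) | values[[col]] <= 0)
    if (length(bad) > 0L) {
      abort_validation(sprintf(
        "non-positive intensity at probe %s, array %s",
        values$probe_id[bad[1L]], col
      ))
    }
  }
  # realign metadata to column order
  metadata <- metadata[match(array_cols, metadata$array_id), ]
  list(values = values, metadata = metadata)
}

#' Read and write probe-level intensity matrices
#'
#' Intensities are linear-scale, strictly positive fluorescence values in a
#' TSV with a `probe_id` column plus one column per array. A sidecar metadata
#' TSV carries one row per array with columns `array_id`, `platform`,
#' `tissue`, `replicate`; rows may appear in any order and are realigned to
#' the value columns by `array_id`. Writers sort rows by `probe_id` and
#' columns by `array_id`.
#'
#' @param values_path,metadata_path File paths for the value matrix and the
#'   array metadata table.
#' @return `read_intensity_matrix()` returns a list with elements `values`
#'   (tibble) and `metadata` (tibble, aligned to the value columns).
#' @export
read_intensity_matrix <- function(values_path, metadata_path) {
  for (p in c(values_path, metadata_path)) {
    if (!file.exists(p)) {
      abort_validation(sprintf("file not found: %s", p))
    }
  }
  values <- readr::read_tsv(values_path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()
  ))
  metadata <- readr::read_tsv(metadata_path, col_types = readr::cols(
    array_id = readr::col_character(),
    platform = readr::col_character(),
    tissue = readr::col_character(),
    replicate = readr::col_integer()
  ))
  validate_intensity(values, metadata)
}

#' @rdname read_intensity_matrix
#' @param matrix A list with elements `values` and `metadata`, as returned by
#'   [read_intensity_matrix()] or [simulate_intensities()].
#' @export
write_intensity_matrix <- function(matrix, values_path, metadata_path) {
  checked <- validate_intensity(matrix$values, matrix$metadata)
  values <- checked$values
  array_cols <- sort(setdiff(names(values), "probe_id"))
  values <- dplyr::arrange(values[, c("probe_id", array_cols)], .data$probe_id)
  metadata <- dplyr::arrange(checked$metadata, .data$array_id)
  readr::write_tsv(values, values_path)
  readr::write_tsv(metadata, metadata_path)
  invisible(values_path)
}

# Convert the wide values tibble to a numeric matrix with probe_id rownames.
intensity_as_matrix <- function(values) {
  m <- as.matrix(values[, setdiff(names(values), "probe_id"), drop = FALSE])
  rownames(m) <- values$probe_id
  m
}

matrix_as_intensity <- function(m) {
  out <- as_tibble(m)
  dplyr::bind_cols(tibble(probe_id = rownames(m)), out)
}
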