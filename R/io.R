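# File interchange: FASTA (reference), FASTQ (reads, Phred+33),
# TSV (manifest, tables), newick (phylogeny).

require_biostrings <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required for FASTA/FASTQ IO")
  }
}

#' Write / read a reference database as FASTA plus taxonomy TSV
#'
#' The FASTA holds `motu_id` headers and barcode sequences; the companion
#' TSV (same path with extension `.taxonomy.tsv`) holds the
#' `motu_id` to `family` mapping.
#'
#' @param db Reference database tibble.
#' @param path FASTA file path.
#' @return `path`, invisibly (writer); the reference tibble (reader).
#' @export
write_reference_fasta <- function(db, path) {
  require_biostrings()
  x <- Biostrings::DNAStringSet(setNames(db$sequence, db$motu_id))
  Biostrings::writeXStringSet(x, path)
  readr::write_tsv(db[, c("motu_id", "family")],
                   paste0(path, ".taxonomy.tsv"))
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  require_biostrings()
  x <- Biostrings::readDNAStringSet(path)
  tax_path <- paste0(path, ".taxonomy.tsv")
  fam <- if (file.exists(tax_path)) {
    tax <- readr::read_tsv(tax_path, show_col_types = FALSE)
    setNames(tax$family, tax$motu_id)[names(x)]
  } else {
    rep(NA_character_, length(x))
  }
  tibble::tibble(motu_id = names(x), family = unname(fam),
                 sequence = unname(as.character(x)))
}

#' Write / read reads as FASTQ (Phred+33)
#'
#' @param reads Read tibble (`id`, `sequence`, `quality`).
#' @param path FASTQ file path.
#' @return `path`, invisibly (writer); a read tibble (reader).
#' @export
write_reads_fastq <- function(reads, path) {
  require_biostrings()
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$id)),
    Biostrings::PhredQuality(reads$quality)
  )
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  require_biostrings()
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # harmless notice about dropped metadata columns
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble::tibble(
    id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write / read a tag manifest as TSV
#'
#' @param manifest Tag manifest tibble.
#' @param path TSV file path.
#' @return `path`, invisibly (writer); a manifest tibble (reader).
#' @export
write_manifest_tsv <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' @rdname write_manifest_tsv
#' @export
read_manifest_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Write / read a MOTU table as TSV (samples as rows, taxa as columns)
#'
#' The first three columns are `sample_id`, `species`, `is_negative`;
#' remaining columns are per-taxon counts.
#'
#' @param table A MOTU table.
#' @param path TSV file path.
#' @param resolution Resolution recorded when reading back.
#' @return `path`, invisibly (writer); a `motu_tbl` (reader).
#' @export
write_motu_tsv <- function(table, path) {
  wide <- table |>
    dplyr::select("sample_id", "species", "is_negative", "taxon", "count") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "count",
                       values_fill = 0)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_motu_tsv
#' @export
read_motu_tsv <- function(path, resolution = "motu") {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(
    wide, cols = -c("sample_id", "species", "is_negative"),
    names_to = "taxon", values_to = "count"
  )
  new_motu_table(long, resolution = resolution)
}
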