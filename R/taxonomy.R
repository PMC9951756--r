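# 100%-identity taxonomic assignment against a closed reference, and
# family-level aggregation.

#' Assign dereplicated sequences to reference MOTUs at 100% identity
#'
#' A query is assigned to a reference MOTU only when it matches a
#' reference sequence with 100% identity over its full length: exact
#' string equality, or (for truncated mini-barcode reads) exact
#' containment of the whole query within the reference when
#' `allow_containment` is on. Queries matching no reference are recorded
#' as unknown and excluded from the table; a query matching more than one
#' reference is an error (the reference must hold distinct barcodes).
#'
#' @param ds Dereplicated tibble (`sequence`, `sample_id`, `count`).
#' @param db Reference database tibble (`motu_id`, `family`, `sequence`).
#' @param manifest Optional tag manifest supplying the species label and
#'   negative-control flag per sample.
#' @param allow_containment Also match full-query substrings of a
#'   reference (default TRUE).
#' @return A MOTU table (`motu_tbl`) with a `family` column; excluded
#'   sequences and their totals are in the `"unknown"` attribute.
#' @export
assign_exact <- function(ds, db, manifest = NULL, allow_containment = TRUE) {
  if (nrow(db) == 0) abort("reference database is empty")
  if (anyDuplicated(db$sequence) > 0) {
    abort("reference database contains duplicate sequences")
  }
  queries <- unique(ds$sequence)
  hit <- match(queries, db$sequence)
  if (allow_containment) {
    for (i in which(is.na(hit))) {
      contained <- which(vapply(db$sequence, grepl, logical(1),
                                pattern = queries[i], fixed = TRUE))
      if (length(contained) > 1) {
        abort(sprintf(
          "query matches %d references with 100%% identity; reference is ambiguous",
          length(contained)
        ))
      }
      if (length(contained) == 1) hit[i] <- contained
    }
  }
  map <- tibble::tibble(sequence = queries,
                        motu_id = db$motu_id[hit])
  unknown <- ds |>
    dplyr::inner_join(dplyr::filter(map, is.na(.data$motu_id)),
                      by = "sequence") |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  assigned <- ds |>
    dplyr::inner_join(dplyr::filter(map, !is.na(.data$motu_id)),
                      by = "sequence") |>
    dplyr::group_by(.data$sample_id, .data$motu_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  if (!is.null(manifest)) {
    assigned <- assigned |>
      dplyr::left_join(
        dplyr::select(manifest, "sample_id", "species"),
        by = "sample_id"
      ) |>
      dplyr::mutate(is_negative = .data$species == "negative")
    # samples in the manifest with no assigned reads still exist (total 0)
    absent <- setdiff(manifest$sample_id, assigned$sample_id)
    if (length(absent) > 0 && nrow(assigned) > 0) {
      pad <- tibble::tibble(
        sample_id = absent,
        motu_id = assigned$motu_id[1],
        count = 0L,
        species = manifest$species[match(absent, manifest$sample_id)]
      )
      pad$is_negative <- pad$species == "negative"
      assigned <- dplyr::bind_rows(assigned, pad)
    }
  } else {
    assigned$species <- NA_character_
    assigned$is_negative <- FALSE
  }
  out <- assigned |>
    dplyr::rename(taxon = "motu_id")
  out <- new_motu_table(out, resolution = "motu")
  out <- attach_taxonomy(out, db)
  attr(out, "unknown") <- unknown
  out
}

#' Aggregate a MOTU table to family resolution
#'
#' Sums counts within each plant family per sample. Families are ordered
#' by descending dataset-wide count, ties broken lexicographically.
#'
#' @param table A MOTU-resolution table carrying a `family` column (see
#'   [attach_taxonomy()]).
#' @return A family-resolution MOTU table.
#' @export
aggregate_family <- function(table) {
  if (!"family" %in% names(table)) {
    abort("table has no `family` column; run attach_taxonomy() first")
  }
  if (anyNA(table$family)) abort("every retained MOTU needs a family label")
  agg <- table |>
    dplyr::group_by(.data$sample_id, .data$species, .data$is_negative,
                    .data$family) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::rename(taxon = "family")
  ord <- agg |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$taxon)
  new_motu_table(agg, resolution = "family", taxon_order = ord$taxon)
}
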