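# The central container: a long-format samples x taxa count table.
# Columns: sample_id, species, is_negative, taxon, count — a complete grid
# (every sample crossed with every retained taxon, zeros explicit), with a
# "resolution" attribute ("motu" or "family").

new_motu_table <- function(x, resolution = c("motu", "family"),
                           taxon_order = NULL) {
  resolution <- match.arg(resolution)
  x <- tibble::as_tibble(x)
  required <- c("sample_id", "species", "is_negative", "taxon", "count")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("MOTU table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(x$count < 0)) abort("counts must be non-negative")
  x <- tidyr::complete(
    x,
    tidyr::nesting(!!rlang::sym("sample_id"), !!rlang::sym("species"),
                   !!rlang::sym("is_negative")),
    !!rlang::sym("taxon"),
    fill = list(count = 0L)
  )
  if (is.null(taxon_order)) taxon_order <- sort(unique(x$taxon))
  x <- dplyr::arrange(x, .data$sample_id,
                      match(.data$taxon, taxon_order))
  attr(x, "resolution") <- resolution
  class(x) <- c("motu_tbl", class(x))
  x
}

#' Build a MOTU count table from a data frame
#'
#' Validates and completes a long-format samples x taxa count table so
#' that every sample x taxon combination is present (zeros explicit).
#'
#' @param x A data frame with columns `sample_id`, `species`,
#'   `is_negative`, `taxon`, `count`.
#' @param resolution `"motu"` or `"family"`.
#' @return A `motu_tbl` tibble.
#' @export
motu_table <- function(x, resolution = c("motu", "family")) {
  new_motu_table(x, resolution)
}

table_resolution <- function(table) {
  attr(table, "resolution") %||% "motu"
}

#' Per-sample read totals of a MOTU table
#'
#' @param table A MOTU table.
#' @return A tibble with `sample_id`, `species`, `is_negative`, `total`.
#' @export
sample_totals <- function(table) {
  table |>
    dplyr::group_by(.data$sample_id, .data$species, .data$is_negative) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
}

#' Widen a MOTU table into a samples x taxa matrix
#'
#' @param table A MOTU table.
#' @param proportions Divide each row by its total (zero-total rows stay 0).
#' @return A numeric matrix, rownames = sample ids, colnames = taxa.
#' @export
motu_matrix <- function(table, proportions = FALSE) {
  wide <- table |>
    dplyr::select("sample_id", "taxon", "count") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "count",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  if (proportions) {
    tot <- rowSums(m)
    m <- sweep(m, 1, pmax(tot, 1), "/")
  }
  m
}

#' Attach family taxonomy to a MOTU-resolution table
#'
#' @param table A MOTU table at MOTU resolution.
#' @param db Reference database tibble (`motu_id`, `family`).
#' @return The table with a `family` column (`"unknown"` where the MOTU is
#'   absent from the reference).
#' @export
attach_taxonomy <- function(table, db) {
  fam <- setNames(db$family, db$motu_id)
  table$family <- unname(fam[table$taxon])
  table$family[is.na(table$family)] <- "unknown"
  table
}

# drop taxa whose counts are zero everywhere, preserving class/attrs
drop_empty_taxa <- function(table) {
  keep <- table |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(tot = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$tot > 0)
  res <- table_resolution(table)
  out <- dplyr::filter(table, .data$taxon %in% keep$taxon)
  attr(out, "resolution") <- res
  out
}
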