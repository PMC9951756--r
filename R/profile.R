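# Diet profiles: per-sample relative-abundance thresholds and group-level
# relative read abundance (RRA).

#' Zero out low-relative-abundance counts
#'
#' Within each sample, counts whose share of that sample's total is
#' strictly below `threshold` are set to zero (the boundary survives:
#' a taxon at exactly the threshold is kept). Counts are not renormalised
#' — downstream proportions are recomputed from the surviving counts.
#' Taxa left with all-zero columns are dropped. `scope = "global"`
#' thresholds on each taxon's share of the dataset-wide total instead.
#'
#' @param table A MOTU table.
#' @param threshold Relative-abundance threshold as a fraction in `[0, 1)`
#'   (0.01 means 1%).
#' @param scope `"sample"` (default, per-sample proportions) or
#'   `"global"`.
#' @return A filtered MOTU table.
#' @export
#' @examples
#' # counts (990, 10): at the 1% threshold the 10-read taxon is exactly
#' # at the boundary and survives
apply_threshold <- function(table, threshold, scope = c("sample", "global")) {
  scope <- match.arg(scope)
  stopifnot(threshold >= 0, threshold < 1)
  res <- table_resolution(table)
  if (threshold == 0) return(table)
  if (scope == "sample") {
    out <- table |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(
        count = ifelse(
          sum(.data$count) > 0 &
            .data$count / pmax(sum(.data$count), 1) < threshold,
          0L, .data$count
        )
      ) |>
      dplyr::ungroup()
  } else {
    out <- table |>
      dplyr::group_by(.data$taxon) |>
      dplyr::mutate(taxon_total = sum(.data$count)) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        count = ifelse(.data$taxon_total / sum(.data$count) < threshold,
                       0L, .data$count)
      ) |>
      dplyr::select(-"taxon_total")
  }
  attr(out, "resolution") <- res
  drop_empty_taxa(out)
}

#' Compute group-level relative read abundance (RRA)
#'
#' For each species, the RRA of taxon i is the mean over that species'
#' samples of the taxon's within-sample read proportion, expressed as a
#' percentage:
#' \deqn{RRA_i = \frac{1}{S}\sum_{k=1}^{S} \frac{n_{i,k}}{\sum_i n_{i,k}}
#'   \times 100\%}
#' Samples with zero total are excluded from S with a warning. Each
#' profile sums to 100.
#'
#' @param table A MOTU table (negative controls, if still present, are
#'   ignored).
#' @param groups Species to profile; default all non-negative species.
#' @return A tibble `species`, `taxon`, `rra`, `n_samples` with a
#'   `resolution` attribute.
#' @export
compute_rra <- function(table, groups = NULL) {
  tab <- dplyr::filter(table, !.data$is_negative)
  if (is.null(groups)) groups <- unique(tab$species)
  tab <- dplyr::filter(tab, .data$species %in% groups)
  totals <- sample_totals(tab)
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0) {
    warn(sprintf("excluding %d zero-total sample(s): %s",
                 length(zero), paste(zero, collapse = ", ")))
    tab <- dplyr::filter(tab, !.data$sample_id %in% zero)
  }
  if (nrow(tab) == 0) abort("no samples with positive totals in the group(s)")
  out <- tab |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(prop = .data$count / sum(.data$count)) |>
    dplyr::group_by(.data$species, .data$taxon) |>
    dplyr::summarise(
      rra = 100 * mean(.data$prop),
      n_samples = dplyr::n_distinct(.data$sample_id),
      .groups = "drop"
    )
  attr(out, "resolution") <- table_resolution(table)
  out
}

#' Extract one group's RRA profile as a proportion vector
#'
#' @param rra Output of [compute_rra()].
#' @param group Species label.
#' @return Named numeric proportions (RRA / 100) over taxa.
#' @export
rra_props <- function(rra, group) {
  x <- rra[rra$species == group, ]
  if (nrow(x) == 0) abort(sprintf("no RRA profile for group '%s'", group))
  setNames(x$rra / 100, x$taxon)
}

#' Per-family between-species significance of diet proportions
#'
#' For every taxon (family), compares the per-sample read proportions of
#' the two species with a two-sided Wilcoxon rank-sum test (optionally a
#' Welch t-test). Stars follow the usual convention: `*` for
#' 0.01 < p < 0.05, `***` for p < 0.01.
#'
#' @param table A MOTU table (family resolution is typical).
#' @param groups Length-2 character vector of species.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return Tibble `taxon`, `p_value`, `signif`, `degenerate`.
#' @export
compare_family_rra <- function(table, groups = c("cattle", "sika_deer"),
                               test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(length(groups) == 2)
  tab <- table |>
    dplyr::filter(.data$species %in% groups, !.data$is_negative) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(prop = ifelse(sum(.data$count) > 0,
                                .data$count / sum(.data$count), 0)) |>
    dplyr::ungroup()
  n_per <- tab |>
    dplyr::distinct(.data$sample_id, .data$species) |>
    dplyr::count(.data$species)
  if (nrow(n_per) < 2 || any(n_per$n < 2)) {
    abort("both groups need at least 2 samples")
  }
  purrr::map_dfr(unique(tab$taxon), function(tx) {
    x <- tab$prop[tab$taxon == tx & tab$species == groups[1]]
    y <- tab$prop[tab$taxon == tx & tab$species == groups[2]]
    degenerate <- length(unique(c(x, y))) == 1
    p <- if (degenerate) {
      1
    } else if (test == "wilcoxon") {
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    } else {
      t.test(x, y)$p.value
    }
    tibble::tibble(
      taxon = tx,
      p_value = p,
      signif = if (p < 0.01) "***" else if (p < 0.05) "*" else "",
      degenerate = degenerate
    )
  })
}
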