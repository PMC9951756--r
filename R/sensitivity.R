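# Threshold-sensitivity sweep: re-run profile -> diversity -> overlap at a
# ladder of relative-abundance thresholds.

#' Sweep the relative-abundance threshold
#'
#' For each threshold in turn: zero out sub-threshold counts
#' ([apply_threshold()]), recompute the group RRA profiles, the taxonomic
#' diversity metrics per group, and the pairwise overlap between the two
#' focal species. The default ladder is the conventional 0.01%, 0.05%,
#' 0.1%, 0.5% and 1%.
#'
#' @param table A MOTU table (negatives removed).
#' @param thresholds Ascending fractions in `[0, 1)`.
#' @param groups Length-2 character vector of focal species.
#' @param null_test Also run the Pianka randomization null per threshold.
#' @param n_iter Null iterations when `null_test` is on.
#' @param seed Integer RNG seed for the nulls.
#' @return A `threshold_sweep` tibble: one row per threshold x group with
#'   `D0`, `D1`, `D2`, `B`, `B_A`, `J`, plus the pair-level `o_jk`,
#'   `bc_sim` (and `p_null` if requested) repeated on both rows.
#' @export
threshold_sweep <- function(table,
                            thresholds = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2),
                            groups = c("cattle", "sika_deer"),
                            null_test = FALSE, n_iter = 10000,
                            seed = NULL) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly increasing")
  }
  rows <- purrr::map_dfr(seq_along(thresholds), function(ti) {
    th <- thresholds[ti]
    tab <- apply_threshold(table, th)
    rra <- compute_rra(tab, groups)
    p_j <- rra_props(rra, groups[1])
    p_k <- rra_props(rra, groups[2])
    o_jk <- pianka(p_j, p_k)
    bc <- bray_curtis_similarity(p_j, p_k)
    p_null <- if (null_test) {
      pianka_null_test(rbind(p_j, p_k), n_iter = n_iter,
                       seed = if (is.null(seed)) NULL else seed + ti)$p_value
    } else {
      NA_real_
    }
    purrr::map_dfr(groups, function(g) {
      p <- rra_props(rra, g)
      h <- hill_numbers(p)
      lv <- levins(p)
      tibble::tibble(
        threshold = th, group = g,
        D0 = h[["D0"]], D1 = h[["D1"]], D2 = h[["D2"]],
        B = lv[["B"]], B_A = lv[["B_A"]], J = pielou(p),
        o_jk = o_jk, bc_sim = bc, p_null = p_null
      )
    })
  })
  class(rows) <- c("threshold_sweep", class(rows))
  rows
}

#' @export
autoplot.threshold_sweep <- function(object, ...) {
  long <- object |>
    dplyr::select("threshold", "group", "D0", "D1", "D2", "B_A", "J",
                  "o_jk", "bc_sim") |>
    tidyr::pivot_longer(cols = -c("threshold", "group"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(
      .data$metric, levels = c("D0", "D1", "D2", "B_A", "J", "o_jk", "bc_sim")
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$value, colour = .data$group
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10(
      labels = function(x) paste0(format(x * 100, drop0trailing = TRUE), "%")
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "relative-abundance threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked RRA composition plot
#'
#' Fig-3-style stacked bars of each species' family (or MOTU) RRA
#' profile, with taxa below `other_below` percent pooled into "Other".
#'
#' @param rra Output of [compute_rra()].
#' @param other_below Pool taxa with RRA below this percentage.
#' @return A ggplot object.
#' @export
plot_rra <- function(rra, other_below = 5) {
  dat <- rra |>
    dplyr::mutate(
      taxon = ifelse(.data$rra < other_below, "Other", .data$taxon)
    ) |>
    dplyr::group_by(.data$species, .data$taxon) |>
    dplyr::summarise(rra = sum(.data$rra), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$species, y = .data$rra, fill = .data$taxon
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative read abundance (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
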