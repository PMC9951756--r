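# Taxonomic and phylogenetic dietary-niche-breadth metrics.

#' Hill numbers of order 0, 1 and 2
#'
#' D0 is richness (number of taxa with positive proportion), D1 the
#' exponential of the Shannon index, D2 the inverse Simpson index.
#'
#' @param p Proportion vector (non-negative, sums to 1).
#' @return Named numeric vector `c(D0, D1, D2)`.
#' @export
#' @examples
#' hill_numbers(c(0.5, 0.25, 0.25))
hill_numbers <- function(p) {
  check_proportions(p)
  pos <- p[p > 0]
  shannon <- -sum(pos * log(pos))
  c(D0 = length(pos), D1 = exp(shannon), D2 = 1 / sum(pos^2))
}

#' Levins' niche breadth
#'
#' B = 1 / sum(p^2); the standardised form rescales to `[0, 1]`:
#' B_A = (B - 1) / (D0 - 1), defined as 1 when only one taxon is used.
#'
#' @param p Proportion vector.
#' @return Named numeric vector `c(B, B_A)`.
#' @export
levins <- function(p) {
  check_proportions(p)
  pos <- p[p > 0]
  B <- 1 / sum(pos^2)
  D0 <- length(pos)
  B_A <- if (D0 == 1) 1 else (B - 1) / (D0 - 1)
  c(B = B, B_A = B_A)
}

#' Pielou's evenness
#'
#' J = Shannon entropy / log(richness) = log(D1) / log(D0). Undefined for
#' a single-taxon profile (returned as NA).
#'
#' @param p Proportion vector.
#' @return Scalar in `[0, 1]`, or NA when richness is 1.
#' @export
pielou <- function(p) {
  check_proportions(p)
  pos <- p[p > 0]
  if (length(pos) == 1) return(NA_real_)
  -sum(pos * log(pos)) / log(length(pos))
}

#' Mean pairwise and mean nearest-taxon phylogenetic distance
#'
#' Abundance-weighted by default:
#' MPD = sum_{i != j} p_i p_j d_ij / sum_{i != j} p_i p_j and
#' MNTD = sum_i p_i min_{j != i} d_ij / sum_i p_i, with d_ij the patristic
#' distance on `tree`. Unweighted mode averages over distinct present
#' taxa instead.
#'
#' @param p Named proportion vector; names must be tip labels.
#' @param tree An [ape::phylo] tree containing every taxon with p > 0.
#' @param weighted Abundance-weighted (default) or presence-based.
#' @return Named numeric vector `c(MPD, MNTD)`.
#' @export
mpd_mntd <- function(p, tree, weighted = TRUE) {
  check_proportions(p)
  if (is.null(names(p))) abort("`p` must be named by tree tip labels")
  p <- p[p > 0]
  missing <- setdiff(names(p), tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("taxa missing from the tree: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(p) < 2) abort("need at least 2 taxa with positive proportion")
  d <- ape::cophenetic.phylo(tree)[names(p), names(p)]
  if (!weighted) p <- rep(1 / length(p), length(p))
  w <- outer(p, p)
  diag(w) <- 0
  mpd <- sum(w * d) / sum(w)
  nearest <- apply(d + diag(Inf, nrow(d)), 1, min)
  mntd <- sum(p * nearest) / sum(p)
  c(MPD = mpd, MNTD = mntd)
}

#' Standardised effect size against a tip-shuffle null
#'
#' Recomputes a phylogenetic metric after shuffling the tree's tip labels
#' uniformly at random (`n_null` times), then standardises the observed
#' value: ses = (obs - mean(null)) / sd(null). The p-value is the lower
#' tail rank of the observation among observation + nulls, ties counting
#' toward the observed tail, so p is always in \{1/(n+1), ..., 1\}.
#'
#' @param p Named proportion vector over tree tips.
#' @param tree An [ape::phylo] tree.
#' @param metric `"mpd"` or `"mntd"`.
#' @param n_null Number of tip shuffles (default 999).
#' @param weighted Abundance weighting, passed to [mpd_mntd()].
#' @param seed Integer RNG seed.
#' @return A tibble: `metric`, `obs`, `ses`, `p_value`, `n_null`
#'   (`ses` is NA when the null has zero variance).
#' @export
ses_phylo <- function(p, tree, metric = c("mpd", "mntd"), n_null = 999,
                      weighted = TRUE, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(n_null >= 1)
  pick <- if (metric == "mpd") 1L else 2L
  obs <- mpd_mntd(p, tree, weighted = weighted)[[pick]]
  # shuffling tip labels is equivalent to permuting which tips the diet's
  # taxa sit on; precompute the patristic matrix once and index into it
  d_full <- ape::cophenetic.phylo(tree)
  pos <- p[p > 0]
  if (!weighted) pos <- rep(1 / length(pos), length(pos))
  ntip <- ncol(d_full)
  k <- length(pos)
  w <- outer(pos, pos); diag(w) <- 0
  metric_on <- function(idx) {
    d <- d_full[idx, idx, drop = FALSE]
    if (pick == 1L) {
      sum(w * d) / sum(w)
    } else {
      nearest <- apply(d + diag(Inf, k), 1, min)
      sum(pos * nearest) / sum(pos)
    }
  }
  with_seed(seed, {
    nulls <- vapply(seq_len(n_null), function(i) {
      metric_on(sample.int(ntip, k))
    }, numeric(1))
  })
  s <- sd(nulls)
  ses <- if (s == 0) NA_real_ else (obs - mean(nulls)) / s
  p_value <- (1 + sum(nulls <= obs)) / (n_null + 1)
  tibble::tibble(metric = metric, obs = obs, ses = ses,
                 p_value = p_value, n_null = n_null)
}

#' Group-level dietary diversity report
#'
#' Computes, per species, the taxonomic metrics (D0, D1, D2, Pielou J,
#' Levins B and B_A) on the pooled RRA profile and — when a tree is given
#' — the abundance-weighted phylogenetic metrics (MPD, sesMPD, p; MNTD,
#' sesMNTD, p) under the tip-shuffle null. Because Levins B equals the
#' inverse Simpson index algebraically, B always matches D2 on the same
#' profile; B_A is additionally reported as the mean of the per-sample
#' standardised breadths (`B_A_sample_mean`), a convention some tables
#' use.
#'
#' @param table A MOTU table (negatives removed).
#' @param tree Optional [ape::phylo] tree (required for MPD/MNTD).
#' @param n_null Tip shuffles for the ses null (default 999).
#' @param seed Integer RNG seed for the null.
#' @return One row per species with the Table-2-shaped columns.
#' @export
diversity_report <- function(table, tree = NULL, n_null = 999, seed = NULL) {
  rra <- compute_rra(table)
  groups <- unique(rra$species)
  per_sample <- sample_diversity(table)
  purrr::map_dfr(seq_along(groups), function(gi) {
    g <- groups[gi]
    p <- rra_props(rra, g)
    h <- hill_numbers(p)
    lv <- levins(p)
    row <- tibble::tibble(
      species = g,
      D0 = h[["D0"]], D1 = h[["D1"]], D2 = h[["D2"]],
      J = pielou(p),
      B = lv[["B"]], B_A = lv[["B_A"]],
      B_A_sample_mean = mean(per_sample$B_A[per_sample$species == g],
                             na.rm = TRUE)
    )
    if (!is.null(tree)) {
      sub_seed <- if (is.null(seed)) NULL else seed + gi
      m1 <- ses_phylo(p, tree, "mpd", n_null = n_null, seed = sub_seed)
      m2 <- ses_phylo(p, tree, "mntd", n_null = n_null,
                      seed = if (is.null(sub_seed)) NULL else sub_seed + 1000L)
      row$MPD <- m1$obs; row$sesMPD <- m1$ses; row$p_MPD <- m1$p_value
      row$MNTD <- m2$obs; row$sesMNTD <- m2$ses; row$p_MNTD <- m2$p_value
      row$n_null <- n_null
    }
    row
  })
}

#' Per-sample dietary diversity
#'
#' Taxonomic metrics computed on each sample's own read proportions;
#' the per-sample distributions back the between-species significance
#' tests that a single pooled value cannot provide.
#'
#' @param table A MOTU table.
#' @return One row per positive-total sample: `sample_id`, `species`,
#'   `D0`, `D1`, `D2`, `J`, `B`, `B_A`.
#' @export
sample_diversity <- function(table) {
  tab <- dplyr::filter(table, !.data$is_negative)
  totals <- sample_totals(tab)
  keep <- totals$sample_id[totals$total > 0]
  purrr::map_dfr(keep, function(sid) {
    rows <- tab[tab$sample_id == sid, ]
    p <- as_props(rows$count)
    h <- hill_numbers(p)
    lv <- levins(p)
    tibble::tibble(
      sample_id = sid, species = rows$species[1],
      D0 = h[["D0"]], D1 = h[["D1"]], D2 = h[["D2"]],
      J = pielou(p), B = lv[["B"]], B_A = lv[["B_A"]]
    )
  })
}

#' Between-species tests on per-sample diversity
#'
#' Two-sided Wilcoxon rank-sum tests comparing the per-sample
#' distributions of each diversity metric between two species.
#'
#' @param table A MOTU table.
#' @param groups Length-2 character vector of species.
#' @return Tibble `metric`, `p_value`, `signif`.
#' @export
compare_sample_diversity <- function(table, groups = c("cattle", "sika_deer")) {
  sd_tab <- sample_diversity(table)
  metrics <- c("D0", "D1", "D2", "J", "B_A")
  purrr::map_dfr(metrics, function(m) {
    x <- sd_tab[[m]][sd_tab$species == groups[1]]
    y <- sd_tab[[m]][sd_tab$species == groups[2]]
    p <- if (length(unique(c(x, y))) == 1) {
      1
    } else {
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    }
    tibble::tibble(
      metric = m, p_value = p,
      signif = if (p < 0.01) "***" else if (p < 0.05) "*" else ""
    )
  })
}
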