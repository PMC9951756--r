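# Pairwise dietary overlap: Pianka's index with a randomization null, and
# Bray-Curtis similarity.

#' Pianka's niche overlap index
#'
#' O_jk = sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2)) on a shared,
#' identically ordered taxon set; 0 means disjoint resource use, 1
#' complete overlap. Symmetric in its arguments.
#'
#' @param p_j,p_k Proportion vectors over the same taxa.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' pianka(c(0.8, 0.2), c(0.2, 0.8)) # 0.32 / 0.68
pianka <- function(p_j, p_k) {
  check_proportions(p_j, "p_j")
  check_proportions(p_k, "p_k")
  if (length(p_j) != length(p_k)) {
    abort("p_j and p_k must be over the same taxon set")
  }
  sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2))
}

#' Bray-Curtis similarity
#'
#' 1 minus the Bray-Curtis dissimilarity
#' sum(|p_j - p_k|) / sum(p_j + p_k); for unit-sum inputs this equals
#' 1 - total-variation distance.
#'
#' @inheritParams pianka
#' @return Scalar in `[0, 1]`.
#' @export
bray_curtis_similarity <- function(p_j, p_k) {
  check_proportions(p_j, "p_j")
  check_proportions(p_k, "p_k")
  if (length(p_j) != length(p_k)) {
    abort("p_j and p_k must be over the same taxon set")
  }
  1 - sum(abs(p_j - p_k)) / sum(p_j + p_k)
}

#' Randomization null test for Pianka overlap
#'
#' Tests whether the observed overlap of a pair of diets exceeds chance
#' expectation by simulating random diets. The default RA3 algorithm
#' reshuffles each diet's proportions across taxa independently each
#' iteration (niche breadth retained, structure destroyed); RA1 redraws
#' every entry uniform(0,1), RA2 redraws only the non-zero entries, RA4
#' reshuffles only the non-zero entries. The p-value is upper-tail with
#' the add-one correction: p = (1 + #\{null >= obs\}) / (1 + n_iter).
#'
#' @param usage A 2 x T matrix (or data frame) of the two diets'
#'   proportions over a shared taxon set, rows = the focal pair.
#' @param n_iter Number of random diet matrices (default 10000).
#' @param algorithm `"RA3"` (default), `"RA1"`, `"RA2"` or `"RA4"`.
#' @param seed Integer RNG seed.
#' @return A `pianka_null` object: observed overlap, p-value, null
#'   summary. Use [tidy()]/[glance()] to extract.
#' @export
pianka_null_test <- function(usage, n_iter = 10000,
                             algorithm = c("RA3", "RA1", "RA2", "RA4"),
                             seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (n_iter < 1) abort("n_iter must be >= 1")
  usage <- as.matrix(usage)
  if (nrow(usage) != 2) {
    abort("`usage` must have exactly the 2 focal diets as rows")
  }
  a <- as_props(usage[1, ])
  b <- as_props(usage[2, ])
  o_obs <- pianka(a, b)
  t_ <- length(a)
  with_seed(seed, {
    nulls <- vapply(seq_len(n_iter), function(i) {
      ra <- randomize_diet(a, algorithm)
      rb <- randomize_diet(b, algorithm)
      sum(ra * rb) / sqrt(sum(ra^2) * sum(rb^2))
    }, numeric(1))
  })
  p <- (1 + sum(nulls >= o_obs)) / (1 + n_iter)
  structure(
    list(
      o_obs = o_obs, p_value = p, n_iter = n_iter, algorithm = algorithm,
      null_mean = mean(nulls), null_sd = sd(nulls),
      null_q = quantile(nulls, c(0.025, 0.5, 0.975), names = FALSE)
    ),
    class = "pianka_null"
  )
}

randomize_diet <- function(p, algorithm) {
  switch(
    algorithm,
    RA1 = runif(length(p)),
    RA2 = {
      out <- p
      out[p > 0] <- runif(sum(p > 0))
      out
    },
    RA3 = p[sample.int(length(p))],
    RA4 = {
      out <- p
      nz <- which(p > 0)
      out[nz] <- p[nz][sample.int(length(nz))]
      out
    }
  )
}

#' @export
print.pianka_null <- function(x, ...) {
  cat(sprintf(
    "Pianka overlap null test (%s, %d iterations)\n  O_obs = %.4f, p = %.4g (null mean %.4f, sd %.4f)\n",
    x$algorithm, x$n_iter, x$o_obs, x$p_value, x$null_mean, x$null_sd
  ))
  invisible(x)
}

#' @export
tidy.pianka_null <- function(x, ...) {
  tibble::tibble(
    estimate = x$o_obs, p.value = x$p_value,
    null.mean = x$null_mean, null.sd = x$null_sd,
    n.iter = x$n_iter, algorithm = x$algorithm
  )
}

#' @export
glance.pianka_null <- function(x, ...) tidy(x)

#' Pairwise overlap report for two species
#'
#' Computes the Pianka index with its randomization null and the
#' Bray-Curtis similarity on the two species' RRA profiles.
#'
#' @param table A MOTU table.
#' @param groups Length-2 character vector of species.
#' @param n_iter Null iterations for the Pianka test.
#' @param algorithm Randomization algorithm (see [pianka_null_test()]).
#' @param seed Integer RNG seed.
#' @return A tibble: `group_j`, `group_k`, `o_jk`, `p_null`, `n_iter`,
#'   `bc_sim`, `resolution`.
#' @export
overlap_report <- function(table, groups = c("cattle", "sika_deer"),
                           n_iter = 10000, algorithm = "RA3", seed = NULL) {
  rra <- compute_rra(table, groups)
  p_j <- rra_props(rra, groups[1])
  p_k <- rra_props(rra, groups[2])
  nt <- pianka_null_test(rbind(p_j, p_k), n_iter = n_iter,
                         algorithm = algorithm, seed = seed)
  tibble::tibble(
    group_j = groups[1], group_k = groups[2],
    o_jk = nt$o_obs, p_null = nt$p_value, n_iter = n_iter,
    bc_sim = bray_curtis_similarity(p_j, p_k),
    resolution = table_resolution(table)
  )
}
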