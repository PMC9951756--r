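# Between-group compositional testing: Bray-Curtis dissimilarity matrix,
# one-factor PERMANOVA, and NMDS by stress majorization.

#' Bray-Curtis dissimilarity matrix over samples
#'
#' D_kl = sum(|p_k - p_l|) / sum(p_k + p_l) on per-sample read
#' proportions. Zero-total samples are excluded with a warning.
#'
#' @param table A MOTU table (negatives are ignored).
#' @return A symmetric dissimilarity matrix with zero diagonal; sample
#'   species labels are kept in the `"labels"` attribute.
#' @export
bc_dissimilarity_matrix <- function(table) {
  tab <- dplyr::filter(table, !.data$is_negative)
  totals <- sample_totals(tab)
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0) {
    warn(sprintf("excluding %d zero-total sample(s)", length(zero)))
    tab <- dplyr::filter(tab, !.data$sample_id %in% zero)
  }
  m <- motu_matrix(tab, proportions = TRUE)
  if (nrow(m) < 2) abort("need at least 2 samples with positive totals")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(n - 1)) {
    for (l in (k + 1):n) {
      D[k, l] <- D[l, k] <-
        sum(abs(m[k, ] - m[l, ])) / sum(m[k, ] + m[l, ])
    }
  }
  meta <- dplyr::distinct(tab, .data$sample_id, .data$species)
  attr(D, "labels") <- setNames(meta$species, meta$sample_id)[rownames(m)]
  D
}

#' One-factor PERMANOVA on a dissimilarity matrix
#'
#' Partitions the dissimilarity-based sums of squares between and within
#' groups: SS_total = sum_{k<l} D_kl^2 / N, SS_within = sum over groups of
#' within-group pair sums divided by group size, pseudo-F =
#' (SS_between/(g-1)) / (SS_within/(N-g)). Significance is by random
#' permutation of the group labels, upper tail, with the add-one
#' correction.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param labels Group label per sample (defaults to the matrix's
#'   `"labels"` attribute).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer RNG seed.
#' @return A `permanova` object with [tidy()]/[glance()] methods.
#' @export
permanova <- function(d, labels = NULL, n_perm = 999, seed = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  labels <- labels %||% attr(d, "labels")
  if (is.null(labels)) abort("`labels` is required")
  labels <- as.character(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  sizes <- table(labels)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) abort("every group needs at least 2 samples")
  g <- length(sizes)
  d2 <- d^2

  ss_from <- function(lab) {
    # indicator matrix trick: within-group pair sums for all groups at once
    G <- outer(lab, sort(unique(lab)), "==") * 1
    within_pairsums <- diag(t(G) %*% d2 %*% G) / 2
    sum(within_pairsums / colSums(G))
  }
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- ss_from(labels)
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / (g - 1)) / (ss_within / (n - g))
  with_seed(seed, {
    f_null <- vapply(seq_len(n_perm), function(i) {
      lab <- labels[sample.int(n)]
      ssw <- ss_from(lab)
      ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
    }, numeric(1))
  })
  structure(
    list(
      pseudo_F = f_obs,
      R2 = ss_between / ss_total,
      p_value = (1 + sum(f_null >= f_obs)) / (1 + n_perm),
      n_perm = n_perm,
      df = c(between = g - 1L, residual = n - g),
      ss = c(between = ss_between, within = ss_within, total = ss_total)
    ),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
    x$df[["between"]], x$df[["residual"]], x$pseudo_F, x$R2, x$p_value,
    x$n_perm
  ))
  invisible(x)
}

#' @export
tidy.permanova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within", "total"),
    df = c(x$df[["between"]], x$df[["residual"]], sum(x$df)),
    sum.squares = unname(x$ss),
    statistic = c(x$pseudo_F, NA, NA),
    p.value = c(x$p_value, NA, NA)
  )
}

#' @export
glance.permanova <- function(x, ...) {
  tibble::tibble(
    pseudo.F = x$pseudo_F, R2 = x$R2, p.value = x$p_value,
    df.between = x$df[["between"]], df.residual = x$df[["residual"]],
    n.perm = x$n_perm
  )
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `k` dimensions by alternating
#' monotone (isotonic) regression of the configuration distances on the
#' dissimilarity ranks with a Guttman-transform update, minimising
#' stress-1 = sqrt(sum((d - dhat)^2) / sum(d^2)). The best of
#' `n_restarts` starts (first start from classical scaling, the rest
#' random) is returned; coordinates are centred.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param k Embedding dimensions (default 2).
#' @param n_restarts Number of starts (default 20).
#' @param max_iter Iterations per start.
#' @param tol Relative stress-improvement convergence tolerance.
#' @param ties Tied-dissimilarity handling in the monotone regression:
#'   `"primary"` (weak — tied dissimilarities may map to different fitted
#'   distances) or `"secondary"` (tied dissimilarities share one fitted
#'   distance).
#' @param seed Integer RNG seed.
#' @return An `nmds` object (coordinates, stress, convergence flag) with
#'   [tidy()]/[glance()]/[autoplot()] methods.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 200, tol = 1e-7,
                 ties = c("primary", "secondary"), seed = NULL) {
  ties <- match.arg(ties)
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) abort("k must be smaller than the number of samples")
  labels <- attr(d, "labels")
  lower <- which(lower.tri(d))
  delta <- d[lower]
  with_seed(seed, {
    runs <- lapply(seq_len(n_restarts), function(r) {
      x0 <- if (r == 1) {
        suppressWarnings(cmdscale(d, k = k))
      } else {
        matrix(rnorm(n * k), n, k)
      }
      if (ncol(x0) < k) {
        x0 <- cbind(x0, matrix(rnorm(n * (k - ncol(x0))) * 1e-4, n))
      }
      nmds_run(x0, delta, lower, n, k, max_iter, tol, ties)
    })
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "stress"))]]
  coords <- scale(best$x, center = TRUE, scale = FALSE)
  dimnames(coords) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(
    list(
      coordinates = coords, stress = best$stress, k = k,
      converged = best$converged, n_restarts = n_restarts,
      stress_trace = best$trace, labels = labels
    ),
    class = "nmds"
  )
}

# pool-adjacent-violators: weighted isotonic regression of y (already in
# the order to be respected)
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  vs <- numeric(n); ws <- numeric(n); cs <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    vs[m] <- y[i]; ws[m] <- w[i]; cs[m] <- 1L
    while (m > 1L && vs[m - 1L] > vs[m]) {
      tot <- ws[m - 1L] + ws[m]
      vs[m - 1L] <- (vs[m - 1L] * ws[m - 1L] + vs[m] * ws[m]) / tot
      ws[m - 1L] <- tot
      cs[m - 1L] <- cs[m - 1L] + cs[m]
      m <- m - 1L
    }
  }
  rep(vs[seq_len(m)], cs[seq_len(m)])
}

nmds_run <- function(x, delta, lower, n, k, max_iter, tol, ties) {
  config_dist <- function(x) {
    as.matrix(dist(x))[lower]
  }
  stress_of <- function(dvec, dhat) {
    sqrt(sum((dvec - dhat)^2) / sum(dvec^2))
  }
  block <- match(delta, sort(unique(delta)))
  monotone_fit <- function(dvec) {
    dhat <- numeric(length(dvec))
    if (ties == "primary") {
      # within tied blocks, follow the current distances (weak ties)
      ord <- order(delta, dvec)
      dhat[ord] <- pava(dvec[ord])
    } else {
      # tied dissimilarities share one fitted value
      means <- tapply(dvec, block, mean)
      sizes <- tabulate(block)
      fit <- pava(as.numeric(means), as.numeric(sizes))
      dhat <- fit[block]
    }
    dhat
  }
  dvec <- config_dist(x)
  dhat <- monotone_fit(dvec)
  stress <- stress_of(dvec, dhat)
  trace <- stress
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Guttman transform with target distances dhat
    B <- matrix(0, n, n)
    ratio <- ifelse(dvec > 0, dhat / dvec, 0)
    B[lower] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    x_new <- B %*% x / n
    dvec_new <- config_dist(x_new)
    dhat_new <- monotone_fit(dvec_new)
    stress_new <- stress_of(dvec_new, dhat_new)
    if (stress_new > stress + 1e-12) break # keep the monotone trace
    improved <- stress - stress_new
    x <- x_new; dvec <- dvec_new; dhat <- dhat_new; stress <- stress_new
    trace <- c(trace, stress)
    if (improved < tol * max(stress, 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(x = x, stress = stress, converged = converged, trace = trace)
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f, %sconverged, %d restarts\n",
              x$k, x$stress, if (x$converged) "" else "not ",
              x$n_restarts))
  invisible(x)
}

#' @export
tidy.nmds <- function(x, ...) {
  out <- tibble::as_tibble(x$coordinates)
  out$sample_id <- rownames(x$coordinates)
  if (!is.null(x$labels)) out$species <- unname(x$labels)
  dplyr::relocate(out, "sample_id")
}

#' @export
glance.nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, converged = x$converged,
                 n.restarts = x$n_restarts)
}

#' @export
autoplot.nmds <- function(object, ...) {
  dat <- tidy(object)
  aes <- if ("species" %in% names(dat)) {
    ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2, colour = .data$species)
  } else {
    ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      subtitle = sprintf("stress = %.2f", object$stress),
      x = "NMDS1", y = "NMDS2"
    ) +
    ggplot2::theme_minimal()
}
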