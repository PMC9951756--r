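test_that("Hill numbers match hand arithmetic and are monotone in q", {
  expect_equal(unname(hill_numbers(rep(0.25, 4))), c(4, 4, 4))
  expect_equal(unname(hill_numbers(1)), c(1, 1, 1))
  h <- hill_numbers(c(0.5, 0.25, 0.25))
  expect_equal(unname(h), c(3, exp(1.5 * log(2)), 1 / 0.375),
               tolerance = 1e-12)
  expect_equal(h[["D1"]], 2.8284, tolerance = 1e-4)
  expect_equal(h[["D2"]], 2.6667, tolerance = 1e-4)
  expect_error(hill_numbers(c(0, 0)), "zero")

  # property: D0 >= D1 >= D2 over random profiles
  set.seed(3)
  for (i in 1:25) {
    p <- as.numeric(rmultinom(1, 200, rgamma(8, 0.5) + 1e-9))
    p <- p[p > 0] / sum(p)
    h <- hill_numbers(p)
    expect_gte(h[["D0"]], h[["D1"]] - 1e-12)
    expect_gte(h[["D1"]], h[["D2"]] - 1e-12)
    # Levins B is the inverse Simpson index, identically
    expect_equal(levins(p)[["B"]], h[["D2"]], tolerance = 1e-12)
    # Pielou J = ln D1 / ln D0 whenever D0 >= 2
    if (h[["D0"]] >= 2) {
      expect_equal(pielou(p), log(h[["D1"]]) / log(h[["D0"]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("Levins breadth and Pielou evenness match closed forms", {
  expect_equal(unname(levins(rep(1 / 6, 6))), c(6, 1))
  expect_equal(unname(levins(1)), c(1, 1))
  lv <- levins(c(0.8, 0.2))
  expect_equal(lv[["B"]], 1 / 0.68, tolerance = 1e-12)
  expect_equal(lv[["B_A"]], 0.4706, tolerance = 1e-4)

  expect_equal(pielou(rep(0.2, 5)), 1)
  expect_equal(pielou(c(0.99, 0.01)), 0.0808, tolerance = 1e-4)
  expect_true(is.na(pielou(1)))
})

test_that("weighted MPD and MNTD agree with brute-force oracles", {
  # two taxa at patristic distance d: MPD = MNTD = d for any weights
  cherry <- ape::read.tree(text = "(a:2,b:3);")
  m <- mpd_mntd(c(a = 0.9, b = 0.1), cherry)
  expect_equal(unname(m), c(5, 5))

  # star tree with equal branches: every pairwise distance is 2b
  star <- ape::read.tree(text = "(a:1.5,b:1.5,c:1.5,d:1.5);")
  ms <- mpd_mntd(setNames(rep(0.25, 4), c("a", "b", "c", "d")), star)
  expect_equal(unname(ms), c(3, 3))

  # random 6-tip tree vs explicit all-pairs sums
  set.seed(8)
  tr <- ape::rtree(6)
  p <- setNames(as.numeric(rmultinom(1, 100, rep(1, 6))) / 100, tr$tip.label)
  p <- p[p > 0]
  d <- ape::cophenetic.phylo(tr)[names(p), names(p)]
  num <- 0; den <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i != j) {
        num <- num + p[i] * p[j] * d[i, j]
        den <- den + p[i] * p[j]
      }
    }
  }
  mntd_brute <- sum(p * vapply(seq_along(p), function(i) {
    min(d[i, -i])
  }, numeric(1)))
  obs <- mpd_mntd(p, tr)
  expect_equal(obs[["MPD"]], unname(num / den), tolerance = 1e-12)
  expect_equal(obs[["MNTD"]], unname(mntd_brute), tolerance = 1e-12)

  # unweighted mode equals weighted with uniform weights
  expect_equal(mpd_mntd(p, tr, weighted = FALSE),
               mpd_mntd(setNames(rep(1 / length(p), length(p)), names(p)), tr))

  # picante cross-check: its weighted MPD normalises by (sum p)^2,
  # ours by sum_{i!=j} p_i p_j = 1 - sum p^2
  skip_if_not_installed("picante")
  smp <- matrix(p, 1, dimnames = list("s", names(p)))
  expect_equal(obs[["MPD"]] * (1 - sum(p^2)),
               picante::mpd(smp, d, abundance.weighted = TRUE))
  expect_equal(obs[["MNTD"]],
               picante::mntd(smp, d, abundance.weighted = TRUE))

  expect_error(mpd_mntd(c(z = 1 / 2, a = 1 / 2), cherry), "missing")
})

test_that("ses is rank-based, scale-invariant, and degenerate-safe", {
  cherry <- ape::read.tree(text = "(a:2,b:3);")
  res <- ses_phylo(c(a = 0.5, b = 0.5), cherry, "mpd", n_null = 49, seed = 1)
  expect_true(is.na(res$ses)) # metric constant under relabeling
  expect_equal(res$p_value, 1)

  set.seed(4)
  tr <- ape::rcoal(10)
  p <- setNames(c(rep(0.2, 5), rep(0, 5)), tr$tip.label)
  r1 <- ses_phylo(p, tr, "mpd", n_null = 199, seed = 2)
  # p in {1/(n+1), ..., 1} exactly
  expect_true(r1$p_value %in% ((1:200) / 200))
  # branch-length scaling leaves ses and p unchanged
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 7.3
  r2 <- ses_phylo(p, tr2, "mpd", n_null = 199, seed = 2)
  expect_equal(r1$ses, r2$ses, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r2$obs, r1$obs * 7.3, tolerance = 1e-10)
})

test_that("a clade-confined diet on a family-clustered tree is clustered", {
  db <- generate_reference_db(18, 6, seed = 13)
  tree <- simulate_phylogeny(db, seed = 14, clustered_by_family = TRUE)
  fam <- names(which.max(table(db$family)))
  taxa <- db$motu_id[db$family == fam]
  p <- setNames(rep(1 / length(taxa), length(taxa)), taxa)
  res <- ses_phylo(p, tree, "mpd", n_null = 399, seed = 15)
  expect_lt(res$ses, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("group and per-sample diversity reports assemble coherently", {
  set.seed(21)
  tab <- random_group_table(n_per_group = 5, n_taxa = 8, depth = 600)
  db <- generate_reference_db(8, 4, seed = 16)
  # rename taxa to the db's motu ids so the tree applies
  tab$taxon <- db$motu_id[match(tab$taxon, sprintf("t%02d", 1:8))]
  tree <- simulate_phylogeny(db, seed = 17)
  rep <- diversity_report(tab, tree = tree, n_null = 99, seed = 18)
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$D0 >= rep$D1 & rep$D1 >= rep$D2))
  expect_equal(rep$B, rep$D2, tolerance = 1e-12)
  expect_true(all(rep$J >= 0 & rep$J <= 1))
  expect_true(all(rep$p_MPD > 0 & rep$p_MPD <= 1))

  ps <- sample_diversity(tab)
  expect_equal(nrow(ps), 10)
  expect_true(all(ps$B_A >= 0 & ps$B_A <= 1))

  cmp <- compare_sample_diversity(tab)
  expect_equal(nrow(cmp), 5)
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
})
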