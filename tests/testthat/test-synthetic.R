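test_that("reference db generation respects size, families and edit distance", {
  one <- generate_reference_db(1, 1, seq_length = 100, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(length(unique(one$family)), 1)

  db <- generate_reference_db(30, 10, seq_length = 100, seed = 7)
  expect_equal(nrow(db), 30)
  expect_equal(length(unique(db$motu_id)), 30)
  expect_equal(length(unique(db$family)), 10)
  expect_true(all(grepl("^[ACGT]+$", db$sequence)))
  d <- utils::adist(db$sequence)
  expect_gte(min(d[upper.tri(d)]), 3)

  expect_identical(db, generate_reference_db(30, 10, seq_length = 100, seed = 7))
  expect_error(
    generate_reference_db(300, 10, seq_length = 30, min_dist = 25,
                          max_rounds = 3, seed = 1),
    "too tight"
  )
})

test_that("tag manifests have the study shape and distance-3 tags", {
  man <- generate_tag_manifest(47, 32, 7, seed = 3)
  expect_equal(nrow(man), 86)
  expect_equal(sum(man$species == "cattle"), 47)
  expect_equal(sum(man$species == "sika_deer"), 32)
  expect_equal(sum(man$species == "negative"), 7)
  expect_true(all(nchar(man$forward_tag) == 7))
  expect_false(anyDuplicated(paste(man$forward_tag, man$reverse_tag)) > 0)
  # brute-force all-pairs Hamming check over the tag set
  tags <- unique(c(man$forward_tag, man$reverse_tag))
  pairs <- utils::combn(tags, 2)
  dists <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, pairs[1, ], pairs[2, ])
  expect_gte(min(dists), 3)

  two <- generate_tag_manifest(1, 1, 0, seed = 1)
  expect_equal(nrow(two), 2)
  expect_error(generate_tag_manifest(20, 20, 0, tag_length = 3, seed = 1,
                                     max_attempts = 500),
               "Hamming")
})

test_that("true diets are Dirichlet draws with analytic Pianka ground truth", {
  man <- generate_tag_manifest(3, 3, 0, seed = 1)
  alphas_same <- list(
    cattle = c(a = 5, b = 5), sika_deer = c(a = 5, b = 5)
  )
  sp <- diet_spec(alphas_same)
  tr <- sample_true_diets(sp, man, seed = 2)
  expect_equal(tr$true_overlap, 1)

  sp2 <- diet_spec(list(cattle = c(a = 1e-9, b = 5, c = 1e-9),
                        sika_deer = c(a = 5, b = 1e-9, c = 1e-9)))
  tr2 <- sample_true_diets(sp2, man, seed = 2)
  expect_equal(tr2$true_overlap, 0, tolerance = 1e-6)

  # hand arithmetic: means (0.8,0.2)/(0.2,0.8) -> 0.32/0.68
  sp3 <- diet_spec(list(cattle = c(a = 8, b = 2), sika_deer = c(a = 2, b = 8)))
  tr3 <- sample_true_diets(sp3, man, seed = 2)
  expect_equal(tr3$true_overlap, 0.32 / 0.68, tolerance = 1e-12)

  sums <- tr3$proportions |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(prop))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("read simulation matches its own count model and error rate", {
  st <- tiny_study(seed = 21)
  reads <- simulate_reads(st$truth, st$db, st$manifest, st$spec, seed = 5)
  tab <- simulate_motu_table(st$truth, st$spec, seed = 5)
  # read counts conserve the drawn depths exactly, per sample
  per_sample <- table(sub(":.*$", "", reads$id))
  totals <- sample_totals(tab)
  totals <- totals[totals$total > 0, ]
  expect_equal(as.numeric(per_sample[totals$sample_id]), totals$total)

  # error-free reads carry exact reference inserts
  pre <- nchar(st$manifest$forward_tag[1]) + nchar(psbcl_primers()[["forward"]])
  suf <- nchar(st$manifest$reverse_tag[1]) + nchar(psbcl_primers()[["reverse"]])
  inserts <- substr(reads$sequence, pre + 1, nchar(reads$sequence) - suf)
  expect_true(all(inserts %in% st$db$sequence))

  expect_identical(
    reads, simulate_reads(st$truth, st$db, st$manifest, st$spec, seed = 5)
  )

  # substitution rate: fraction of reads with >= 1 insert error near
  # 1 - (1 - e)^L within 3 binomial SEs
  e <- 0.002
  st2 <- tiny_study(seed = 22, error_rate = e, n_deer = 2, n_cattle = 2,
                    n_negatives = 0, mean_depth = 2500)
  reads2 <- simulate_reads(st2$truth, st2$db, st2$manifest, st2$spec, seed = 6)
  inserts2 <- substr(reads2$sequence, pre + 1, nchar(reads2$sequence) - suf)
  hit <- !inserts2 %in% st2$db$sequence
  L <- nchar(st2$db$sequence[1])
  expected <- 1 - (1 - e)^L
  se <- sqrt(expected * (1 - expected) / length(hit))
  expect_lt(abs(mean(hit) - expected), 3 * se)
})

test_that("direct MOTU-table simulation is multinomial and deterministic", {
  man <- generate_tag_manifest(1, 1, 0, seed = 1)
  sp <- diet_spec(list(cattle = c(a = 1, b = 1), sika_deer = c(a = 1, b = 1)),
                  mean_depth = 1e6, depth_dispersion = 1e9,
                  contamination_rate = 0)
  tr <- sample_true_diets(
    diet_spec(list(cattle = c(a = 5e5, b = 5e5),
                   sika_deer = c(a = 5e5, b = 5e5)),
              mean_depth = 1e6, depth_dispersion = 1e9,
              contamination_rate = 0),
    man, seed = 3
  )
  tab <- simulate_motu_table(tr, tr_spec <- diet_spec(
    list(cattle = c(a = 5e5, b = 5e5), sika_deer = c(a = 5e5, b = 5e5)),
    mean_depth = 1e6, depth_dispersion = 1e9, contamination_rate = 0
  ), seed = 4)
  m <- motu_matrix(tab)
  depth <- rowSums(m)
  # each count within 3 * sqrt(depth * 0.25) of depth/2
  expect_true(all(abs(m - depth / 2) <= 3 * sqrt(depth * 0.25)))
  expect_identical(tab, simulate_motu_table(tr, tr_spec, seed = 4))

  # zero-depth samples give all-zero rows
  sp0 <- diet_spec(list(cattle = c(a = 1, b = 1), sika_deer = c(a = 1, b = 1)),
                   mean_depth = 0, negative_depth = 0)
  tr0 <- sample_true_diets(sp0, man, seed = 1)
  tab0 <- simulate_motu_table(tr0, sp0, seed = 1)
  expect_true(all(tab0$count == 0))
})

test_that("simulated phylogenies are ultrametric with optional family clades", {
  db2 <- generate_reference_db(2, 1, seed = 2)
  tr2 <- simulate_phylogeny(db2, seed = 1)
  expect_setequal(tr2$tip.label, db2$motu_id)
  expect_equal(ape::Ntip(tr2), 2)

  db <- generate_reference_db(20, 6, seed = 4)
  tr <- simulate_phylogeny(db, seed = 9, clustered_by_family = TRUE)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  expect_setequal(tr$tip.label, db$motu_id)
  for (f in unique(db$family)) {
    taxa <- db$motu_id[db$family == f]
    if (length(taxa) > 1) {
      expect_true(ape::is.monophyletic(tr, taxa))
    }
  }
  expect_identical(
    ape::write.tree(tr),
    ape::write.tree(simulate_phylogeny(db, seed = 9,
                                       clustered_by_family = TRUE))
  )
})

test_that("paired-read emission reconstructs the merged read", {
  st <- tiny_study(seed = 31, n_deer = 2, n_cattle = 2, n_negatives = 0,
                   mean_depth = 60)
  merged <- simulate_reads(st$truth, st$db, st$manifest, st$spec, seed = 7)
  pair <- simulate_reads(st$truth, st$db, st$manifest, st$spec, seed = 7,
                         paired = TRUE, overlap = 30)
  remerged <- merge_pairs(pair$r1, pair$r2, min_overlap = 10)
  expect_equal(attr(remerged, "n_dropped"), 0)
  expect_equal(remerged$sequence, merged$sequence)
})
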