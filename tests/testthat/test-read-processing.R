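q40 <- function(n) strrep("I", n)

test_that("merge_pairs reconstructs templates and drops hopeless pairs", {
  template <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                    collapse = "")
  r1 <- tibble::tibble(id = "p1", sequence = substr(template, 1, 60),
                       quality = q40(60))
  r2 <- tibble::tibble(id = "p1", sequence = revcomp(substr(template, 41, 100)),
                       quality = q40(60))
  merged <- merge_pairs(r1, r2, min_overlap = 20)
  expect_equal(merged$sequence, template)
  expect_equal(attr(merged, "n_dropped"), 0)

  # identical full-overlap reads merge to themselves
  full <- tibble::tibble(id = "x", sequence = substr(template, 1, 80),
                         quality = q40(80))
  full_rc <- tibble::tibble(id = "x", sequence = revcomp(full$sequence),
                            quality = q40(80))
  expect_equal(merge_pairs(full, full_rc, min_overlap = 20)$sequence,
               full$sequence)

  # unrelated mates have no admissible overlap and are dropped
  noise <- tibble::tibble(id = "p1", sequence = strrep("A", 60),
                          quality = q40(60))
  noise2 <- tibble::tibble(id = "p1", sequence = strrep("C", 60),
                           quality = q40(60))
  out <- merge_pairs(noise, noise2, min_overlap = 20)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_dropped"), 1)

  expect_error(merge_pairs(r1, dplyr::mutate(r2, id = "other"), 10), "ids")

  # conflicting position resolved toward the higher-quality base
  t1 <- "ACGTACGTACGTACGTACGT"
  t2 <- sub("^A", "G", t1)
  ra <- tibble::tibble(id = "c", sequence = t1, quality = q40(20))
  rb <- tibble::tibble(id = "c", sequence = revcomp(t2),
                       quality = paste0(strrep("5", 19), "J")) # J=41 at pos 1
  m <- merge_pairs(ra, rb, min_overlap = 10)
  expect_equal(substr(m$sequence, 1, 1), "G")
})

test_that("quality filter keeps mean-Phred >= 40, boundary inclusive", {
  reads <- tibble::tibble(
    id = c("hi", "lo", "edge"),
    sequence = rep(strrep("A", 10), 3),
    quality = c(q40(10), strrep("5", 10),            # Q20
                paste0(strrep("N", 5), strrep("D", 5))) # Q45/Q35, mean 40
  )
  kept <- quality_filter(reads, min_score = 40)
  expect_setequal(kept$id, c("hi", "edge"))
  expect_equal(attr(kept, "n_removed"), 1)
  # idempotent
  expect_equal(quality_filter(kept, 40)$id, kept$id)
})

test_that("demultiplexing is exact on tags and primers, both orientations", {
  man <- generate_tag_manifest(2, 2, 0, seed = 5)
  pr <- psbcl_primers()
  insert <- strrep("ACGT", 25)
  build <- function(i, insert_seq = insert) {
    paste0(man$forward_tag[i], pr[["forward"]], insert_seq,
           revcomp(pr[["reverse"]]), revcomp(man$reverse_tag[i]))
  }
  bad_tag <- man$forward_tag[3]
  substr(bad_tag, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                   substr(bad_tag, 1, 1))[1]
  seqs <- c(build(1), revcomp(build(2)),
            paste0(bad_tag, pr[["forward"]], insert,
                   revcomp(pr[["reverse"]]), revcomp(man$reverse_tag[3])))
  reads <- tibble::tibble(
    id = c("r1", "r2_rc", "r3_bad_tag"),
    sequence = seqs,
    quality = q40(nchar(seqs))
  )
  out <- demultiplex(reads, man)
  expect_equal(out$sample_id[out$id == "r1"], man$sample_id[1])
  expect_equal(out$sample_id[out$id == "r2_rc"], man$sample_id[2])
  expect_equal(out$sequence[out$id == "r1"], insert)
  expect_false("r3_bad_tag" %in% out$id)
  expect_equal(attr(out, "n_unassigned"), 1)

  dup <- man
  dup$forward_tag <- man$forward_tag[1]
  dup$reverse_tag <- man$reverse_tag[1]
  expect_error(demultiplex(reads, dup), "duplicate")

  # on synthetic error-free reads, assignment equals the generator labels
  st <- tiny_study(seed = 41, n_deer = 3, n_cattle = 3, n_negatives = 1,
                   mean_depth = 150)
  reads2 <- simulate_reads(st$truth, st$db, st$manifest, st$spec, seed = 8)
  out2 <- demultiplex(reads2, st$manifest)
  expect_equal(attr(out2, "n_unassigned"), 0)
  expect_equal(out2$sample_id, sub(":.*$", "", out2$id))
})

test_that("dereplication groups identical sequences and conserves counts", {
  assigned <- tibble::tibble(
    sample_id = c("A", "A", "A", "B", "B", "C"),
    sequence = c("AAA", "AAA", "AAA", "AAA", "AAA", "CCC")
  )
  ds <- dereplicate(assigned)
  expect_equal(ds$count[ds$sequence == "AAA" & ds$sample_id == "A"], 3L)
  expect_equal(ds$count[ds$sequence == "AAA" & ds$sample_id == "B"], 2L)
  expect_equal(derep_totals(ds)$total[derep_totals(ds)$sequence == "AAA"], 5L)
  expect_equal(sum(ds$count), nrow(assigned))

  distinct <- tibble::tibble(sample_id = "A",
                             sequence = c("AA", "CC", "GG"))
  expect_equal(nrow(dereplicate(distinct)), 3)
  expect_true(all(dereplicate(distinct)$count == 1))

  # conservation on a random fixture
  set.seed(99)
  fx <- tibble::tibble(
    sample_id = sample(LETTERS[1:4], 200, replace = TRUE),
    sequence = sample(c("ACGT", "ACGA", "TTTT"), 200, replace = TRUE)
  )
  expect_equal(sum(dereplicate(fx)$count), 200L)
})

test_that("length/count filter boundaries follow the <80 bp and <10 rules", {
  ds <- tibble::tibble(
    sequence = c(strrep("A", 79), strrep("C", 100), strrep("G", 100)),
    sample_id = "s1",
    count = c(1000L, 10L, 9L)
  )
  out <- length_count_filter(ds)
  expect_equal(out$sequence, strrep("C", 100)) # 80 bp / total 10 kept
  # idempotent
  expect_identical(length_count_filter(out), out)
})

test_that("denoiser discards 1-off low-count children and keeps sample maxima", {
  parent <- strrep("ACGT", 25)
  child <- sub("^A", "C", parent)
  far <- paste0("TTT", substr(parent, 4, 100)) # edit distance 3
  ds <- tibble::tibble(
    sequence = c(parent, child, far),
    sample_id = "s1",
    count = c(1000L, 10L, 10L)
  )
  out <- denoise(ds)
  expect_true(parent %in% out$sequence)
  expect_false(child %in% out$sequence)
  expect_true(far %in% out$sequence)

  single <- tibble::tibble(sequence = parent, sample_id = "s1", count = 5L)
  expect_identical(denoise(single), single)

  # head-in-one-sample retention: child dominant elsewhere survives with
  # all its counts
  ds2 <- tibble::tibble(
    sequence = c(parent, child, child),
    sample_id = c("s1", "s1", "s2"),
    count = c(1000L, 10L, 500L)
  )
  out2 <- denoise(ds2)
  expect_equal(sum(out2$count[out2$sequence == child]), 510L)

  # property: the strict per-sample maximum is never removed
  set.seed(7)
  seqs <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  }, character(1))
  for (rep in 1:5) {
    cnt <- sample(1:500, 6)
    dsr <- tibble::tibble(sequence = seqs, sample_id = "s1",
                          count = as.integer(cnt))
    kept <- denoise(dsr)
    expect_true(seqs[which.max(cnt)] %in% kept$sequence)
  }
})

test_that("negative-control filter removes samples below the negative max", {
  counts <- matrix(c(70, 90, 50, 80), ncol = 1)
  tab <- make_table(counts, species = c("cattle", "cattle",
                                        "negative", "negative"),
                    negative = c(FALSE, FALSE, TRUE, TRUE))
  res <- negative_control_filter(tab)
  expect_equal(res$removed, "s01")
  expect_setequal(unique(res$table$sample_id), "s02")
  expect_false(any(res$table$is_negative))

  # no negatives -> no removals
  tab2 <- make_table(matrix(c(5, 9), ncol = 1),
                     species = c("cattle", "sika_deer"))
  res2 <- negative_control_filter(tab2)
  expect_equal(length(res2$removed), 0)
  expect_equal(dplyr::n_distinct(res2$table$sample_id), 2)

  # mean variant uses the negative mean as the floor
  res3 <- negative_control_filter(tab, stat = "mean") # mean = 65
  expect_equal(length(res3$removed), 0)
})

test_that("stage report computes percentages of raw and rejects increases", {
  rep <- build_report(c(raw = 1000, quality = 987))
  expect_equal(rep$percentage, c(100.0, 98.7))
  expect_equal(build_report(c(raw = 500))$percentage, 100.0)
  expect_error(build_report(c(raw = 10, more = 20)), "non-increasing")

  st <- tiny_study(seed = 51, n_deer = 3, n_cattle = 3, n_negatives = 1,
                   error_rate = 0.003, contamination_rate = 0.01,
                   mean_depth = 200)
  reads <- simulate_reads(st$truth, st$db, st$manifest, st$spec, seed = 9)
  proc <- process_reads(reads, st$manifest)
  expect_true(all(diff(proc$report$count) <= 0))
  expect_equal(proc$report$percentage,
               round(100 * proc$report$count / proc$report$count[1], 1))
})

test_that("error-free pipeline reproduces generator counts exactly", {
  st <- tiny_study(seed = 61)
  reads <- simulate_reads(st$truth, st$db, st$manifest, st$spec, seed = 10)
  proc <- process_reads(reads, st$manifest, min_total = 1)
  tab <- assign_exact(proc$derep, st$db, st$manifest)
  direct <- simulate_motu_table(st$truth, st$spec, seed = 10)
  m1 <- motu_matrix(tab)
  m2 <- motu_matrix(direct)[rownames(m1), colnames(m1)]
  expect_equal(m1, m2)
})
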