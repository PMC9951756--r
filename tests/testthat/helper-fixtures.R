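# small in-code fixtures shared across test files

# build a motu_tbl from a counts matrix (rows = samples, cols = taxa)
make_table <- function(counts, species, negative = rep(FALSE, nrow(counts)),
                       resolution = "motu") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("t%02d", seq_len(ncol(counts)))
  }
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(counts), species = species,
                     is_negative = negative),
      tibble::as_tibble(counts)
    ),
    cols = -c(sample_id, species, is_negative),
    names_to = "taxon", values_to = "count"
  )
  motu_table(long, resolution = resolution)
}

# two-group table with iid-Dirichlet diets and multinomial counts
random_group_table <- function(n_per_group = 6, n_taxa = 8, depth = 500,
                               alpha = 1) {
  counts <- t(vapply(seq_len(2 * n_per_group), function(i) {
    p <- rgamma(n_taxa, alpha)
    p <- p / sum(p)
    as.numeric(rmultinom(1, depth, p))
  }, numeric(n_taxa)))
  make_table(counts, species = rep(c("cattle", "sika_deer"),
                                   each = n_per_group))
}

# tiny complete study bundle for pipeline-level tests
tiny_study <- function(seed = 11, error_rate = 0, contamination_rate = 0,
                       n_deer = 5, n_cattle = 4, n_negatives = 2,
                       n_taxa = 8, n_families = 4, mean_depth = 250) {
  db <- generate_reference_db(n_taxa, n_families, seed = seed)
  manifest <- generate_tag_manifest(n_cattle, n_deer, n_negatives,
                                    seed = seed + 1)
  spec <- dietniche:::study_diet_spec(
    db, mean_depth = mean_depth, error_rate = error_rate,
    contamination_rate = contamination_rate, negative_depth = 15
  )
  truth <- sample_true_diets(spec, manifest, seed = seed + 2)
  list(db = db, manifest = manifest, spec = spec, truth = truth)
}
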