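# The read-processing chain: merge, quality filter, exact-tag demultiplex,
# dereplicate, length/count filters, obiclean-style denoising,
# negative-control screening, and the stage-accounting report.

#' Merge paired reads by best ungapped overlap
#'
#' Aligns each R1 against the reverse complement of its mate over every
#' ungapped overlap of at least `min_overlap` bases and keeps the
#' highest-scoring one (score = matches - mismatches; ties favour the
#' longer overlap). The consensus takes the higher-quality base at
#' conflicting positions (R1 wins exact quality ties); merged qualities
#' take the position-wise maximum in the overlap. Pairs with no overlap at
#' `min_identity` or better are dropped and counted in the
#' `"n_dropped"` attribute.
#'
#' @param r1,r2 Read tibbles (`id`, `sequence`, `quality`) with matching
#'   ids in the same order.
#' @param min_overlap Minimum admissible overlap length in bp.
#' @param min_identity Minimum fraction of matching bases in the overlap.
#' @return A merged read tibble with attribute `n_dropped`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10, min_identity = 0.75) {
  if (nrow(r1) != nrow(r2) || !identical(r1$id, r2$id)) {
    abort("r1 and r2 must contain the same read ids in the same order")
  }
  out_id <- character(0); out_seq <- character(0); out_qual <- character(0)
  dropped <- 0L
  for (i in seq_len(nrow(r1))) {
    m <- merge_one_pair(
      r1$sequence[i], r1$quality[i],
      revcomp(r2$sequence[i]), reverse_string(r2$quality[i]),
      min_overlap, min_identity
    )
    if (is.null(m)) {
      dropped <- dropped + 1L
    } else {
      out_id <- c(out_id, r1$id[i])
      out_seq <- c(out_seq, m$sequence)
      out_qual <- c(out_qual, m$quality)
    }
  }
  out <- tibble::tibble(id = out_id, sequence = out_seq, quality = out_qual)
  attr(out, "n_dropped") <- dropped
  out
}

reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

merge_one_pair <- function(s1, q1, s2, q2, min_overlap, min_identity) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  qa <- utf8ToInt(q1) - 33L; qb <- utf8ToInt(q2) - 33L
  n1 <- length(a); n2 <- length(b)
  if (min(n1, n2) < min_overlap) return(NULL)
  best <- NULL; best_score <- -Inf; best_ov <- -1L
  for (ov in seq(min(n1, n2), min_overlap)) {
    ia <- (n1 - ov + 1):n1
    ib <- 1:ov
    match_mask <- a[ia] == b[ib]
    nmatch <- sum(match_mask)
    if (nmatch / ov < min_identity) next
    score <- nmatch - (ov - nmatch)
    if (score > best_score || (score == best_score && ov > best_ov)) {
      best_score <- score
      best_ov <- ov
      best <- list(ia = ia, ib = ib)
    }
  }
  if (is.null(best)) return(NULL)
  ov <- best_ov
  ia <- best$ia; ib <- best$ib
  cons <- a[ia]; consq <- pmax(qa[ia], qb[ib])
  use_b <- (a[ia] != b[ib]) & (qb[ib] > qa[ia])
  cons[use_b] <- b[ib][use_b]
  merged_seq <- c(a[seq_len(n1 - ov)], cons, b[-(1:ov)])
  merged_q <- c(qa[seq_len(n1 - ov)], consq, qb[-(1:ov)])
  list(
    sequence = paste(merged_seq, collapse = ""),
    quality = intToUtf8(merged_q + 33L)
  )
}

#' Filter reads on mean Phred quality
#'
#' Retains reads whose mean per-base Phred score is at least `min_score`
#' (the boundary is kept).
#'
#' @param reads Read tibble (`id`, `sequence`, `quality`).
#' @param min_score Mean-quality threshold (default 40).
#' @return Filtered read tibble with attribute `n_removed`.
#' @export
quality_filter <- function(reads, min_score = 40) {
  if (nrow(reads) == 0) return(reads)
  keep <- mean_phred(reads$quality) >= min_score
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Demultiplex reads by exact tag and primer match
#'
#' A read is assigned to a sample iff its leading bases equal that
#' sample's `forward_tag + forward_primer` exactly AND its trailing bases
#' equal the reverse complement of `reverse_tag + reverse_primer` exactly;
#' reads failing in the given orientation are retried reverse-complemented
#' before being declared unassigned. Tags and primers are stripped from
#' assigned reads. No mismatches are tolerated anywhere in the tag or
#' primer region.
#'
#' @param reads Read tibble (`id`, `sequence`, `quality`).
#' @param manifest Tag manifest tibble.
#' @param fwd_primer,rev_primer Primer sequences; default [psbcl_primers()].
#' @return A tibble of assigned inserts (`sample_id`, `id`, `sequence`,
#'   `quality`) with attribute `n_unassigned`.
#' @export
demultiplex <- function(reads, manifest,
                        fwd_primer = psbcl_primers()[["forward"]],
                        rev_primer = psbcl_primers()[["reverse"]]) {
  key <- paste(manifest$forward_tag, manifest$reverse_tag)
  if (anyDuplicated(key) > 0) {
    abort("manifest contains duplicate tag pairs")
  }
  prefixes <- paste0(manifest$forward_tag, fwd_primer)
  suffixes <- revcomp(paste0(manifest$reverse_tag, rev_primer))
  pre_len <- nchar(prefixes[1])
  suf_len <- nchar(suffixes[1])
  if (length(unique(nchar(prefixes))) != 1 ||
      length(unique(nchar(suffixes))) != 1) {
    abort("tags must all have the same length")
  }

  assign_orientation <- function(seqs) {
    pre <- substr(seqs, 1, pre_len)
    suf <- substr(seqs, nchar(seqs) - suf_len + 1, nchar(seqs))
    idx <- match(pre, prefixes)
    ok <- !is.na(idx) & suf == suffixes[idx] &
      nchar(seqs) > pre_len + suf_len
    idx[!ok] <- NA_integer_
    idx
  }

  idx <- assign_orientation(reads$sequence)
  flip <- is.na(idx)
  seq_use <- reads$sequence
  qual_use <- reads$quality
  if (any(flip)) {
    rc <- revcomp(reads$sequence[flip])
    idx2 <- assign_orientation(rc)
    seq_use[flip] <- rc
    qual_use[flip] <- reverse_string(reads$quality[flip])
    idx[flip] <- idx2
  }
  assigned <- !is.na(idx)
  n <- nchar(seq_use)
  out <- tibble::tibble(
    sample_id = manifest$sample_id[idx[assigned]],
    id = reads$id[assigned],
    sequence = substr(seq_use[assigned], pre_len + 1,
                      n[assigned] - suf_len),
    quality = substr(qual_use[assigned], pre_len + 1,
                     n[assigned] - suf_len)
  )
  attr(out, "n_unassigned") <- sum(!assigned)
  out
}

#' Dereplicate assigned reads into unique sequences
#'
#' Groups identical insert sequences and records per-sample counts
#' (exact string equality, the obiuniq semantics).
#'
#' @param assigned Tibble from [demultiplex()] (`sample_id`, `sequence`),
#'   or a named list of read tibbles keyed by sample id.
#' @return A dereplicated tibble: `sequence`, `sample_id`, `count`.
#' @export
dereplicate <- function(assigned) {
  if (is.list(assigned) && !is.data.frame(assigned)) {
    assigned <- purrr::imap_dfr(assigned, function(df, sid) {
      tibble::tibble(sample_id = sid, sequence = df$sequence)
    })
  }
  assigned |>
    dplyr::count(.data$sequence, .data$sample_id, name = "count") |>
    dplyr::arrange(.data$sequence, .data$sample_id)
}

#' Total counts per dereplicated sequence
#'
#' @param ds Dereplicated tibble.
#' @return Tibble `sequence`, `total`.
#' @export
derep_totals <- function(ds) {
  ds |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
}

#' Remove short and rare dereplicated sequences
#'
#' Keeps sequences of length >= `min_len` whose dataset-wide total count
#' is >= `min_total` (sequences shorter than 80 bp or with total < 10 are
#' removed under the defaults; both boundaries are inclusive keeps).
#'
#' @param ds Dereplicated tibble.
#' @param min_len Minimum sequence length in bp (default 80).
#' @param min_total Minimum dataset-wide count (default 10).
#' @return Filtered dereplicated tibble.
#' @export
length_count_filter <- function(ds, min_len = 80, min_total = 10) {
  tot <- derep_totals(ds)
  keep <- tot$sequence[tot$total >= min_total &
                         nchar(tot$sequence) >= min_len]
  dplyr::filter(ds, .data$sequence %in% keep)
}

#' Remove likely PCR/sequencing error variants (obiclean semantics)
#'
#' Within each sample, sequence `s` receives an edge from `t` when their
#' edit distance (substitutions and indels) is at most `max_dist` and
#' `count_s <= ratio * count_t`. A sequence is a "head" in a sample if it
#' has no incoming edge there; sequences that are heads in at least one
#' sample are retained with all their counts, the rest are discarded as
#' amplification/sequencing errors.
#'
#' @param ds Dereplicated tibble.
#' @param max_dist Maximum edit distance to a putative parent (default 1).
#' @param ratio Maximum child/parent count ratio (default 0.5).
#' @return Denoised dereplicated tibble.
#' @export
denoise <- function(ds, max_dist = 1, ratio = 0.5) {
  stopifnot(ratio > 0, ratio <= 1)
  seqs <- unique(ds$sequence)
  if (length(seqs) <= 1) return(ds)
  d <- adist(seqs)
  neighbor <- d <= max_dist & d > 0
  counts <- ds |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0)
  cm <- as.matrix(counts[, -1, drop = FALSE])
  rownames(cm) <- counts$sequence
  cm <- cm[seqs, , drop = FALSE]
  head_somewhere <- rep(FALSE, length(seqs))
  for (j in seq_len(ncol(cm))) {
    cnt <- cm[, j]
    present <- cnt > 0
    for (i in which(present)) {
      parents <- which(neighbor[i, ] & present & cnt[i] <= ratio * cnt)
      if (length(parents) == 0) head_somewhere[i] <- TRUE
    }
  }
  keep <- seqs[head_somewhere]
  dplyr::filter(ds, .data$sequence %in% keep)
}

#' Remove samples with fewer reads than the negative controls
#'
#' Computes a contamination floor from the negative-control totals (their
#' maximum by default, strictest reading; optionally their mean) and
#' removes every real sample whose total read count falls strictly below
#' it. Negative-control rows are dropped from the returned table.
#'
#' @param table A MOTU table including flagged negative controls.
#' @param stat `"max"` (default) or `"mean"` of the negative totals.
#' @return A list: `table` (filtered, negatives removed) and `removed`
#'   (character vector of removed sample ids).
#' @export
negative_control_filter <- function(table, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  totals <- sample_totals(table)
  neg <- totals[totals$is_negative, ]
  thr <- if (nrow(neg) == 0) {
    -Inf
  } else if (stat == "max") {
    max(neg$total)
  } else {
    mean(neg$total)
  }
  real <- totals[!totals$is_negative, ]
  removed <- real$sample_id[real$total < thr]
  res <- table_resolution(table)
  out <- table |>
    dplyr::filter(!.data$is_negative,
                  !.data$sample_id %in% removed)
  attr(out, "resolution") <- res
  list(table = out, removed = removed)
}

#' Build a stage-accounting report
#'
#' Turns the ordered per-stage read counts of a processing run into the
#' standard accounting table: stage, count, and percentage of raw reads
#' (one decimal).
#'
#' @param stage_counts Named numeric vector of read counts, ordered along
#'   the chain; the first element is the raw count.
#' @return Tibble `stage`, `count`, `percentage`.
#' @export
#' @examples
#' build_report(c(raw = 1000, quality = 987))
build_report <- function(stage_counts) {
  if (is.null(names(stage_counts)) || any(names(stage_counts) == "")) {
    abort("stage counts must be named")
  }
  if (any(diff(stage_counts) > 0)) {
    abort("stage counts must be non-increasing along the chain")
  }
  raw <- stage_counts[[1]]
  tibble::tibble(
    stage = names(stage_counts),
    count = as.numeric(stage_counts),
    percentage = round(100 * as.numeric(stage_counts) / raw, 1)
  )
}

#' Run the full read-processing chain
#'
#' Convenience wrapper: quality filter, exact demultiplex, dereplicate,
#' length/count filter, denoise — returning the dereplicated set together
#' with a stage-accounting report. Pair merging is done first when `r2`
#' is supplied.
#'
#' @param reads Merged read tibble, or R1 when `r2` is given.
#' @param manifest Tag manifest.
#' @param r2 Optional mate reads; triggers [merge_pairs()].
#' @param fwd_primer,rev_primer Primer pair.
#' @param min_quality,min_len,min_total,max_dist,ratio,min_overlap
#'   Stage parameters (see the individual stage functions).
#' @return A list: `derep` (denoised dereplicated tibble) and `report`
#'   (stage accounting tibble).
#' @export
process_reads <- function(reads, manifest, r2 = NULL,
                          fwd_primer = psbcl_primers()[["forward"]],
                          rev_primer = psbcl_primers()[["reverse"]],
                          min_quality = 40, min_len = 80, min_total = 10,
                          max_dist = 1, ratio = 0.5, min_overlap = 10) {
  stages <- c(raw = nrow(reads))
  if (!is.null(r2)) {
    reads <- merge_pairs(reads, r2, min_overlap = min_overlap)
    stages <- c(stages, merged = nrow(reads))
  }
  reads <- quality_filter(reads, min_score = min_quality)
  stages <- c(stages, quality_filtered = nrow(reads))
  assigned <- demultiplex(reads, manifest, fwd_primer, rev_primer)
  stages <- c(stages, tag_primer_matched = nrow(assigned))
  ds <- dereplicate(assigned)
  ds <- length_count_filter(ds, min_len = min_len, min_total = min_total)
  stages <- c(stages, length_count_filtered = sum(ds$count))
  ds <- denoise(ds, max_dist = max_dist, ratio = ratio)
  stages <- c(stages, denoised = sum(ds$count))
  list(derep = ds, report = build_report(stages))
}
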