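# shared internal helpers: sequence manipulation, quality encoding, RNG scoping

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement nucleotide sequences
#'
#' Vectorised over a character vector of A/C/G/T(/N) strings.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

# Phred+33 encode/decode
phred_to_chr <- function(q) {
  vapply(q, function(qs) intToUtf8(pmin(qs, 93L) + 33L), character(1))
}

chr_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

mean_phred <- function(s) {
  vapply(s, function(x) mean(utf8ToInt(x)) - 33, numeric(1))
}

# Evaluate `code` under a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Dirichlet draws via normalised gamma variates; rows are draws.
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# random nucleotide strings
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

# Hamming distance between equal-length strings (vectorised over pairs)
hamming <- function(a, b) {
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

# all-pairs minimum over a string metric; utils::adist counts substitutions
# and indels (Levenshtein), which is the distance the denoiser also uses
min_pairwise_edit_dist <- function(seqs) {
  if (length(seqs) < 2) return(Inf)
  d <- adist(seqs)
  min(d[upper.tri(d)])
}

check_proportions <- function(p, arg = "p", tol = 1e-6) {
  if (!is.numeric(p) || length(p) == 0 || anyNA(p)) {
    abort(sprintf("`%s` must be a numeric vector without NAs.", arg))
  }
  if (any(p < 0)) abort(sprintf("`%s` must be non-negative.", arg))
  if (sum(p) == 0) abort(sprintf("`%s` is a zero vector.", arg))
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.8f).", arg, sum(p)))
  }
  invisible(p)
}

# normalise a count/weight vector to proportions
as_props <- function(x) {
  s <- sum(x)
  if (s == 0) abort("cannot normalise a zero vector")
  x / s
}
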