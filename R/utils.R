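# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded operations never perturb the
#' global random stream. With `seed = NULL` the code runs on the current
#' stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Encode a nucleotide string as integers 1..4 (A,C,G,T); anything else
# (N, gaps) becomes NA and can never match a motif column.
encode_seq <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], .BASES)
}

# Vectorised reverse complement of character sequences.
revcomp <- function(seq) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

# Set of distinct k-mers of a sequence (used by promoter pruning).
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

# Shannon entropy (bits) of a vector of counts or probabilities.
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  p <- p / sum(p)
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
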