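# Matrix-distance comparison of motifs and redundancy removal.
#
# Two PWMs are compared over every ungapped alignment with at least one
# overlapping column, in both orientations of the second matrix; the
# alignment distance is the mean per-column Euclidean distance between the
# probability rows, and the motif distance is the minimum over alignments.
# Significance is assessed against random PWM pairs of the same lengths with
# columns drawn from a symmetric Dirichlet(1,1,1,1).

min_alignment_distance <- function(pa, pb) {
  la <- nrow(pa); lb <- nrow(pb)
  best <- Inf; best_off <- 0L
  offsets <- seq.int(-(lb - 1L), la - 1L)
  offsets <- offsets[order(abs(offsets), offsets)]  # prefer centred alignments
  for (o in offsets) {
    i0 <- max(0L, o)
    i1 <- min(la, o + lb) - 1L
    ia <- seq.int(i0, i1)
    ib <- ia - o
    d <- mean(sqrt(rowSums((pa[ia + 1L, , drop = FALSE] -
                            pb[ib + 1L, , drop = FALSE])^2)))
    if (d < best - 1e-12) { best <- d; best_off <- o }
  }
  list(distance = best, offset = best_off)
}

random_pwm_probs <- function(L) {
  m <- matrix(stats::rexp(L * 4L), nrow = L)
  m / rowSums(m)
}

motif_distance_stat <- function(pa, pb_fwd, pb_rc) {
  fwd <- min_alignment_distance(pa, pb_fwd)
  rc <- min_alignment_distance(pa, pb_rc)
  if (rc$distance < fwd$distance - 1e-12) {
    c(list(orientation = "reverse-complement"), rc)
  } else {
    c(list(orientation = "same"), fwd)
  }
}

#' Distance between two motif matrices
#'
#' Minimum over all alignments (overlap >= 1 column, both orientations of
#' `b`) of the mean per-column Euclidean distance between probability
#' columns. The empirical p-value is the fraction of `n_null` random PWM
#' pairs of the same lengths whose distance is at most the observed one.
#'
#' @param a,b [pwm()] objects.
#' @param n_null Number of random pairs for the null distribution (a warning
#'   is issued below 100; the default resolves p = 0.001).
#' @param seed Seed for the null sampler.
#' @return List with `distance`, `pvalue`, `offset` (offset of b's first
#'   column relative to a's first column in the best alignment) and
#'   `orientation` (`"same"` or `"reverse-complement"`).
#' @export
motif_distance <- function(a, b, n_null = 1000L, seed = 1L) {
  if (n_null < 100L) warning("n_null < 100: p-value will be unstable")
  obs <- motif_distance_stat(a$probs, b$probs, revcomp_pwm(b)$probs)
  null <- null_distance_sample(pwm_length(a), pwm_length(b), n_null, seed)
  list(distance = obs$distance,
       pvalue = mean(null <= obs$distance),
       offset = obs$offset,
       orientation = obs$orientation)
}

# Null distances for a given length pair (memoised per call site by callers
# that compare many motifs).
null_distance_sample <- function(la, lb, n_null, seed) {
  with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      pa <- random_pwm_probs(la)
      pb <- random_pwm_probs(lb)
      pb_rc <- pb[rev(seq_len(lb)), c(4L, 3L, 2L, 1L), drop = FALSE]
      motif_distance_stat(pa, pb, pb_rc)$distance
    }, numeric(1))
  })
}

#' Remove redundant motifs, keeping the more informative matrix
#'
#' All motif pairs are compared with [motif_distance()]; for every pair with
#' comparison p-value at or below `p_threshold`, the motif with lower
#' information content is marked for removal (ties: database motifs outrank
#' de novo motifs, then the lexicographically smaller name is retained).
#' Marking is decided on the original pair list, so a motif similar only to
#' an already-removed motif is still removed. Motifs showing no similarity
#' to any other motif are retained.
#'
#' @param motifs List of [pwm()] objects with unique names.
#' @param p_threshold Similarity p-value cutoff (default 0.001).
#' @param background Background frequencies for information content.
#' @param n_null,seed Passed to the null sampler (one null distribution is
#'   drawn per distinct length pair).
#' @return The retained list of `pwm` objects (input order preserved).
#' @export
deduplicate_motifs <- function(motifs, p_threshold = 0.001,
                               background = rep(0.25, 4),
                               n_null = 1000L, seed = 1L) {
  nms <- vapply(motifs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_param("duplicate motif names: %s",
               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  n <- length(motifs)
  if (n <= 1L) return(motifs)
  ic <- vapply(motifs, information_content, numeric(1), background = background)
  lens <- vapply(motifs, pwm_length, integer(1))
  null_cache <- new.env(parent = emptyenv())
  removed <- logical(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      key <- paste(sort(c(lens[i], lens[j])), collapse = "_")
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- null_distance_sample(lens[i], lens[j], n_null, seed)
      }
      obs <- motif_distance_stat(motifs[[i]]$probs, motifs[[j]]$probs,
                                 revcomp_pwm(motifs[[j]])$probs)$distance
      p <- mean(null_cache[[key]] <= obs)
      if (p <= p_threshold) {
        loser <- redundancy_loser(i, j, ic, motifs, nms)
        removed[loser] <- TRUE
      }
    }
  }
  motifs[!removed]
}

redundancy_loser <- function(i, j, ic, motifs, nms) {
  if (abs(ic[i] - ic[j]) > 1e-12) {
    return(if (ic[i] < ic[j]) i else j)
  }
  src_i <- motifs[[i]]$source
  src_j <- motifs[[j]]$source
  if (src_i != src_j) {
    return(if (src_i == "database") j else i)
  }
  if (nms[i] < nms[j]) j else i
}
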