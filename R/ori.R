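# Overrepresentation index (ORI) of a motif in target promoters versus
# background regions, with a subset-permutation significance test.
#
# ORI = (occurrences per kb in the target set / occurrences per kb in the
# background regions) * (fraction of target promoters containing at least
# one occurrence). The permutation test redraws target sets of the same size
# from the promoter universe and recomputes the ORI for each draw.

as_sequences <- function(x) {
  if (is.data.frame(x)) stats::setNames(x$seq, x$gene_id) else as.character(x)
}

# Per-sequence occurrence counts of one motif (both strands).
motif_hit_counts <- function(pwm, seqs, background, threshold_fraction) {
  vapply(seqs, function(s) {
    nrow(scan_promoter(pwm, s, background = background,
                       threshold_fraction = threshold_fraction))
  }, integer(1), USE.NAMES = FALSE)
}

ori_from_counts <- function(target_counts, target_kb, bg_density) {
  dens <- sum(target_counts) / target_kb
  frac <- mean(target_counts > 0)
  if (bg_density == 0) {
    out <- if (dens == 0) 0 else Inf
    attr(out, "zero_background") <- TRUE
    return(out)
  }
  (dens / bg_density) * frac
}

#' Overrepresentation index of a motif
#'
#' @param motif A [pwm()].
#' @param target_promoters Target sequences: a [promoter_set()] or character
#'   vector.
#' @param background_regions Background (non-promoter) sequences, same types.
#' @param threshold_fraction Scanner threshold (see [scan_promoter()]).
#' @param background Background base frequencies for the scanner.
#' @return The ORI (nonnegative; `Inf` with attribute `zero_background` when
#'   the motif never occurs in the background regions but does in the
#'   target).
#' @export
overrepresentation_index <- function(motif, target_promoters,
                                     background_regions,
                                     threshold_fraction = 0.8,
                                     background = rep(0.25, 4)) {
  tseq <- as_sequences(target_promoters)
  bseq <- as_sequences(background_regions)
  if (length(tseq) == 0L || length(bseq) == 0L) {
    stop_param("target and background sets must be nonempty")
  }
  tc <- motif_hit_counts(motif, tseq, background, threshold_fraction)
  bc <- motif_hit_counts(motif, bseq, background, threshold_fraction)
  bg_density <- sum(bc) / (sum(nchar(bseq)) / 1000)
  ori_from_counts(tc, sum(nchar(tseq)) / 1000, bg_density)
}

#' Permutation test for motif overrepresentation
#'
#' Scans every promoter in the universe once, computes the observed ORI of
#' the target set, then draws `n_perm` random subsets of the same size from
#' the universe and recomputes the ORI for each. The p-value is the fraction
#' of random ORI values strictly greater than the observed one.
#'
#' @param motif A [pwm()].
#' @param target_ids Gene ids of the target set (must be in the universe).
#' @param universe A [promoter_set()] of all candidate promoters.
#' @param background_regions Background sequences (shared by all draws).
#' @param n_perm Number of random subsets (>= 100; default 10000 — the
#'   full-scale analysis uses one million and is a matter of budget only).
#' @param seed Seed making the draw deterministic.
#' @inheritParams overrepresentation_index
#' @return An object of class `ori_result`: list with `motif`, `ori`,
#'   `pvalue`, `n_perm`, `overrepresented` (p < 0.01).
#' @export
ori_permutation_test <- function(motif, target_ids, universe,
                                 background_regions, n_perm = 10000L,
                                 seed = 1L, threshold_fraction = 0.8,
                                 background = rep(0.25, 4)) {
  if (n_perm < 100L) stop_param("n_perm must be at least 100")
  useq <- as_sequences(universe)
  idx <- match(target_ids, names(useq))
  if (anyNA(idx)) {
    stop_param("target ids missing from universe: %s",
               paste(target_ids[is.na(idx)], collapse = ", "))
  }
  set_size <- length(idx)
  if (set_size > length(useq)) stop_param("set size exceeds universe")

  counts <- motif_hit_counts(motif, useq, background, threshold_fraction)
  kb <- nchar(useq) / 1000
  bseq <- as_sequences(background_regions)
  bc <- motif_hit_counts(motif, bseq, background, threshold_fraction)
  bg_density <- sum(bc) / (sum(nchar(bseq)) / 1000)

  obs <- ori_from_counts(counts[idx], sum(kb[idx]), bg_density)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      s <- sample.int(length(useq), set_size)
      ori_from_counts(counts[s], sum(kb[s]), bg_density)
    }, numeric(1))
  })
  p <- mean(perm > obs)
  structure(list(motif = motif$name, ori = as.numeric(obs), pvalue = p,
                 n_perm = as.integer(n_perm),
                 overrepresented = p < 0.01),
            class = "ori_result")
}

#' @export
print.ori_result <- function(x, ...) {
  cat(sprintf("ORI of %s: %.3f (p = %.4g, %d permutations)%s\n",
              x$motif, x$ori, x$pvalue, x$n_perm,
              if (x$overrepresented) " *overrepresented*" else ""))
  invisible(x)
}
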