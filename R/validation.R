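# Model validation: genome-wide ranking, hypergeometric enrichment of the
# top-scoring genes in an expressed set, FDR adjustment, label-shuffle
# F-score significance, and strict-containment overlap of predicted motif
# occurrences with annotated intervals.

#' Rank a promoter universe with a trained model
#'
#' Scores every non-excluded promoter with the weighted occurrence-count
#' score and returns genes in descending score order. Ties are broken by
#' lexicographic gene id for reproducibility.
#'
#' @param model A [promoter_model()] (or named weight vector).
#' @param occurrences Occurrence data frame covering the universe.
#' @param gene_ids The promoter universe.
#' @param exclude Gene ids used for training (both stage-expressed and
#'   control), never scored or returned.
#' @param n_top Number of top genes to flag (default 100).
#' @param config A [feature_config()] (taken from the model when given).
#' @return Data frame `gene_id`, `score`, `rank`, `top` ordered by rank.
#' @export
rank_genome <- function(model, occurrences, gene_ids, exclude = character(0),
                        n_top = 100L, config = feature_config()) {
  universe <- setdiff(gene_ids, exclude)
  if (n_top > length(universe)) {
    stop_param("n_top = %d exceeds universe size %d after exclusion",
               n_top, length(universe))
  }
  sc <- score_promoters(model, occurrences, universe, config)
  ord <- order(-sc, universe)
  data.frame(gene_id = universe[ord], score = as.numeric(sc[ord]),
             rank = seq_along(ord), top = seq_along(ord) <= n_top,
             stringsAsFactors = FALSE)
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of observing at least `count` expressed genes among `n_top`
#' draws from a universe of `n_universe` genes of which `n_expressed` are
#' expressed.
#'
#' @param count Observed overlap.
#' @param n_top Number of top-ranked genes drawn.
#' @param n_expressed Expressed genes in the universe.
#' @param n_universe Universe size.
#' @return Upper-tail p-value `P(X >= count)`.
#' @export
hypergeometric_enrichment <- function(count, n_top, n_expressed, n_universe) {
  if (count > min(n_top, n_expressed) || n_expressed > n_universe ||
      n_top > n_universe || count < 0) {
    stop_param("inconsistent counts for hypergeometric test")
  }
  stats::phyper(count - 1, n_expressed, n_universe - n_expressed, n_top,
                lower.tail = FALSE)
}

#' Enrichment of the top-ranked genes in an expressed set
#'
#' @param ranked Output of [rank_genome()].
#' @param expressed_ids Genes called expressed in the matching sample.
#' @return Object of class `enrichment_result`: `n_top`, `count`,
#'   `expressed_fraction` (fraction of the scored universe that is
#'   expressed), `pvalue`.
#' @export
enrichment_report <- function(ranked, expressed_ids) {
  n_universe <- nrow(ranked)
  n_expressed <- sum(ranked$gene_id %in% expressed_ids)
  n_top <- sum(ranked$top)
  count <- sum(ranked$top & ranked$gene_id %in% expressed_ids)
  structure(list(n_top = n_top, count = count,
                 expressed_fraction = n_expressed / n_universe,
                 pvalue = hypergeometric_enrichment(count, n_top, n_expressed,
                                                    n_universe)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d of top %d expressed (universe fraction %.3f), p = %.3g\n",
              x$count, x$n_top, x$expressed_fraction, x$pvalue))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper around `stats::p.adjust(method = "fdr")` with input
#' validation, matching the reference step-up procedure exactly.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_param("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "fdr")
}

#' Label-shuffle significance of a feature set's F-score
#'
#' Recomputes the any-selected-feature F-score under `n_perm` random
#' shufflings of the class labels; the p-value is the fraction of shuffled
#' F-scores strictly greater than the observed one.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param features Consensus descriptor strings (or a 0/1 mask over
#'   `fm$features`).
#' @param n_perm Number of shuffles (>= 100; default 10000, the full-scale
#'   analysis uses one million).
#' @param seed Seed for the shuffles.
#' @return List with `observed` F-score, `pvalue`, `n_perm`.
#' @export
fscore_permutation_pvalue <- function(fm, features, n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) stop_param("n_perm must be at least 100")
  mask <- if (is.character(features)) {
    as.integer(fm$features$desc %in% features)
  } else {
    as.integer(features)
  }
  ypos <- fm$labels == "positive"
  pred <- if (any(mask > 0)) {
    rowSums(fm$values[, mask > 0, drop = FALSE]) > 0
  } else {
    rep(FALSE, length(ypos))
  }
  f_of <- function(y) {
    tp <- sum(pred & y)
    fscore(tp, sum(pred) - tp, sum(y) - tp)$fscore
  }
  obs <- f_of(ypos)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) f_of(sample(ypos)), numeric(1))
  })
  list(observed = obs, pvalue = mean(perm > obs), n_perm = as.integer(n_perm))
}

#' Occurrences lying entirely inside annotated intervals
#'
#' Strict containment: an occurrence is kept only when
#' `interval.start <= occ.start` and `occ.end <= interval.end` on the same
#' chromosome; strand is ignored. Partial overlaps are dropped.
#'
#' @param occurrences Data frame with genomic `chrom`, `start`, `end`
#'   columns (see [occurrences_to_genomic()]).
#' @param intervals Data frame of BED-style intervals (`chrom`, `start`,
#'   `end`); sorted internally.
#' @return The contained occurrence rows.
#' @export
overlap_with_intervals <- function(occurrences, intervals) {
  if (nrow(occurrences) == 0L || nrow(intervals) == 0L) {
    return(occurrences[0, , drop = FALSE])
  }
  if (length(intersect(unique(occurrences$chrom), unique(intervals$chrom))) == 0L) {
    warning("no shared chromosome names between occurrences and intervals")
  }
  occ_gr <- GenomicRanges::GRanges(
    occurrences$chrom,
    IRanges::IRanges(start = occurrences$start + 1L, end = occurrences$end))
  int_gr <- GenomicRanges::sort(GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)))
  hits <- GenomicRanges::findOverlaps(occ_gr, int_gr, type = "within")
  occurrences[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Read a BED file of intervals
#'
#' @param path BED path (3+ tab-separated columns, no header).
#' @return Data frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed)[seq_len(min(6L, ncol(bed)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(bed)))]
  bed
}
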