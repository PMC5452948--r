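# Log-odds PWM scanning of promoters on both strands.
#
# Occurrences are recorded in promoter coordinates (0-based, half-open) in
# gene orientation; a minus-strand occurrence is a match of the motif's
# reverse complement at that window. Positions containing N score -Inf and
# can never reach any threshold.

# Score every window of an encoded sequence against an L x 4 log-odds matrix.
scan_scores <- function(seqint, lo) {
  L <- nrow(lo)
  n <- length(seqint)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    v <- lo[j, ][seqint[seq.int(j, j + nw - 1L)]]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

log_odds <- function(pwm, background) {
  lo <- log2(sweep(pwm$probs, 2L, background, "/"))
  lo[pwm$probs == 0] <- -Inf
  lo
}

#' Scan one promoter with a PWM on both strands
#'
#' Windows whose log-odds score (bits, relative to `background`) reaches
#' `threshold_fraction` times the maximum attainable score of the PWM are
#' reported. Minus-strand hits are matches of the reverse-complement matrix,
#' reported with the gene-orientation coordinates of the matched window.
#'
#' @param pwm A [pwm()].
#' @param promoter A single-row [promoter_set()], or a character sequence.
#' @param background Background base frequencies (A, C, G, T).
#' @param threshold_fraction Fraction in (0, 1] of the maximum attainable
#'   log-odds score (default 0.8).
#' @return Data frame of occurrences: `motif`, `gene_id`, `start`, `end`,
#'   `strand`, `score`. Empty (zero rows) when nothing matches or the
#'   promoter is shorter than the motif.
#' @export
scan_promoter <- function(pwm, promoter, background = rep(0.25, 4),
                          threshold_fraction = 0.8) {
  check_background(background)
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1) {
    stop_param("threshold_fraction must lie in (0, 1]")
  }
  if (is.data.frame(promoter)) {
    stopifnot(nrow(promoter) == 1L)
    gene_id <- promoter$gene_id
    seq <- promoter$seq
  } else {
    gene_id <- names(promoter) %||% "promoter"
    seq <- as.character(promoter)
  }
  seqint <- encode_seq(seq)
  occ_list <- list()
  lo_fwd <- log_odds(pwm, background)
  max_score <- sum(apply(lo_fwd, 1L, max))
  thr <- threshold_fraction * max_score
  for (str in c("+", "-")) {
    lo <- if (str == "+") lo_fwd else log_odds(revcomp_pwm(pwm), background)
    sc <- scan_scores(seqint, lo)
    hit <- which(sc >= thr)
    if (length(hit) > 0L) {
      occ_list[[str]] <- data.frame(
        motif = pwm$name, gene_id = gene_id, start = hit - 1L,
        end = hit - 1L + pwm_length(pwm), strand = str, score = sc[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (length(occ_list) == 0L) return(empty_occurrences())
  out <- do.call(rbind, occ_list)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

empty_occurrences <- function() {
  data.frame(motif = character(0), gene_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Scan a promoter set with a collection of PWMs
#'
#' @param pwms List of [pwm()] objects.
#' @param promoters A [promoter_set()].
#' @inheritParams scan_promoter
#' @return A single occurrence data frame (see [scan_promoter()]).
#' @export
scan_promoters <- function(pwms, promoters, background = rep(0.25, 4),
                           threshold_fraction = 0.8) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  out <- list()
  for (i in seq_len(nrow(promoters))) {
    row <- promoters[i, , drop = FALSE]
    for (p in pwms) {
      occ <- scan_promoter(p, row, background = background,
                           threshold_fraction = threshold_fraction)
      if (nrow(occ) > 0L) out[[length(out) + 1L]] <- occ
    }
  }
  if (length(out) == 0L) return(empty_occurrences())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write motif occurrences as BED6
#'
#' The chrom column holds the promoter's gene id and coordinates are
#' promoter-relative; use [occurrences_to_genomic()] first for genomic BED.
#'
#' @param occ Occurrence data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(occ, path) {
  bed <- data.frame(occ$gene_id, occ$start, occ$end, occ$motif,
                    round(occ$score, 4), occ$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motif occurrences from BED6
#' @param path BED path written by [write_occurrences_bed()].
#' @return Occurrence data frame.
#' @export
read_occurrences_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "start", "end", "motif",
                                         "score", "strand"))
  data.frame(motif = bed$motif, gene_id = bed$gene_id,
             start = as.integer(bed$start), end = as.integer(bed$end),
             strand = bed$strand, score = bed$score, stringsAsFactors = FALSE)
}

#' Map promoter-relative occurrences to genomic coordinates
#'
#' @param occ Occurrence data frame (promoter coordinates).
#' @param promoters The [promoter_set()] the occurrences came from; must
#'   carry genomic provenance (chrom/tss/strand).
#' @return Data frame with `chrom`, `start`, `end` genomic columns plus
#'   `motif`, `gene_id`, `strand` (genomic strand of the match) and `score`.
#' @export
occurrences_to_genomic <- function(occ, promoters) {
  idx <- match(occ$gene_id, promoters$gene_id)
  if (anyNA(idx)) stop_param("occurrences reference unknown gene ids")
  chrom <- promoters$chrom[idx]
  tss <- promoters$tss[idx]
  pstrand <- promoters$strand[idx]
  off <- promoters$offset_of_tss[idx]
  if (anyNA(chrom) || anyNA(tss)) {
    stop_param("promoter set lacks genomic provenance (chrom/tss are NA)")
  }
  plus <- pstrand == "+"
  gstart <- ifelse(plus, tss - off + occ$start, tss + off + 1L - occ$end)
  gend <- gstart + (occ$end - occ$start)
  gstrand <- ifelse((occ$strand == "+") == plus, "+", "-")
  data.frame(chrom = chrom, start = as.integer(gstart), end = as.integer(gend),
             motif = occ$motif, gene_id = occ$gene_id, strand = gstrand,
             score = occ$score, stringsAsFactors = FALSE)
}
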