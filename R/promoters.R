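# Promoter extraction, pruning of near-duplicate regions, and gene-set splits.
#
# A promoter is the TSS-anchored window [-1500, +500) in gene orientation:
# index 0 of the sequence is the most upstream base (-1500), index 1500 is the
# TSS base, index 1999 is +499. Coordinates are 0-based half-open throughout.

PROMOTER_UPSTREAM <- 1500L
PROMOTER_DOWNSTREAM <- 500L
PROMOTER_LENGTH <- PROMOTER_UPSTREAM + PROMOTER_DOWNSTREAM

#' Build a promoter set from components
#'
#' A `promoter_set` is a data frame with one row per gene and columns
#' `gene_id`, `chrom`, `tss`, `strand`, `seq`, `offset_of_tss`, `truncated`.
#' Sequences are stored in gene orientation.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param seq Character vector of promoter sequences (gene orientation).
#' @param chrom,tss,strand Optional genomic provenance (NA for synthetic or
#'   FASTA-only promoters).
#' @param offset_of_tss Index (0-based) of the TSS base within `seq`;
#'   defaults to 1500 for full-length promoters.
#' @param truncated Logical flag, `TRUE` when the region was clipped at a
#'   contig edge.
#' @return A `promoter_set` data frame.
#' @export
promoter_set <- function(gene_id, seq, chrom = NA_character_, tss = NA_integer_,
                         strand = "+", offset_of_tss = PROMOTER_UPSTREAM,
                         truncated = FALSE) {
  if (anyDuplicated(gene_id)) {
    stop_param("duplicate gene ids in promoter set: %s",
               paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  if (length(gene_id) == 0L) {
    chrom <- character(0); tss <- integer(0); strand <- character(0)
    seq <- character(0); offset_of_tss <- integer(0); truncated <- logical(0)
  }
  out <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    tss = as.integer(tss),
    strand = as.character(strand),
    seq = as.character(seq),
    offset_of_tss = as.integer(offset_of_tss),
    truncated = as.logical(truncated),
    stringsAsFactors = FALSE
  )
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters (%d truncated), lengths %s\n",
              nrow(x), sum(x$truncated),
              paste(range(nchar(x$seq)), collapse = "-")))
  invisible(x)
}

#' Extract TSS-anchored promoter regions from a genome
#'
#' Retrieves the region from 1.5 kb upstream to 500 bp downstream of each
#' gene's TSS. Minus-strand promoters are reverse-complemented so that the
#' returned sequence reads in gene orientation (index 1500 is the TSS base).
#' Regions running off a contig edge are clipped and flagged as truncated.
#'
#' @param genome A named character vector, a `Biostrings::DNAStringSet`, or a
#'   path to a FASTA file.
#' @param genes Data frame with columns `gene_id`, `chrom`, `tss` (0-based
#'   genomic coordinate of the TSS base) and `strand` (`"+"` or `"-"`);
#'   see [read_gene_table()].
#' @param upstream,downstream Window extents in bp.
#' @return A [promoter_set()].
#' @export
extract_promoters <- function(genome, genes, upstream = PROMOTER_UPSTREAM,
                              downstream = PROMOTER_DOWNSTREAM) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))

  bad_strand <- !(genes$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    warning(sprintf("rejecting %d rows with malformed strand: %s",
                    sum(bad_strand),
                    paste(genes$gene_id[bad_strand], collapse = ", ")))
    genes <- genes[!bad_strand, , drop = FALSE]
  }
  unknown <- setdiff(unique(genes$chrom), names(genome))
  if (length(unknown) > 0L) {
    off <- genes$gene_id[genes$chrom %in% unknown]
    stop_param("unknown chromosome(s) %s for gene(s) %s",
               paste(unknown, collapse = ", "), paste(off, collapse = ", "))
  }

  n <- nrow(genes)
  seqs <- character(n)
  offs <- integer(n)
  trunc <- logical(n)
  for (i in seq_len(n)) {
    contig <- genome[[genes$chrom[i]]]
    clen <- nchar(contig)
    tss <- as.integer(genes$tss[i])
    if (genes$strand[i] == "+") {
      s0 <- tss - upstream
      e0 <- tss + downstream
    } else {
      # gene orientation runs toward decreasing coordinates:
      # promoter index p maps to genomic base tss + upstream - p
      s0 <- tss - downstream + 1L
      e0 <- tss + upstream + 1L
    }
    s <- max(s0, 0L)
    e <- min(e0, clen)
    if (s >= e) stop_param("promoter of gene %s lies outside contig %s",
                           genes$gene_id[i], genes$chrom[i])
    piece <- substr(contig, s + 1L, e)
    if (genes$strand[i] == "-") piece <- revcomp(piece)
    seqs[i] <- piece
    offs[i] <- if (genes$strand[i] == "+") tss - s else e - 1L - tss
    trunc[i] <- (s != s0) || (e != e0)
  }
  promoter_set(gene_id = genes$gene_id, seq = seqs, chrom = genes$chrom,
               tss = genes$tss, strand = genes$strand,
               offset_of_tss = offs, truncated = trunc)
}

#' Read a BED6-style gene table
#'
#' Columns: chrom, start, end, name, score, strand (tab-separated, no header).
#' With `strand_aware_tss = TRUE` (the BED convention for gene bodies) the TSS
#' is `start` for plus-strand genes and `end - 1` for minus-strand genes;
#' otherwise the TSS is taken as `start` for every row.
#'
#' @param path Path to the BED file.
#' @param strand_aware_tss Logical, see Description.
#' @return Data frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_table <- function(path, strand_aware_tss = TRUE) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  tss <- if (strand_aware_tss) {
    ifelse(bed$strand == "-", bed$end - 1L, bed$start)
  } else {
    bed$start
  }
  data.frame(gene_id = bed$name, chrom = bed$chrom, tss = as.integer(tss),
             strand = bed$strand, stringsAsFactors = FALSE)
}

#' Read a plain-text gene list (one id per line)
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write promoters to FASTA
#' @param promoters A [promoter_set()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(promoters$seq, promoters$gene_id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read promoters from FASTA
#'
#' Genomic provenance (chrom/tss/strand) is not stored in FASTA and comes back
#' as NA; the TSS offset is assumed to be 1500 for full-length records.
#'
#' @param path FASTA path.
#' @return A [promoter_set()].
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  off <- ifelse(nchar(seqs) >= PROMOTER_UPSTREAM, PROMOTER_UPSTREAM,
                nchar(seqs))
  promoter_set(gene_id = nm, seq = seqs, offset_of_tss = as.integer(off),
               truncated = nchar(seqs) != PROMOTER_LENGTH)
}

#' Remove near-duplicate promoters
#'
#' Greedy clustering in order of decreasing sequence length: a promoter is
#' discarded when its similarity to an already retained representative exceeds
#' `threshold`. Similarity is the containment Jaccard of k-mer sets,
#' |K(a) intersect K(b)| / min(|K(a)|, |K(b)|): 1 for identical sequences,
#' near 0 for unrelated random 2-kb sequences at the default k, and roughly
#' the shared fraction for sequences sharing a contiguous block.
#'
#' @param promoters A [promoter_set()].
#' @param threshold Similarity above which a promoter is discarded (default
#'   0.6, i.e. remove regions more than 60% similar).
#' @param k Word length for the k-mer sets (default 12).
#' @return The retained [promoter_set()] (input order preserved).
#' @export
prune_similar_promoters <- function(promoters, threshold = 0.6, k = 12L) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_param("threshold must lie in (0, 1], got %s", format(threshold))
  }
  if (any(!nzchar(promoters$seq))) stop_param("empty promoter sequence")
  ord <- order(-nchar(promoters$seq))
  reps <- list()
  keep <- logical(nrow(promoters))
  for (i in ord) {
    ks <- kmer_set(promoters$seq[i], k)
    dup <- FALSE
    for (r in reps) {
      sim <- length(intersect(ks, r)) / min(length(ks), length(r))
      if (sim > threshold) { dup <- TRUE; break }
    }
    if (!dup) {
      reps[[length(reps) + 1L]] <- ks
      keep[i] <- TRUE
    }
  }
  out <- promoters[keep, , drop = FALSE]
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Split gene sets into the three working subsets plus controls
#'
#' Positive (stage-expressed) genes are randomly partitioned 40% / 20% / 40%
#' into motif-prediction, feature-computation and model-construction subsets
#' (largest-remainder rounding so the sizes sum to the input size). Control
#' genes are evenly split into a feature-computation control half and a
#' model-construction control half.
#'
#' @param positive_ids,control_ids Character vectors of gene ids (disjoint).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param fractions Positive-set fractions (motif-prediction,
#'   feature-computation, model-construction).
#' @return An object of class `gene_split`: a list with elements
#'   `motif_prediction`, `feature_computation`, `model_construction`,
#'   `control_feature`, `control_model`, `seed`.
#' @export
split_gene_sets <- function(positive_ids, control_ids, seed,
                            fractions = c(0.4, 0.2, 0.4)) {
  positive_ids <- as.character(positive_ids)
  control_ids <- as.character(control_ids)
  overlap <- intersect(positive_ids, control_ids)
  if (length(overlap) > 0L) {
    stop_param("positive and control sets overlap: %s",
               paste(overlap, collapse = ", "))
  }
  if (length(positive_ids) < 5L) {
    stop_param("need at least 5 positive genes, got %d", length(positive_ids))
  }
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)

  sizes <- largest_remainder(length(positive_ids), fractions)
  with_seed(seed, {
    pos <- sample(positive_ids)
    ctrl <- sample(control_ids)
    cuts <- cumsum(sizes)
    n1 <- ceiling(length(ctrl) / 2)
    out <- list(
      motif_prediction = pos[seq_len(cuts[1])],
      feature_computation = pos[seq.int(cuts[1] + 1L, cuts[2])],
      model_construction = pos[seq.int(cuts[2] + 1L, cuts[3])],
      control_feature = ctrl[seq_len(n1)],
      control_model = if (length(ctrl) > n1) ctrl[seq.int(n1 + 1L, length(ctrl))] else character(0),
      seed = seed
    )
    class(out) <- "gene_split"
    out
  })
}

# Largest-remainder apportionment of n into round(n * fractions) summing to n.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(-(raw - base))[seq_len(short)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' @export
print.gene_split <- function(x, ...) {
  cat(sprintf(paste0("gene_split (seed %s): motif-prediction %d, ",
                     "feature-computation %d, model-construction %d; ",
                     "controls %d + %d\n"),
              format(x$seed), length(x$motif_prediction),
              length(x$feature_computation), length(x$model_construction),
              length(x$control_feature), length(x$control_model)))
  invisible(x)
}
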