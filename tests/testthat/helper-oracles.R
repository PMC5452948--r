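# Independent brute-force oracles and small fixture builders. None of these
# call the package's own implementation of the quantity they check.

rnd_seq <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

plant_word <- function(seq, word, at) {
  # 0-based position
  paste0(substr(seq, 1, at), word, substr(seq, at + nchar(word) + 1, nchar(seq)))
}

rc_word <- function(word) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(word, "")[[1]]), collapse = ""))
}

# --- entropy / SU oracle (contingency-table computation) -------------------

naive_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

naive_su <- function(x, y) {
  hx <- naive_entropy(x)
  hy <- naive_entropy(y)
  if (hx == 0 || hy == 0) return(0)
  joint <- table(x, y) / length(x)
  joint <- joint[joint > 0]
  hxy <- -sum(joint * log2(joint))
  2 * (hx + hy - hxy) / (hx + hy)
}

# Literal FCBF: rank by SU with class, then scan down the ranking removing
# any feature whose SU with a retained higher-ranked feature is at least its
# SU with the class. Returns retained column indices in ranking order.
naive_fcbf <- function(X, y, delta = 0) {
  keep <- which(apply(X, 2, function(c) length(unique(c)) > 1))
  su_c <- vapply(keep, function(j) naive_su(X[, j], y), numeric(1))
  o <- order(-su_c, colnames(X)[keep])
  ord <- keep[o]
  su_c <- su_c[o]
  ord <- ord[su_c >= delta]
  su_c <- su_c[su_c >= delta]
  retained <- integer(0)
  removed <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (removed[i]) next
    retained <- c(retained, ord[i])
    if (i < length(ord)) {
      for (j in seq.int(i + 1, length(ord))) {
        if (removed[j]) next
        if (naive_su(X[, ord[i]], X[, ord[j]]) >= su_c[j]) removed[j] <- TRUE
      }
    }
  }
  retained
}

# --- feature detection oracle (exhaustive pair enumeration) ----------------

# f: one row of a parsed feature frame; occ: occurrence data frame of one
# promoter. Returns the count of qualifying occurrences / ordered pairs.
naive_feature_count <- function(f, occ, window = 100, upstream = 1500,
                                n_ptss_bins = 15) {
  n <- nrow(occ)
  if (n == 0) return(0)
  cnt <- 0
  if (f$ftype == "PRESENCE") {
    return(sum(occ$motif == f$motif_a))
  }
  if (f$ftype == "PRESENCE_ORIENTED") {
    return(sum(occ$motif == f$motif_a & occ$strand == f$strand_a))
  }
  if (f$ftype == "POSITION_TSS") {
    lo <- f$bin * window - upstream
    r <- occ$start - upstream
    return(sum(occ$motif == f$motif_a & occ$strand == f$strand_a &
                 r >= lo & r < lo + window))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- occ[i, ]; b <- occ[j, ]
      if (f$ftype == "PAIR_DISTANCE") {
        ok <- a$motif == f$motif_a && a$strand == f$strand_a &&
          b$motif == f$motif_b && b$strand == f$strand_b
        if (ok) {
          sep <- b$start - a$start
          if (sep >= f$bin * window && sep < (f$bin + 1) * window) cnt <- cnt + 1
        }
      } else if (f$ftype == "ORDER") {
        side_ok <- if (f$side == "up") {
          a$start < upstream && b$start < upstream
        } else {
          a$start >= upstream && b$start >= upstream
        }
        ok <- side_ok && a$motif == f$motif_a && a$strand == f$strand_a &&
          b$motif == f$motif_b && b$strand == f$strand_b && a$start < b$start
        if (ok) cnt <- cnt + 1
      } else if (f$ftype == "PAIR_TSS_DISTANCE") {
        ok <- a$motif == f$motif_a && b$motif == f$motif_b
        if (ok) {
          d <- min(abs(a$start - upstream), abs(b$start - upstream))
          lo <- f$bin * window
          hi <- if (f$bin == n_ptss_bins - 1) upstream + 0.5 else lo + window
          if (d >= lo && d < hi) cnt <- cnt + 1
        }
      }
    }
  }
  # unordered pair classes count each pair once; the double loop above counts
  # ordered (i, j) pairs, and the qualifying conditions are asymmetric for
  # PAIR_DISTANCE/ORDER (a then b). PAIR_TSS_DISTANCE is symmetric in (a, b)
  # unless the two motifs differ, in which case roles are fixed by name.
  if (f$ftype == "PAIR_TSS_DISTANCE" && f$motif_a == f$motif_b) cnt <- cnt / 2
  cnt
}

random_occurrences <- function(n, motifs, gene = "g", len = 2000, width = 8) {
  if (n == 0) {
    return(data.frame(motif = character(0), gene_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0)))
  }
  out <- data.frame(motif = sample(motifs, n, replace = TRUE),
                    gene_id = gene,
                    start = sample.int(len - width, n, replace = TRUE) - 1L,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    score = 0, stringsAsFactors = FALSE)
  out$end <- out$start + width
  out[, c("motif", "gene_id", "start", "end", "strand", "score")]
}

# --- overlap oracle --------------------------------------------------------

naive_overlap <- function(occ, intervals) {
  keep <- vapply(seq_len(nrow(occ)), function(i) {
    any(intervals$chrom == occ$chrom[i] &
          intervals$start <= occ$start[i] &
          occ$end[i] <= intervals$end)
  }, logical(1))
  occ[keep, , drop = FALSE]
}

# --- motif distance oracle -------------------------------------------------

naive_min_dist <- function(pa, pb) {
  la <- nrow(pa); lb <- nrow(pb)
  rc <- function(p) p[rev(seq_len(nrow(p))), c(4, 3, 2, 1), drop = FALSE]
  best <- Inf
  for (mat in list(pb, rc(pb))) {
    for (o in seq.int(-(lb - 1), la - 1)) {
      ds <- c()
      for (i in seq_len(la)) {
        j <- i - o
        if (j >= 1 && j <= lb) {
          ds <- c(ds, sqrt(sum((pa[i, ] - mat[j, ])^2)))
        }
      }
      if (length(ds) > 0) best <- min(best, mean(ds))
    }
  }
  best
}

random_probs <- function(L) {
  m <- matrix(rexp(L * 4), nrow = L)
  m / rowSums(m)
}

# Minimal feature_matrix stand-in for scoring/filter tests that start from a
# designed 0/1 matrix rather than sequences.
make_fm <- function(values, labels, counts = values) {
  desc <- colnames(values) %||% paste0("PRES:M", seq_len(ncol(values)))
  colnames(values) <- desc
  colnames(counts) <- desc
  structure(list(genes = rownames(values) %||% paste0("g", seq_len(nrow(values))),
                 features = data.frame(desc = desc, ftype = "PRESENCE",
                                       motif_a = desc, motif_b = NA,
                                       strand_a = "any", strand_b = NA,
                                       bin = NA_integer_, side = NA,
                                       stringsAsFactors = FALSE),
                 values = values, counts = counts,
                 labels = factor(labels, levels = c("positive", "control")),
                 config = feature_config()),
            class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
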