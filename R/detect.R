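# Feature detection: counting how often each structural feature is
# instantiated in a promoter's motif occurrences, and assembly of the binary
# promoter x feature matrix.
#
# All six predicates are existential and monotone in the occurrence set:
# adding occurrences can only raise a count, never flip a detection 1 -> 0.
# For single-motif features the count is the number of qualifying
# occurrences; for pair features it is the number of qualifying ordered
# occurrence pairs (distinct occurrences).

# Precompute grouped lookup tables so per-gene counting is vectorised.
prepare_feature_index <- function(features, config) {
  f <- features
  ix <- list(config = config)
  sel <- function(t) which(f$ftype == t)

  i <- sel("PRESENCE")
  ix$pres <- stats::setNames(i, f$motif_a[i])
  i <- sel("PRESENCE_ORIENTED")
  ix$preso <- stats::setNames(i, paste(f$motif_a[i], f$strand_a[i]))
  i <- sel("POSITION_TSS")
  ix$pos <- stats::setNames(i, paste(f$motif_a[i], f$strand_a[i], f$bin[i]))

  i <- sel("PAIR_DISTANCE")
  key <- paste(f$motif_a[i], f$strand_a[i], f$motif_b[i], f$strand_b[i])
  ix$pdist <- split(data.frame(bin = f$bin[i], idx = i), key)
  ix$pdist_keys <- lapply(split(
    data.frame(ka = paste(f$motif_a[i], f$strand_a[i]),
               kb = paste(f$motif_b[i], f$strand_b[i]),
               stringsAsFactors = FALSE), key),
    function(d) d[1L, ])

  i <- sel("ORDER")
  ix$order <- data.frame(side = f$side[i],
                         ka = paste(f$motif_a[i], f$strand_a[i]),
                         kb = paste(f$motif_b[i], f$strand_b[i]),
                         idx = i, stringsAsFactors = FALSE)
  i <- sel("PAIR_TSS_DISTANCE")
  key <- paste(f$motif_a[i], f$motif_b[i])
  ix$ptss <- split(data.frame(bin = f$bin[i], idx = i), key)
  ix$ptss_keys <- lapply(split(
    data.frame(ma = f$motif_a[i], mb = f$motif_b[i], stringsAsFactors = FALSE),
    key), function(d) d[1L, ])
  ix$n <- nrow(f)
  ix
}

# Count all features for one promoter's occurrences.
count_gene_features <- function(occ, ix) {
  res <- integer(ix$n)
  if (is.null(occ) || nrow(occ) == 0L) return(res)
  cfg <- ix$config
  w <- cfg$window
  tss_at <- cfg$upstream

  key <- paste(occ$motif, occ$strand)
  starts_by_key <- split(occ$start, key)
  starts_by_m <- split(occ$start, occ$motif)

  add_table <- function(map, tab) {
    hit <- intersect(names(tab), names(map))
    if (length(hit) > 0L) res[map[hit]] <<- res[map[hit]] + as.integer(tab[hit])
  }
  add_table(ix$pres, table(occ$motif))
  add_table(ix$preso, table(key))
  binv <- occ$start %/% w
  ok <- binv >= 0L & binv < cfg$n_pos_bins
  add_table(ix$pos, table(paste(occ$motif, occ$strand, binv)[ok]))

  for (ck in names(ix$pdist)) {
    kk <- ix$pdist_keys[[ck]]
    A <- starts_by_key[[kk$ka]]
    B <- starts_by_key[[kk$kb]]
    if (is.null(A) || is.null(B)) next
    D <- outer(B, A, "-")
    if (kk$ka == kk$kb) D[cbind(seq_along(B), seq_along(A))] <- NA
    sep <- D[!is.na(D) & D >= 0]
    if (length(sep) == 0L) next
    sbin <- sep %/% w
    tab <- table(sbin[sbin < cfg$n_pair_bins])
    spec <- ix$pdist[[ck]]
    hit <- match(spec$bin, as.integer(names(tab)))
    got <- !is.na(hit)
    res[spec$idx[got]] <- res[spec$idx[got]] + as.integer(tab[hit[got]])
  }

  up <- occ$start < tss_at
  for (side in c("up", "down")) {
    onside <- if (side == "up") up else !up
    if (!any(onside)) next
    sk <- split(occ$start[onside], key[onside])
    spec <- ix$order[ix$order$side == side, , drop = FALSE]
    for (r in seq_len(nrow(spec))) {
      A <- sk[[spec$ka[r]]]
      B <- sk[[spec$kb[r]]]
      if (is.null(A) || is.null(B)) next
      res[spec$idx[r]] <- sum(length(B) - findInterval(A, sort(B)))
    }
  }

  if (length(ix$ptss) > 0L) {
    absr_by_m <- split(abs(occ$start - tss_at), occ$motif)
    thr <- c((seq_len(cfg$n_ptss_bins) - 1L) * w, cfg$upstream + 0.5)
    for (ck in names(ix$ptss)) {
      kk <- ix$ptss_keys[[ck]]
      A <- absr_by_m[[kk$ma]]
      B <- absr_by_m[[kk$mb]]
      if (is.null(A) || is.null(B)) next
      f_of_t <- if (kk$ma == kk$mb) {
        vapply(thr, function(t) { n <- sum(A >= t); n * (n - 1) / 2 }, numeric(1))
      } else {
        vapply(thr, function(t) sum(A >= t) * sum(B >= t), numeric(1))
      }
      cnt <- f_of_t[-length(f_of_t)] - f_of_t[-1L]
      spec <- ix$ptss[[ck]]
      res[spec$idx] <- res[spec$idx] + as.integer(cnt[spec$bin + 1L])
    }
  }
  res
}

#' Count feature instantiations per promoter
#'
#' @param features Feature data frame (or descriptor strings).
#' @param occurrences Occurrence data frame covering all genes (promoter
#'   coordinates, TSS at index `config$upstream`).
#' @param gene_ids Genes to evaluate (genes absent from `occurrences` get
#'   all-zero rows).
#' @param config A [feature_config()].
#' @return Integer matrix, genes x features, of qualifying occurrence /
#'   occurrence-pair counts.
#' @export
count_feature_matrix <- function(features, occurrences, gene_ids,
                                 config = feature_config()) {
  features <- as_feature_frame(features, config)
  ix <- prepare_feature_index(features, config)
  occ_by_gene <- split(occurrences, occurrences$gene_id)
  out <- matrix(0L, nrow = length(gene_ids), ncol = nrow(features),
                dimnames = list(gene_ids, features$desc))
  for (g in seq_along(gene_ids)) {
    out[g, ] <- count_gene_features(occ_by_gene[[gene_ids[g]]], ix)
  }
  out
}

#' Detect a single feature in one promoter's occurrences
#'
#' @param feature One descriptor string or a one-row feature data frame.
#' @param occs Occurrences of a single promoter.
#' @param config A [feature_config()].
#' @return 0 or 1.
#' @export
detect_feature <- function(feature, occs, config = feature_config()) {
  f <- as_feature_frame(feature, config)
  stopifnot(nrow(f) == 1L)
  if (nrow(occs) > 0L && length(unique(occs$gene_id)) > 1L) {
    stop_param("detect_feature expects occurrences of a single promoter")
  }
  gid <- if (nrow(occs) > 0L) occs$gene_id[1L] else "g"
  cnt <- count_feature_matrix(f, occs, gid, config)
  as.integer(cnt[1L, 1L] > 0L)
}

#' Build the binary promoter x feature matrix
#'
#' Rows are positive-class promoters followed by control promoters; entries
#' are 1 when the feature is instantiated at least once. The qualifying
#' instantiation counts are kept alongside for the weighted scoring scheme.
#'
#' @param features Feature data frame or descriptor strings.
#' @param occurrences Occurrence data frame (all genes).
#' @param positive_ids,control_ids Gene ids of the two classes (disjoint).
#' @param config A [feature_config()].
#' @return Object of class `feature_matrix`: list with `genes`, `features`
#'   (data frame), `values` (0/1 integer matrix), `counts` (integer matrix),
#'   `labels` (factor `positive`/`control`), `config`.
#' @export
build_feature_matrix <- function(features, occurrences, positive_ids,
                                 control_ids, config = feature_config()) {
  overlap <- intersect(positive_ids, control_ids)
  if (length(overlap) > 0L) {
    stop_param("ids in both classes: %s", paste(overlap, collapse = ", "))
  }
  genes <- c(positive_ids, control_ids)
  if (anyDuplicated(genes)) stop_param("duplicate gene ids")
  features <- as_feature_frame(features, config)
  counts <- count_feature_matrix(features, occurrences, genes, config)
  structure(list(
    genes = genes,
    features = features,
    values = (counts > 0L) + 0L,
    counts = counts,
    labels = factor(rep(c("positive", "control"),
                        c(length(positive_ids), length(control_ids))),
                    levels = c("positive", "control")),
    config = config
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d genes (%d positive, %d control) x %d features\n",
              length(x$genes), sum(x$labels == "positive"),
              sum(x$labels == "control"), nrow(x$features)))
  invisible(x)
}

# Row subset preserving structure (used by cross-validation folds).
fm_rows <- function(fm, idx) {
  structure(list(genes = fm$genes[idx], features = fm$features,
                 values = fm$values[idx, , drop = FALSE],
                 counts = fm$counts[idx, , drop = FALSE],
                 labels = droplevels_keep(fm$labels[idx]),
                 config = fm$config),
            class = "feature_matrix")
}

droplevels_keep <- function(x) factor(x, levels = c("positive", "control"))

# Column subset by descriptor strings.
fm_cols <- function(fm, desc) {
  j <- match(desc, fm$features$desc)
  if (anyNA(j)) stop_param("unknown feature descriptors")
  structure(list(genes = fm$genes, features = fm$features[j, , drop = FALSE],
                 values = fm$values[, j, drop = FALSE],
                 counts = fm$counts[, j, drop = FALSE],
                 labels = fm$labels, config = fm$config),
            class = "feature_matrix")
}

#' Write a feature matrix as TSV
#'
#' Header row holds `gene_id`, `label`, then one column per canonical
#' descriptor string; entries are 0/1.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(gene_id = fm$genes, label = as.character(fm$labels),
                   fm$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' Counts are not stored in the TSV; they are restored as the binary values
#' (sufficient for filtering and the GA, not for weighted scoring).
#'
#' @param path TSV path.
#' @param config The [feature_config()] used to build the matrix.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, config = feature_config()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "integer"
  rownames(vals) <- df$gene_id
  structure(list(genes = df$gene_id,
                 features = parse_features(colnames(vals), config),
                 values = vals, counts = vals,
                 labels = factor(df$label, levels = c("positive", "control")),
                 config = config),
            class = "feature_matrix")
}
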