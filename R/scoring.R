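# Kullback-Leibler feature weights and the weighted occurrence-count score.
#
# For feature i with presence/absence value j, the weight is
#   w_i = sum_j P(o_ij) * D_KL(C | o_ij)  /  -sum_j P(o_ij) * log P(o_ij)
# with D_KL(C | o_ij) = sum_c P(c | o_ij) * log(P(c | o_ij) / P(c)).
# Natural logarithms are used throughout; the ratio is base-independent.
# Weights are deliberately NOT renormalised to sum to one across features,
# so that meaningful features keep large weights. A promoter region's score
# is sum_i w_i * n_i, where n_i counts the feature's qualifying occurrences
# (occurrence pairs for pair features).

class_frequencies <- function(labels) {
  p <- as.vector(table(labels)) / length(labels)
  stats::setNames(p, levels(labels))
}

#' Kullback-Leibler divergence of the class distribution given a feature value
#'
#' `D_KL(C | o_ij)` compares the class distribution among promoters where
#' feature `i` takes value `j` against the class priors estimated from the
#' matrix labels (maximum-likelihood frequencies, natural log, 0 log 0 = 0).
#'
#' @param fm A [build_feature_matrix()] result with both classes present.
#' @param feature Descriptor string or column index.
#' @param value The feature value `j` (0 or 1); must occur in the column.
#' @return Nonnegative divergence (natural-log units).
#' @export
kl_divergence_for_value <- function(fm, feature, value) {
  col <- feature_column(fm, feature)
  rows <- col == value
  if (!any(rows)) stop_param("value %s absent from feature column", value)
  prior <- class_frequencies(fm$labels)
  cond <- class_frequencies(droplevels_keep(fm$labels[rows]))
  nz <- cond > 0
  sum(cond[nz] * log(cond[nz] / prior[nz]))
}

feature_column <- function(fm, feature) {
  j <- if (is.character(feature)) match(feature, fm$features$desc) else feature
  if (is.na(j) || j < 1L || j > ncol(fm$values)) {
    stop_param("unknown feature '%s'", as.character(feature))
  }
  fm$values[, j]
}

#' Kullback-Leibler weight of one feature
#'
#' The weight averages `D_KL(C | o_ij)` over the feature's value frequencies
#' and divides by the value entropy. A constant column leaves the
#' denominator at zero; the weight is then defined as 0 and flagged.
#'
#' @inheritParams kl_divergence_for_value
#' @return Object of class `feature_weight`: list with `feature`, `w`,
#'   `p_o` (value frequencies), `kl` (per-value divergences), `constant`.
#' @export
feature_weight <- function(fm, feature) {
  col <- feature_column(fm, feature)
  vals <- sort(unique(col))
  desc <- if (is.character(feature)) feature else fm$features$desc[feature]
  if (length(vals) < 2L) {
    return(structure(list(feature = desc, w = 0,
                          p_o = stats::setNames(1, vals), kl = NA_real_,
                          constant = TRUE),
                     class = "feature_weight"))
  }
  p_o <- vapply(vals, function(v) mean(col == v), numeric(1))
  kl <- vapply(vals, function(v) kl_divergence_for_value(fm, feature, v),
               numeric(1))
  w <- sum(p_o * kl) / (-sum(p_o * log(p_o)))
  structure(list(feature = desc, w = w,
                 p_o = stats::setNames(p_o, vals),
                 kl = stats::setNames(kl, vals), constant = FALSE),
            class = "feature_weight")
}

#' @export
print.feature_weight <- function(x, ...) {
  cat(sprintf("feature_weight %s: w = %.4f%s\n", x$feature, x$w,
              if (x$constant) " (constant column, weight set to 0)" else ""))
  invisible(x)
}

#' Weights for several features at once
#'
#' @param fm A [build_feature_matrix()] result.
#' @param features Descriptor strings (default: all features of `fm`).
#' @return Named numeric vector of weights (0 for constant columns).
#' @export
compute_weights <- function(fm, features = NULL) {
  features <- features %||% fm$features$desc
  vapply(features, function(f) feature_weight(fm, f)$w, numeric(1))
}

#' Score a promoter region with weighted feature counts
#'
#' @param weights Named numeric vector of feature weights (names are
#'   descriptor strings), or a `promoter_model`.
#' @param occs Occurrences of one promoter.
#' @param config A [feature_config()].
#' @return Object of class `promoter_score`: list with `gene_id`, `score`,
#'   and the per-feature counts `n`.
#' @export
score_region <- function(weights, occs, config = feature_config()) {
  if (inherits(weights, "promoter_model")) {
    config <- weights$config
    weights <- weights$weights
  }
  gid <- if (nrow(occs) > 0L) occs$gene_id[1L] else NA_character_
  n <- if (length(weights) == 0L) {
    integer(0)
  } else {
    count_feature_matrix(names(weights), occs,
                         if (is.na(gid)) "g" else gid, config)[1L, ]
  }
  structure(list(gene_id = gid, score = sum(weights * n), n = n),
            class = "promoter_score")
}

#' @export
print.promoter_score <- function(x, ...) {
  cat(sprintf("promoter_score %s: %.4f (%d features instantiated)\n",
              x$gene_id, x$score, sum(x$n > 0)))
  invisible(x)
}

#' Score many promoters at once
#'
#' @inheritParams score_region
#' @param occurrences Occurrence data frame covering the genes.
#' @param gene_ids Genes to score.
#' @return Named numeric vector of scores.
#' @export
score_promoters <- function(weights, occurrences, gene_ids,
                            config = feature_config()) {
  if (inherits(weights, "promoter_model")) {
    config <- weights$config
    weights <- weights$weights
  }
  if (length(weights) == 0L) {
    return(stats::setNames(numeric(length(gene_ids)), gene_ids))
  }
  cnt <- count_feature_matrix(names(weights), occurrences, gene_ids, config)
  stats::setNames(as.numeric(cnt %*% weights), gene_ids)
}

#' Assemble a trained promoter model
#'
#' @param features Consensus feature descriptor strings.
#' @param weights Numeric weights aligned with `features`.
#' @param motifs Motif names the features refer to.
#' @param config The [feature_config()] used throughout.
#' @param cv Optional cross-validation summary (stored as-is).
#' @return Object of class `promoter_model`.
#' @export
promoter_model <- function(features, weights, motifs = character(0),
                           config = feature_config(), cv = NULL) {
  stopifnot(length(features) == length(weights))
  structure(list(version = "1.0",
                 features = as.character(features),
                 weights = stats::setNames(as.numeric(weights), features),
                 motifs = as.character(motifs),
                 config = config, cv = cv),
            class = "promoter_model")
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf("promoter_model v%s: %d consensus features over %d motifs\n",
              x$version, length(x$features), length(x$motifs)))
  if (!is.null(x$cv$overall_fscore)) {
    cat(sprintf("  cross-validated Fscore: %.3f\n", x$cv$overall_fscore))
  }
  for (i in seq_along(x$features)) {
    cat(sprintf("  %-40s w = %.4f\n", x$features[i], x$weights[i]))
  }
  invisible(x)
}

#' Write a promoter model as versioned JSON
#' @param model A [promoter_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(version = model$version,
              features = model$features,
              weights = as.numeric(model$weights),
              motifs = model$motifs,
              config = model$config[c("window", "upstream", "downstream")],
              cv = model$cv)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a promoter model written by [write_model()]
#' @param path JSON path.
#' @return A [promoter_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- feature_config(window = obj$config$window,
                        upstream = obj$config$upstream,
                        downstream = obj$config$downstream)
  promoter_model(features = obj$features %||% character(0),
                 weights = obj$weights %||% numeric(0),
                 motifs = obj$motifs %||% character(0),
                 config = cfg, cv = obj$cv)
}
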