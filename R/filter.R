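# Symmetrical uncertainty and the fast correlation-based filter (FCBF) used
# to remove uninformative and redundant features before optimisation.
#
# SU(X, Y) = 2 * IG(X; Y) / (H(X) + H(Y)), entropies in bits, with the
# conventions 0 * log 0 = 0 and SU = 0 whenever either variable is constant
# (avoids 0/0 and makes constant features carry no information).

#' Symmetrical uncertainty between two discrete variables
#'
#' @param x,y Vectors of equal length (binary 0/1 in this package, any
#'   discrete coding accepted).
#' @return SU in \[0, 1\]: 1 for deterministic dependence, 0 for
#'   independence or when either variable is constant.
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  if (length(x) == 0L) stop_param("empty vectors")
  hx <- entropy_bits(table(x))
  hy <- entropy_bits(table(y))
  if (hx == 0 || hy == 0) return(0)
  hxy <- entropy_bits(table(x, y))
  2 * (hx + hy - hxy) / (hx + hy)
}

# Vectorised SU of every binary column of X against a binary reference
# vector, from the 2x2 counts (n = length, a = sum(ref), n1 = colSums(X),
# n11 = colSums(X[ref == 1, ])).
su_columns <- function(X, ref) {
  n <- nrow(X)
  a <- sum(ref)
  n1 <- colSums(X)
  n11 <- if (a > 0) colSums(X[ref == 1L, , drop = FALSE]) else numeric(ncol(X))
  h2 <- function(k, n) {
    p <- k / n
    q <- 1 - p
    out <- numeric(length(p))
    nz <- p > 0 & p < 1
    out[nz] <- -(p[nz] * log2(p[nz]) + q[nz] * log2(q[nz]))
    out
  }
  hx <- h2(n1, n)
  hy <- rep(h2(a, n), ncol(X))
  cells <- cbind(n11, n1 - n11, a - n11, n - n1 - a + n11)
  hxy <- apply(cells, 1L, function(k) entropy_bits(k))
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  su[hx == 0 | hy == 0] <- 0
  su
}

#' Correlation-based feature filter (FCBF)
#'
#' Ranks features by symmetrical uncertainty with the class label
#' (positive = feature-computation promoters, control = negative), drops
#' features below `delta`, then removes every feature that has a
#' *predominant* feature: a higher-ranked retained feature whose SU with it
#' is at least its SU with the class. Constant (never or always present)
#' columns carry no information and are removed up front. Ties in the
#' ranking are broken by the canonical feature order, making the result
#' invariant to input column order.
#'
#' @param fm A [build_feature_matrix()] result with both classes present.
#' @param delta Minimum class SU to enter the ranking (default 0: keep any
#'   feature with positive class correlation and rely on redundancy
#'   removal).
#' @return The retained rows of `fm$features` in ranking order, with an
#'   `su` column giving each feature's class SU. Warns (and returns zero
#'   rows) when nothing survives.
#' @export
correlation_filter <- function(fm, delta = 0) {
  if (delta < 0) stop_param("delta must be >= 0")
  if (nlevels(droplevels(fm$labels)) < 2L) {
    stop_param("feature matrix must contain both classes")
  }
  X <- fm$values
  y <- as.integer(fm$labels == "positive")
  keep <- colSums(X) > 0L & colSums(X) < nrow(X)
  X <- X[, keep, drop = FALSE]
  feats <- fm$features[keep, , drop = FALSE]
  if (ncol(X) == 0L) {
    warning("no non-constant features; returning empty set")
    return(cbind(feats, su = numeric(0)))
  }
  su_cls <- su_columns(X, y)
  # ties in the ranking break by canonical descriptor order, so the result
  # does not depend on input column order
  ord <- order(-su_cls, feats$desc)
  ord <- ord[su_cls[ord] >= delta]
  alive <- rep(TRUE, length(su_cls))
  retained <- integer(0)
  for (pos in seq_along(ord)) {
    j <- ord[pos]
    if (!alive[j]) next
    retained <- c(retained, j)
    if (pos == length(ord)) break
    rest <- ord[seq.int(pos + 1L, length(ord))]
    rest <- rest[alive[rest]]
    if (length(rest) == 0L) next
    su_fr <- su_columns(X[, rest, drop = FALSE], X[, j])
    alive[rest[su_fr >= su_cls[rest]]] <- FALSE
  }
  if (length(retained) == 0L) {
    warning("correlation filter removed every feature")
  }
  out <- feats[retained, , drop = FALSE]
  out$su <- su_cls[retained]
  rownames(out) <- NULL
  out
}
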