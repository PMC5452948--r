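# Structural feature descriptors: the six classes of binary predicates on a
# promoter's motif occurrences, their canonical string grammar, and the
# enumeration of all candidate features for a motif collection.
#
# Classes and grammar (positions are TSS-relative, bins half-open):
#   PRESENCE            PRES:<motif>
#   PRESENCE_ORIENTED   PRESO:<motif>:<strand>
#   POSITION_TSS        POS:<motif>:<strand>:[lo,hi)
#   PAIR_DISTANCE       PDIST:<a>(<sa>)><b>(<sb>):[lo,hi)     (start-to-start
#                       separation, a is the starting point)
#   ORDER               ORDER:<up|down>:<a>(<sa>)><b>(<sb>)   (a before b,
#                       reading upstream -> downstream, on one side of TSS)
#   PAIR_TSS_DISTANCE   PTSS:<a>:<b>:[lo,hi)                  (distance of the
#                       pair's closest motif to the TSS, any strands)

FEATURE_TYPES <- c("PRESENCE", "PRESENCE_ORIENTED", "POSITION_TSS",
                   "PAIR_DISTANCE", "ORDER", "PAIR_TSS_DISTANCE")

#' Windowing configuration for feature enumeration
#'
#' The promoter spans `[-upstream, +downstream)` around the TSS and is tiled
#' with `window`-bp bins: 20 position bins over the whole region, 20
#' separation bins for pairwise distances, and `upstream / window` bins for
#' the pair-to-TSS distance (min |r| never exceeds `upstream`; the last bin
#' is closed so |r| = upstream is representable).
#'
#' @param window Bin width in bp (default 100).
#' @param upstream,downstream Promoter extent around the TSS.
#' @return A `feature_config` list.
#' @export
feature_config <- function(window = 100L, upstream = PROMOTER_UPSTREAM,
                           downstream = PROMOTER_DOWNSTREAM) {
  stopifnot(window > 0, upstream %% window == 0, downstream %% window == 0)
  structure(list(
    window = as.integer(window),
    upstream = as.integer(upstream),
    downstream = as.integer(downstream),
    n_pos_bins = as.integer((upstream + downstream) / window),
    n_pair_bins = as.integer((upstream + downstream) / window),
    n_ptss_bins = as.integer(upstream / window)
  ), class = "feature_config")
}

bin_label <- function(bin, lo_of_bin, window) {
  lo <- lo_of_bin(bin)
  sprintf("[%d,%d)", lo, lo + window)
}

feature_frame <- function(desc, ftype, motif_a, motif_b = NA_character_,
                          strand_a = "any", strand_b = NA_character_,
                          bin = NA_integer_, side = NA_character_) {
  data.frame(desc = desc, ftype = ftype, motif_a = motif_a, motif_b = motif_b,
             strand_a = strand_a, strand_b = strand_b, bin = as.integer(bin),
             side = side, stringsAsFactors = FALSE)
}

#' Enumerate all candidate structural features for a motif collection
#'
#' For `m` motifs and `P = m(m+1)/2` unordered motif pairs (self-pairs
#' included) the default configuration yields
#' `m` PRESENCE + `2m` PRESENCE_ORIENTED + `40m` POSITION_TSS +
#' `80P` PAIR_DISTANCE (4 strand combinations x 20 bins) +
#' `15P` PAIR_TSS_DISTANCE + `8m^2` ORDER (ordered oriented pairs x 2 sides)
#' descriptors, in a deterministic canonical order.
#'
#' @param motif_names Character vector of distinct motif names.
#' @param config A [feature_config()].
#' @return Feature data frame (`desc`, `ftype`, `motif_a`, `motif_b`,
#'   `strand_a`, `strand_b`, `bin`, `side`), one row per descriptor.
#' @export
enumerate_candidate_features <- function(motif_names, config = feature_config()) {
  if (length(motif_names) == 0L) {
    return(data.frame(desc = character(0), ftype = character(0),
                      motif_a = character(0), motif_b = character(0),
                      strand_a = character(0), strand_b = character(0),
                      bin = integer(0), side = character(0),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(motif_names)) stop_param("duplicate motif names")
  if (any(grepl("[:()>]", motif_names))) {
    stop_param("motif names must not contain the reserved characters :()>")
  }
  m <- sort(as.character(motif_names))
  strands <- c("+", "-")
  w <- config$window
  pos_lo <- function(b) b * w - config$upstream
  sep_lo <- function(b) b * w
  out <- list()

  out$pres <- feature_frame(paste0("PRES:", m), "PRESENCE", m)

  g <- expand.grid(s = strands, m = m, stringsAsFactors = FALSE)
  out$preso <- feature_frame(paste0("PRESO:", g$m, ":", g$s),
                             "PRESENCE_ORIENTED", g$m, strand_a = g$s)

  g <- expand.grid(b = seq_len(config$n_pos_bins) - 1L, s = strands, m = m,
                   stringsAsFactors = FALSE)
  out$pos <- feature_frame(
    paste0("POS:", g$m, ":", g$s, ":", bin_label(g$b, pos_lo, w)),
    "POSITION_TSS", g$m, strand_a = g$s, bin = g$b)

  pairs <- which(upper.tri(matrix(0, length(m), length(m)), diag = TRUE),
                 arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  pa <- m[pairs[, "row"]]
  pb <- m[pairs[, "col"]]
  g <- expand.grid(b = seq_len(config$n_pair_bins) - 1L,
                   sb = strands, sa = strands, i = seq_along(pa),
                   stringsAsFactors = FALSE)
  out$pdist <- feature_frame(
    paste0("PDIST:", pa[g$i], "(", g$sa, ")>", pb[g$i], "(", g$sb, "):",
           bin_label(g$b, sep_lo, w)),
    "PAIR_DISTANCE", pa[g$i], motif_b = pb[g$i],
    strand_a = g$sa, strand_b = g$sb, bin = g$b)

  g <- expand.grid(b = seq_len(config$n_ptss_bins) - 1L, i = seq_along(pa),
                   stringsAsFactors = FALSE)
  out$ptss <- feature_frame(
    paste0("PTSS:", pa[g$i], ":", pb[g$i], ":", bin_label(g$b, sep_lo, w)),
    "PAIR_TSS_DISTANCE", pa[g$i], motif_b = pb[g$i], bin = g$b)

  g <- expand.grid(sb = strands, sa = strands, mb = m, ma = m,
                   side = c("up", "down"), stringsAsFactors = FALSE)
  out$order <- feature_frame(
    paste0("ORDER:", g$side, ":", g$ma, "(", g$sa, ")>", g$mb, "(", g$sb, ")"),
    "ORDER", g$ma, motif_b = g$mb, strand_a = g$sa, strand_b = g$sb,
    side = g$side)

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parse feature descriptor strings
#'
#' Inverse of the canonical string grammar used by
#' [enumerate_candidate_features()]; `parse_features(df$desc)` round-trips.
#'
#' @param desc Character vector of descriptor strings.
#' @param config The [feature_config()] the descriptors refer to (needed to
#'   recover bin indices from interval labels).
#' @return Feature data frame as in [enumerate_candidate_features()].
#' @export
parse_features <- function(desc, config = feature_config()) {
  w <- config$window
  one <- function(d) {
    parts <- strsplit(d, ":", fixed = TRUE)[[1L]]
    tag <- parts[1L]
    bin_from <- function(label, lo0) {
      mt <- regmatches(label, regexec("^\\[(-?\\d+),(-?\\d+)\\)$", label))[[1L]]
      if (length(mt) == 0L) stop_param("malformed bin label '%s' in '%s'", label, d)
      lo <- as.integer(mt[2L])
      if ((lo - lo0) %% w != 0L) stop_param("bin '%s' off the %d-bp grid in '%s'", label, w, d)
      (lo - lo0) %/% w
    }
    pair_from <- function(s) {
      mt <- regmatches(s, regexec("^(.+)\\(([+-])\\)>(.+)\\(([+-])\\)$", s))[[1L]]
      if (length(mt) == 0L) stop_param("malformed motif pair '%s' in '%s'", s, d)
      mt[-1L]
    }
    switch(tag,
      PRES = {
        if (length(parts) != 2L) stop_param("malformed descriptor '%s'", d)
        feature_frame(d, "PRESENCE", parts[2L])
      },
      PRESO = {
        if (length(parts) != 3L || !parts[3L] %in% c("+", "-"))
          stop_param("malformed descriptor '%s'", d)
        feature_frame(d, "PRESENCE_ORIENTED", parts[2L], strand_a = parts[3L])
      },
      POS = {
        if (length(parts) != 4L || !parts[3L] %in% c("+", "-"))
          stop_param("malformed descriptor '%s'", d)
        feature_frame(d, "POSITION_TSS", parts[2L], strand_a = parts[3L],
                      bin = bin_from(parts[4L], -config$upstream))
      },
      PDIST = {
        if (length(parts) != 3L) stop_param("malformed descriptor '%s'", d)
        p <- pair_from(parts[2L])
        feature_frame(d, "PAIR_DISTANCE", p[1L], motif_b = p[3L],
                      strand_a = p[2L], strand_b = p[4L],
                      bin = bin_from(parts[3L], 0L))
      },
      ORDER = {
        if (length(parts) != 3L || !parts[2L] %in% c("up", "down"))
          stop_param("malformed descriptor '%s'", d)
        p <- pair_from(parts[3L])
        feature_frame(d, "ORDER", p[1L], motif_b = p[3L], strand_a = p[2L],
                      strand_b = p[4L], side = parts[2L])
      },
      PTSS = {
        if (length(parts) != 4L) stop_param("malformed descriptor '%s'", d)
        feature_frame(d, "PAIR_TSS_DISTANCE", parts[2L], motif_b = parts[3L],
                      bin = bin_from(parts[4L], 0L))
      },
      stop_param("unknown feature type tag '%s' in '%s'", tag, d)
    )
  }
  res <- do.call(rbind, lapply(desc, one))
  rownames(res) <- NULL
  res
}

as_feature_frame <- function(features, config = feature_config()) {
  if (is.character(features)) return(parse_features(features, config))
  stopifnot(is.data.frame(features), "desc" %in% names(features))
  features
}
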