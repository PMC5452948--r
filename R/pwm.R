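# Position weight matrices: construction, information content, and motif-file
# parsers (JASPAR PFM and MEME minimal formats).

#' Construct a position weight matrix
#'
#' @param name Motif name (must not contain the characters `: ( ) >`, which
#'   are reserved by the feature-descriptor grammar).
#' @param probs Numeric L x 4 matrix of per-position base probabilities,
#'   columns A, C, G, T. Each row must sum to 1 (tolerance 1e-9).
#' @param pseudocount Pseudocount used if the matrix was built from counts
#'   (recorded for provenance).
#' @param source `"denovo"` or `"database"`; database motifs outrank de novo
#'   motifs on information-content ties during deduplication.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, probs, pseudocount = 0, source = c("denovo", "database")) {
  source <- match.arg(source)
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop_param("pwm '%s': probs must have 4 columns", name)
  if (grepl("[:()>]", name)) {
    stop_param("motif name '%s' contains reserved characters :()> ", name)
  }
  colnames(probs) <- .BASES
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9)) {
    stop_param("pwm '%s': rows must sum to 1 (max deviation %.3g)",
               name, max(abs(rs - 1)))
  }
  if (any(probs < 0)) stop_param("pwm '%s': negative probabilities", name)
  if (nrow(probs) > 12L) {
    warning(sprintf("pwm '%s' is %d bp long; typical motifs are 6-12 bp",
                    name, nrow(probs)))
  }
  structure(list(name = name, probs = probs, pseudocount = pseudocount,
                 source = source),
            class = "pwm")
}

#' Build a PWM from a count matrix
#'
#' @param name Motif name.
#' @param counts L x 4 nonnegative count matrix (columns A, C, G, T).
#' @param pseudocount Added to every cell before normalisation (default 0.01
#'   per cell keeps log-odds finite for sparse count matrices).
#' @param source See [pwm()].
#' @return A `pwm`.
#' @export
pwm_from_counts <- function(name, counts, pseudocount = 0.01,
                            source = c("denovo", "database")) {
  counts <- as.matrix(counts) + pseudocount
  pwm(name, counts / rowSums(counts), pseudocount = pseudocount,
      source = match.arg(source))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%s): %d positions, IC %.2f bits\n",
              x$name, x$source, nrow(x$probs), information_content(x)))
  invisible(x)
}

pwm_length <- function(x) nrow(x$probs)

#' Reverse complement of a PWM
#' @param x A [pwm()].
#' @return A `pwm` describing the motif on the opposite strand.
#' @export
revcomp_pwm <- function(x) {
  p <- x$probs[rev(seq_len(nrow(x$probs))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(p) <- .BASES
  pwm(x$name, p, pseudocount = x$pseudocount, source = x$source)
}

#' Information content of a PWM
#'
#' Sum over positions of the Kullback-Leibler divergence (in bits) of the
#' position's base distribution from the background:
#' `sum_b p(b) * log2(p(b) / q(b))`, with `0 * log 0 = 0`.
#'
#' @param pwm A [pwm()].
#' @param background Background base frequencies (A, C, G, T), summing to 1,
#'   all positive.
#' @return Information content in bits (nonnegative).
#' @export
information_content <- function(pwm, background = rep(0.25, 4)) {
  check_background(background)
  p <- pwm$probs
  ratio <- sweep(p, 2L, background, "/")
  terms <- ifelse(p > 0, p * log2(ratio), 0)
  sum(terms)
}

check_background <- function(background) {
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop_param("background must be 4 positive frequencies summing to 1")
  }
  invisible(background)
}

#' Read motifs from a JASPAR PFM file
#'
#' Accepts the JASPAR format: a `>identifier [name]` header line followed by
#' four rows `A [ 1 2 3 ]` ... `T [ ... ]` (brackets optional). Count
#' matrices are converted to probabilities with `pseudocount`.
#'
#' @param path File path.
#' @param pseudocount Passed to [pwm_from_counts()].
#' @param source Motif provenance, default `"database"`.
#' @return A list of [pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01, source = "database") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop_param("no '>' headers in %s", path)
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    name <- strsplit(hdr, "\\s+")[[1L]][1L]
    body <- lines[seq.int(starts[i] + 1L, bounds[i + 1L] - 1L)]
    rows <- lapply(body, function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1L]]
      base <- toupper(parts[1L])
      if (base %in% .BASES) parts <- parts[-1L] else base <- NA_character_
      list(base = base, vals = as.numeric(parts))
    })
    vals <- lapply(rows, `[[`, "vals")
    bases <- vapply(rows, `[[`, character(1), "base")
    mat <- do.call(rbind, vals)
    if (!anyNA(bases)) mat <- mat[match(.BASES, bases), , drop = FALSE]
    counts <- t(mat)  # rows = positions, cols = A,C,G,T
    out[[i]] <- pwm_from_counts(name, counts, pseudocount = pseudocount,
                                source = source)
  }
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Write motifs to a JASPAR-style PFM file
#'
#' Probabilities are written directly (JASPAR files may hold counts or
#' frequencies); [read_jaspar()] with `pseudocount = 0` round-trips them.
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (b in seq_along(.BASES)) {
      writeLines(sprintf("%s  [ %s ]", .BASES[b],
                         paste(format(p$probs[, b], digits = 10),
                               collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read motifs from a MEME minimal-format file
#'
#' Parses `MOTIF <name>` blocks with their `letter-probability matrix:`
#' sections (alphabet ACGT assumed).
#'
#' @param path File path.
#' @param source Motif provenance, default `"denovo"` (MEME output).
#' @return A list of [pwm()] objects.
#' @export
read_meme <- function(path, source = "denovo") {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^MOTIF\\s", lines)
  if (length(heads) == 0L) stop_param("no MOTIF blocks in %s", path)
  out <- list()
  for (h in heads) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[h])), "\\s+")[[1L]][1L]
    mstart <- h + grep("letter-probability matrix", lines[seq.int(h, length(lines))])[1L] - 1L
    if (is.na(mstart)) stop_param("MOTIF %s has no letter-probability matrix", name)
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mstart])))
    rows <- list()
    i <- mstart + 1L
    while (i <= length(lines)) {
      parts <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
      if (length(parts) != 4L || anyNA(parts)) break
      rows[[length(rows) + 1L]] <- parts
      i <- i + 1L
      if (!is.na(w) && length(rows) == w) break
    }
    probs <- do.call(rbind, rows)
    probs <- probs / rowSums(probs)  # guard against rounding in the file
    out[[name]] <- pwm(name, probs, source = source)
  }
  out
}
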