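# Synthetic promoter cohorts with planted motif architectures.
#
# Background sequences are 0-order i.i.d. at a chosen GC content; each
# planted feature descriptor is instantiated per promoter with its class
# penetrance by sampling motif instances from the PWMs and writing them at
# positions/strands/separations satisfying the descriptor (uniformly over
# satisfying placements, rejection sampling against previously planted
# instances). Control promoters receive the same features at their control
# penetrance, emulating imperfect class separation.

#' Generate a PWM from a consensus word
#'
#' Each column puts probability `sharpness` on the consensus base and the
#' remainder uniformly on the other three bases; `sharpness = 1` gives a
#' deterministic motif, `sharpness = 0.25` a fully uninformative one.
#'
#' @param consensus Word over A/C/G/T, length 6-12.
#' @param sharpness Probability mass on the consensus base, in (0, 1].
#' @param source Motif provenance tag.
#' @return A [pwm()] named after the consensus.
#' @export
generate_pwm <- function(consensus, sharpness = 1, source = "denovo") {
  consensus <- toupper(consensus)
  letters_ <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  if (!all(letters_ %in% .BASES)) {
    stop_param("consensus '%s' contains characters outside ACGT", consensus)
  }
  if (nchar(consensus) < 6L || nchar(consensus) > 12L) {
    stop_param("consensus length must be 6-12, got %d", nchar(consensus))
  }
  if (sharpness <= 0 || sharpness > 1) stop_param("sharpness must be in (0, 1]")
  probs <- matrix((1 - sharpness) / 3, nrow = length(letters_), ncol = 4L,
                  dimnames = list(NULL, .BASES))
  probs[cbind(seq_along(letters_), match(letters_, .BASES))] <- sharpness
  pwm(consensus, probs, source = source)
}

#' Specification of a synthetic promoter cohort
#'
#' @param planted Data frame with columns `desc` (feature descriptor
#'   string), `penetrance_pos`, `penetrance_ctrl` (fractions of each class's
#'   promoters in which the feature is instantiated).
#' @param n_pos,n_ctrl Cohort sizes (defaults 200 + 200, the scale at which
#'   the workflow is exercised end to end).
#' @param promoter_length Fixed at 2000 nt (TSS at index 1500).
#' @param background_gc Background GC content; the default 0.42 matches a
#'   fly-like genome.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param id_prefix Prefix for generated gene ids (keeps independent cohorts
#'   disjoint, e.g. `"val_"` for a validation universe).
#' @param config A [feature_config()].
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(planted, n_pos = 200L, n_ctrl = 200L,
                              promoter_length = 2000L, background_gc = 0.42,
                              seed = 1L, id_prefix = "",
                              config = feature_config()) {
  stopifnot(is.data.frame(planted),
            all(c("desc", "penetrance_pos", "penetrance_ctrl") %in% names(planted)))
  if (any(planted$penetrance_pos < 0 | planted$penetrance_pos > 1 |
          planted$penetrance_ctrl < 0 | planted$penetrance_ctrl > 1)) {
    stop_param("penetrances must lie in [0, 1]")
  }
  if (background_gc <= 0 || background_gc >= 1) {
    stop_param("background_gc must lie in (0, 1)")
  }
  if (promoter_length != config$upstream + config$downstream) {
    stop_param("promoter_length must equal upstream + downstream of config")
  }
  features <- parse_features(planted$desc, config)
  structure(list(planted = planted, features = features,
                 n_pos = as.integer(n_pos), n_ctrl = as.integer(n_ctrl),
                 promoter_length = as.integer(promoter_length),
                 background_gc = background_gc, seed = seed,
                 id_prefix = id_prefix, config = config),
            class = "architecture_spec")
}

# Draw one motif instance (character string) from a PWM.
sample_motif_instance <- function(pwm) {
  idx <- apply(pwm$probs, 1L, function(p) sample.int(4L, 1L, prob = p))
  paste(.BASES[idx], collapse = "")
}

overlaps_any <- function(start, end, occupied) {
  any(start < occupied$end & occupied$start < end)
}

rand_strand <- function(s) if (s %in% c("+", "-")) s else sample(c("+", "-"), 1L)

# Sample placements (start positions + strands for one or two instances)
# satisfying a parsed descriptor row; NULL when no satisfying placement was
# found within the retry budget.
sample_placement <- function(f, la, lb, plen, cfg, occupied, retries = 50L) {
  w <- cfg$window
  up <- cfg$upstream
  for (r in seq_len(retries)) {
    pl <- switch(f$ftype,
      PRESENCE = ,
      PRESENCE_ORIENTED = {
        list(list(start = sample.int(plen - la + 1L, 1L) - 1L,
                  strand = rand_strand(f$strand_a), which = "a"))
      },
      POSITION_TSS = {
        lo <- f$bin * w
        hi <- min(lo + w, plen - la + 1L)
        if (hi <= lo) return(NULL)
        list(list(start = lo + sample.int(hi - lo, 1L) - 1L,
                  strand = rand_strand(f$strand_a), which = "a"))
      },
      PAIR_DISTANCE = {
        lo <- f$bin * w
        hi <- lo + w
        sep <- lo + sample.int(hi - lo, 1L) - 1L
        amax <- plen - lb - sep
        if (amax < 1L || sep < la) next  # also reject overlapping pairs
        a <- sample.int(amax, 1L) - 1L
        list(list(start = a, strand = rand_strand(f$strand_a), which = "a"),
             list(start = a + sep, strand = rand_strand(f$strand_b), which = "b"))
      },
      ORDER = {
        rng <- if (f$side == "up") c(0L, up - 1L) else c(up, plen - 1L)
        amax <- rng[2L] - lb + 1L  # leave room for b after a
        if (amax <= rng[1L]) return(NULL)
        a <- rng[1L] + sample.int(amax - rng[1L], 1L) - 1L
        bmin <- a + la  # strict order, non-overlapping
        bmax <- rng[2L] - lb + 1L
        if (bmax < bmin) next
        b <- bmin + sample.int(bmax - bmin + 1L, 1L) - 1L
        list(list(start = a, strand = f$strand_a, which = "a"),
             list(start = b, strand = f$strand_b, which = "b"))
      },
      PAIR_TSS_DISTANCE = {
        lo <- f$bin * w
        hi <- if (f$bin == cfg$n_ptss_bins - 1L) up else f$bin * w + w - 1L
        absr_a <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        # choose upstream or downstream placement for the close motif
        sides <- c(if (up - absr_a >= 0L) "u",
                   if (absr_a + la <= plen - up) "d")
        if (length(sides) == 0L) next
        a <- if (sample(sides, 1L) == "u") up - absr_a else up + absr_a
        if (a < 0L || a + la > plen) next
        # the partner sits at least as far from the TSS
        cand <- which(abs(seq_len(plen - lb + 1L) - 1L - up) >= absr_a) - 1L
        if (length(cand) == 0L) next
        b <- cand[sample.int(length(cand), 1L)]
        list(list(start = a, strand = rand_strand("any"), which = "a"),
             list(start = b, strand = rand_strand("any"), which = "b"))
      },
      stop_param("unknown feature type %s", f$ftype)
    )
    if (is.null(pl)) return(NULL)
    lens <- vapply(pl, function(p) if (p$which == "a") la else lb, integer(1))
    starts <- vapply(pl, `[[`, numeric(1), "start")
    ends <- starts + lens
    self_clash <- length(pl) == 2L &&
      (starts[1L] < ends[2L] && starts[2L] < ends[1L])
    if (self_clash) next
    clash <- any(vapply(seq_along(pl), function(i) {
      overlaps_any(starts[i], ends[i], occupied)
    }, logical(1)))
    if (!clash) return(pl)
  }
  NULL
}

#' Generate a synthetic promoter cohort with planted architectures
#'
#' @param spec An [architecture_spec()].
#' @param pwms List of [pwm()] objects covering every motif named in the
#'   planted descriptors.
#' @return List with `positives` and `controls` ([promoter_set()]s), and
#'   `truth`: one row per planting attempt (`gene_id`, `class`, `desc`,
#'   `motif`, `start`, `strand`, `placed`).
#' @export
generate_cohort <- function(spec, pwms) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  need <- unique(c(spec$features$motif_a,
                   spec$features$motif_b[!is.na(spec$features$motif_b)]))
  missing <- setdiff(need, names(pwms))
  if (length(missing) > 0L) {
    stop_param("no PWM for planted motif(s): %s", paste(missing, collapse = ", "))
  }
  validate_realizable(spec, pwms)
  gc <- spec$background_gc
  bgp <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  with_seed(spec$seed, {
    make_class <- function(n, prefix, pen_col) {
      seqs <- character(n)
      truth <- list()
      ids <- sprintf("%s%s_%04d", spec$id_prefix %||% "", prefix, seq_len(n))
      for (i in seq_len(n)) {
        chars <- sample(.BASES, spec$promoter_length, replace = TRUE, prob = bgp)
        occupied <- data.frame(start = integer(0), end = integer(0))
        for (fi in seq_len(nrow(spec$features))) {
          if (stats::runif(1L) >= spec$planted[[pen_col]][fi]) next
          f <- spec$features[fi, ]
          pa <- pwms[[f$motif_a]]
          pb <- if (!is.na(f$motif_b)) pwms[[f$motif_b]] else pa
          pl <- sample_placement(f, pwm_length(pa), pwm_length(pb),
                                 spec$promoter_length, spec$config, occupied)
          if (is.null(pl)) {
            warning(sprintf("gene %s: no placement for %s; skipped",
                            ids[i], f$desc))
            truth[[length(truth) + 1L]] <- data.frame(
              gene_id = ids[i], class = prefix, desc = f$desc,
              motif = NA_character_, start = NA_integer_,
              strand = NA_character_, placed = FALSE)
            next
          }
          for (p in pl) {
            mot <- if (p$which == "a") pa else pb
            inst <- sample_motif_instance(mot)
            if (p$strand == "-") inst <- revcomp(inst)
            pos <- p$start
            chars[seq.int(pos + 1L, pos + nchar(inst))] <-
              strsplit(inst, "", fixed = TRUE)[[1L]]
            occupied <- rbind(occupied,
                              data.frame(start = pos, end = pos + nchar(inst)))
            truth[[length(truth) + 1L]] <- data.frame(
              gene_id = ids[i], class = prefix, desc = f$desc,
              motif = mot$name, start = pos, strand = p$strand, placed = TRUE)
          }
        }
        seqs[i] <- paste(chars, collapse = "")
      }
      list(ps = promoter_set(gene_id = ids, seq = seqs),
           truth = if (length(truth) > 0L) do.call(rbind, truth) else NULL)
    }
    pos <- make_class(spec$n_pos, "pos", "penetrance_pos")
    ctrl <- make_class(spec$n_ctrl, "ctrl", "penetrance_ctrl")
    truth <- rbind(pos$truth, ctrl$truth)
    if (is.null(truth)) {
      truth <- data.frame(gene_id = character(0), class = character(0),
                          desc = character(0), motif = character(0),
                          start = integer(0), strand = character(0),
                          placed = logical(0))
    }
    list(positives = pos$ps, controls = ctrl$ps, truth = truth, spec = spec)
  })
}

validate_realizable <- function(spec, pwms) {
  plen <- spec$promoter_length
  w <- spec$config$window
  for (fi in seq_len(nrow(spec$features))) {
    f <- spec$features[fi, ]
    la <- pwm_length(pwms[[f$motif_a]])
    lb <- if (!is.na(f$motif_b)) pwm_length(pwms[[f$motif_b]]) else la
    # the smallest value in the bin must leave room inside the promoter
    bad <- switch(f$ftype,
      PAIR_DISTANCE = f$bin * w + lb > plen,        # separation beyond the end
      POSITION_TSS = f$bin * w + la > plen,         # window beyond the end
      PAIR_TSS_DISTANCE = f$bin * w > spec$config$upstream,
      FALSE)
    if (isTRUE(bad)) {
      stop_param("descriptor '%s' is unsatisfiable in a %d-nt promoter",
                 f$desc, plen)
    }
  }
  invisible(spec)
}

#' The default synthetic study conditions
#'
#' Six 8-bp consensus motifs and four planted features, one from each of the
#' positionally informative classes (TSS-relative position, oriented
#' presence, pairwise distance, order), planted at penetrance 0.9 in
#' positives and 0.1 in controls over a 200 + 200 cohort.
#'
#' @param seed Cohort seed.
#' @param n_pos,n_ctrl Cohort sizes.
#' @param sharpness PWM sharpness (default 1: exact consensus words, so that
#'   planting penetrance and detection penetrance coincide).
#' @return List with `spec` (an [architecture_spec()]) and `pwms`.
#' @export
example_cohort <- function(seed = 1L, n_pos = 200L, n_ctrl = 200L,
                           sharpness = 1) {
  consensi <- c("ACGGATTC", "TGCCGTAA", "CAGTTGCC", "GGATACGG",
                "TTGCACGA", "CATGGTCC")
  pwms <- lapply(consensi, generate_pwm, sharpness = sharpness)
  planted <- data.frame(
    desc = c("POS:ACGGATTC:+:[-300,-200)",
             "PRESO:TGCCGTAA:-",
             "PDIST:CAGTTGCC(+)>GGATACGG(+):[100,200)",
             "ORDER:up:TTGCACGA(-)>CATGGTCC(+)"),
    penetrance_pos = rep(0.9, 4),
    penetrance_ctrl = rep(0.1, 4),
    stringsAsFactors = FALSE)
  spec <- architecture_spec(planted, n_pos = n_pos, n_ctrl = n_ctrl,
                            seed = seed)
  list(spec = spec, pwms = pwms)
}
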