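# PWM information content, scanning, matrix comparison, deduplication, ORI.

test_that("information content matches closed forms", {
  uni <- pwm("uni", matrix(0.25, 1, 4))
  expect_equal(information_content(uni), 0)
  det <- pwm("det", matrix(c(1, 0, 0, 0), 1, 4))
  expect_equal(information_content(det), 2)
  det8 <- pwm("det8", matrix(rep(c(1, 0, 0, 0), each = 8), 8, 4))
  expect_equal(information_content(det8), 16)
  # per-position sum against an independent column-wise computation
  set.seed(41)
  p <- random_probs(6)
  bg <- c(0.3, 0.2, 0.2, 0.3)
  manual <- sum(vapply(1:6, function(i) {
    sum(ifelse(p[i, ] > 0, p[i, ] * log2(p[i, ] / bg), 0))
  }, numeric(1)))
  expect_equal(information_content(pwm("r", p), bg), manual)
  expect_error(information_content(uni, c(0, 0.5, 0.25, 0.25)), "background")
})

test_that("scanning finds planted matches on both strands with promoter coordinates", {
  word <- "ACGGTACA"
  m <- pwm(word, local({
    idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
    mat <- matrix(0, 8, 4); mat[cbind(1:8, idx)] <- 1; mat
  }))
  set.seed(42)
  base <- rnd_seq(2000)
  s <- plant_word(plant_word(base, word, 300), rc_word(word), 700)
  occ <- scan_promoter(m, promoter_set("g", s), threshold_fraction = 1)
  plus <- occ[occ$strand == "+", ]
  minus <- occ[occ$strand == "-", ]
  expect_true(any(plus$start == 300))
  expect_true(any(minus$start == 700))
  expect_equal(occ$end - occ$start, rep(8L, nrow(occ)))
})

test_that("N positions never match and short promoters yield empty results", {
  m <- generate_pwm("ACGGTACA")
  allN <- promoter_set("n", paste(rep("N", 2000), collapse = ""))
  expect_equal(nrow(scan_promoter(m, allN, threshold_fraction = 1)), 0L)
  short <- promoter_set("s", "ACG")
  expect_equal(nrow(scan_promoter(m, short)), 0L)
})

test_that("lowering the threshold only adds occurrences (monotonicity)", {
  set.seed(43)
  for (rep in 1:5) {
    m <- pwm(paste0("r", rep), random_probs(8))
    s <- promoter_set("g", rnd_seq(2000))
    prev <- NULL
    for (tf in c(1, 0.9, 0.8, 0.7)) {
      occ <- scan_promoter(m, s, threshold_fraction = tf)
      key <- paste(occ$start, occ$strand)
      if (!is.null(prev)) expect_true(all(prev %in% key))
      prev <- key
    }
  }
})

test_that("scanning the reverse complement mirrors coordinates and swaps strands", {
  set.seed(44)
  m <- pwm("r", random_probs(7))
  s <- rnd_seq(500)
  occ_f <- scan_promoter(m, promoter_set("g", s), threshold_fraction = 0.85)
  occ_r <- scan_promoter(m, promoter_set("g", rc_word(s)),
                         threshold_fraction = 0.85)
  mirrored <- data.frame(start = nchar(s) - occ_f$end,
                         strand = ifelse(occ_f$strand == "+", "-", "+"))
  expect_setequal(paste(occ_r$start, occ_r$strand),
                  paste(mirrored$start, mirrored$strand))
})

test_that("the scanner agrees with an independent PWM matcher on plus-strand hits", {
  set.seed(45)
  probs <- (0.7 * diag(4)[rep_len(1:4, 9), ] + 0.1)
  probs <- probs / rowSums(probs)
  m <- pwm("x", probs)
  # plant exact and one-mismatch copies of the consensus among random sequence
  word <- "ACGTACGTA"
  s <- rnd_seq(3000)
  s <- plant_word(s, word, 100)
  s <- plant_word(s, sub("^A", "C", word), 500)   # 1 mismatch
  s <- plant_word(s, "TTTTTTTTT", 900)            # far from consensus
  occ <- scan_promoter(m, promoter_set("g", s), threshold_fraction = 0.6)
  expect_true(100 %in% occ$start)
  lo <- t(log2(m$probs / 0.25))
  rownames(lo) <- c("A", "C", "G", "T")
  thr <- 0.6 * sum(apply(lo, 2, max))
  ref <- Biostrings::matchPWM(lo, s, min.score = thr)
  expect_setequal(occ$start[occ$strand == "+"],
                  Biostrings::start(ref) - 1L)
})

test_that("motif distance is zero for identity and reverse complements", {
  set.seed(46)
  a <- pwm("a", random_probs(8))
  d <- motif_distance(a, a, n_null = 100, seed = 1)
  expect_equal(d$distance, 0)
  expect_equal(d$offset, 0L)
  expect_equal(d$orientation, "same")
  expect_lte(d$pvalue, 0.01)

  drc <- motif_distance(a, revcomp_pwm(a), n_null = 100, seed = 1)
  expect_equal(drc$distance, 0)
  expect_equal(drc$orientation, "reverse-complement")
})

test_that("letter-disjoint homopolymer matrices sit at the sqrt(2) plateau", {
  a <- pwm("a", matrix(rep(c(1, 0, 0, 0), each = 6), 6, 4))
  b <- pwm("b", matrix(rep(c(0, 1, 0, 0), each = 6), 6, 4))
  # every alignment (and both orientations give C- or G-columns) pairs a
  # deterministic A column with a disjoint column: distance sqrt(2) per
  # column at any overlap, so the minimum over partial overlaps is sqrt(2)
  d <- motif_distance(a, b, n_null = 100, seed = 1)
  expect_equal(d$distance, sqrt(2))
})

test_that("motif distance equals the brute-force minimum and is symmetric", {
  set.seed(47)
  for (rep in 1:8) {
    pa <- random_probs(sample(6:9, 1))
    pb <- random_probs(sample(6:9, 1))
    a <- pwm("a", pa); b <- pwm("b", pb)
    dab <- motif_distance(a, b, n_null = 100, seed = rep)
    expect_equal(dab$distance, naive_min_dist(pa, pb), tolerance = 1e-12)
    dba <- motif_distance(b, a, n_null = 100, seed = rep)
    expect_equal(dab$distance, dba$distance, tolerance = 1e-12)
  }
})

test_that("deduplication keeps the higher-information motif of a similar pair", {
  counts <- matrix(rep(c(90, 3, 3, 4), each = 8), 8, 4)
  sharp <- pwm_from_counts("sharp", counts, pseudocount = 0.01)
  # same counts smoothed harder: nearly the same matrix, lower information
  blurred <- pwm_from_counts("blurred", counts, pseudocount = 0.5)
  expect_lt(information_content(blurred), information_content(sharp))
  kept <- deduplicate_motifs(list(blurred, sharp), n_null = 2000, seed = 1)
  expect_equal(vapply(kept, `[[`, "", "name"), "sharp")

  dup <- deduplicate_motifs(list(sharp, pwm_from_counts(
    "zcopy", counts, pseudocount = 0.01)), n_null = 2000, seed = 1)
  # equal information content: lexicographically smaller name retained
  expect_equal(vapply(dup, `[[`, "", "name"), "sharp")

  set.seed(48)
  rnd <- lapply(1:3, function(i) pwm(paste0("r", i), random_probs(8)))
  expect_equal(length(deduplicate_motifs(rnd, n_null = 1000, seed = 2)), 3L)
  expect_error(deduplicate_motifs(list(sharp, sharp)), "duplicate")
})

test_that("ORI matches hand-computed density-ratio x containment values", {
  word <- "CCGGTTCC"  # no A: poly-A filler can never match on either strand
  m <- generate_pwm(word)
  filler <- function(n) paste(rep("A", n), collapse = "")
  tgt_hit <- plant_word(filler(1000), word, 100)
  tgt_miss <- filler(1000)
  bg_hit <- plant_word(filler(1000), word, 500)

  expect_equal(overrepresentation_index(m, c(tgt_miss, tgt_miss),
                                        c(bg_hit, filler(1000))), 0)
  # equal densities, motif in every target promoter -> ORI 1
  expect_equal(overrepresentation_index(m, c(tgt_hit, tgt_hit),
                                        c(bg_hit, bg_hit)), 1)
  # density ratio 3 (6 copies / 4 kb vs 0.5 / kb), containment 0.5 -> 1.5
  tgt3 <- plant_word(plant_word(plant_word(filler(1000), word, 100), word, 300),
                     word, 600)
  ori <- overrepresentation_index(m, c(tgt3, tgt3, tgt_miss, tgt_miss),
                                  c(bg_hit, filler(1000)))
  expect_equal(ori, 1.5)
  # empty background occurrences flag an infinite index
  inf <- overrepresentation_index(m, c(tgt_hit), c(filler(1000)))
  expect_true(is.infinite(inf))
  expect_true(isTRUE(attr(inf, "zero_background")))
})

test_that("the ORI permutation test is deterministic and nails planted sets", {
  word <- "CCGGTTCC"
  m <- generate_pwm(word)
  filler <- function(n) paste(rep("A", n), collapse = "")
  set.seed(49)
  seqs <- replicate(30, filler(1000))
  seqs[1:5] <- vapply(1:5, function(i) plant_word(filler(1000), word, 50 * i),
                      character(1))
  uni <- promoter_set(paste0("g", 1:30), seqs)
  bg <- c(plant_word(filler(1000), word, 10))
  r1 <- ori_permutation_test(m, paste0("g", 1:5), uni, bg, n_perm = 1000,
                             seed = 5)
  expect_equal(r1$pvalue, 0)
  expect_true(r1$overrepresented)
  r2 <- ori_permutation_test(m, paste0("g", 1:5), uni, bg, n_perm = 1000,
                             seed = 5)
  expect_identical(r1$pvalue, r2$pvalue)
  expect_error(ori_permutation_test(m, "gX", uni, bg), "missing from universe")
  expect_error(ori_permutation_test(m, "g1", uni, bg, n_perm = 10), "at least")
})

test_that("JASPAR and MEME motif files round-trip / parse", {
  p1 <- generate_pwm("ACGGTACA")
  p2 <- pwm("mix", random_probs(6))
  path <- tempfile(fileext = ".jaspar")
  write_jaspar(list(p1, p2), path)
  back <- read_jaspar(path, pseudocount = 0)
  expect_equal(names(back), c("ACGGTACA", "mix"))
  expect_equal(back$mix$probs, p2$probs, tolerance = 1e-8)

  meme <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF mot1", "letter-probability matrix: alength= 4 w= 2 nsites= 20",
               " 0.25 0.25 0.25 0.25", " 0.70 0.10 0.10 0.10"), meme)
  mm <- read_meme(meme)
  expect_equal(unname(mm$mot1$probs[2, 1]), 0.7)
  expect_equal(nrow(mm$mot1$probs), 2L)
})
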