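# Feature enumeration, the descriptor grammar, detection semantics, the
# binary matrix, symmetrical uncertainty and the correlation filter.

test_that("enumeration counts follow the closed form and are canonical", {
  count_formula <- function(m) {
    P <- m * (m + 1) / 2
    m + 2 * m + 40 * m + 80 * P + 15 * P + 8 * m^2
  }
  for (m in 1:4) {
    feats <- enumerate_candidate_features(paste0("M", seq_len(m)))
    expect_equal(nrow(feats), count_formula(m))
    expect_false(anyDuplicated(feats$desc) > 0)
  }
  expect_equal(nrow(enumerate_candidate_features(character(0))), 0L)
  expect_identical(enumerate_candidate_features(c("B", "A")),
                   enumerate_candidate_features(c("A", "B")))
  expect_error(enumerate_candidate_features(c("A", "A")), "duplicate")
  expect_error(enumerate_candidate_features("bad:name"), "reserved")
})

test_that("descriptor strings round-trip through parsing", {
  feats <- enumerate_candidate_features(c("DM-1", "DM-6"))
  idx <- round(seq(1, nrow(feats), length.out = 60))
  back <- parse_features(feats$desc[idx])
  expect_equal(back, `rownames<-`(feats[idx, ], NULL))
  expect_error(parse_features("POS:DM-1:+:[-250,-150)"), "grid")
  expect_error(parse_features("NOPE:DM-1"), "unknown feature type")
  expect_error(parse_features("ORDER:sideways:A(+)>B(-)"), "malformed")
})

occ_row <- function(motif, start, strand, gene = "g", width = 8) {
  data.frame(motif = motif, gene_id = gene, start = start,
             end = start + width, strand = strand, score = 0,
             stringsAsFactors = FALSE)
}

test_that("positional bins are half-open with the documented boundaries", {
  f <- "POS:A:+:[-300,-200)"
  expect_equal(detect_feature(f, occ_row("A", 1250, "+")), 1L)  # r = -250
  expect_equal(detect_feature(f, occ_row("A", 1300, "+")), 0L)  # r = -200
  expect_equal(detect_feature(f, occ_row("A", 1200, "+")), 1L)  # r = -300
  expect_equal(detect_feature(f, occ_row("A", 1250, "-")), 0L)  # wrong strand
  expect_equal(detect_feature(f, occ_row("B", 1250, "+")), 0L)  # wrong motif
})

test_that("order features respect side, orientation and position order", {
  f <- "ORDER:up:A(-)>B(+)"
  good <- rbind(occ_row("A", 700, "-"), occ_row("B", 1200, "+"))
  expect_equal(detect_feature(f, good), 1L)
  swapped <- rbind(occ_row("A", 1200, "-"), occ_row("B", 700, "+"))
  expect_equal(detect_feature(f, swapped), 0L)
  downstream <- rbind(occ_row("A", 1600, "-"), occ_row("B", 1800, "+"))
  expect_equal(detect_feature(f, downstream), 0L)
  expect_equal(detect_feature("ORDER:down:A(-)>B(+)", downstream), 1L)
})

test_that("a planted architecture produces the hand-computed feature vector", {
  # A+ at r=-250, A- at r=-800, B+ at r=-100 (150 after A-? no: pairs below),
  # B- at r=+200
  occ <- rbind(occ_row("A", 1250, "+"), occ_row("A", 700, "-"),
               occ_row("B", 1400, "+"), occ_row("B", 1700, "-"))
  expect_equal(detect_feature("PRES:A", occ), 1L)
  expect_equal(detect_feature("PRES:B", occ), 1L)
  expect_equal(detect_feature("PRESO:A:-", occ), 1L)
  expect_equal(detect_feature("PRESO:B:-", occ), 1L)
  expect_equal(detect_feature("POS:A:+:[-300,-200)", occ), 1L)
  expect_equal(detect_feature("POS:B:-:[200,300)", occ), 1L)
  # separation A+(1250) -> B+(1400) = 150
  expect_equal(detect_feature("PDIST:A(+)>B(+):[100,200)", occ), 1L)
  expect_equal(detect_feature("PDIST:A(+)>B(+):[200,300)", occ), 0L)
  # upstream order: A-(700) before B+(1400)? B+ is at r=-100, still upstream
  expect_equal(detect_feature("ORDER:up:A(-)>B(+)", occ), 1L)
  # closest of the A/B pair to the TSS: min(|-250|, |-100|) = 100
  expect_equal(detect_feature("PTSS:A:B:[100,200)", occ), 1L)
  expect_equal(detect_feature("PTSS:A:B:[0,100)", occ), 0L)
})

test_that("counts match the exhaustive pair-enumeration oracle", {
  set.seed(61)
  feats <- enumerate_candidate_features(c("A", "B"))
  for (rep in 1:12) {
    occ <- random_occurrences(sample(0:9, 1), c("A", "B"))
    got <- count_feature_matrix(feats, occ, "g")[1, ]
    want <- vapply(seq_len(nrow(feats)), function(i) {
      naive_feature_count(feats[i, ], occ)
    }, numeric(1))
    expect_equal(unname(got), unname(want))
  }
})

test_that("detection is monotone under added occurrences", {
  set.seed(62)
  feats <- enumerate_candidate_features(c("A", "B"))
  for (rep in 1:6) {
    occ <- random_occurrences(8, c("A", "B"))
    sub <- occ[sample.int(8, 4), ]
    v_full <- count_feature_matrix(feats, occ, "g")[1, ] > 0
    v_sub <- count_feature_matrix(feats, sub, "g")[1, ] > 0
    expect_true(all(v_full >= v_sub))
  }
})

test_that("PRESENCE equals the OR of oriented presence and of position bins", {
  set.seed(63)
  feats <- enumerate_candidate_features("A")
  for (rep in 1:8) {
    occ <- random_occurrences(sample(1:6, 1), "A")
    v <- count_feature_matrix(feats, occ, "g")[1, ] > 0
    pres <- v[["PRES:A"]]
    oriented <- v[grep("^PRESO:", names(v))]
    positions <- v[grep("^POS:", names(v))]
    expect_equal(pres, any(oriented))
    expect_equal(pres, any(positions))
  }
})

test_that("the binary matrix is assembled with labels and is order-invariant", {
  feats <- enumerate_candidate_features("A")
  empty <- build_feature_matrix(feats, promoarch:::empty_occurrences(),
                                c("p1", "p2"), c("c1", "c2"))
  expect_true(all(empty$values == 0L))
  expect_equal(as.character(empty$labels), c("positive", "positive",
                                             "control", "control"))

  occ <- rbind(occ_row("A", 100, "+", gene = "p1"),
               occ_row("A", 1600, "-", gene = "c2"))
  fm1 <- build_feature_matrix(feats, occ, c("p1", "p2"), c("c1", "c2"))
  fm2 <- build_feature_matrix(feats, occ, c("p2", "p1"), c("c2", "c1"))
  expect_equal(colSums(fm1$values), colSums(fm2$values))
  expect_error(build_feature_matrix(feats, occ, c("p1"), c("p1")), "both classes")
})

test_that("symmetrical uncertainty matches the entropy oracle and conventions", {
  x <- c(0, 0, 1, 1, 0, 1)
  expect_equal(symmetrical_uncertainty(x, x), 1)
  expect_equal(symmetrical_uncertainty(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  x8 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  y8 <- c(0, 0, 0, 0, 0, 1, 1, 1)
  expect_equal(symmetrical_uncertainty(x8, y8), naive_su(x8, y8))
  expect_equal(symmetrical_uncertainty(rep(0, 6), x), 0)  # constant convention
  expect_error(symmetrical_uncertainty(1:3, 1:4), "equal length")

  set.seed(64)
  for (rep in 1:20) {
    a <- rbinom(30, 1, 0.4)
    b <- rbinom(30, 1, 0.6)
    expect_equal(symmetrical_uncertainty(a, b), symmetrical_uncertainty(b, a))
    expect_equal(symmetrical_uncertainty(a, b), naive_su(a, b))
  }
})

test_that("the correlation filter keeps the class-defining feature and drops duplicates", {
  set.seed(65)
  y <- rep(c(1, 0), each = 20)
  X <- cbind(perfect = y,
             perfect2 = y,
             noise1 = rbinom(40, 1, 0.5),
             noise2 = rbinom(40, 1, 0.5))
  fm <- make_fm(X, ifelse(y == 1, "positive", "control"))
  kept <- correlation_filter(fm)
  # SU ties break by canonical name, so "perfect" tops the ranking and its
  # exact duplicate is removed as redundant
  expect_equal(kept$desc[1], "perfect")
  expect_false("perfect2" %in% kept$desc)
})

test_that("the correlation filter equals naive FCBF and ignores column order", {
  set.seed(66)
  for (rep in 1:10) {
    y <- rbinom(40, 1, 0.5)
    X <- sapply(1:10, function(j) {
      if (j <= 3) (y + rbinom(40, 1, 0.2)) %% 2 else rbinom(40, 1, 0.4)
    })
    colnames(X) <- paste0("f", sprintf("%02d", 1:10))
    labels <- ifelse(y == 1, "positive", "control")
    fm <- make_fm(X, labels)
    kept <- correlation_filter(fm)
    want <- colnames(X)[naive_fcbf(X, y)]
    expect_equal(kept$desc, want)

    perm <- sample(10)
    fmp <- make_fm(X[, perm], labels)
    expect_setequal(correlation_filter(fmp)$desc, kept$desc)
  }
})
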