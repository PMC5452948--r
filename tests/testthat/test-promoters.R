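# Promoter extraction, near-duplicate pruning, and gene-set splitting.

make_genome <- function(len = 10000, seed = 11) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(c(chr1 = rnd_seq(len)))
}

test_that("plus-strand promoters are the [TSS-1500, TSS+500) genomic window", {
  genome <- make_genome()
  genes <- data.frame(gene_id = "gA", chrom = "chr1", tss = 5000, strand = "+")
  ps <- extract_promoters(genome, genes)
  expect_equal(nchar(ps$seq), 2000)
  expect_equal(ps$seq, substr(genome[["chr1"]], 3501, 5500))
  expect_equal(ps$offset_of_tss, 1500)
  expect_false(ps$truncated)
  # the base at promoter index 1500 is the genomic TSS base
  expect_equal(substr(ps$seq, 1501, 1501), substr(genome[["chr1"]], 5001, 5001))
})

test_that("minus-strand promoters are reverse-complemented into gene orientation", {
  genome <- make_genome()
  word <- "GATCCGTA"
  genome["chr1"] <- plant_word(genome[["chr1"]], word, 5600)
  genes <- data.frame(gene_id = "gB", chrom = "chr1", tss = 5000, strand = "-")
  ps <- extract_promoters(genome, genes)
  expect_equal(nchar(ps$seq), 2000)
  # promoter index p maps to genomic base tss + 1500 - p; the word at
  # genomic [5600, 5608) lands reverse-complemented at promoter [893, 901)
  expect_equal(substr(ps$seq, 894, 901), rc_word(word))
  # TSS base invariant, strand-adjusted (complement on the minus strand)
  expect_equal(substr(ps$seq, 1501, 1501),
               chartr("ACGT", "TGCA", substr(genome[["chr1"]], 5001, 5001)))
})

test_that("contig edges clip the promoter and set the truncation flag", {
  genome <- make_genome()
  genes <- data.frame(gene_id = "gC", chrom = "chr1", tss = 1000, strand = "+")
  ps <- extract_promoters(genome, genes)
  expect_true(ps$truncated)
  expect_equal(nchar(ps$seq), 1500)
  expect_equal(ps$offset_of_tss, 1000)
})

test_that("bad gene rows are handled as specified", {
  genome <- make_genome()
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(5000, 5200), strand = c("+", "*"))
  expect_warning(ps <- extract_promoters(genome, genes), "malformed strand")
  expect_equal(ps$gene_id, "g1")
  genes2 <- data.frame(gene_id = "g3", chrom = "chrX", tss = 5000, strand = "+")
  expect_error(extract_promoters(genome, genes2), "unknown chromosome.*g3")
})

test_that("promoter FASTA round-trips sequences exactly", {
  set.seed(21)
  ps <- promoter_set(gene_id = c("a", "b"),
                     seq = c(rnd_seq(2000), rnd_seq(2000)))
  path <- tempfile(fileext = ".fa")
  write_promoters_fasta(ps, path)
  back <- read_promoters_fasta(path)
  expect_equal(back$gene_id, ps$gene_id)
  expect_equal(back$seq, ps$seq)
  expect_equal(back$offset_of_tss, c(1500L, 1500L))
})

test_that("pruning removes duplicates but keeps unrelated random promoters", {
  set.seed(31)
  s <- rnd_seq(2000)
  ps <- promoter_set(c("a", "b"), c(s, s))
  expect_equal(nrow(prune_similar_promoters(ps)), 1L)

  # independent random pairs are far below the 0.6 similarity threshold
  for (i in 1:100) {
    pair <- promoter_set(c("x", "y"), c(rnd_seq(2000), rnd_seq(2000)))
    expect_equal(nrow(prune_similar_promoters(pair)), 2L)
  }

  one <- promoter_set("solo", rnd_seq(2000))
  expect_equal(prune_similar_promoters(one)$gene_id, "solo")

  # sharing most of the sequence trips the threshold
  shared <- substr(s, 1, 1600)
  ps2 <- promoter_set(c("a", "b"),
                      c(paste0(shared, rnd_seq(400)), paste0(rnd_seq(400), shared)))
  expect_equal(nrow(prune_similar_promoters(ps2)), 1L)

  expect_error(prune_similar_promoters(ps, threshold = 1.5), "threshold")
})

test_that("gene sets split 40/20/40 with largest-remainder rounding", {
  pos <- paste0("p", 1:100)
  ctrl <- paste0("c", 1:50)
  sp <- split_gene_sets(pos, ctrl, seed = 7)
  expect_equal(lengths(sp[c("motif_prediction", "feature_computation",
                            "model_construction")]),
               c(motif_prediction = 40L, feature_computation = 20L,
                 model_construction = 40L))
  expect_equal(lengths(sp[c("control_feature", "control_model")]),
               c(control_feature = 25L, control_model = 25L))

  sp55 <- split_gene_sets(paste0("p", 1:55), ctrl, seed = 7)
  expect_equal(lengths(sp55[1:3]),
               c(motif_prediction = 22L, feature_computation = 11L,
                 model_construction = 22L))
})

test_that("splits are deterministic and partition the inputs for any size", {
  pos <- paste0("p", 1:100)
  ctrl <- paste0("c", 1:30)
  expect_identical(split_gene_sets(pos, ctrl, seed = 3),
                   split_gene_sets(pos, ctrl, seed = 3))
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:500, 1)
    m <- sample(0:200, 1)
    p <- paste0("p", seq_len(n))
    c_ <- if (m > 0) paste0("c", seq_len(m)) else character(0)
    sp <- split_gene_sets(p, c_, seed = rep)
    got_pos <- c(sp$motif_prediction, sp$feature_computation,
                 sp$model_construction)
    expect_setequal(got_pos, p)
    expect_equal(length(got_pos), n)  # disjoint + covering
    got_ctrl <- c(sp$control_feature, sp$control_model)
    expect_setequal(got_ctrl, c_)
    expect_equal(length(got_ctrl), m)
  }
})

test_that("overlapping positive/control sets are rejected by name", {
  expect_error(split_gene_sets(paste0("g", 1:10), c("g3", "x"), seed = 1),
               "overlap.*g3")
  expect_error(split_gene_sets(paste0("g", 1:4), "c1", seed = 1),
               "at least 5")
})

test_that("BED gene tables resolve the TSS by strand", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t900\tgPlus\t0\t+",
               "chr1\t2000\t2600\tgMinus\t0\t-"), path)
  gt <- read_gene_table(path)
  expect_equal(gt$tss[gt$gene_id == "gPlus"], 100L)
  expect_equal(gt$tss[gt$gene_id == "gMinus"], 2599L)
  gt2 <- read_gene_table(path, strand_aware_tss = FALSE)
  expect_equal(gt2$tss, c(100L, 2000L))
})
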