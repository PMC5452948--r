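# F-score fitness, chromosome evaluation, GA evolution, cross-validation.

test_that("precision/recall/Fscore follow the degenerate-zero convention", {
  expect_equal(fscore(10, 0, 0), list(precision = 1, recall = 1, fscore = 1))
  f <- fscore(50, 50, 0)
  expect_equal(f$precision, 0.5)
  expect_equal(f$recall, 1)
  expect_equal(f$fscore, 2 / 3)
  expect_equal(fscore(0, 5, 5), list(precision = 0, recall = 0, fscore = 0))
  expect_error(fscore(-1, 0, 0), "nonnegative")
})

ga_fixture <- function() {
  # 6 genes (3 positive, 3 control), 3 features
  X <- rbind(c(1, 0, 1),
             c(1, 1, 0),
             c(0, 0, 1),
             c(0, 1, 0),
             c(0, 0, 1),
             c(0, 0, 0))
  colnames(X) <- c("PRES:A", "PRES:B", "PRES:C")
  make_fm(X, rep(c("positive", "control"), each = 3))
}

test_that("chromosome fitness equals exhaustive confusion counting", {
  fm <- ga_fixture()
  expect_equal(evaluate_chromosome(c(0, 0, 0), fm), 0)
  for (mask_bits in 0:7) {
    mask <- as.integer(intToBits(mask_bits))[1:3]
    pred <- apply(fm$values[, mask == 1, drop = FALSE], 1,
                  function(r) any(r == 1))
    if (sum(mask) == 0) pred <- rep(FALSE, 6)
    tp <- sum(pred[1:3]); fp <- sum(pred[4:6]); fn <- 3 - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    want <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(evaluate_chromosome(mask, fm), want)
  }
})

separable_fm <- function(n = 15, n_noise = 9, seed = 81) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n)
  X <- cbind(signal = y, sapply(seq_len(n_noise),
                                function(i) rbinom(2 * n, 1, 0.3)))
  colnames(X) <- c("PRES:SIG", paste0("PRES:N", seq_len(n_noise)))
  make_fm(X, ifelse(y == 1, "positive", "control"))
}

test_that("the GA finds a perfectly separating feature across seeds", {
  # stop criteria disabled (fscore_stop = 1, separation fraction 1) so the
  # optimiser itself is under test, not the stopping rules
  fm <- separable_fm(n = 25)
  for (s in 1:20) {
    ev <- evolve(fm, ga_config(seed = s, max_iters = 300, fscore_stop = 1,
                               early_stop_pos_fraction = 1))
    expect_gte(ev$best_fitness, 0.95)
    expect_equal(unname(ev$best_mask["PRES:SIG"]), 1)
  }
})

test_that("a one-generation budget returns the best of the initial population", {
  fm <- separable_fm()
  ev <- evolve(fm, ga_config(seed = 4, max_iters = 1, fscore_stop = 1,
                             early_stop_pos_fraction = 1))
  expect_equal(nrow(ev$log), 1L)
  expect_equal(ev$stop_reason, "max_iterations")
})

test_that("evolution is deterministic given the seed", {
  fm <- separable_fm()
  e1 <- evolve(fm, ga_config(seed = 9, max_iters = 30, fscore_stop = 1))
  e2 <- evolve(fm, ga_config(seed = 9, max_iters = 30, fscore_stop = 1))
  expect_identical(e1$log, e2$log)
  expect_identical(e1$best_mask, e2$best_mask)
  e3 <- evolve(fm, ga_config(seed = 10, max_iters = 30, fscore_stop = 1,
                             selection = "roulette"))
  expect_true(is.finite(e3$best_fitness))
})

test_that("the elitist best-ever fitness never decreases across generations", {
  fm <- separable_fm(n = 12, n_noise = 12, seed = 82)
  ev <- evolve(fm, ga_config(seed = 2, max_iters = 40, fscore_stop = 1))
  expect_true(all(diff(ev$log$best) >= 0))
})

test_that("the Fscore stop triggers as soon as a good solution appears", {
  fm <- separable_fm()
  ev <- evolve(fm, ga_config(seed = 1, max_iters = 500, fscore_stop = 0.8))
  expect_equal(ev$stop_reason, "fscore_threshold")
  expect_gte(ev$best_fitness, 0.8)
})

test_that("adding positive-exclusive features never hurts the fitness", {
  # features present only in positives: switching more of them on is
  # monotone non-decreasing in TP with FP fixed at 0
  X <- cbind(f1 = c(1, 0, 0, 0, 0, 0, 0, 0),
             f2 = c(0, 1, 0, 0, 0, 0, 0, 0),
             f3 = c(0, 0, 1, 1, 0, 0, 0, 0))
  colnames(X) <- paste0("PRES:", c("A", "B", "C"))
  fm <- make_fm(X, rep(c("positive", "control"), each = 4))
  fits <- vapply(list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
                 evaluate_chromosome, numeric(1), fm = fm)
  expect_true(all(diff(fits) >= 0))
})

test_that("cross-validation reports fold scores, consensus and weights", {
  fm <- separable_fm(n = 25, n_noise = 6, seed = 83)
  cv <- cross_validate(fm, ga_config(seed = 11, max_iters = 50,
                                     fscore_stop = 1), k = 5)
  expect_length(cv$fold_fscores, 5L)
  expect_equal(cv$overall_fscore, mean(cv$fold_fscores))
  expect_gte(cv$overall_fscore, 0.8)
  # the perfect separator is in every fold-best mask, hence in consensus
  expect_true("PRES:SIG" %in% cv$consensus_features)
  # the consensus rule: >= 4 of 5 fold-best masks, no exceptions
  appearances <- colSums(cv$masks)
  expect_setequal(cv$consensus_features, names(appearances)[appearances >= 4])
  expect_equal(names(cv$weights), cv$consensus_features)
  expect_error(cross_validate(make_fm(matrix(1, 4, 1),
                                      rep(c("positive", "control"), 2)),
                              ga_config(), k = 5),
               "at least k")
})

test_that("label shuffling drops the Fscore to the any-feature null level", {
  fm <- separable_fm(n = 25, n_noise = 6, seed = 84)
  cv <- cross_validate(fm, ga_config(seed = 12, max_iters = 50,
                                     fscore_stop = 1), k = 5)
  mask <- as.integer(fm$features$desc %in% cv$consensus_features)
  pred <- rowSums(fm$values[, mask == 1, drop = FALSE]) > 0
  q <- mean(pred)
  set.seed(85)
  null_f <- replicate(50, {
    y <- sample(fm$labels == "positive")
    tp <- sum(pred & y)
    f <- fscore(tp, sum(pred) - tp, sum(y) - tp)
    f$fscore
  })
  # expected null F for prediction rate q on a balanced cohort:
  # precision -> 0.5, recall -> q, F -> 2*0.5*q/(0.5+q)
  expected <- 2 * 0.5 * q / (0.5 + q)
  expect_lt(mean(null_f), cv$overall_fscore)
  expect_equal(mean(null_f), expected, tolerance = 0.15)
})
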