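# Genetic-algorithm selection of informative feature subsets.
#
# Each individual carries a binary chromosome over the candidate features; a
# promoter is predicted positive when it contains at least one selected
# feature, and fitness is the F-score of the resulting confusion counts on
# the training rows. The population size equals the number of training
# promoters. Evolution uses uniform crossover, per-bit mutation, tournament
# (k = 2) or roulette selection, and elitism; it terminates at the iteration
# cap, when a solution reaches the F-score threshold, or when the
# score-separation criterion is met (more than half of the positive regions
# score above the 0.9 quantile of the control scores under the
# Kullback-Leibler weighted score).

#' Precision, recall and F-score from confusion counts
#'
#' Degenerate denominators yield 0 by convention.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return List with `precision`, `recall`, `fscore`.
#' @export
fscore <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop_param("counts must be nonnegative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, fscore = f)
}

#' Genetic-algorithm settings
#'
#' Defaults follow the reference workflow: mutation probability 0.05,
#' uniform crossover, at most 10,000 generations, stop at F-score >= 0.8 or
#' when >50% of positives outscore 90% of controls.
#'
#' @param mutation_prob Per-bit mutation probability.
#' @param max_iters Generation cap.
#' @param fscore_stop Stop once the best fitness reaches this value.
#' @param early_stop_pos_fraction,early_stop_neg_quantile Parameters of the
#'   score-separation stop.
#' @param seed Integer seed (all GA randomness is derived from it).
#' @param selection `"tournament_k2"` or `"roulette"`.
#' @param elitism Number of best-ever individuals copied into each
#'   generation (>= 1 so the best solution is never lost).
#' @param init_prob Per-bit probability of 1 in the initial population;
#'   sparse masks (default 0.1) match the small informative sets the method
#'   is after.
#' @return A `ga_config` list.
#' @export
ga_config <- function(mutation_prob = 0.05, max_iters = 10000L,
                      fscore_stop = 0.8, early_stop_pos_fraction = 0.5,
                      early_stop_neg_quantile = 0.9, seed = 1L,
                      selection = c("tournament_k2", "roulette"),
                      elitism = 1L, init_prob = 0.1) {
  stopifnot(mutation_prob >= 0, mutation_prob <= 1,
            fscore_stop >= 0, fscore_stop <= 1,
            early_stop_pos_fraction >= 0, early_stop_pos_fraction <= 1,
            early_stop_neg_quantile >= 0, early_stop_neg_quantile <= 1,
            init_prob >= 0, init_prob <= 1, max_iters >= 1)
  structure(list(mutation_prob = mutation_prob,
                 max_iters = as.integer(max_iters),
                 fscore_stop = fscore_stop,
                 early_stop_pos_fraction = early_stop_pos_fraction,
                 early_stop_neg_quantile = early_stop_neg_quantile,
                 seed = seed, selection = match.arg(selection),
                 elitism = as.integer(elitism), init_prob = init_prob),
            class = "ga_config")
}

# Confusion counts of the any-selected-feature rule for one mask.
confusion_for_mask <- function(mask, X, ypos) {
  pred <- if (any(mask > 0)) {
    rowSums(X[, mask > 0, drop = FALSE]) > 0
  } else {
    rep(FALSE, nrow(X))
  }
  c(tp = sum(pred & ypos), fp = sum(pred & !ypos),
    fn = sum(!pred & ypos), tn = sum(!pred & !ypos))
}

#' Fitness of one chromosome
#'
#' A region is predicted positive when it contains at least one selected
#' feature; fitness is the F-score of the resulting confusion counts.
#'
#' @param mask 0/1 (or logical) vector over the candidate features.
#' @param fm Training [build_feature_matrix()] (or a plain 0/1 matrix with
#'   `labels` supplied).
#' @param labels Optional factor when `fm` is a plain matrix.
#' @return Fitness in \[0, 1\].
#' @export
evaluate_chromosome <- function(mask, fm, labels = NULL) {
  if (inherits(fm, "feature_matrix")) {
    X <- fm$values
    labels <- fm$labels
  } else {
    X <- fm
  }
  cf <- confusion_for_mask(as.integer(mask), X, labels == "positive")
  unname(fscore(cf[["tp"]], cf[["fp"]], cf[["fn"]])$fscore)
}

# Vectorised fitness for a population matrix M (F x P).
fitness_of_population <- function(M, X, ypos) {
  predcount <- X %*% M
  pred <- predcount > 0
  tp <- as.numeric(crossprod(ypos, pred))
  fp <- colSums(pred) - tp
  fn <- sum(ypos) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
}

#' Evolve a feature-subset population
#'
#' @param fm Training [build_feature_matrix()].
#' @param config A [ga_config()].
#' @param weights Optional named weight vector (Kullback-Leibler weights of
#'   the candidate features, typically computed on the feature-computation
#'   matrix) enabling the score-separation stop; when `NULL` the criterion
#'   is evaluated with weights computed from the training matrix itself.
#' @return List with `best_mask` (named 0/1 vector), `best_fitness`,
#'   `stop_reason` (`"fscore_threshold"`, `"score_separation"` or
#'   `"max_iterations"`), and `log` (per-generation best/mean fitness).
#' @export
evolve <- function(fm, config = ga_config(), weights = NULL) {
  X <- fm$values
  ypos <- as.integer(fm$labels == "positive")
  nf <- ncol(X)
  if (nf == 0L) stop_param("no candidate features to optimise")
  if (sum(ypos) == 0L || sum(ypos) == length(ypos)) {
    stop_param("training matrix must contain both classes")
  }
  if (is.null(weights)) {
    weights <- compute_weights(fm)
  } else {
    weights <- weights[fm$features$desc]
    weights[is.na(weights)] <- 0
  }
  counts <- fm$counts
  pop <- nrow(X)

  with_seed(config$seed, {
    M <- matrix(as.integer(stats::runif(nf * pop) < config$init_prob),
                nrow = nf, ncol = pop)
    best_mask <- NULL
    best_fit <- -Inf
    log_best <- numeric(0)
    log_mean <- numeric(0)
    stop_reason <- "max_iterations"
    for (gen in seq_len(config$max_iters)) {
      fit <- fitness_of_population(M, X, ypos)
      # best-ever update; ties resolved toward fewer selected features
      gi <- which.max(fit)
      nbits <- colSums(M)
      cand <- which(fit >= fit[gi] - 1e-12)
      gi <- cand[which.min(nbits[cand])]
      if (fit[gi] > best_fit + 1e-12 ||
          (fit[gi] > best_fit - 1e-12 && !is.null(best_mask) &&
           nbits[gi] < sum(best_mask))) {
        best_fit <- fit[gi]
        best_mask <- M[, gi]
      }
      log_best[gen] <- best_fit
      log_mean[gen] <- mean(fit)
      if (best_fit >= config$fscore_stop) {
        stop_reason <- "fscore_threshold"
        break
      }
      if (score_separation_met(best_mask, counts, weights, ypos, config)) {
        stop_reason <- "score_separation"
        break
      }
      if (gen == config$max_iters) break
      M <- next_generation(M, fit, best_mask, config)
    }
    names(best_mask) <- colnames(X)
    list(best_mask = best_mask, best_fitness = best_fit,
         stop_reason = stop_reason,
         log = data.frame(generation = seq_along(log_best),
                          best = log_best, mean = log_mean))
  })
}

score_separation_met <- function(mask, counts, weights, ypos, config) {
  on <- mask > 0
  if (!any(on)) return(FALSE)
  s <- as.numeric(counts[, on, drop = FALSE] %*% weights[on])
  neg <- s[ypos == 0L]
  if (length(neg) == 0L) return(FALSE)
  cut <- stats::quantile(neg, config$early_stop_neg_quantile, names = FALSE)
  mean(s[ypos == 1L] > cut) > config$early_stop_pos_fraction
}

next_generation <- function(M, fit, best_mask, config) {
  nf <- nrow(M)
  pop <- ncol(M)
  if (config$selection == "tournament_k2") {
    pick <- function() {
      i <- sample.int(pop, pop, replace = TRUE)
      j <- sample.int(pop, pop, replace = TRUE)
      ifelse(fit[i] >= fit[j], i, j)
    }
    pa <- pick()
    pb <- pick()
  } else {
    pr <- fit + 1e-9
    pa <- sample.int(pop, pop, replace = TRUE, prob = pr)
    pb <- sample.int(pop, pop, replace = TRUE, prob = pr)
  }
  U <- matrix(stats::runif(nf * pop) < 0.5, nrow = nf)
  child <- M[, pa, drop = FALSE] * U + M[, pb, drop = FALSE] * (1 - U)
  mut <- matrix(stats::runif(nf * pop) < config$mutation_prob, nrow = nf)
  child <- (child + mut) %% 2
  if (config$elitism > 0L && !is.null(best_mask)) {
    for (e in seq_len(min(config$elitism, pop))) child[, e] <- best_mask
  }
  child
}

#' Fivefold cross-validated model construction
#'
#' Positive and control rows are split into `k` stratified folds (seeded);
#' per fold the GA is trained on the other `k - 1` folds and its best
#' chromosome is evaluated on the held-out fold. The overall F-score is the
#' mean of the fold-test F-scores, and the consensus feature set contains
#' the features present in at least `consensus_min` of the fold-best masks.
#'
#' @param fm Full [build_feature_matrix()] over model-construction and
#'   control promoters.
#' @param config A [ga_config()]; fold seeds are derived from `config$seed`.
#' @param k Number of folds (default 5).
#' @param weight_matrix Optional feature matrix (feature-computation +
#'   control) from which feature weights are computed for the
#'   score-separation stop and for the final model; defaults to `fm`.
#' @param consensus_min Minimum number of fold-best masks a feature must
#'   appear in (default `k - 1`, i.e. >= 4 of 5).
#' @return Object of class `model_result`: per-fold results (best mask,
#'   test confusion, test F-score, stop reason), `overall_fscore`,
#'   `consensus_features`, `weights` (for consensus features), `masks`.
#' @export
cross_validate <- function(fm, config = ga_config(), k = 5L,
                           weight_matrix = NULL, consensus_min = k - 1L) {
  ypos <- fm$labels == "positive"
  if (sum(ypos) < k || sum(!ypos) < k) {
    stop_param("each class needs at least k = %d members", k)
  }
  wm <- weight_matrix %||% fm
  cand_weights <- compute_weights(wm, fm$features$desc)

  folds <- with_seed(config$seed, {
    f <- integer(length(ypos))
    f[ypos] <- sample(rep_len(seq_len(k), sum(ypos)))
    f[!ypos] <- sample(rep_len(seq_len(k), sum(!ypos)))
    f
  })

  fold_res <- vector("list", k)
  masks <- matrix(0L, nrow = k, ncol = ncol(fm$values),
                  dimnames = list(NULL, colnames(fm$values)))
  test_f <- numeric(k)
  for (i in seq_len(k)) {
    train <- fm_rows(fm, folds != i)
    test <- fm_rows(fm, folds == i)
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    ev <- evolve(train, cfg_i, weights = cand_weights)
    cf <- confusion_for_mask(ev$best_mask, test$values,
                             test$labels == "positive")
    test_f[i] <- fscore(cf[["tp"]], cf[["fp"]], cf[["fn"]])$fscore
    masks[i, ] <- ev$best_mask
    fold_res[[i]] <- list(best_mask = ev$best_mask,
                          train_fitness = ev$best_fitness,
                          stop_reason = ev$stop_reason,
                          test_fscore = test_f[i], confusion = cf)
  }
  consensus <- colnames(masks)[colSums(masks) >= consensus_min]
  w <- compute_weights(wm, consensus)
  structure(list(folds = fold_res, overall_fscore = mean(test_f),
                 fold_fscores = test_f,
                 consensus_features = consensus, weights = w,
                 masks = masks, consensus_min = as.integer(consensus_min),
                 k = as.integer(k), config = config),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("model_result: %d-fold CV, overall Fscore %.3f (folds: %s)\n",
              x$k, x$overall_fscore,
              paste(sprintf("%.3f", x$fold_fscores), collapse = ", ")))
  cat(sprintf("  consensus (>= %d of %d folds): %d features\n",
              x$consensus_min, x$k, length(x$consensus_features)))
  invisible(x)
}

#' Convert a cross-validation result into a scoring model
#'
#' @param result A [cross_validate()] result.
#' @param motifs Motif names (stored in the model file).
#' @param config The [feature_config()] used to build the matrices.
#' @return A [promoter_model()] over the consensus features.
#' @export
as_promoter_model <- function(result, motifs = character(0),
                              config = feature_config()) {
  promoter_model(features = result$consensus_features,
                 weights = result$weights,
                 motifs = motifs, config = config,
                 cv = list(overall_fscore = result$overall_fscore,
                           fold_fscores = result$fold_fscores,
                           k = result$k,
                           stop_reasons = vapply(result$folds, `[[`,
                                                 character(1), "stop_reason")))
}
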