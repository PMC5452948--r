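# One-command orchestration of the full workflow: cohort -> gene-set split
# -> motif deduplication -> ORI overrepresentation selection -> occurrence
# scanning -> feature matrix -> correlation filter -> GA + cross-validation
# -> model JSON -> genome ranking -> enrichment report. Every stage is also
# callable on its own through the exported module functions; the pipeline
# only wires them together and records a manifest.

#' Default pipeline configuration
#'
#' All method defaults are configuration, never hard-coded downstream:
#' 100-bp windows, scanner threshold 0.8, motif-comparison p <= 0.001,
#' ORI p < 0.01 at 10,000 permutations, filter delta 0, GA mutation 0.05 /
#' cap 10,000 / F-score stop 0.8, fivefold CV with >= 4-of-5 consensus,
#' top-100 retrieval. The synthetic input block reproduces the default
#' study conditions of [example_cohort()] plus an independent validation
#' universe (150 expressed + 350 background promoters).
#'
#' @param seed Master seed; every stage seed is derived from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    input = list(
      mode = "synthetic",
      synthetic = list(n_pos = 200L, n_ctrl = 200L, sharpness = 1,
                       background_gc = 0.42,
                       n_val_expressed = 150L, n_val_background = 350L,
                       n_background_regions = 100L),
      files = list(promoters = NULL, pwms = NULL, positives = NULL,
                   controls = NULL, background = NULL, expressed = NULL)
    ),
    prune = list(enabled = TRUE, threshold = 0.6, k = 12L),
    split = list(fractions = c(0.4, 0.2, 0.4)),
    scan = list(threshold_fraction = 0.8),
    # dedup 'auto': run on file-supplied motif collections (merged de novo +
    # database matrices can be redundant), skip for synthetic motif sets,
    # which are distinct by construction.
    dedup = list(enabled = "auto", p_threshold = 0.001, n_null = 1000L),
    ori = list(n_perm = 10000L, p_threshold = 0.01),
    features = list(window = 100L, upstream = 1500L, downstream = 500L),
    filter = list(delta = 0),
    ga = list(mutation_prob = 0.05, max_iters = 10000L, fscore_stop = 0.8,
              selection = "tournament_k2", elitism = 1L, init_prob = 0.1),
    cv = list(k = 5L, consensus_min = 4L),
    validation = list(n_top = 100L, n_perm = 10000L)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_pipeline_config(seed = user$seed %||% 1L), user)
}

pipeline_error <- function(stage, msg) {
  stop(structure(class = c("pipeline_error", "error", "condition"),
                 list(message = sprintf("[stage %s] %s", stage, msg),
                      call = NULL, stage = stage)))
}

random_sequences <- function(n, len, gc, prefix) {
  bgp <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(.BASES, len, replace = TRUE, prob = bgp), collapse = "")
  }, character(1))
  promoter_set(gene_id = sprintf("%s_%04d", prefix, seq_len(n)), seq = seqs)
}

#' Run the whole promoter-architecture workflow
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param out_dir Directory for artifacts (`model.json`, `scores.tsv`,
#'   `enrichment.json`, `manifest.json`); created if missing.
#' @param verbose Print stage progress.
#' @return Object of class `pipeline_result`: the manifest plus in-memory
#'   `model`, `cv`, `ranked`, `enrichment`, `significance`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("promoarch_run_"),
                         verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  stages <- list()
  timed <- function(name, code) {
    s <- Sys.time()
    res <- force(code)
    stages[[name]] <<- list(seconds = as.numeric(difftime(Sys.time(), s,
                                                          units = "secs")))
    say("stage %-16s done (%.1fs)", name, stages[[name]]$seconds)
    res
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  fcfg <- feature_config(window = config$features$window,
                         upstream = config$features$upstream,
                         downstream = config$features$downstream)

  ## ---- inputs -----------------------------------------------------------
  inp <- timed("input", {
    if (identical(config$input$mode, "synthetic")) {
      sy <- config$input$synthetic
      ec <- example_cohort(seed = seed, n_pos = sy$n_pos, n_ctrl = sy$n_ctrl,
                           sharpness = sy$sharpness)
      cohort <- generate_cohort(ec$spec, ec$pwms)
      vspec <- architecture_spec(ec$spec$planted,
                                 n_pos = sy$n_val_expressed,
                                 n_ctrl = sy$n_val_background,
                                 background_gc = sy$background_gc,
                                 seed = seed + 1000L, id_prefix = "val_",
                                 config = fcfg)
      val <- generate_cohort(vspec, ec$pwms)
      bg <- with_seed(seed + 2000L, {
        random_sequences(sy$n_background_regions,
                         fcfg$upstream + fcfg$downstream,
                         sy$background_gc, "bg")
      })
      list(promoters = rbind(cohort$positives, cohort$controls),
           positives = cohort$positives$gene_id,
           controls = cohort$controls$gene_id,
           pwms = ec$pwms, background = bg,
           val_universe = rbind(val$positives, val$controls),
           expressed = val$positives$gene_id,
           truth = cohort$truth)
    } else {
      fl <- config$input$files
      need <- c("promoters", "pwms", "positives", "controls", "background",
                "expressed")
      miss <- need[vapply(need, function(n) is.null(fl[[n]]), logical(1))]
      if (length(miss) > 0L) {
        pipeline_error("input", paste("missing input file(s):",
                                      paste(miss, collapse = ", ")))
      }
      promoters <- read_promoters_fasta(fl$promoters)
      list(promoters = promoters,
           positives = read_gene_list(fl$positives),
           controls = read_gene_list(fl$controls),
           pwms = read_jaspar(fl$pwms),
           background = read_promoters_fasta(fl$background),
           val_universe = promoters,
           expressed = read_gene_list(fl$expressed),
           truth = NULL)
    }
  })
  proms <- inp$promoters
  class(proms) <- c("promoter_set", "data.frame")

  ## ---- prune + split ----------------------------------------------------
  if (isTRUE(config$prune$enabled)) {
    proms_pos <- proms[proms$gene_id %in% inp$positives, , drop = FALSE]
    class(proms_pos) <- c("promoter_set", "data.frame")
    kept <- timed("prune", prune_similar_promoters(
      proms_pos, threshold = config$prune$threshold, k = config$prune$k))
    inp$positives <- intersect(inp$positives, kept$gene_id)
  }
  split <- timed("split", split_gene_sets(inp$positives, inp$controls,
                                          seed = seed,
                                          fractions = config$split$fractions))

  ## ---- motif dedup + ORI selection --------------------------------------
  dedup_on <- config$dedup$enabled
  if (identical(dedup_on, "auto")) {
    dedup_on <- !identical(config$input$mode, "synthetic")
  }
  pwms <- if (isTRUE(dedup_on)) {
    timed("dedup", deduplicate_motifs(
      inp$pwms, p_threshold = config$dedup$p_threshold,
      n_null = config$dedup$n_null, seed = seed + 1L))
  } else {
    inp$pwms
  }
  universe_all <- rbind(proms, inp$val_universe)
  class(universe_all) <- c("promoter_set", "data.frame")
  if (anyDuplicated(universe_all$gene_id)) {
    pipeline_error("input", "duplicate gene ids across promoter universes")
  }
  ori <- timed("ori", lapply(seq_along(pwms), function(i) {
    ori_permutation_test(pwms[[i]], split$motif_prediction, universe_all,
                         inp$background, n_perm = config$ori$n_perm,
                         seed = seed + 10L + i,
                         threshold_fraction = config$scan$threshold_fraction)
  }))
  sel <- vapply(ori, function(o) o$pvalue < config$ori$p_threshold, logical(1))
  pwms_sel <- pwms[sel]
  if (length(pwms_sel) == 0L) {
    pipeline_error("ori", "no overrepresented motifs at the configured threshold")
  }

  ## ---- occurrences + matrices -------------------------------------------
  occ <- timed("scan", scan_promoters(
    pwms_sel, universe_all,
    threshold_fraction = config$scan$threshold_fraction))
  motif_names <- vapply(pwms_sel, `[[`, character(1), "name")
  cand <- enumerate_candidate_features(motif_names, fcfg)
  fm_fc <- timed("feature_matrix", build_feature_matrix(
    cand, occ, split$feature_computation, split$control_feature, fcfg))
  kept_feats <- timed("filter", correlation_filter(fm_fc,
                                                   delta = config$filter$delta))
  if (nrow(kept_feats) == 0L) {
    pipeline_error("filter", "correlation filter removed every feature")
  }
  fm_fc_kept <- fm_cols(fm_fc, kept_feats$desc)
  fm_mc <- timed("mc_matrix", build_feature_matrix(
    kept_feats$desc, occ, split$model_construction, split$control_model, fcfg))

  ## ---- GA + cross-validation --------------------------------------------
  gacfg <- ga_config(mutation_prob = config$ga$mutation_prob,
                     max_iters = config$ga$max_iters,
                     fscore_stop = config$ga$fscore_stop,
                     seed = seed + 100L,
                     selection = config$ga$selection,
                     elitism = config$ga$elitism,
                     init_prob = config$ga$init_prob)
  cv <- timed("ga_cv", cross_validate(fm_mc, gacfg, k = config$cv$k,
                                      weight_matrix = fm_fc_kept,
                                      consensus_min = config$cv$consensus_min))
  model <- as_promoter_model(cv, motifs = motif_names, config = fcfg)
  degenerate <- length(model$features) == 0L
  if (degenerate) {
    warning("empty consensus feature set: the model is degenerate (all scores 0)")
  }

  ## ---- validation --------------------------------------------------------
  training <- c(split$motif_prediction, split$feature_computation,
                split$model_construction, split$control_feature,
                split$control_model)
  ranked <- timed("rank", rank_genome(
    model, occ, inp$val_universe$gene_id, exclude = training,
    n_top = config$validation$n_top, config = fcfg))
  enr <- enrichment_report(ranked, inp$expressed)
  signif <- timed("significance", fscore_permutation_pvalue(
    fm_mc, model$features, n_perm = config$validation$n_perm,
    seed = seed + 200L))

  ## ---- artifacts + manifest ---------------------------------------------
  paths <- list(model = file.path(out_dir, "model.json"),
                scores = file.path(out_dir, "scores.tsv"),
                enrichment = file.path(out_dir, "enrichment.json"),
                manifest = file.path(out_dir, "manifest.json"))
  write_model(model, paths$model)
  utils::write.table(ranked, paths$scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(n_top = enr$n_top, count = enr$count,
                            expressed_fraction = enr$expressed_fraction,
                            pvalue = enr$pvalue,
                            fscore = cv$overall_fscore,
                            fscore_shuffle_pvalue = signif$pvalue),
                       paths$enrichment, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("promoarch")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    n_motifs_input = length(inp$pwms),
    n_motifs_nonredundant = length(pwms),
    n_motifs_overrepresented = length(pwms_sel),
    ori_pvalues = stats::setNames(vapply(ori, `[[`, numeric(1), "pvalue"),
                                  vapply(pwms, `[[`, character(1), "name")),
    n_candidate_features = nrow(cand),
    n_filtered_features = nrow(kept_feats),
    n_consensus_features = length(model$features),
    degenerate = degenerate,
    stop_reasons = vapply(cv$folds, `[[`, character(1), "stop_reason"),
    overall_fscore = cv$overall_fscore,
    files = lapply(paths[c("model", "scores", "enrichment")], function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    stages = stages,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  structure(list(manifest = manifest, model = model, cv = cv,
                 ranked = ranked, enrichment = enr, significance = signif,
                 split = split, truth = inp$truth, out_dir = out_dir,
                 paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("pipeline_result (seed %d): %d/%d motifs overrepresented, %d -> %d features, Fscore %.3f\n",
              m$seed, m$n_motifs_overrepresented, m$n_motifs_input,
              m$n_candidate_features, m$n_filtered_features,
              m$overall_fscore))
  cat(sprintf("  consensus: %d features; enrichment %d/%d expressed (p = %.3g); shuffle p = %.3g\n",
              m$n_consensus_features, x$enrichment$count, x$enrichment$n_top,
              x$enrichment$pvalue, x$significance$pvalue))
  cat(sprintf("  artifacts in %s\n", x$out_dir))
  invisible(x)
}
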