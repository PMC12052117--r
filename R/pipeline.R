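#' Pipeline configuration
#'
#' Bundles every stage's configuration so a full run is reproducible from
#' the config and the global seed alone. Each stage derives its own seed
#' from the global seed and the stage name, so stages are independently
#' reproducible.
#'
#' @param cohort A [cohort_spec()] (synthetic run) or a path to a cohort
#'   `manifest.csv` (see [read_cohort()]).
#' @param texture A [texture_config()].
#' @param alpha_ttest Significance level of the t-test screen.
#' @param n_bins Quantile bins of the rough-set discretization.
#' @param vote_policy Pseudo-label vote policy (see
#'   [assign_pseudo_labels()]).
#' @param scso_agents,scso_iter SCSO population size and iterations for the
#'   pseudo-weight search.
#' @param ucnet A [ucnet_config()].
#' @param val_fraction Fraction of labeled patients held out (patient-level,
#'   never slice-level) for validation.
#' @param out_dir Output directory for artifacts.
#' @param seed Global seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            texture = texture_config(),
                            alpha_ttest = 0.05, n_bins = 4,
                            vote_policy = "majority",
                            scso_agents = 5, scso_iter = 6,
                            ucnet = ucnet_config(),
                            val_fraction = 0.25,
                            out_dir = tempfile("gliosemi_run_"),
                            seed = 1L) {
  structure(
    list(cohort = cohort, texture = texture, alpha_ttest = alpha_ttest,
         n_bins = n_bins, vote_policy = vote_policy,
         scso_agents = as.integer(scso_agents),
         scso_iter = as.integer(scso_iter), ucnet = ucnet,
         val_fraction = val_fraction, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(global, stage) {
  as.integer((sum(utf8ToInt(stage)) * 1009L + global * 31L) %% 2147483647L)
}

log_line <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full semi-supervised pipeline
#'
#' Executes the complete flow: synthetic cohort generation (or manifest
#' loading), radiomics feature extraction on the labeled subset, t-test
#' screening, rough-set positive-region attribute reduction, Youden-rule
#' construction and pseudo-labeling of the unlabeled subset, autoencoder
#' training, SCSO tuning of the pseudo-label weight on the validation loss,
#' and final weighted CRNN training. Every intermediate artifact is written
#' to `cfg$out_dir`; if a stage fails, the error names the stage and all
#' prior artifacts are preserved. With no unlabeled patients the
#' pseudo-labeling and weight-tuning stages are skipped and the classifier
#' trains on the labeled data alone.
#'
#' @param cfg A [pipeline_config()].
#' @return A run report (list): reduct, rules, pseudo-labels, tuned alpha,
#'   validation metrics, artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  cat("", file = log_path)
  art <- function(name) file.path(cfg$out_dir, name)
  report <- list(artifacts = character(0), config = cfg)
  stage <- function(name, expr) {
    log_line(log_path, "stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (inherits(cfg$cohort, "cohort_spec")) generate_cohort(cfg$cohort)
    else read_cohort(cfg$cohort)
  })
  labeled <- Filter(function(v) !is.na(v$label), cohort)
  unlabeled <- Filter(function(v) is.na(v$label), cohort)
  log_line(log_path, sprintf("%d labeled / %d unlabeled patients",
                             length(labeled), length(unlabeled)))

  ft <- stage("extract_features", {
    tab <- extract_feature_table(labeled, cfg$texture)
    utils::write.csv(tab, art("features_labeled.csv"), row.names = FALSE)
    report$artifacts <- c(report$artifacts, art("features_labeled.csv"))
    tab
  })

  tt <- stage("ttest_filter", {
    res <- ttest_filter(ft, alpha = cfg$alpha_ttest)
    utils::write.csv(res$stats, art("ttest_stats.csv"), row.names = FALSE)
    report$artifacts <- c(report$artifacts, art("ttest_stats.csv"))
    log_line(log_path, sprintf("t-test retained %d / %d features (P < %g)",
                               length(res$kept), nrow(res$stats), cfg$alpha_ttest))
    res
  })
  if (length(tt$kept) == 0) stop("pipeline stage 'ttest_filter' failed: no significant features")

  red <- stage("reduce_attributes", {
    dt <- discretize(tt$table, n_bins = cfg$n_bins)
    r <- reduce_attributes(dt, order_policy = "weakest_first", t_stats = tt$stats,
                           seed = stage_seed(cfg$seed, "reduce"))
    write_reduct(r, art("reduct.json"))
    report$artifacts <- c(report$artifacts, art("reduct.json"))
    log_line(log_path, sprintf("reduct: %d attributes, |POS| = %d",
                               length(r$attributes), r$pos_size))
    r
  })

  rules <- stage("youden_rules", {
    rl <- build_rules(ft, features = red$attributes)
    write_rules(rl, art("rules.csv"))
    report$artifacts <- c(report$artifacts, art("rules.csv"))
    rl
  })

  pseudo <- NULL
  if (length(unlabeled) > 0) {
    pseudo <- stage("pseudo_label", {
      fu <- extract_feature_table(unlabeled, cfg$texture)
      pl <- assign_pseudo_labels(fu, rules, policy = cfg$vote_policy)
      utils::write.csv(pl, art("pseudo_labels.csv"), row.names = FALSE)
      report$artifacts <- c(report$artifacts, art("pseudo_labels.csv"))
      log_line(log_path, sprintf("pseudo-labeled %d patients (%d mutant / %d wild)",
                                 nrow(pl), sum(pl$pseudo_label == "mutant"),
                                 sum(pl$pseudo_label == "wild")))
      pl
    })
  } else {
    log_line(log_path, "no unlabeled patients: supervised-only path")
  }

  # patient-level labeled train/validation split
  split <- stage("split", {
    with_seed(stage_seed(cfg$seed, "split"), {
      lab <- vapply(labeled, function(v) v$label, "")
      val_idx <- unlist(lapply(c("mutant", "wild"), function(cl) {
        ids <- which(lab == cl)
        sample(ids, max(1L, round(cfg$val_fraction * length(ids))))
      }))
      list(train = setdiff(seq_along(labeled), val_idx), val = val_idx)
    })
  })

  ae <- stage("train_autoencoder", {
    ucfg <- cfg$ucnet
    ucfg$seed <- stage_seed(cfg$seed, "autoencoder")
    model <- build_feature_extractor(ucfg)
    vols <- c(labeled[split$train], unlabeled)
    model <- train_autoencoder(model, vols)
    utils::write.csv(
      data.frame(epoch = seq_along(model$history), loss = model$history),
      art("autoencoder_history.csv"), row.names = FALSE)
    report$artifacts <- c(report$artifacts, art("autoencoder_history.csv"))
    model
  })

  feats <- stage("feature_sequences", {
    list(
      train = lapply(labeled[split$train], extract_feature_sequence, model = ae),
      val = lapply(labeled[split$val], extract_feature_sequence, model = ae),
      unlabeled = lapply(unlabeled, extract_feature_sequence, model = ae)
    )
  })
  y_train <- vapply(labeled[split$train], function(v) v$label, "")
  y_val <- vapply(labeled[split$val], function(v) v$label, "")

  alpha <- 1
  if (length(unlabeled) > 0) {
    alpha <- stage("tune_pseudo_weight", {
      seqs <- c(feats$train, feats$unlabeled)
      labs <- c(y_train, pseudo$pseudo_label)
      scfg <- scso_config(n_agents = cfg$scso_agents, max_iter = cfg$scso_iter,
                          bounds = c(0, 1),
                          seed = stage_seed(cfg$seed, "scso"))
      fit_fn <- function(a) {
        ucfg <- cfg$ucnet
        ucfg$seed <- stage_seed(cfg$seed, "crnn_inner")
        m <- build_crnn(ucfg)
        w <- c(rep(1, length(feats$train)), rep(a, length(feats$unlabeled)))
        m <- train_classifier(m, seqs, labs, weights = w)
        classifier_metrics(m, feats$val, y_val)$loss
      }
      res <- optimize_pseudo_weight(fit_fn, cfg = scfg)
      write_scso_trace(res$trace, art("scso_trace.csv"))
      report$artifacts <- c(report$artifacts, art("scso_trace.csv"))
      log_line(log_path, sprintf("SCSO tuned pseudo-label weight alpha = %.3f", res$alpha))
      res$alpha
    })
  }

  final <- stage("train_classifier", {
    ucfg <- cfg$ucnet
    ucfg$seed <- stage_seed(cfg$seed, "crnn_final")
    m <- build_crnn(ucfg)
    if (length(unlabeled) > 0) {
      seqs <- c(feats$train, feats$unlabeled)
      labs <- c(y_train, pseudo$pseudo_label)
      w <- c(rep(1, length(feats$train)), rep(alpha, length(feats$unlabeled)))
    } else {
      seqs <- feats$train; labs <- y_train; w <- rep(1, length(feats$train))
    }
    m <- train_classifier(m, seqs, labs, weights = w,
                          validation = list(sequences = feats$val, labels = y_val))
    utils::write.csv(m$history, art("classifier_history.csv"), row.names = FALSE)
    report$artifacts <- c(report$artifacts, art("classifier_history.csv"))
    m
  })

  metrics <- stage("metrics", {
    vm <- classifier_metrics(final, feats$val, y_val)
    rule_metrics <- evaluate_rules(ft[split$val, , drop = FALSE],
                                   labels = y_val, rules = rules)
    out <- list(
      alpha = alpha,
      val_loss = vm$loss, val_accuracy = vm$accuracy,
      rule_holdout_accuracy = rule_metrics$accuracy,
      n_labeled = length(labeled), n_unlabeled = length(unlabeled),
      n_val = length(split$val),
      reduct_size = length(red$attributes),
      n_significant = length(tt$kept)
    )
    jsonlite::write_json(out, art("metrics.json"), auto_unbox = TRUE, digits = NA)
    report$artifacts <- c(report$artifacts, art("metrics.json"))
    out
  })

  saveRDS(list(extractor = ae[c("params", "cfg")],
               classifier = final[c("params", "cfg", "feature_dim",
                                    "input_mean", "input_sd")]),
          art("model.rds"))
  report$artifacts <- c(report$artifacts, art("model.rds"), log_path)
  report$reduct <- red
  report$rules <- rules
  report$pseudo_labels <- pseudo
  report$alpha <- alpha
  report$metrics <- metrics
  report$extractor <- ae
  report$classifier <- final
  log_line(log_path, "pipeline complete")
  report
}
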