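#' Experiment configuration
#'
#' Bundles every setting of an end-to-end run: generator, split fractions,
#' architecture, training, tasks, comparator models, mother-feature fusion
#' and run averaging. The patient population is divided into a
#' pre-training pool and a fine-tuning pool before any splitting, so the
#' two populations are disjoint by construction.
#'
#' @param sim An [ehr_sim_config()].
#' @param models Character subset of
#'   `c("bert", "tdecoder", "nn_remb", "lr", "rf")`.
#' @param tasks Character subset of `c("diagnosis", "los")`.
#' @param embedding_spec Input embedding specification (see
#'   [encoder_config()]).
#' @param encoder An [encoder_config()] template (attention mode is set
#'   per model).
#' @param pretrain_tcfg,finetune_tcfg [train_config()]s for the two
#'   phases.
#' @param pretrain_frac Fraction of patients reserved for the pre-training
#'   pool.
#' @param pretrain_split,finetune_split Role fractions inside each pool.
#' @param with_mother Fuse mother features into every model.
#' @param n_runs Number of independent runs to average.
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @return A list of class `experiment_config` with a semantic `hash`.
#' @export
experiment_config <- function(sim,
                              models = c("bert", "nn_remb", "lr"),
                              tasks = c("diagnosis", "los"),
                              embedding_spec = "base",
                              encoder = NULL,
                              pretrain_tcfg = NULL,
                              finetune_tcfg = NULL,
                              pretrain_frac = 0.5,
                              pretrain_split = c(train = 0.8, val = 0.2),
                              finetune_split = c(train = 0.7, val = 0.1,
                                                 test = 0.2),
                              with_mother = FALSE,
                              n_runs = 5L,
                              seed = 1L) {
  models <- match.arg(models, c("bert", "tdecoder", "nn_remb", "lr", "rf"),
                      several.ok = TRUE)
  tasks <- match.arg(tasks, c("diagnosis", "los"), several.ok = TRUE)
  if ("rf" %in% models && "diagnosis" %in% tasks && length(tasks) == 1) {
    stop("The RF comparator applies only to the LoS task; drop `rf` or add ",
         "`los` to `tasks`.", call. = FALSE)
  }
  if (is.null(encoder)) {
    encoder <- encoder_config(embedding_spec = embedding_spec)
  }
  if (is.null(pretrain_tcfg)) pretrain_tcfg <- train_config("pretrain")
  if (is.null(finetune_tcfg)) finetune_tcfg <- train_config("finetune")
  stopifnot(abs(sum(pretrain_split) - 1) < 1e-9,
            abs(sum(finetune_split) - 1) < 1e-9,
            pretrain_frac > 0, pretrain_frac < 1, n_runs >= 1)
  cfg <- list(sim = sim, models = models, tasks = tasks,
              embedding_spec = embedding_spec, encoder = encoder,
              pretrain_tcfg = pretrain_tcfg, finetune_tcfg = finetune_tcfg,
              pretrain_frac = pretrain_frac, pretrain_split = pretrain_split,
              finetune_split = finetune_split, with_mother = with_mother,
              n_runs = as.integer(n_runs), seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "experiment_config")
}

#' Run a full simulate / pre-train / fine-tune / evaluate experiment
#'
#' Executes the end-to-end workflow for every requested model and task:
#' simulate a cohort, filter to patients with at least three encounters,
#' carve disjoint pre-training and fine-tuning populations, split each by
#' patient id, pre-train the encoder models, fine-tune (or train the
#' multi-hot comparators), and evaluate per-patient and per-class metrics
#' on the held-out test split. Metrics are averaged over `n_runs`
#' independent runs (seeds `seed .. seed + n_runs - 1`).
#'
#' @param config An [experiment_config()].
#' @param out Optional directory; per-run and averaged metric tables are
#'   written there as tab-delimited text stamped with the config hash.
#' @param verbose Print progress.
#' @return A list of class `experiment_result`: `per_run` (tibble: run,
#'   seed, model, task, mean_aps, mean_auc, macro_auc), `averaged`
#'   (mean over runs), and `config`.
#' @export
run_experiment <- function(config, out = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  per_run <- list()
  for (r in seq_len(config$n_runs)) {
    run_seed <- config$seed + r - 1L
    if (verbose) message("run ", r, " (seed ", run_seed, ")")
    res <- run_once(config, run_seed)
    res$run <- r
    res$seed <- run_seed
    per_run[[r]] <- res
  }
  per_run <- dplyr::bind_rows(per_run)
  averaged <- per_run |>
    dplyr::group_by(.data$model, .data$task) |>
    dplyr::summarise(dplyr::across(c("mean_aps", "mean_auc", "macro_auc"),
                                   mean),
                     n_runs = dplyr::n(), .groups = "drop")
  result <- structure(list(per_run = per_run, averaged = averaged,
                           config = config),
                      class = "experiment_result")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    stamp <- substr(config$hash, 1, 8)
    utils::write.table(per_run, file.path(out, paste0("per_run_", stamp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(averaged, file.path(out, paste0("averaged_", stamp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}

run_once <- function(config, run_seed) {
  sim <- config$sim
  sim$seed <- run_seed
  coh <- simulate_cohort(sim)
  visits <- filter_min_encounters(coh$visits, 3L)
  ids <- unique(visits$patient_id)
  vocab <- build_vocabulary(default_code_set(sim$n_codes))

  pools <- assign_splits(ids, c(pretrain = config$pretrain_frac,
                                finetune = 1 - config$pretrain_frac),
                         seed = run_seed)
  pre_ids <- pools$patient_id[pools$role == "pretrain"]
  fin_ids <- pools$patient_id[pools$role == "finetune"]
  pre_roles <- assign_splits(pre_ids, config$pretrain_split, seed = run_seed + 1L)
  fin_roles <- assign_splits(fin_ids, config$finetune_split, seed = run_seed + 2L)

  sub_visits <- function(keep) visits[visits$patient_id %in% keep, , drop = FALSE]
  county_levels <- sort(unique(visits$county))
  enc <- config$encoder
  enc$embedding_spec <- config$embedding_spec

  corp <- function(role) {
    tokenize_corpus(sub_visits(pre_roles$patient_id[pre_roles$role == role]),
                    vocab, max_len = enc$max_len,
                    county_levels = county_levels)
  }
  schema <- if (config$with_mother) mother_feature_schema(coh$mothers)
  fset <- function(role, s) {
    build_finetune_set(
      sub_visits(fin_roles$patient_id[fin_roles$role == role]), vocab,
      mothers = coh$mothers, schema = schema,
      max_len = enc$max_len, county_levels = county_levels, seed = s)
  }
  ft_train <- fset("train", run_seed + 3L)
  ft_val <- fset("val", run_seed + 4L)
  ft_test <- fset("test", run_seed + 5L)

  pre_tcfg <- config$pretrain_tcfg; pre_tcfg$seed <- run_seed
  fin_tcfg <- config$finetune_tcfg; fin_tcfg$seed <- run_seed

  pretrained <- list()
  need_pre <- intersect(config$models, c("bert", "tdecoder"))
  if (length(need_pre) > 0) {
    tr <- corp("train"); va <- corp("val")
    for (m in need_pre) {
      cfg_m <- enc
      cfg_m$attention_mode <- if (m == "tdecoder") "causal" else "bidirectional"
      pretrained[[m]] <- pretrain(tr, va, vocab, cfg_m, pre_tcfg,
                                  eval_metrics = FALSE)
    }
  }

  rows <- list()
  for (task in config$tasks) {
    y_test <- if (task == "diagnosis") ft_test$dx_label else ft_test$los_label
    n_cls <- if (task == "diagnosis") length(vocab$codes) else 3L
    cls_labels <- if (task == "diagnosis") vocab$codes else
      c("same-day", "1-3d", ">3d")
    for (m in config$models) {
      if (m == "rf" && task == "diagnosis") next
      probs <- switch(
        m,
        bert = ,
        tdecoder = predict(
          finetune(ft_train, ft_val, task = task, pretrained = pretrained[[m]],
                   tcfg = fin_tcfg, n_classes = n_cls), ft_test),
        nn_remb = {
          cfg_r <- enc
          cfg_r$n_layers <- 0L
          cfg_r$pooling <- "mean"
          hc <- head_config(hidden_units = 564L, n_classes = n_cls,
                            mother_fusion = config$with_mother)
          predict(finetune(ft_train, ft_val, task = task, config = cfg_r,
                           tcfg = fin_tcfg, hcfg = hc, n_classes = n_cls),
                  ft_test)
        },
        lr = predict(
          train_logistic(ft_train, ft_val, task = task, tcfg = fin_tcfg,
                         vocab = vocab, with_mother = config$with_mother,
                         n_classes = n_cls),
          multihot_from_set(ft_test, vocab, with_mother = config$with_mother)),
        rf = predict(
          train_random_forest(ft_train, task = "los", seed = run_seed,
                              vocab = vocab,
                              with_mother = config$with_mother),
          multihot_from_set(ft_test, vocab, with_mother = config$with_mother))
      )
      ps <- prediction_set(probs, y_test, task = task,
                           class_labels = cls_labels,
                           subgroups = ft_test$subgroups,
                           patient_id = ft_test$patient_id)
      pp <- per_patient_metrics(ps)
      pc <- per_class_metrics(ps)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = m, task = task,
        mean_aps = pp$mean_aps, mean_auc = pp$mean_auc,
        macro_auc = pc$macro$macro_auc)
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", x$config$n_runs, " run(s)\n", sep = "")
  print(x$averaged)
  invisible(x)
}
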