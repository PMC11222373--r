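# Pre-training (masked diagnosis modeling), fine-tuning (next-visit
# diagnosis / LoS heads), and prediction entry points built on the engine
# in nn-core.R.

# Assemble the flattened id tracks for a row subset of a token corpus.
corpus_batch <- function(corpus, idx) {
  zipm <- corpus$zip
  if (is.null(zipm)) zipm <- matrix(0L, length(idx), ncol(corpus$ids))
  else zipm <- zipm[idx, , drop = FALSE]
  idsm <- if (is.null(corpus$input_ids)) corpus$ids else corpus$input_ids
  list(
    fb = flatten_batch(list(
      ids = idsm[idx, , drop = FALSE],
      vis = corpus$vis[idx, , drop = FALSE],
      age = corpus$age[idx, , drop = FALSE],
      cnty = corpus$cnty[idx, , drop = FALSE],
      zip = zipm
    )),
    mask = corpus$mask[idx, , drop = FALSE]
  )
}

# Grow a config's id-space sizes to cover a corpus.
fit_config_to_corpus <- function(cfg, corpus, vocab_size = NULL) {
  cfg$n_counties <- max(cfg$n_counties, max(corpus$cnty))
  if (!is.null(corpus$zip)) cfg$n_zips <- max(cfg$n_zips, max(corpus$zip))
  if (!is.null(vocab_size)) cfg$vocab_size <- as.integer(vocab_size)
  cfg$max_len <- as.integer(ncol(corpus$ids))
  cfg
}

#' Pre-train the encoder with masked diagnosis modeling
#'
#' Trains the transformer encoder (bidirectional) or decoder comparator
#' (`attention_mode = "causal"`) to predict corrupted diagnosis tokens.
#' For bidirectional models the objective is cross-entropy at the masked
#' positions of a [mask_corpus()] corruption (drawn once per call — static
#' masking — unless `remask_each_epoch`). For causal models the objective
#' is next-token prediction over all real positions, the standard
#' left-context pre-training objective. Optimization is Adam with decoupled
#' weight decay.
#'
#' @param train,val [tokenize_corpus()] results (a pre-masked
#'   [mask_corpus()] is also accepted for `train`/`val` of bidirectional
#'   models).
#' @param vocab The [build_vocabulary()] vocabulary.
#' @param config An [encoder_config()].
#' @param tcfg A [train_config()] (phase `"pretrain"`).
#' @param mask_rate MLM corruption rate.
#' @param remask_each_epoch Redraw the corruption every epoch (dynamic
#'   masking) instead of the static default.
#' @param eval_metrics Compute validation APS / ROC AUC (macro one-vs-rest
#'   over vocabulary tokens at masked positions) each epoch.
#' @param verbose Print one line per epoch.
#' @return An object of class `pedvisit_pretrain`: trained `params`,
#'   `config`, `tcfg`, `vocab`, and `history` (tibble: epoch, split, loss,
#'   aps, auc).
#' @export
pretrain <- function(train, val, vocab, config, tcfg = train_config("pretrain"),
                     mask_rate = 0.15, remask_each_epoch = FALSE,
                     eval_metrics = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "encoder_config"), inherits(tcfg, "train_config"))
  if (nrow(train$ids) == 0 || nrow(val$ids) == 0) {
    stop("Pre-training requires non-empty training and validation corpora.",
         call. = FALSE)
  }
  causal <- config$attention_mode == "causal"
  config <- fit_config_to_corpus(config, train, vocab_size = vocab$size)
  config <- fit_config_to_corpus(config, val)
  with_seed_(tcfg$seed, {
    P <- c(init_encoder_params(config), init_mlm_head(config))
    st <- adam_init(P)
    if (!causal && !inherits(train, "masked_corpus")) {
      train <- mask_corpus(train, vocab, rate = mask_rate)
    }
    if (!causal && !inherits(val, "masked_corpus")) {
      val <- mask_corpus(val, vocab, rate = mask_rate)
    }
    n <- nrow(train$ids)
    hist <- list()
    for (epoch in seq_len(tcfg$epochs)) {
      if (!causal && remask_each_epoch && epoch > 1) {
        train <- mask_corpus(train, vocab, rate = mask_rate)
      }
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
        step <- mlm_step(P, config, train, idx, vocab, causal, train_mode = TRUE)
        G <- step$G
        losses <- c(losses, step$loss)
        upd <- adam_step(P, G, st, tcfg$learning_rate, tcfg$weight_decay)
        P <- upd$P; st <- upd$st
      }
      ev <- mlm_evaluate(P, config, val, vocab, causal,
                         batch_size = tcfg$batch_size,
                         metrics = eval_metrics)
      hist[[length(hist) + 1L]] <- tibble::tibble(
        epoch = epoch,
        split = c("train", "val"),
        loss = c(mean(losses), ev$loss),
        aps = c(NA_real_, ev$aps), auc = c(NA_real_, ev$auc)
      )
      if (verbose) {
        message(sprintf("epoch %d  train loss %.4f  val loss %.4f", epoch,
                        mean(losses), ev$loss))
      }
    }
    structure(
      list(params = P, config = config, tcfg = tcfg, vocab = vocab,
           history = dplyr::bind_rows(hist)),
      class = "pedvisit_pretrain"
    )
  })
}

# One forward/backward pass of the pre-training objective on corpus rows
# `idx`. For causal models the target at each real position i > 1 is the
# observed token at i, predicted from positions < i (achieved by shifting:
# logits at i-1 score the token at i).
mlm_step <- function(P, config, corpus, idx, vocab, causal, train_mode) {
  cb <- corpus_batch(corpus, idx)
  fwd <- encoder_fwd(P, config, cb$fb, cb$mask, train = train_mode)
  sel <- pretrain_targets(corpus, idx, cb, causal)
  H <- fwd$out[sel$pos, , drop = FALSE]
  logits <- addb(H %*% P$mlm.W, P$mlm.b)
  ce <- ce_loss(logits, sel$truth)
  G <- zeros_like(P)
  G$mlm.W <- crossprod(H, ce$dlogits)
  G$mlm.b <- colSums(ce$dlogits)
  dOut <- matrix(0, nrow(fwd$out), ncol(fwd$out))
  dOut[sel$pos, ] <- ce$dlogits %*% t(P$mlm.W)
  G <- encoder_bwd(P, G, config, cb$fb, cb$mask, fwd, dOut)
  list(G = G, loss = ce$loss)
}

# Flat positions and 0-based target ids of the pre-training objective for
# a batch. Bidirectional: labeled (masked) positions. Causal: every real
# position whose successor is real predicts the successor's token.
pretrain_targets <- function(corpus, idx, cb, causal) {
  L <- ncol(corpus$ids)
  if (!causal) {
    lab <- as.vector(t(corpus$labels[idx, , drop = FALSE]))
    pos <- which(lab >= 0L)
    return(list(pos = pos, truth = lab[pos]))
  }
  maskf <- as.vector(t(cb$mask))
  idsf <- as.vector(t(corpus$ids[idx, , drop = FALSE]))
  n <- length(idsf)
  cur_real <- maskf == 1L
  nxt_real <- c(maskf[-1] == 1L, FALSE)
  not_last <- (seq_len(n) %% L) != 0L
  pos <- which(cur_real & nxt_real & not_last)
  list(pos = pos, truth = idsf[pos + 1L])
}

# Validation loss (+ optional macro ranking metrics) on a corpus.
mlm_evaluate <- function(P, config, corpus, vocab, causal, batch_size = 64L,
                         metrics = TRUE) {
  n <- nrow(corpus$ids)
  tot_loss <- 0; tot_n <- 0
  probs_list <- list(); truth_list <- list()
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    cb <- corpus_batch(corpus, idx)
    fwd <- encoder_fwd(P, config, cb$fb, cb$mask, train = FALSE)
    sel <- pretrain_targets(corpus, idx, cb, causal)
    H <- fwd$out[sel$pos, , drop = FALSE]
    logits <- addb(H %*% P$mlm.W, P$mlm.b)
    ce <- ce_loss(logits, sel$truth)
    tot_loss <- tot_loss + ce$loss * length(sel$pos)
    tot_n <- tot_n + length(sel$pos)
    if (metrics) {
      probs_list[[length(probs_list) + 1L]] <- ce$probs
      truth_list[[length(truth_list) + 1L]] <- sel$truth
    }
  }
  out <- list(loss = tot_loss / tot_n, aps = NA_real_, auc = NA_real_)
  if (metrics && length(probs_list) > 0) {
    mm <- ranking_macro_metrics(do.call(rbind, probs_list),
                                unlist(truth_list))
    out$aps <- mm$aps; out$auc <- mm$auc
  }
  out
}

#' Predicted token probabilities at masked positions
#'
#' Runs a pre-trained model over a masked corpus and returns the predicted
#' probability vector, the ground-truth id, and the source patient row for
#' every labeled position.
#'
#' @param model A [pretrain()] result.
#' @param corpus A [mask_corpus()] result.
#' @param batch_size Forward-pass batch size.
#' @return List with `probs` (positions x vocabulary matrix), `truth`
#'   (0-based true token ids) and `row` (corpus row of each position).
#' @export
mlm_predict <- function(model, corpus, batch_size = 64L) {
  stopifnot(inherits(model, "pedvisit_pretrain"),
            inherits(corpus, "masked_corpus"))
  config <- fit_config_to_corpus(model$config, corpus)
  n <- nrow(corpus$ids)
  L <- ncol(corpus$ids)
  probs_list <- list(); truth <- integer(0); row <- integer(0)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    cb <- corpus_batch(corpus, idx)
    fwd <- encoder_fwd(P = model$params, cfg = config, fb = cb$fb,
                       mask = cb$mask, train = FALSE)
    lab <- as.vector(t(corpus$labels[idx, , drop = FALSE]))
    pos <- which(lab >= 0L)
    H <- fwd$out[pos, , drop = FALSE]
    probs_list[[length(probs_list) + 1L]] <-
      softmax_rows(addb(H %*% model$params$mlm.W, model$params$mlm.b))
    truth <- c(truth, lab[pos])
    row <- c(row, idx[(pos - 1L) %/% L + 1L])
  }
  list(probs = do.call(rbind, probs_list), truth = truth, row = row)
}

#' Fine-tune a model for next-visit diagnosis or LoS prediction
#'
#' Puts a one-hidden-layer softmax head on the pooled final-layer
#' representation (optionally concatenated with mother features) and
#' updates all parameters — encoder included — by Adam with cross-entropy,
#' early-stopping on validation loss and restoring the best epoch.
#' Starting from a [pretrain()] model gives the pre-trained configuration;
#' passing `pretrained = NULL` with an [encoder_config()] trains from
#' random initialization (with `n_layers = 0` and mean pooling this is the
#' random-embedding comparator).
#'
#' @param train,val [build_finetune_set()] results.
#' @param task `"diagnosis"` (principal code of the next visit) or
#'   `"los"` (LoS class of the next visit).
#' @param pretrained A `pedvisit_pretrain` model, or NULL.
#' @param config An [encoder_config()]; required when `pretrained` is NULL.
#' @param tcfg A [train_config()] (phase `"finetune"`).
#' @param hcfg A [head_config()]; defaults to 64 hidden units and the
#'   task's class count, with mother fusion iff `train` carries mother
#'   features.
#' @param n_classes Label-space size for the diagnosis task (default 115).
#' @param verbose Print one line per epoch.
#' @return An object of class `pedvisit_finetune` with trained `params`,
#'   `config`, `hcfg`, `task`, `history`, `best_epoch`.
#' @export
finetune <- function(train, val, task = c("diagnosis", "los"),
                     pretrained = NULL, config = NULL,
                     tcfg = train_config("finetune"), hcfg = NULL,
                     n_classes = 115L, verbose = FALSE) {
  task <- match.arg(task)
  stopifnot(inherits(train, "finetune_set"), inherits(val, "finetune_set"))
  y_train <- if (task == "diagnosis") train$dx_label else train$los_label
  y_val <- if (task == "diagnosis") val$dx_label else val$los_label
  n_cls <- if (task == "diagnosis") as.integer(n_classes) else 3L
  if (max(c(y_train, y_val)) >= n_cls) {
    stop("Labels exceed the task's class count (task/label mismatch).",
         call. = FALSE)
  }
  n_mother <- 0L
  if (!is.null(train$mother_features)) n_mother <- ncol(train$mother_features)
  if (is.null(hcfg)) {
    hcfg <- head_config(n_classes = n_cls, mother_fusion = n_mother > 0)
  }
  if (hcfg$n_classes != n_cls) {
    stop("Head configured for ", hcfg$n_classes, " classes but task `", task,
         "` has ", n_cls, ".", call. = FALSE)
  }
  if (hcfg$mother_fusion && n_mother == 0L) {
    stop("`mother_fusion` requested but the training set carries no mother ",
         "features.", call. = FALSE)
  }
  if (!hcfg$mother_fusion) n_mother <- 0L
  if (!is.null(pretrained)) {
    config <- pretrained$config
  } else if (is.null(config)) {
    stop("Provide `config` when fine-tuning from random initialization.",
         call. = FALSE)
  }
  config <- fit_config_to_corpus(config, train)
  config <- fit_config_to_corpus(config, val)

  with_seed_(tcfg$seed, {
    if (!is.null(pretrained)) {
      P <- pretrained$params
      P$mlm.W <- NULL; P$mlm.b <- NULL
    } else {
      P <- init_encoder_params(config)
    }
    P <- c(P, init_cls_head(config, hcfg, n_mother))
    st <- adam_init(P)
    n <- nrow(train$ids)
    hist <- list()
    best <- list(loss = Inf, epoch = 0L, params = P)
    stall <- 0L
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
        step <- head_step(P, config, hcfg, train, idx, y_train[idx], n_mother,
                          head_dropout = tcfg$head_dropout, train_mode = TRUE)
        losses <- c(losses, step$loss)
        upd <- adam_step(P, step$G, st, tcfg$learning_rate, tcfg$weight_decay)
        P <- upd$P; st <- upd$st
      }
      vl <- head_evaluate(P, config, hcfg, val, y_val, n_mother,
                          batch_size = tcfg$batch_size)
      hist[[length(hist) + 1L]] <- tibble::tibble(
        epoch = epoch, split = c("train", "val"),
        loss = c(mean(losses), vl)
      )
      if (verbose) {
        message(sprintf("epoch %d  train loss %.4f  val loss %.4f",
                        epoch, mean(losses), vl))
      }
      if (vl < best$loss - tcfg$min_delta) {
        best <- list(loss = vl, epoch = epoch, params = P)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tcfg$patience) break
      }
    }
    structure(
      list(params = best$params, config = config, hcfg = hcfg, tcfg = tcfg,
           task = task, n_classes = n_cls, n_mother = n_mother,
           history = dplyr::bind_rows(hist), best_epoch = best$epoch,
           best_val_loss = best$loss),
      class = "pedvisit_finetune"
    )
  })
}

# Forward/backward of pooled-representation -> hidden(ReLU, dropout) ->
# softmax head; returns grads for all parameters (encoder included).
head_step <- function(P, config, hcfg, set, idx, y, n_mother, head_dropout,
                      train_mode) {
  cb <- corpus_batch(set, idx)
  fwd <- encoder_fwd(P, config, cb$fb, cb$mask, train = train_mode)
  pool <- pool_fwd(fwd$out, cb$mask, config$pooling)
  U <- pool$pooled
  if (n_mother > 0L) {
    U <- cbind(U, set$mother_features[idx, , drop = FALSE])
  }
  pre <- addb(U %*% P$head.W1, P$head.b1)
  H1 <- pmax(pre, 0)
  dr <- drop_fwd(H1, head_dropout, train_mode)
  logits <- addb(dr$y %*% P$head.W2, P$head.b2)
  ce <- ce_loss(logits, y)
  G <- zeros_like(P)
  G$head.W2 <- crossprod(dr$y, ce$dlogits)
  G$head.b2 <- colSums(ce$dlogits)
  dH1 <- drop_bwd(ce$dlogits %*% t(P$head.W2), dr$m) * (pre > 0)
  G$head.W1 <- crossprod(U, dH1)
  G$head.b1 <- colSums(dH1)
  dU <- dH1 %*% t(P$head.W1)
  dPooled <- dU[, seq_len(config$d_model), drop = FALSE]
  dOut <- pool_bwd(dPooled, pool, cb$mask, nrow(fwd$out))
  G <- encoder_bwd(P, G, config, cb$fb, cb$mask, fwd, dOut)
  list(G = G, loss = ce$loss, probs = ce$probs)
}

head_forward_probs <- function(P, config, hcfg, set, idx, n_mother) {
  cb <- corpus_batch(set, idx)
  fwd <- encoder_fwd(P, config, cb$fb, cb$mask, train = FALSE)
  pool <- pool_fwd(fwd$out, cb$mask, config$pooling)
  U <- pool$pooled
  if (n_mother > 0L) U <- cbind(U, set$mother_features[idx, , drop = FALSE])
  H1 <- pmax(addb(U %*% P$head.W1, P$head.b1), 0)
  softmax_rows(addb(H1 %*% P$head.W2, P$head.b2))
}

head_evaluate <- function(P, config, hcfg, set, y, n_mother, batch_size) {
  n <- nrow(set$ids)
  tot <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs <- head_forward_probs(P, config, hcfg, set, idx, n_mother)
    ll <- -log(pmax(probs[cbind(seq_along(idx), y[idx] + 1L)], 1e-12))
    tot <- tot + sum(ll)
  }
  tot / n
}

#' Predict class probabilities for a fine-tuning set
#'
#' @param object A [finetune()] model.
#' @param newdata A [build_finetune_set()].
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Numeric matrix (patients x classes); rows sum to 1.
#' @export
predict.pedvisit_finetune <- function(object, newdata, batch_size = 128L, ...) {
  stopifnot(inherits(newdata, "finetune_set"))
  config <- fit_config_to_corpus(object$config, newdata)
  n <- nrow(newdata$ids)
  out <- matrix(NA_real_, n, object$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- head_forward_probs(object$params, config, object$hcfg,
                                     newdata, idx, object$n_mother)
  }
  out
}

#' Pooled final-layer representation of each sequence
#'
#' The fine-tuning input representation: the final encoder layer's vector
#' at the `[CLS]` position (or the mean over real tokens under
#' `pooling = "mean"`).
#'
#' @param params Parameter list of a trained model (or [pretrain()] /
#'   [finetune()] object, from which params and config are taken).
#' @param corpus A `token_corpus` / `finetune_set`.
#' @param config An [encoder_config()] (ignored when `params` is a fitted
#'   model).
#' @param batch_size Forward-pass batch size.
#' @return Numeric matrix (sequences x `d_model`).
#' @export
pooled_representation <- function(params, corpus, config = NULL,
                                  batch_size = 128L) {
  if (inherits(params, c("pedvisit_pretrain", "pedvisit_finetune"))) {
    config <- params$config
    params <- params$params
  }
  stopifnot(inherits(config, "encoder_config"))
  config <- fit_config_to_corpus(config, corpus)
  n <- nrow(corpus$ids)
  out <- matrix(NA_real_, n, config$d_model)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    cb <- corpus_batch(corpus, idx)
    fwd <- encoder_fwd(params, config, cb$fb, cb$mask, train = FALSE)
    out[idx, ] <- pool_fwd(fwd$out, cb$mask, config$pooling)$pooled
  }
  out
}

#' Low-level encoder operations on a single tokenized history
#'
#' `embed_inputs()` composes the per-token input representation (token +
#' visit-position embeddings, plus age / county / zip embeddings according
#' to the embedding spec); `encoder_forward()` additionally runs the
#' encoder stack; `mlm_logits()` maps final-layer vectors to vocabulary
#' scores and `mlm_probs()` to probabilities.
#'
#' @param history A [build_history_tokens()] result.
#' @param params A parameter list (e.g. `model$params`, or
#'   [init_params()] for a random model).
#' @param config An [encoder_config()].
#' @return `embed_inputs()` / `encoder_forward()`: `max_len x d_model`
#'   matrix; `mlm_logits()`: `max_len x vocab_size` matrix.
#' @export
embed_inputs <- function(history, params, config) {
  fb <- history_tracks(history)
  check_track_ranges(fb, params, config)
  embed_fwd(params, config, fb)
}

#' @rdname embed_inputs
#' @export
encoder_forward <- function(history, params, config) {
  fb <- history_tracks(history)
  check_track_ranges(fb, params, config)
  mask <- matrix(history$attention_mask, nrow = 1)
  encoder_fwd(params, config, fb, mask, train = FALSE)$out
}

#' @rdname embed_inputs
#' @param final_out A final-layer output matrix from `encoder_forward()`.
#' @export
mlm_logits <- function(final_out, params) {
  addb(final_out %*% params$mlm.W, params$mlm.b)
}

#' @rdname embed_inputs
#' @export
mlm_probs <- function(final_out, params) {
  softmax_rows(mlm_logits(final_out, params))
}

#' @rdname embed_inputs
#' @param with_mlm_head Include the masked-prediction output layer.
#' @param seed Seed for the random initialization.
#' @export
init_params <- function(config, with_mlm_head = TRUE, seed = 1L) {
  with_seed_(seed, {
    P <- init_encoder_params(config)
    if (with_mlm_head) P <- c(P, init_mlm_head(config))
    P
  })
}

history_tracks <- function(history) {
  stopifnot(inherits(history, "tokenized_history"))
  list(ids = history$token_ids, vis = history$visit_ordinals,
       age = history$ages, cnty = history$counties,
       zip = history$zips %||% rep(0L, length(history$token_ids)))
}

check_track_ranges <- function(fb, params, config) {
  if (max(fb$ids) >= nrow(params$tok) || max(fb$cnty) >= nrow(params$cntyE) ||
      max(fb$age) >= nrow(params$ageE) || max(fb$vis) >= nrow(params$vis) ||
      max(fb$zip) >= nrow(params$zipE)) {
    stop("Track id out of range for the model's embedding tables.",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Learned token-embedding matrix
#'
#' @param model A [pretrain()] or [finetune()] result.
#' @return Numeric matrix (vocabulary x `d_model`); row names are token
#'   strings when the model carries its vocabulary.
#' @export
token_embeddings <- function(model) {
  emb <- model$params$tok
  if (!is.null(model$vocab)) rownames(emb) <- model$vocab$id_to_code
  emb
}

#' @export
print.pedvisit_pretrain <- function(x, ...) {
  cat("<pedvisit_pretrain> ", x$config$attention_mode, " encoder, ",
      x$config$n_layers, " layers, d_model ", x$config$d_model, "\n", sep = "")
  invisible(x)
}

#' @export
print.pedvisit_finetune <- function(x, ...) {
  cat("<pedvisit_finetune> task ", x$task, ", ", x$n_classes,
      " classes, best epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}
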