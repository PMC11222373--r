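# Non-transformer comparators on multi-hot code-history inputs: a
# dropout-regularized softmax ("logistic regression" trained by gradient
# descent, the only reading under which a dropout rate applies to LR) and
# a small balanced-bootstrap random forest for the LoS task.

#' Multi-hot features for one patient history
#'
#' Indicator vector over the diagnosis vocabulary: position c is 1 iff
#' code c occurs in any of visits `1..v`. Codes outside the vocabulary are
#' ignored. Labels are derived exactly as in [make_finetune_pair()] for
#' the same `(record, v)`.
#'
#' @param record_visits One patient's visits, ordered by `visit_ordinal`.
#' @param v History split index (`2 <= v < T`).
#' @param vocab The vocabulary.
#' @param mother_features Optional numeric vector appended to the code
#'   block.
#' @return List of class `multihot_example` with `features`,
#'   `diagnosis_label`, `los_label`.
#' @export
multi_hot_features <- function(record_visits, v, vocab,
                               mother_features = NULL) {
  T_ <- nrow(record_visits)
  if (v < 2 || v >= T_) stop("`v` must satisfy 2 <= v < T.", call. = FALSE)
  seen <- unlist(record_visits[seq_len(v), c("dx1", "dx2", "dx3")],
                 use.names = FALSE)
  seen <- seen[!is.na(seen)]
  feat <- numeric(length(vocab$codes))
  idx <- match(seen, vocab$codes)
  feat[idx[!is.na(idx)]] <- 1
  if (!is.null(mother_features)) feat <- c(feat, as.numeric(mother_features))
  pair <- make_finetune_pair(record_visits, vocab, v = v,
                             max_len = max(40L, 3L * T_ + 2L))
  structure(list(features = feat, diagnosis_label = pair$diagnosis_label,
                 los_label = pair$los_label),
            class = "multihot_example")
}

#' Multi-hot design matrix from a fine-tuning set
#'
#' Reuses the tokenized visits `1..v` of a [build_finetune_set()] (token
#' ids at or above the special-token block are code occurrences), so the
#' multi-hot comparators see exactly the same histories and labels as the
#' sequence models.
#'
#' @param set A [build_finetune_set()].
#' @param vocab The vocabulary.
#' @param with_mother Append the set's mother-feature block.
#' @return List with `X` (patients x features matrix), `dx_label`,
#'   `los_label`, `patient_id`, `subgroups`.
#' @export
multihot_from_set <- function(set, vocab, with_mother = FALSE) {
  stopifnot(inherits(set, "finetune_set"))
  n <- nrow(set$ids)
  C <- length(vocab$codes)
  X <- matrix(0, n, C,
              dimnames = list(NULL, vocab$codes))
  code_pos <- set$ids >= vocab$n_special
  rows <- row(set$ids)[code_pos]
  cols <- set$ids[code_pos] - vocab$n_special + 1L
  X[cbind(rows, cols)] <- 1
  if (with_mother) {
    if (is.null(set$mother_features)) {
      stop("`with_mother = TRUE` but the set carries no mother features.",
           call. = FALSE)
    }
    X <- cbind(X, set$mother_features)
  }
  list(X = X, dx_label = set$dx_label, los_label = set$los_label,
       patient_id = set$patient_id, subgroups = set$subgroups)
}

#' Dropout-regularized multinomial logistic regression
#'
#' A single softmax layer on multi-hot inputs, trained by Adam with input
#' dropout (a "logistic regression with a dropout rate" is well-defined
#' only as a one-layer network trained by gradient descent, which is how
#' it is implemented here), early-stopping on validation loss.
#'
#' @param train,val Lists with `X` and the task's label vector (e.g. from
#'   [multihot_from_set()]), or [build_finetune_set()] objects together
#'   with `vocab`.
#' @param task `"diagnosis"` or `"los"`.
#' @param tcfg A [train_config()] (phase `"finetune"`); learning rate
#'   3e-4 by default.
#' @param dropout Input dropout rate (default 0.1).
#' @param vocab Required when `train`/`val` are fine-tuning sets.
#' @param with_mother Append mother features (fine-tuning-set input only).
#' @param n_classes Diagnosis label-space size.
#' @return An object of class `pedvisit_lr` with `W`, `b`, `history`,
#'   `best_epoch`.
#' @export
train_logistic <- function(train, val, task = c("diagnosis", "los"),
                           tcfg = train_config("finetune"), dropout = 0.1,
                           vocab = NULL, with_mother = FALSE,
                           n_classes = 115L) {
  task <- match.arg(task)
  tr <- as_multihot(train, vocab, with_mother)
  va <- as_multihot(val, vocab, with_mother)
  y_tr <- if (task == "diagnosis") tr$dx_label else tr$los_label
  y_va <- if (task == "diagnosis") va$dx_label else va$los_label
  C <- if (task == "diagnosis") as.integer(n_classes) else 3L
  if (length(y_tr) == 0) stop("Empty training set.", call. = FALSE)
  if (length(unique(y_tr)) < 2) {
    stop("Training labels are single-class; nothing to discriminate.",
         call. = FALSE)
  }
  X <- tr$X
  with_seed_(tcfg$seed, {
    P <- list(W = rmat(ncol(X), C), b = numeric(C))
    st <- adam_init(P)
    n <- nrow(X)
    best <- list(loss = Inf, epoch = 0L, P = P)
    stall <- 0L
    hist <- list()
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
        xb <- X[idx, , drop = FALSE]
        dr <- drop_fwd(xb, dropout, TRUE)
        logits <- addb(dr$y %*% P$W, P$b)
        ce <- ce_loss(logits, y_tr[idx])
        G <- list(W = crossprod(dr$y, ce$dlogits), b = colSums(ce$dlogits))
        upd <- adam_step(P, G, st, tcfg$learning_rate, tcfg$weight_decay)
        P <- upd$P; st <- upd$st
        losses <- c(losses, ce$loss)
      }
      vlogits <- addb(va$X %*% P$W, P$b)
      vl <- ce_loss(vlogits, y_va)$loss
      hist[[length(hist) + 1L]] <- tibble::tibble(
        epoch = epoch, split = c("train", "val"),
        loss = c(mean(losses), vl))
      if (vl < best$loss - tcfg$min_delta) {
        best <- list(loss = vl, epoch = epoch, P = P)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tcfg$patience) break
      }
    }
    structure(
      list(W = best$P$W, b = best$P$b, task = task, n_classes = C,
           history = dplyr::bind_rows(hist), best_epoch = best$epoch),
      class = "pedvisit_lr"
    )
  })
}

as_multihot <- function(x, vocab, with_mother) {
  if (inherits(x, "finetune_set")) {
    if (is.null(vocab)) {
      stop("Provide `vocab` to build multi-hot features from a fine-tuning ",
           "set.", call. = FALSE)
    }
    multihot_from_set(x, vocab, with_mother = with_mother)
  } else {
    stopifnot(is.list(x), !is.null(x$X))
    x
  }
}

#' @export
predict.pedvisit_lr <- function(object, newdata, ...) {
  X <- if (is.list(newdata) && !is.null(newdata$X)) newdata$X else as.matrix(newdata)
  softmax_rows(addb(X %*% object$W, object$b))
}

#' Balanced-bootstrap random forest for the LoS task
#'
#' Ten trees of maximum depth five with per-tree bootstrap sampling
#' balanced across the three LoS classes (each tree draws, with
#' replacement, the smallest class's count from every class). Probability
#' output is the average of per-tree class frequencies. Following the
#' restriction that decision-tree models handle the 100+-class diagnosis
#' task poorly, the forest is only available for `task = "los"`.
#'
#' @param train A list with `X` and `los_label` (e.g. from
#'   [multihot_from_set()]), or a [build_finetune_set()] with `vocab`.
#' @param task Must be `"los"`; the diagnosis task is rejected.
#' @param num_trees,max_depth Forest size and depth cap.
#' @param seed RNG seed.
#' @param vocab Required when `train` is a fine-tuning set.
#' @param with_mother Append mother features.
#' @return An object of class `pedvisit_rf` wrapping the fitted
#'   \pkg{ranger} forest.
#' @export
train_random_forest <- function(train, task = "los", num_trees = 10L,
                                max_depth = 5L, seed = 1L, vocab = NULL,
                                with_mother = FALSE) {
  if (!identical(task, "los")) {
    stop("The random-forest comparator applies exclusively to the LoS task; ",
         "tree ensembles are not fielded for the 115-class diagnosis task.",
         call. = FALSE)
  }
  tr <- as_multihot(train, vocab, with_mother)
  y <- factor(tr$los_label, levels = 0:2)
  counts <- table(y)
  if (sum(counts > 0) < 2) {
    stop("Training labels are single-class; cannot grow a forest.",
         call. = FALSE)
  }
  y <- droplevels(y)
  counts <- table(y)
  n <- length(y)
  frac <- as.numeric(min(counts) / n)  # equal draws per class
  frac <- rep(frac, nlevels(y))
  dat <- data.frame(y = y, tr$X, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = "y", data = dat,
    num.trees = num_trees, max.depth = max_depth,
    probability = TRUE, replace = TRUE, sample.fraction = frac,
    seed = seed, num.threads = 1
  )
  structure(list(forest = fit, task = "los", n_classes = 3L,
                 levels = levels(y)),
            class = "pedvisit_rf")
}

#' @export
predict.pedvisit_rf <- function(object, newdata, ...) {
  X <- if (is.list(newdata) && !is.null(newdata$X)) newdata$X else as.matrix(newdata)
  dat <- data.frame(X, check.names = FALSE)
  pr <- stats::predict(object$forest, data = dat, num.threads = 1)$predictions
  out <- matrix(0, nrow(pr), object$n_classes)
  out[, as.integer(object$levels) + 1L] <- pr
  out
}
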