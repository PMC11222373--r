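# Ranking metrics with the averaging schemes used for next-visit
# prediction: average precision (threshold-weighted precision) and ROC AUC
# (Mann-Whitney with half-credit for ties), per-patient and per-class.

#' Average precision score
#'
#' The weighted mean of precisions achieved at each descending score
#' threshold, with the increase in recall from the previous threshold as
#' the weight: `AP = sum_n (R_n - R_{n-1}) P_n`. Tied scores form a single
#' threshold. Returns `NA` (the undefined-marker) when there are no
#' positive labels; callers exclude such cases from averages and count
#' them.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1 = positive) of the same length.
#' @return A number in \[0, 1\], or `NA` if no positives.
#' @examples
#' average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 5/6
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels != 0)
  npos <- sum(labels)
  if (npos == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  b <- cumsum(rle(s)$lengths)  # last index at each unique threshold
  tp <- cumsum(y)[b]
  prec <- tp / b
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' ROC AUC
#'
#' Computed in the Mann-Whitney form `P(score_pos > score_neg) +
#' 0.5 P(tie)` via mid-ranks, which equals trapezoidal integration of the
#' ROC curve. Returns `NA` when labels are single-class.
#'
#' @inheritParams average_precision
#' @return A number in \[0, 1\], or `NA` if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels != 0)
  npos <- sum(labels)
  nneg <- length(labels) - npos
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' @inheritParams average_precision
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, beginning at
#'   (0, 0) and ending at (1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  npos <- sum(labels)
  nneg <- length(labels) - npos
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  b <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[b]
  fp <- b - tp
  tibble::tibble(
    threshold = c(Inf, s[b]),
    fpr = c(0, fp / max(nneg, 1)),
    tpr = c(0, tp / max(npos, 1))
  )
}

#' Bundle predictions, truth and subgroup keys
#'
#' @param probs Numeric matrix (patients x classes); rows must be
#'   nonnegative and sum to 1 (tolerance 1e-6).
#' @param true_class 0-based true class index per patient.
#' @param task `"diagnosis"` or `"los"`.
#' @param class_labels Optional class names (length `ncol(probs)`).
#' @param subgroups Optional tibble of per-patient subgroup keys.
#' @param patient_id Optional patient ids.
#' @return A tibble of class `prediction_set` with a matrix column
#'   `probs`, integer column `true`, and any subgroup columns.
#' @export
prediction_set <- function(probs, true_class, task = c("diagnosis", "los"),
                           class_labels = NULL, subgroups = NULL,
                           patient_id = NULL) {
  task <- match.arg(task)
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == length(true_class))
  if (any(probs < -1e-12) || any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("Probability rows must be nonnegative and sum to 1.", call. = FALSE)
  }
  true_class <- as.integer(true_class)
  if (any(true_class < 0L | true_class >= ncol(probs))) {
    stop("`true_class` out of range for the probability matrix.", call. = FALSE)
  }
  if (is.null(patient_id)) patient_id <- sprintf("p%06d", seq_len(nrow(probs)))
  if (is.null(class_labels)) class_labels <- as.character(seq_len(ncol(probs)) - 1L)
  out <- tibble::tibble(patient_id = patient_id, true = true_class)
  out$probs <- probs
  if (!is.null(subgroups)) {
    out <- dplyr::bind_cols(out, dplyr::select(subgroups,
                                               -dplyr::any_of("patient_id")))
  }
  attr(out, "task") <- task
  attr(out, "class_labels") <- class_labels
  class(out) <- c("prediction_set", class(out))
  out
}

#' Per-patient ranking metrics
#'
#' For each patient the C-class probability vector is scored one-vs-rest
#' with a single positive (the true class): with mid-rank `r` of the true
#' class among the C scores, patient AUC is `(C - r) / (C - 1)` and
#' patient AP is `1 / r`; the report is the unweighted mean over patients.
#'
#' @param pred A [prediction_set()].
#' @return One-row tibble with `mean_aps`, `mean_auc`, `n_patients`; the
#'   per-patient values are attached as attribute `"per_patient"`.
#' @export
per_patient_metrics <- function(pred) {
  stopifnot(inherits(pred, "prediction_set"))
  if (nrow(pred) == 0) stop("Empty prediction set.", call. = FALSE)
  probs <- pred$probs
  n <- nrow(probs)
  C <- ncol(probs)
  s_true <- probs[cbind(seq_len(n), pred$true + 1L)]
  st <- matrix(s_true, n, C)
  gt <- rowSums(probs > st)
  ties <- rowSums(probs == st) - 1L
  r <- 1 + gt + ties / 2
  auc <- (C - r) / (C - 1)
  aps <- 1 / r
  out <- tibble::tibble(mean_aps = mean(aps), mean_auc = mean(auc),
                        n_patients = n)
  attr(out, "per_patient") <- tibble::tibble(
    patient_id = pred$patient_id, rank = r, aps = aps, auc = auc)
  out
}

#' Per-class ranking metrics
#'
#' One-vs-rest over all patients pooled: for class c the scores are the
#' predicted probability of c and the labels indicate `true == c`. Classes
#' without positives are reported with `NA` metrics and excluded from the
#' macro means.
#'
#' @param pred A [prediction_set()].
#' @param curves Attach ROC curve points per class (list column `roc`).
#' @return A list of class `class_metrics`: `per_class` (tibble: class,
#'   label, support, aps, auc) and `macro` (one-row tibble with macro
#'   means and counts of defined classes).
#' @export
per_class_metrics <- function(pred, curves = FALSE) {
  stopifnot(inherits(pred, "prediction_set"))
  if (nrow(pred) == 0) stop("Empty prediction set.", call. = FALSE)
  probs <- pred$probs
  C <- ncol(probs)
  labels_all <- attr(pred, "class_labels")
  per_class <- purrr::map_dfr(seq_len(C), function(c) {
    y <- as.integer(pred$true == (c - 1L))
    tibble::tibble(
      class = c - 1L,
      label = labels_all[c],
      support = sum(y),
      aps = average_precision(probs[, c], y),
      auc = roc_auc(probs[, c], y)
    )
  })
  if (curves) {
    per_class$roc <- purrr::map(seq_len(C), function(c) {
      roc_points(probs[, c], as.integer(pred$true == (c - 1L)))
    })
  }
  macro <- tibble::tibble(
    macro_aps = mean(per_class$aps, na.rm = TRUE),
    macro_auc = mean(per_class$auc, na.rm = TRUE),
    n_classes_aps = sum(!is.na(per_class$aps)),
    n_classes_auc = sum(!is.na(per_class$auc)),
    n_undefined = sum(is.na(per_class$auc))
  )
  structure(list(per_class = per_class, macro = macro),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("<class_metrics> macro APS ", round(x$macro$macro_aps, 4),
      ", macro AUC ", round(x$macro$macro_auc, 4), " over ",
      x$macro$n_classes_auc, " defined classes\n", sep = "")
  invisible(x)
}

#' @export
tidy.class_metrics <- function(x, ...) x$per_class

#' @export
glance.class_metrics <- function(x, ...) x$macro

# Macro one-vs-rest ranking metrics over pooled positions: used for the
# masked-prediction validation metrics. `truth` is 0-based.
ranking_macro_metrics <- function(probs, truth) {
  present <- sort(unique(truth))
  aps <- auc <- numeric(0)
  for (t in present) {
    y <- as.integer(truth == t)
    a <- average_precision(probs[, t + 1L], y)
    u <- roc_auc(probs[, t + 1L], y)
    if (!is.na(a)) aps <- c(aps, a)
    if (!is.na(u)) auc <- c(auc, u)
  }
  list(aps = mean(aps), auc = mean(auc))
}

# ---- embedding diagnostics -----------------------------------------------

#' Cosine-similarity summary of an embedding matrix
#'
#' @param emb Numeric matrix (tokens x dimensions).
#' @param rows Optional row subset (indices or names) to restrict to, e.g.
#'   the disease-code rows of the full embedding table.
#' @return A list of class `cosine_summary`: `similarity` (the full
#'   pairwise matrix, diagonal 1) and `summary` (tibble with min, p25,
#'   p50, p95, max over off-diagonal pairs).
#' @export
cosine_similarity_summary <- function(emb, rows = NULL) {
  if (!is.null(rows)) emb <- emb[rows, , drop = FALSE]
  nrm <- sqrt(rowSums(emb^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)[1]
    nm <- rownames(emb)[bad] %||% as.character(bad)
    stop("Zero-norm embedding row: ", nm, call. = FALSE)
  }
  X <- emb / nrm
  S <- tcrossprod(X)
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- 1
  off <- S[upper.tri(S)]
  summary <- tibble::tibble(
    min = min(off),
    p25 = unname(quantile(off, 0.25)),
    p50 = unname(quantile(off, 0.50)),
    p95 = unname(quantile(off, 0.95)),
    max = max(off)
  )
  structure(list(similarity = S, summary = summary), class = "cosine_summary")
}

#' @export
print.cosine_summary <- function(x, ...) {
  cat("<cosine_summary>\n")
  print(x$summary)
  invisible(x)
}

#' Project token embeddings to 2-D with t-SNE
#'
#' Exact (non-Barnes-Hut) t-SNE with a fixed seed, suitable for the ~120
#' rows of the token-embedding table.
#'
#' @param emb Numeric matrix (tokens x dimensions); row names become token
#'   labels.
#' @param seed RNG seed; identical seeds give identical coordinates.
#' @param perplexity t-SNE perplexity; default `min(30, (n - 1) / 3)`.
#' @param max_iter Gradient-descent iterations.
#' @param chapter_map Optional named vector mapping token labels to a
#'   grouping (e.g. ICD-9 chapter) used for coloring.
#' @return Tibble with columns `token`, `x`, `y` (and `chapter` when a map
#'   is supplied).
#' @export
project_embeddings_2d <- function(emb, seed = 1L, perplexity = NULL,
                                  max_iter = 400L, chapter_map = NULL) {
  n <- nrow(emb)
  if (n < 4) stop("t-SNE needs at least 4 rows.", call. = FALSE)
  max_perp <- floor((n - 1) / 3)
  if (is.null(perplexity)) perplexity <- min(30, max_perp)
  if (perplexity > max_perp) {
    stop("Perplexity ", perplexity, " too large for ", n,
         " rows; use perplexity <= ", max_perp, ".", call. = FALSE)
  }
  Y <- with_seed_(seed, tsne_exact(emb, perplexity = perplexity,
                                   max_iter = max_iter))
  tokens <- rownames(emb) %||% as.character(seq_len(n))
  out <- tibble::tibble(token = tokens, x = Y[, 1], y = Y[, 2])
  if (!is.null(chapter_map)) {
    out$chapter <- unname(chapter_map[out$token])
  }
  out
}

# ---- Fisher's exact test -------------------------------------------------

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Direct hypergeometric enumeration: with margins fixed, the two-sided
#' p-value is the sum of the probabilities of all tables whose probability
#' does not exceed that of the observed table (with the customary 1e-7
#' relative tolerance for ties).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fishers_exact(matrix(c(2, 0, 0, 2), 2))  # 1/3
#' @export
fishers_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    stop("`table` must be a 2x2 matrix of nonnegative integer counts.",
         call. = FALSE)
  }
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  if (r1 + r2 == 0) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  pobs <- stats::dhyper(table[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Extrinsic gender-association test of masked predictions
#'
#' Evaluates whether the model's masked-token predictions reproduce a
#' gender-skewed prevalence for a set of target codes: each evaluated
#' patient is marked according to whether any of their top-1 masked
#' predictions is a target code, the marks are cross-tabulated against
#' patient gender, and a two-sided Fisher's exact p-value is reported.
#'
#' @param model A [pretrain()] result.
#' @param corpus A [mask_corpus()] evaluation corpus.
#' @param gender Character vector (`"F"`/`"M"`) aligned with
#'   `corpus$patient_id`.
#' @param target_codes Character vector of sub-chapter codes.
#' @param vocab The vocabulary.
#' @return A list of class `gender_test`: `table` (2x2 gender x
#'   predicted-target counts), `p_value`, and `counts` (tibble form).
#' @export
extrinsic_gender_test <- function(model, corpus, gender, target_codes, vocab) {
  if (length(target_codes) == 0) {
    stop("`target_codes` must be non-empty.", call. = FALSE)
  }
  stopifnot(length(gender) == nrow(corpus$ids))
  mp <- mlm_predict(model, corpus)
  top1 <- max.col(mp$probs, ties.method = "first") - 1L
  target_ids <- encode_code(vocab, target_codes)
  hit_by_row <- tapply(top1 %in% target_ids, mp$row, any)
  rows <- as.integer(names(hit_by_row))
  g <- factor(gender[rows], levels = c("F", "M"))
  h <- factor(ifelse(unname(hit_by_row), "target", "other"),
              levels = c("target", "other"))
  tab <- table(g, h)
  p <- fishers_exact(matrix(as.integer(tab), 2, 2))
  structure(
    list(table = tab, p_value = p,
         counts = tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))),
    class = "gender_test"
  )
}

#' @export
print.gender_test <- function(x, ...) {
  print(x$table)
  cat("Fisher's exact two-sided p = ", format(x$p_value, digits = 4), "\n",
      sep = "")
  invisible(x)
}

# ---- fairness ------------------------------------------------------------

fairness_bins <- function(pred, attribute) {
  x <- pred[[attribute]]
  if (attribute == "patient_age") {
    cut(x, c(-Inf, 2, 17, Inf), labels = c("0-2", "3-17", "17+"))
  } else if (attribute == "visit_count") {
    cut(x, c(-Inf, 3, 6, Inf), labels = c("3", "4-6", "7+"))
  } else {
    v <- as.character(x)
    v[is.na(v)] <- "unknown"
    factor(v)
  }
}

#' Subgroup fairness report
#'
#' Computes per-subgroup prediction metrics to audit whether errors are
#' uniform across patient subgroups. Patient age is binned into 0-2, 3-17
#' and 17+ years; visit counts into 3, 4-6 and 7+; all other attributes
#' use their observed levels (with `NA` as `"unknown"`). An optional
#' county-to-region lookup adds a `region` attribute.
#'
#' @param pred A [prediction_set()] carrying subgroup columns.
#' @param attributes Character vector of subgroup columns to audit
#'   (default: all subgroup columns present).
#' @param min_support Subgroups with fewer patients are flagged.
#' @param region_lookup Optional data frame with columns `county`,
#'   `region`, joined on the `birth_county` subgroup key.
#' @return A tibble of class `fairness_report`: one row per (attribute,
#'   level) with `support`, per-patient `mean_aps` / `mean_auc`, per-class
#'   `macro_auc`, and `flagged`.
#' @export
fairness_report <- function(pred, attributes = NULL, min_support = 20L,
                            region_lookup = NULL) {
  stopifnot(inherits(pred, "prediction_set"))
  if (!is.null(region_lookup)) {
    stopifnot(all(c("county", "region") %in% names(region_lookup)))
    if (!"birth_county" %in% names(pred)) {
      stop("`region_lookup` supplied but no `birth_county` subgroup key ",
           "present.", call. = FALSE)
    }
    pred$region <- region_lookup$region[
      match(pred$birth_county, region_lookup$county)]
  }
  available <- setdiff(names(pred), c("patient_id", "true", "probs"))
  if (is.null(attributes)) attributes <- available
  unknown <- setdiff(attributes, available)
  if (length(unknown) > 0) {
    stop("Unknown subgroup attribute(s): ", paste(unknown, collapse = ", "),
         ". Available: ", paste(available, collapse = ", "), call. = FALSE)
  }
  out <- purrr::map_dfr(attributes, function(attribute) {
    bins <- fairness_bins(pred, attribute)
    purrr::map_dfr(levels(droplevels(bins)), function(lv) {
      sub <- pred[which(bins == lv), , drop = FALSE]
      class(sub) <- class(pred)
      attr(sub, "class_labels") <- attr(pred, "class_labels")
      pp <- per_patient_metrics(sub)
      pc <- per_class_metrics(sub)
      tibble::tibble(
        attribute = attribute, level = lv, support = nrow(sub),
        mean_aps = pp$mean_aps, mean_auc = pp$mean_auc,
        macro_auc = pc$macro$macro_auc,
        flagged = nrow(sub) < min_support
      )
    })
  })
  class(out) <- c("fairness_report", class(out))
  out
}
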