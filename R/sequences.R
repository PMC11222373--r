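# Reserved "none" ids for tracks attached to [CLS] and padding:
# visit-ordinal none = 0, county none = 0, age none = n_age_bins (last row).
AGE_BINS <- 26L      # integer-year bins 0..25, clipped
NONE_AGE <- 26L
VISIT_BINS <- 20L    # visit ordinals clipped at 20 (a 40-token history
                     # cannot hold more than 19 visits)

age_bin <- function(age_years) {
  pmin(pmax(floor(age_years), 0), AGE_BINS - 1L)
}

#' Tokenize one patient's visit history
#'
#' Builds the parallel-track representation consumed by the encoder:
#' `[CLS]`, then for each visit its 1-3 diagnosis codes followed by
#' `[SEP]`. Every code and its visit-closing `[SEP]` carry the visit's
#' ordinal, age bin (integer years 0-25) and county id; `[CLS]` and padding
#' carry reserved "none" ids. If the full history exceeds `max_len` tokens,
#' whole earliest visits are dropped until it fits (keeping the most recent
#' context), and the sequence is right-padded to `max_len`.
#'
#' @param record_visits Tibble of one patient's visits (columns `dx1`,
#'   `dx2`, `dx3`, `age_years`, `county`, ordered by `visit_ordinal`).
#' @param vocab A [build_vocabulary()] object.
#' @param max_len Maximum token-sequence length (default 40).
#' @param upto_visit Use only visits `1..upto_visit` (default: all).
#' @param county_levels Character vector defining the county id mapping;
#'   defaults to the sorted counties present in `record_visits`.
#' @param zip_levels Optional character vector defining a zip id mapping
#'   (used only by the `base+zip` embedding spec); without it the zip track
#'   is all "none".
#' @return A list of class `tokenized_history` with integer vectors
#'   `token_ids`, `visit_ordinals`, `ages`, `counties`, `zips`,
#'   `attention_mask` (all of length `max_len`, ids 0-based) and `n_real`
#'   (tokens before padding).
#' @export
build_history_tokens <- function(record_visits, vocab, max_len = 40L,
                                 upto_visit = NULL, county_levels = NULL,
                                 zip_levels = NULL) {
  stopifnot(inherits(vocab, "dx_vocab"))
  n_vis <- nrow(record_visits)
  if (n_vis < 1) stop("Record must contain at least one visit.", call. = FALSE)
  if (!is.null(upto_visit)) {
    if (upto_visit > n_vis) stop("`upto_visit` exceeds the number of visits.",
                                 call. = FALSE)
    record_visits <- record_visits[seq_len(upto_visit), , drop = FALSE]
    n_vis <- upto_visit
  }
  if (is.null(county_levels)) {
    county_levels <- sort(unique(record_visits$county))
  }
  codes <- lapply(seq_len(n_vis), function(i) {
    v <- c(record_visits$dx1[i], record_visits$dx2[i], record_visits$dx3[i])
    v[!is.na(v)]
  })
  block_len <- lengths(codes) + 1L  # codes + [SEP]
  if (1L + max(block_len) > max_len) {
    stop("A single visit's token block exceeds max_len = ", max_len,
         "; cannot truncate within a visit.", call. = FALSE)
  }
  # Drop whole earliest visits until [CLS] + blocks fit.
  first <- 1L
  while (1L + sum(block_len[first:n_vis]) > max_len) first <- first + 1L
  keep <- first:n_vis

  tok <- integer(0); vis <- integer(0); agev <- integer(0)
  cty <- integer(0); zp <- integer(0)
  has_zip <- !is.null(zip_levels) && "zip" %in% names(record_visits)
  for (i in keep) {
    ids <- c(encode_code(vocab, codes[[i]]), vocab$sep_id)
    ordv <- min(record_visits$visit_ordinal[i], VISIT_BINS)
    tok <- c(tok, ids)
    vis <- c(vis, rep(as.integer(ordv), length(ids)))
    agev <- c(agev, rep(age_bin(record_visits$age_years[i]), length(ids)))
    ctyid <- match(record_visits$county[i], county_levels)
    if (is.na(ctyid)) ctyid <- 0L
    cty <- c(cty, rep(as.integer(ctyid), length(ids)))
    zid <- if (has_zip) match(record_visits$zip[i], zip_levels) else NA
    if (is.na(zid)) zid <- 0L
    zp <- c(zp, rep(as.integer(zid), length(ids)))
  }
  tok <- c(vocab$cls_id, tok)
  vis <- c(0L, vis)
  agev <- c(NONE_AGE, agev)
  cty <- c(0L, cty)
  zp <- c(0L, zp)
  n_real <- length(tok)
  pad <- max_len - n_real
  structure(
    list(
      token_ids = c(tok, rep(vocab$pad_id, pad)),
      visit_ordinals = c(vis, rep(0L, pad)),
      ages = c(as.integer(agev), rep(NONE_AGE, pad)),
      counties = c(cty, rep(0L, pad)),
      zips = c(zp, rep(0L, pad)),
      attention_mask = c(rep(1L, n_real), rep(0L, pad)),
      n_real = n_real
    ),
    class = "tokenized_history"
  )
}

#' Recover the visit code lists from a tokenized history
#'
#' Inverse of [build_history_tokens()] for non-truncated histories: splits
#' the real tokens at `[SEP]` boundaries and decodes each visit's codes.
#'
#' @param history A `tokenized_history`.
#' @param vocab The vocabulary used to build it.
#' @return List of character vectors, one per visit.
#' @export
decode_history <- function(history, vocab) {
  ids <- history$token_ids[history$attention_mask == 1L]
  ids <- ids[ids != vocab$cls_id]
  out <- list()
  cur <- integer(0)
  for (id in ids) {
    if (id == vocab$sep_id) {
      out[[length(out) + 1L]] <- decode_id(vocab, cur)
      cur <- integer(0)
    } else {
      cur <- c(cur, id)
    }
  }
  out
}

#' Tokenize a whole visit table into aligned matrices
#'
#' Corpus-level companion to [build_history_tokens()]: one row per patient,
#' columns are token positions. The county id mapping is shared across the
#' corpus (pass `county_levels` to reuse a mapping from another corpus).
#'
#' @param visits Visit table with columns `patient_id`, `visit_ordinal`,
#'   `dx1`, `dx2`, `dx3`, `age_years`, `county`.
#' @param vocab A [build_vocabulary()] object.
#' @param max_len Maximum token-sequence length.
#' @param county_levels Optional county id mapping.
#' @return A list of class `token_corpus` with integer matrices `ids`,
#'   `vis`, `age`, `cnty`, `mask` (patients x `max_len`), the `patient_id`
#'   vector, `county_levels`, and `vocab_size`.
#' @export
tokenize_corpus <- function(visits, vocab, max_len = 40L,
                            county_levels = NULL, zip_levels = NULL) {
  if (is.null(county_levels)) county_levels <- sort(unique(visits$county))
  if (is.null(zip_levels) && "zip" %in% names(visits)) {
    zip_levels <- sort(unique(visits$zip))
  }
  visits <- dplyr::arrange(visits, .data$patient_id, .data$visit_ordinal)
  parts <- split(visits, visits$patient_id)
  n <- length(parts)
  ids <- vis <- age <- cnty <- zip <- mask <- matrix(0L, n, max_len)
  for (i in seq_len(n)) {
    h <- build_history_tokens(parts[[i]], vocab, max_len = max_len,
                              county_levels = county_levels,
                              zip_levels = zip_levels)
    ids[i, ] <- h$token_ids
    vis[i, ] <- h$visit_ordinals
    age[i, ] <- h$ages
    cnty[i, ] <- h$counties
    zip[i, ] <- h$zips
    mask[i, ] <- h$attention_mask
  }
  structure(
    list(ids = ids, vis = vis, age = age, cnty = cnty, zip = zip, mask = mask,
         patient_id = names(parts), county_levels = county_levels,
         zip_levels = zip_levels,
         vocab_size = vocab$size, max_len = as.integer(max_len)),
    class = "token_corpus"
  )
}

# ---- Masked-language-model corruption ------------------------------------

# Core of the BERT-style corruption recipe, operating on one id vector.
# Returns modified ids, labels (-1 everywhere except selected positions)
# and the selected positions.
mask_ids_once <- function(ids, maskable, vocab, rate) {
  pos <- which(maskable)
  n_sel <- max(1L, round(rate * length(pos)))
  sel <- if (length(pos) == 1L) pos else sample(pos, n_sel)
  labels <- rep(-1L, length(ids))
  labels[sel] <- ids[sel]
  u <- runif(length(sel))
  to_mask <- sel[u < 0.8]
  to_rand <- sel[u >= 0.8 & u < 0.9]
  ids[to_mask] <- vocab$mask_id
  if (length(to_rand) > 0) {
    ids[to_rand] <- vocab$n_special - 1L +
      sample.int(length(vocab$codes), length(to_rand), replace = TRUE)
  }
  list(ids = ids, labels = labels, positions = sel)
}

#' Apply masked-language-model corruption to a tokenized history
#'
#' Selects `max(1, round(rate * n))` of the `n` disease tokens uniformly at
#' random (special tokens and padding are never candidates). Each selected
#' position is independently replaced by `[MASK]` with probability 0.8, by
#' a random disease id with probability 0.1, or left unchanged with
#' probability 0.1 — the original BERT recipe. Labels hold the original id
#' at selected positions and `-1` elsewhere.
#'
#' @param history A `tokenized_history`.
#' @param vocab The vocabulary.
#' @param rate Masking rate in (0, 1]; default 0.15.
#' @return A list of class `masked_example` with `input_ids`, `label_ids`,
#'   `mask_positions`, and the original history's tracks.
#' @export
apply_mlm_mask <- function(history, vocab, rate = 0.15) {
  if (rate <= 0 || rate > 1) stop("`rate` must lie in (0, 1].", call. = FALSE)
  maskable <- history$token_ids >= vocab$n_special
  if (!any(maskable)) {
    stop("History contains no disease tokens to mask.", call. = FALSE)
  }
  m <- mask_ids_once(history$token_ids, maskable, vocab, rate)
  structure(
    c(list(input_ids = m$ids, label_ids = m$labels,
           mask_positions = m$positions), unclass(history)),
    class = "masked_example"
  )
}

#' Apply MLM corruption to a whole token corpus
#'
#' Row-wise [apply_mlm_mask()]; masking is drawn once (static masking), so
#' repeated epochs see the same corruption unless the corpus is re-masked.
#'
#' @param corpus A [tokenize_corpus()] result.
#' @param vocab The vocabulary.
#' @param rate Masking rate.
#' @param seed Optional seed for the corruption draw.
#' @return The corpus with added matrices `input_ids` (corrupted) and
#'   `labels` (-1 = ignore), of class `masked_corpus`.
#' @export
mask_corpus <- function(corpus, vocab, rate = 0.15, seed = NULL) {
  with_seed_(seed, {
    input <- corpus$ids
    labels <- matrix(-1L, nrow(input), ncol(input))
    maskable_all <- corpus$ids >= vocab$n_special
    for (i in seq_len(nrow(input))) {
      if (!any(maskable_all[i, ])) next
      m <- mask_ids_once(corpus$ids[i, ], maskable_all[i, ], vocab, rate)
      input[i, ] <- m$ids
      labels[i, ] <- m$labels
    }
    out <- corpus
    out$input_ids <- input
    out$labels <- labels
    class(out) <- c("masked_corpus", "token_corpus")
    out
  })
}

# ---- Fine-tuning input-output pairs --------------------------------------

#' Build one fine-tuning input-output pair
#'
#' Chooses a visit index `v` uniformly on `{2, ..., T-1}`, tokenizes visits
#' `1..v` as the input, and labels the pair with the next visit's principal
#' (first-listed) diagnosis and LoS class. The label visit is never part of
#' the input.
#'
#' @param record_visits One patient's visits, ordered by `visit_ordinal`
#'   (needs `T >= 3`).
#' @param vocab The vocabulary.
#' @param max_len Maximum token-sequence length.
#' @param county_levels Optional shared county mapping.
#' @param v Optionally fix the split index instead of drawing it.
#' @return A list of class `finetune_pair` with `input_history`
#'   (a `tokenized_history`), `v`, `diagnosis_label` (0-based index into
#'   `vocab$codes`), `los_label` (0-2), and one-hot vectors
#'   `diagnosis_onehot` (length `length(vocab$codes)`) and `los_onehot`
#'   (length 3).
#' @export
make_finetune_pair <- function(record_visits, vocab, max_len = 40L,
                               county_levels = NULL, zip_levels = NULL,
                               v = NULL) {
  T_ <- nrow(record_visits)
  if (T_ < 3) stop("Fine-tuning requires at least three visits (T >= 3).",
                   call. = FALSE)
  if (is.null(v)) {
    v <- if (T_ == 3L) 2L else sample(2:(T_ - 1L), 1L)
  }
  if (v < 2 || v >= T_) stop("`v` must satisfy 2 <= v < T.", call. = FALSE)
  input <- build_history_tokens(record_visits, vocab, max_len = max_len,
                                upto_visit = v, county_levels = county_levels,
                                zip_levels = zip_levels)
  nxt <- record_visits[v + 1L, ]
  dx_idx <- match(nxt$dx1, vocab$codes) - 1L
  if (is.na(dx_idx)) {
    stop("Principal code of the label visit is outside the vocabulary.",
         call. = FALSE)
  }
  los_lab <- los_class(nxt$los_days)
  dx_onehot <- integer(length(vocab$codes)); dx_onehot[dx_idx + 1L] <- 1L
  los_onehot <- integer(3L); los_onehot[los_lab + 1L] <- 1L
  structure(
    list(input_history = input, v = as.integer(v),
         diagnosis_label = as.integer(dx_idx), los_label = as.integer(los_lab),
         diagnosis_onehot = dx_onehot, los_onehot = los_onehot),
    class = "finetune_pair"
  )
}

#' Build a fine-tuning dataset from a visit table
#'
#' Draws one input-output pair per patient (patients with fewer than three
#' visits, or whose label visit carries an out-of-vocabulary principal
#' code, are dropped with a message) and assembles the aligned matrices,
#' labels, optional mother features and subgroup keys used by the trainers.
#'
#' @param visits Visit table (schema of [simulate_cohort()]).
#' @param vocab The vocabulary.
#' @param mothers Optional mother table; when supplied together with
#'   `schema`, mother feature vectors are attached.
#' @param schema Optional [mother_feature_schema()].
#' @param max_len Maximum token-sequence length.
#' @param county_levels Optional shared county mapping.
#' @param seed Seed for the visit-index draws.
#' @return A list of class `finetune_set`: a `token_corpus` (`ids`, `vis`,
#'   `age`, `cnty`, `mask`), `dx_label` and `los_label` (0-based integer
#'   vectors), `v` (chosen split index per patient), `mother_features`
#'   (matrix or NULL), and `subgroups` (tibble of fairness keys).
#' @export
build_finetune_set <- function(visits, vocab, mothers = NULL, schema = NULL,
                               max_len = 40L, county_levels = NULL,
                               seed = NULL) {
  with_seed_(seed, {
    if (is.null(county_levels)) county_levels <- sort(unique(visits$county))
    zip_levels <- if ("zip" %in% names(visits)) sort(unique(visits$zip))
    visits <- dplyr::arrange(visits, .data$patient_id, .data$visit_ordinal)
    parts <- split(visits, visits$patient_id)
    keep <- vapply(parts, nrow, 1L) >= 3L
    if (!all(keep)) {
      message(sum(!keep), " patient(s) with T < 3 dropped from the fine-tuning set.")
    }
    parts <- parts[keep]
    n <- length(parts)
    ids <- vis <- age <- cnty <- zip <- mask <- matrix(0L, n, max_len)
    dx_label <- los_label <- v_out <- integer(n)
    age_at_v <- n_vis <- numeric(n)
    ok <- rep(TRUE, n)
    for (i in seq_len(n)) {
      p <- parts[[i]]
      pair <- tryCatch(
        make_finetune_pair(p, vocab, max_len = max_len,
                           county_levels = county_levels,
                           zip_levels = zip_levels),
        error = function(e) NULL
      )
      if (is.null(pair)) { ok[i] <- FALSE; next }
      h <- pair$input_history
      ids[i, ] <- h$token_ids; vis[i, ] <- h$visit_ordinals
      age[i, ] <- h$ages; cnty[i, ] <- h$counties; zip[i, ] <- h$zips
      mask[i, ] <- h$attention_mask
      dx_label[i] <- pair$diagnosis_label
      los_label[i] <- pair$los_label
      v_out[i] <- pair$v
      age_at_v[i] <- p$age_years[pair$v]
      n_vis[i] <- nrow(p)
    }
    if (!all(ok)) {
      message(sum(!ok), " patient(s) dropped (out-of-vocabulary label visit).")
    }
    sel <- which(ok)
    pid <- names(parts)[sel]
    subgroups <- tibble::tibble(
      patient_id = pid,
      patient_age = age_at_v[sel],
      visit_count = as.integer(n_vis[sel])
    )
    mother_features <- NULL
    if (!is.null(mothers)) {
      m <- mothers[match(pid, mothers$patient_id), , drop = FALSE]
      subgroups <- dplyr::bind_cols(
        subgroups,
        dplyr::select(m, -dplyr::any_of(c("patient_id", "birth_county_id",
                                          "birth_zip")))
      )
      if (!is.null(schema)) {
        mother_features <- encode_mother_features(m, schema)
      }
    }
    structure(
      list(ids = ids[sel, , drop = FALSE], vis = vis[sel, , drop = FALSE],
           age = age[sel, , drop = FALSE], cnty = cnty[sel, , drop = FALSE],
           zip = zip[sel, , drop = FALSE], mask = mask[sel, , drop = FALSE],
           patient_id = pid, county_levels = county_levels,
           zip_levels = zip_levels,
           vocab_size = vocab$size, max_len = as.integer(max_len),
           dx_label = dx_label[sel], los_label = los_label[sel],
           v = v_out[sel], mother_features = mother_features,
           subgroups = subgroups),
      class = c("finetune_set", "token_corpus")
    )
  })
}

# ---- Mother-attribute feature encoding -----------------------------------

#' Declare the mother-attribute feature schema
#'
#' Captures the level sets of the categorical attributes (adding an
#' `"unknown"` level that also absorbs `NA`) and the min-max range of the
#' count attributes, so that [encode_mother_features()] is deterministic
#' and produces vectors of fixed length.
#'
#' @param mothers A mother table; levels and ranges are read from it.
#' @return A list of class `mother_schema` with fields `categorical`
#'   (named list of level vectors) and `numeric` (named list of
#'   `c(min, max)` ranges).
#' @export
mother_feature_schema <- function(mothers) {
  cat_cols <- intersect(
    c("baby_gender", "baby_race", "mother_race", "mother_education",
      "prenatal_care_month", "mother_birth_country", "birth_county"),
    names(mothers)
  )
  num_cols <- intersect(
    c("n_prenatal_visits", "mother_visits_before", "mother_visits_after"),
    names(mothers)
  )
  categorical <- lapply(stats::setNames(cat_cols, cat_cols), function(col) {
    lv <- sort(unique(as.character(mothers[[col]])))
    lv <- lv[!is.na(lv)]
    if (!"unknown" %in% lv) lv <- c(lv, "unknown")
    lv
  })
  numeric <- lapply(stats::setNames(num_cols, num_cols), function(col) {
    rng <- range(mothers[[col]], na.rm = TRUE)
    if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
    rng
  })
  structure(list(categorical = categorical, numeric = numeric),
            class = "mother_schema")
}

#' Encode mother attributes as a numeric feature matrix
#'
#' One-hot blocks for each categorical attribute (with `NA` and
#' out-of-schema values sent to the `"unknown"` level if the schema
#' declares one, otherwise rejected) and min-max-scaled columns for the
#' count attributes.
#'
#' @param mothers Mother table rows to encode.
#' @param schema A [mother_feature_schema()].
#' @return Numeric matrix `nrow(mothers) x feature_length(schema)` with
#'   named columns.
#' @export
encode_mother_features <- function(mothers, schema) {
  stopifnot(inherits(schema, "mother_schema"))
  n <- nrow(mothers)
  blocks <- list()
  for (col in names(schema$categorical)) {
    lv <- schema$categorical[[col]]
    x <- as.character(mothers[[col]])
    x[is.na(x)] <- "unknown"
    unknown_ok <- "unknown" %in% lv
    out_of_set <- !(x %in% lv)
    if (any(out_of_set)) {
      if (!unknown_ok) {
        stop("Value(s) of `", col, "` outside declared levels and no ",
             "'unknown' level in the schema: ",
             paste(unique(x[out_of_set]), collapse = ", "), call. = FALSE)
      }
      x[out_of_set] <- "unknown"
    }
    b <- matrix(0, n, length(lv),
                dimnames = list(NULL, paste0(col, "=", lv)))
    b[cbind(seq_len(n), match(x, lv))] <- 1
    blocks[[col]] <- b
  }
  for (col in names(schema$numeric)) {
    rng <- schema$numeric[[col]]
    x <- as.numeric(mothers[[col]])
    x[is.na(x)] <- rng[1]
    b <- matrix(pmin(pmax((x - rng[1]) / (rng[2] - rng[1]), 0), 1), n, 1,
                dimnames = list(NULL, col))
    blocks[[col]] <- b
  }
  do.call(cbind, blocks)
}

#' @rdname mother_feature_schema
#' @param schema A `mother_schema`.
#' @param path File path for the JSON serialization.
#' @export
write_mother_schema <- function(schema, path) {
  jsonlite::write_json(unclass(schema), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname mother_feature_schema
#' @export
read_mother_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(categorical = as.list(raw$categorical),
                 numeric = as.list(raw$numeric)),
            class = "mother_schema")
}
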