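vocab30 <- build_vocabulary(default_code_set(30))

tiny_cfg <- function(...) {
  encoder_config(d_model = 8L, n_layers = 2L, n_heads = 2L, ffn_hidden = 10L,
                 vocab_size = vocab30$size, max_len = 24L, dropout = 0,
                 n_counties = 4L, n_zips = 4L, ...)
}

tiny_history <- function() {
  v <- visits_from_codes(list(c("10", "11"), "12", c("13", "14", "15"), "16"))
  build_history_tokens(v, vocab30, max_len = 24)
}

test_that("embedding table for a 115-code vocabulary has 120 rows", {
  v115 <- build_vocabulary(default_code_set(115))
  cfg <- encoder_config(vocab_size = v115$size)
  P <- init_params(cfg, seed = 1)
  expect_equal(dim(P$tok), c(120L, 128L))
  expect_equal(dim(P$mlm.W), c(128L, 120L))
})

test_that("masked-prediction probabilities are a softmax over the vocabulary", {
  cfg <- tiny_cfg()
  P <- init_params(cfg, seed = 2)
  out <- encoder_forward(tiny_history(), P, cfg)
  pr <- mlm_probs(out, P)
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
  # all-zero scores -> uniform 1 / V
  expect_equal(pedvisit:::softmax_rows(matrix(0, 2, vocab30$size))[1, ],
               rep(1 / vocab30$size, vocab30$size))
  # shift invariance per position
  logits <- mlm_logits(out, P)
  expect_equal(pedvisit:::softmax_rows(logits + 5),
               pedvisit:::softmax_rows(logits), tolerance = 1e-12)
})

test_that("embedding composition uses exactly the tracks of its embedding specification", {
  h <- tiny_history()
  cfg_base <- tiny_cfg(embedding_spec = "base")
  P <- init_params(cfg_base, seed = 3)
  X1 <- embed_inputs(h, P, cfg_base)
  # base is blind to age/county perturbations
  h2 <- h
  h2$ages <- rev(h$ages)
  h2$counties[2] <- 3L
  expect_identical(embed_inputs(h2, P, cfg_base), X1)
  # base+age sees age but not county; base+age+cnty sees both
  cfg_age <- tiny_cfg(embedding_spec = "base+age")
  cfg_ac <- tiny_cfg(embedding_spec = "base+age+cnty")
  h3 <- h
  h3$counties[2] <- 3L
  expect_identical(embed_inputs(h3, P, cfg_age), embed_inputs(h, P, cfg_age))
  expect_false(identical(embed_inputs(h3, P, cfg_ac),
                         embed_inputs(h, P, cfg_ac)))
  # additivity: age spec = base + age-embedding rows
  expect_equal(embed_inputs(h, P, cfg_age),
               X1 + P$ageE[h$ages + 1L, ])
  h_bad <- h
  h_bad$counties[3] <- 99L
  expect_error(embed_inputs(h_bad, P, cfg_ac), "out of range")
})

test_that("causal attention is exactly blind to the future; bidirectional is not", {
  h <- tiny_history()
  cfg_c <- tiny_cfg(attention_mode = "causal")
  cfg_b <- tiny_cfg()
  P <- init_params(cfg_c, seed = 4)
  j <- 6L
  h2 <- h
  h2$token_ids[j] <- (h2$token_ids[j] + 3L) %% vocab30$size
  out_c1 <- encoder_forward(h, P, cfg_c)
  out_c2 <- encoder_forward(h2, P, cfg_c)
  expect_identical(out_c1[1:(j - 1), ], out_c2[1:(j - 1), ])
  out_b1 <- encoder_forward(h, P, cfg_b)
  out_b2 <- encoder_forward(h2, P, cfg_b)
  expect_gt(max(abs(out_b1[1:(j - 1), ] - out_b2[1:(j - 1), ])), 1e-8)
})

test_that("causal gradients with respect to future-only tokens are exactly zero", {
  # token "29" appears only at position j; a loss on positions < j must
  # have zero gradient on its embedding under the causal mask
  v <- visits_from_codes(list("10", "11", "29"))
  h <- build_history_tokens(v, vocab30, max_len = 24)
  j <- which(h$token_ids == encode_code(vocab30, "29"))
  fb <- pedvisit:::history_tracks(h)
  mask <- matrix(h$attention_mask, nrow = 1)
  for (mode in c("causal", "bidirectional")) {
    cfg <- tiny_cfg(attention_mode = mode)
    P <- init_params(cfg, seed = 5, with_mlm_head = FALSE)
    fwd <- pedvisit:::encoder_fwd(P, cfg, fb, mask, train = FALSE)
    dOut <- matrix(0, nrow(fwd$out), ncol(fwd$out))
    dOut[1:(j - 1), ] <- 1
    G <- pedvisit:::encoder_bwd(P, pedvisit:::zeros_like(P), cfg, fb, mask,
                                fwd, dOut)
    g_future <- G$tok[encode_code(vocab30, "29") + 1L, ]
    if (mode == "causal") {
      expect_identical(unname(g_future), rep(0, cfg$d_model))
    } else {
      expect_gt(max(abs(g_future)), 0)
    }
  }
})

test_that("outputs at real positions ignore padding content", {
  h <- tiny_history()
  cfg <- tiny_cfg()
  P <- init_params(cfg, seed = 6)
  n <- h$n_real
  h2 <- h
  h2$token_ids[(n + 1):24] <- 7L  # garbage beyond the attention mask
  out1 <- encoder_forward(h, P, cfg)
  out2 <- encoder_forward(h2, P, cfg)
  expect_identical(out1[1:n, ], out2[1:n, ])
})

test_that("pooling returns the [CLS] vector or the masked mean", {
  h <- tiny_history()
  cfg <- tiny_cfg()
  P <- init_params(cfg, seed = 7)
  fb <- pedvisit:::history_tracks(h)
  mask <- matrix(h$attention_mask, nrow = 1)
  out <- pedvisit:::encoder_fwd(P, cfg, fb, mask, FALSE)$out
  expect_equal(pedvisit:::pool_fwd(out, mask, "cls")$pooled[1, ], out[1, ])
  mn <- pedvisit:::pool_fwd(out, mask, "mean")$pooled[1, ]
  expect_equal(mn, colMeans(out[h$attention_mask == 1, ]))
  # mean over a single real token equals that token's vector
  mask1 <- matrix(c(1L, rep(0L, 23)), nrow = 1)
  expect_equal(pedvisit:::pool_fwd(out, mask1, "mean")$pooled[1, ], out[1, ])
})

test_that("backpropagation matches finite differences (MLM and head paths)", {
  coh <- simulate_cohort(ehr_sim_config(n_patients = 12, n_codes = 30,
                                        n_counties = 3, seed = 13))
  v <- filter_min_encounters(coh$visits)
  corp <- tokenize_corpus(v, vocab30, max_len = 24)
  mc <- mask_corpus(corp, vocab30, seed = 1)
  cfg <- tiny_cfg(embedding_spec = "base+age+cnty")
  cfg <- pedvisit:::fit_config_to_corpus(cfg, mc)
  withr::with_seed(2, {
    P <- c(pedvisit:::init_encoder_params(cfg), pedvisit:::init_mlm_head(cfg))
  })
  idx <- seq_len(min(3, nrow(mc$ids)))
  loss_of <- function(P) {
    pedvisit:::mlm_step(P, cfg, mc, idx, vocab30, FALSE, FALSE)$loss
  }
  G <- pedvisit:::mlm_step(P, cfg, mc, idx, vocab30, FALSE, FALSE)$G
  eps <- 1e-5
  withr::with_seed(3, {
    for (nm in c("tok", "ageE", "L1.Wq", "L1.Wo", "L2.W1", "L2.g2", "mlm.W")) {
      for (i in sample(length(P[[nm]]), 3)) {
        Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
        Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
        fd <- (loss_of(Pp) - loss_of(Pm)) / (2 * eps)
        expect_equal(G[[nm]][i], fd, tolerance = 1e-4)
      }
    }
  })

  # classification-head path, with mother fusion and mean pooling
  suppressMessages({
    fs <- build_finetune_set(v, vocab30, mothers = coh$mothers,
                             schema = mother_feature_schema(coh$mothers),
                             max_len = 24, seed = 4)
  })
  cfg2 <- tiny_cfg(pooling = "mean")
  cfg2 <- pedvisit:::fit_config_to_corpus(cfg2, fs)
  hc <- head_config(hidden_units = 6, n_classes = 3, mother_fusion = TRUE)
  nm_feat <- ncol(fs$mother_features)
  withr::with_seed(5, {
    P2 <- c(pedvisit:::init_encoder_params(cfg2),
            pedvisit:::init_cls_head(cfg2, hc, nm_feat))
  })
  idx2 <- seq_len(min(3, nrow(fs$ids)))
  y2 <- fs$los_label[idx2]
  loss2 <- function(P) {
    pedvisit:::head_step(P, cfg2, hc, fs, idx2, y2, nm_feat, 0, FALSE)$loss
  }
  G2 <- pedvisit:::head_step(P2, cfg2, hc, fs, idx2, y2, nm_feat, 0, FALSE)$G
  withr::with_seed(6, {
    for (nm in c("tok", "L2.Wv", "head.W1", "head.W2")) {
      for (i in sample(length(P2[[nm]]), 3)) {
        Pp <- P2; Pp[[nm]][i] <- Pp[[nm]][i] + eps
        Pm <- P2; Pm[[nm]][i] <- Pm[[nm]][i] - eps
        fd <- (loss2(Pp) - loss2(Pm)) / (2 * eps)
        expect_equal(G2[[nm]][i], fd, tolerance = 1e-4)
      }
    }
  })
})

test_that("pre-training is seed-reproducible and reduces loss on a learnable corpus", {
  vis <- make_pair_visits(150, seed = 31)
  corp <- tokenize_corpus(vis, vocab30, max_len = 24)
  tr <- sub_corpus(corp, 1:130)
  va <- sub_corpus(corp, 131:150)
  cfg <- small_encoder(vocab30)
  tcfg <- train_config("pretrain", epochs = 2, learning_rate = 1e-3,
                       batch_size = 32, seed = 11)
  m1 <- pretrain(tr, va, vocab30, cfg, tcfg, eval_metrics = FALSE)
  m2 <- pretrain(tr, va, vocab30, cfg, tcfg, eval_metrics = FALSE)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$tok, m2$params$tok)
  train_loss <- m1$history$loss[m1$history$split == "train"]
  expect_lt(train_loss[length(train_loss)], train_loss[1])
  expect_error(pretrain(sub_corpus(corp, integer(0)), va, vocab30, cfg, tcfg),
               "non-empty")
})

test_that("an untrained model scores at chance on a uniform-code corpus", {
  withr::with_seed(17, {
    n_vis <- sample(3:5, 120, replace = TRUE)
    pid <- rep(sprintf("p%04d", 1:120), n_vis)
    vis <- tibble::tibble(
      patient_id = pid,
      visit_ordinal = unlist(lapply(n_vis, seq_len)),
      dx1 = sample(vocab30$codes, length(pid), replace = TRUE),
      dx2 = NA_character_, dx3 = NA_character_,
      age_years = unlist(lapply(n_vis, seq_len)) - 1,
      county = "c01", zip = "01000", los_days = 0L)
  })
  corp <- tokenize_corpus(vis, vocab30, max_len = 24)
  mc <- mask_corpus(corp, vocab30, seed = 2)
  cfg <- pedvisit:::fit_config_to_corpus(small_encoder(vocab30), mc)
  fake <- structure(list(params = init_params(cfg, seed = 9), config = cfg,
                         vocab = vocab30),
                    class = "pedvisit_pretrain")
  mp <- mlm_predict(fake, mc)
  acc <- mean(max.col(mp$probs) - 1L == mp$truth)
  expect_lt(acc, 0.15)  # chance is 1/30 on this corpus
})

test_that("fine-tuning rejects label/head mismatches and reproduces under seed", {
  coh <- simulate_cohort(ehr_sim_config(n_patients = 120, n_codes = 30,
                                        n_counties = 3, seed = 23))
  v <- filter_min_encounters(coh$visits)
  roles <- split_roles(v, c(train = 0.8, val = 0.2), seed = 1)
  suppressMessages({
    tr <- build_finetune_set(role_visits(v, roles, "train"), vocab30,
                             max_len = 24, seed = 2)
    va <- build_finetune_set(role_visits(v, roles, "val"), vocab30,
                             max_len = 24, seed = 3)
  })
  cfg <- encoder_config(d_model = 16, n_layers = 1, n_heads = 2,
                        ffn_hidden = 16, vocab_size = vocab30$size,
                        max_len = 24)
  tcfg <- train_config("finetune", epochs = 2, learning_rate = 1e-3,
                       batch_size = 32, seed = 5)
  expect_error(
    finetune(tr, va, task = "los", config = cfg, tcfg = tcfg,
             hcfg = head_config(n_classes = 115L)),
    "classes")
  expect_error(
    finetune(tr, va, task = "los", config = cfg, tcfg = tcfg,
             hcfg = head_config(n_classes = 3L, mother_fusion = TRUE)),
    "mother")
  m1 <- finetune(tr, va, task = "los", config = cfg, tcfg = tcfg)
  m2 <- finetune(tr, va, task = "los", config = cfg, tcfg = tcfg)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$best_epoch, m2$best_epoch)
  p <- predict(m1, va)
  expect_equal(rowSums(p), rep(1, nrow(va$ids)), tolerance = 1e-6)
  # pooled representations have the configured width and ignore padding
  pr <- pooled_representation(m1, va)
  expect_equal(dim(pr), c(nrow(va$ids), 16L))
})

test_that("shuffled labels collapse fine-tuned skill to the no-signal baseline", {
  coh <- simulate_cohort(los_sim(250, seed = 41))
  v <- filter_min_encounters(coh$visits)
  roles <- split_roles(v, c(train = 0.7, val = 0.15, test = 0.15), seed = 1)
  mk <- function(role, s) {
    suppressMessages(build_finetune_set(role_visits(v, roles, role), vocab30,
                                        max_len = 24, seed = s))
  }
  tr <- mk("train", 2); va <- mk("val", 3); te <- mk("test", 4)
  withr::with_seed(6, {
    tr$los_label <- sample(tr$los_label)
    va$los_label <- sample(va$los_label)
  })
  cfg <- encoder_config(d_model = 16, n_layers = 0, n_heads = 2,
                        ffn_hidden = 16, vocab_size = vocab30$size,
                        max_len = 24, pooling = "mean")
  m <- finetune(tr, va, task = "los", config = cfg,
                tcfg = train_config("finetune", epochs = 3,
                                    learning_rate = 1e-3, batch_size = 32,
                                    seed = 7))
  ps <- prediction_set(predict(m, te), te$los_label, task = "los")
  aps_model <- per_patient_metrics(ps)$mean_aps
  # prevalence-only predictor on the same test truths
  prev <- tabulate(tr$los_label + 1L, 3L) / length(tr$los_label)
  probs_prev <- matrix(prev, nrow(te$ids), 3, byrow = TRUE)
  aps_prev <- per_patient_metrics(
    prediction_set(probs_prev, te$los_label, task = "los"))$mean_aps
  expect_lt(abs(aps_model - aps_prev), 0.12)
})
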