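vocab30 <- build_vocabulary(default_code_set(30))

test_that("tokenization lays out [CLS], per-visit code blocks and [SEP]s", {
  # five visits with code counts 2, 1, 2, 1, 1 -> 13 tokens before padding
  v <- visits_from_codes(list(c("10", "11"), "10", c("10", "11"), "10", "10"))
  h <- build_history_tokens(v, vocab30, max_len = 40)
  expect_equal(h$n_real, 13L)
  toks <- decode_id(vocab30, h$token_ids[1:13])
  expect_equal(toks, c("[CLS]", "10", "11", "[SEP]", "10", "[SEP]",
                       "10", "11", "[SEP]", "10", "[SEP]", "10", "[SEP]"))
  # one visit, one code -> [CLS] code [SEP]
  h1 <- build_history_tokens(visits_from_codes(list("10")), vocab30, max_len = 40)
  expect_equal(h1$n_real, 3L)

  # parallel tracks share length and padding conventions
  expect_equal(length(h$visit_ordinals), 40L)
  expect_equal(length(h$ages), 40L)
  expect_equal(length(h$attention_mask), 40L)
  expect_equal(h$token_ids[14:40], rep(0L, 27))        # pad id 0
  expect_equal(h$attention_mask[14:40], rep(0L, 27))
  expect_equal(h$visit_ordinals[1], 0L)                # [CLS] has "none" ids
  expect_equal(h$ages[1], 26L)
  expect_equal(h$counties[1], 0L)
  # [SEP] inherits its visit's attributes
  expect_equal(h$visit_ordinals[4], 1L)
  expect_equal(h$visit_ordinals[6], 2L)
})

test_that("over-long histories drop whole earliest visits until they fit", {
  # 20 single-code visits: 1 + 20 * 2 = 41 tokens > 40 -> drop visit 1 -> 39
  v <- visits_from_codes(rep(list("10"), 20))
  h <- build_history_tokens(v, vocab30, max_len = 40)
  expect_equal(h$n_real, 39L)
  # the earliest remaining visit is ordinal 2
  expect_equal(min(h$visit_ordinals[h$visit_ordinals > 0]), 2L)
  # a single visit that cannot fit is rejected rather than split
  v1 <- visits_from_codes(list(c("10", "11", "12")))
  expect_error(build_history_tokens(v1, vocab30, max_len = 4),
               "cannot truncate within a visit")
})

test_that("decoding a non-truncated history reproduces the visit code lists", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      codes <- lapply(seq_len(sample(1:6, 1)), function(i) {
        sample(vocab30$codes, sample(1:3, 1))
      })
      h <- build_history_tokens(visits_from_codes(codes), vocab30, max_len = 40)
      expect_equal(decode_history(h, vocab30), codes)
    }
  })
})

test_that("masking selects max(1, round(rate * n)) disease tokens, never specials", {
  v <- visits_from_codes(rep(list(c("10", "11")), 10))  # 20 disease tokens
  h <- build_history_tokens(v, vocab30, max_len = 40)
  withr::with_seed(1, {
    m <- apply_mlm_mask(h, vocab30, rate = 0.15)
    expect_equal(length(m$mask_positions), 3L)
    expect_true(all(h$token_ids[m$mask_positions] >= vocab30$n_special))
    expect_equal(which(m$label_ids >= 0), sort(m$mask_positions))

    h1 <- build_history_tokens(visits_from_codes(list("10")), vocab30, 40)
    m1 <- apply_mlm_mask(h1, vocab30, rate = 0.15)
    expect_equal(length(m1$mask_positions), 1L)   # max-1 floor
  })
  expect_error(apply_mlm_mask(h, vocab30, rate = 0), "rate")
  expect_error(apply_mlm_mask(h, vocab30, rate = 1.2), "rate")
})

test_that("corruption follows the 80/10/10 recipe within binomial bounds", {
  v <- visits_from_codes(rep(list(c("10", "11")), 10))
  h <- build_history_tokens(v, vocab30, max_len = 40)
  withr::with_seed(33, {
    n_mask <- 0L; n_rand <- 0L; n_keep <- 0L; total <- 0L
    for (i in 1:3400) {  # 3 selections each -> > 10,000 selections
      m <- apply_mlm_mask(h, vocab30, rate = 0.15)
      sel <- m$mask_positions
      orig <- h$token_ids[sel]
      now <- m$input_ids[sel]
      n_mask <- n_mask + sum(now == vocab30$mask_id)
      n_keep <- n_keep + sum(now == orig)
      n_rand <- n_rand + sum(now != orig & now != vocab30$mask_id)
      total <- total + length(sel)
    }
    # 99% binomial intervals at p = 0.8 / 0.1 / 0.1, n > 10,000
    expect_true(n_mask / total > 0.78 && n_mask / total < 0.82)
    expect_true(n_rand / total > 0.09 && n_rand / total < 0.11)
    expect_true(n_keep / total > 0.09 && n_keep / total < 0.11)
    # random replacements are disease ids, never specials
  })
})

test_that("fine-tuning pairs: v uniform on 2..T-1, labels from visit v+1 only", {
  v3 <- visits_from_codes(list("10", "11", c("12", "13")), los = c(0, 0, 0))
  withr::with_seed(4, {
    pair <- make_finetune_pair(v3, vocab30)
    expect_equal(pair$v, 2L)                      # T = 3 forces v = 2
    expect_equal(decode_id(vocab30, vocab30$n_special + pair$diagnosis_label),
                 "12")                            # principal = first-listed
    expect_equal(pair$los_label, 0L)
    expect_equal(sum(pair$diagnosis_onehot), 1L)
    expect_equal(sum(pair$los_onehot), 1L)
    # label visit is never part of the input
    expect_equal(max(pair$input_history$visit_ordinals), 2L)

    # explicit example: next visit ["48","52"], LoS 0
    vb <- build_vocabulary(c("48", "52", "10"))
    vv <- visits_from_codes(list("10", "10", c("48", "52")), los = c(0, 0, 0))
    p2 <- make_finetune_pair(vv, vb)
    expect_equal(p2$diagnosis_label, match("48", vb$codes) - 1L)
    expect_equal(p2$los_label, 0L)

    expect_error(make_finetune_pair(visits_from_codes(list("10", "11")), vocab30),
                 "at least three")
  })
})

test_that("v is drawn uniformly over {2, ..., T-1}", {
  v5 <- visits_from_codes(rep(list("10"), 5))
  withr::with_seed(12, {
    vs <- replicate(10000, make_finetune_pair(v5, vocab30)$v)
  })
  expect_setequal(unique(vs), 2:4)
  p2 <- mean(vs == 2)
  expect_true(p2 > 0.30 && p2 < 0.37)  # binomial band at p = 1/3
})

test_that("fine-tuning sets drop short histories and align labels with tokens", {
  coh <- simulate_cohort(ehr_sim_config(n_patients = 80, n_codes = 30, seed = 5))
  v <- coh$visits
  suppressMessages(
    fs <- build_finetune_set(v, vocab30, mothers = coh$mothers,
                             schema = mother_feature_schema(coh$mothers),
                             max_len = 24, seed = 6)
  )
  kept <- table(v$patient_id)[fs$patient_id]
  expect_true(all(kept >= 3))
  expect_true(all(rowSums(fs$ids == vocab30$cls_id) == 1))
  expect_true(all(fs$dx_label >= 0 & fs$dx_label < length(vocab30$codes)))
  expect_true(all(fs$los_label %in% 0:2))
  expect_equal(nrow(fs$mother_features), nrow(fs$ids))
  expect_equal(fs$subgroups$visit_count, as.integer(kept))
  # input history stops at v: highest ordinal in tokens equals v
  expect_equal(unname(apply(fs$vis, 1, max)), fs$v)
  # determinism under seed
  suppressMessages(
    fs2 <- build_finetune_set(v, vocab30, mothers = coh$mothers,
                              schema = mother_feature_schema(coh$mothers),
                              max_len = 24, seed = 6)
  )
  expect_identical(fs$ids, fs2$ids)
  expect_identical(fs$v, fs2$v)
})

test_that("mother features: one-hot blocks, unknown absorption, min-max counts", {
  mothers <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    baby_gender = c("F", "M", "F"),
    mother_education = c("<HS", "college", NA),
    n_prenatal_visits = c(0L, 10L, 20L)
  )
  schema <- mother_feature_schema(mothers)
  X <- encode_mother_features(mothers, schema)
  expect_equal(unname(X[1, c("baby_gender=F", "baby_gender=M")]), c(1, 0))
  # NA education lands on the added "unknown" level
  expect_equal(unname(X[3, "mother_education=unknown"]), 1)
  # counts min-max scaled to [0, 1]
  expect_equal(unname(X[, "n_prenatal_visits"]), c(0, 0.5, 1))
  # rows differing only in education differ only inside that block
  m2 <- mothers[1:2, ]
  m2$baby_gender <- "F"; m2$n_prenatal_visits <- 5L
  m2$mother_education <- c("<HS", "college")
  X2 <- encode_mother_features(m2, schema)
  diff_cols <- which(X2[1, ] != X2[2, ])
  expect_true(all(grepl("^mother_education=", colnames(X2)[diff_cols])))
  # out-of-schema value without an unknown level is rejected
  schema_strict <- schema
  schema_strict$categorical$baby_gender <- c("F", "M")
  m3 <- mothers[1, ]; m3$baby_gender <- "X"
  expect_error(encode_mother_features(m3, schema_strict), "unknown")
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_mother_schema(schema, path)
  schema_rt <- read_mother_schema(path)
  expect_equal(schema_rt$categorical, schema$categorical)
  expect_equal(unname(vapply(schema_rt$numeric, length, 1L)),
               rep(2L, length(schema$numeric)))
  expect_identical(encode_mother_features(mothers, schema_rt), X)
})
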