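test_that("average precision matches hand-derived values", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 5 / 6)
  expect_equal(average_precision(c(0.9, 0.8), c(1, 1)), 1)            # perfect
  # single positive at rank r among C scores -> 1 / r
  for (C in c(3, 7, 20)) {
    for (r in c(1, 2, C)) {
      scores <- rev(seq_len(C)) / C
      labels <- integer(C); labels[r] <- 1
      expect_equal(average_precision(scores, labels), 1 / r)
    }
  }
  expect_true(is.na(average_precision(c(0.2, 0.1), c(0, 0))))         # undefined
})

test_that("ROC AUC matches pair-counting values and tie conventions", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)           # pure ties
  expect_true(is.na(roc_auc(c(0.3, 0.2), c(1, 1))))
})

test_that("AP and AUC agree with exhaustive brute-force oracles to 1e-9", {
  # all label patterns for n <= 8, scores with deliberate ties
  withr::with_seed(5, {
    for (n in 2:8) {
      scores <- sample(round(runif(n), 1))  # one-decimal grid forces ties
      for (bits in 0:(2^n - 1)) {
        labels <- as.integer(intToBits(bits))[1:n]
        if (sum(labels) == 0 || sum(labels) == n) next
        expect_equal(average_precision(scores, labels),
                     oracle_average_precision(scores, labels),
                     tolerance = 1e-9)
        expect_equal(roc_auc(scores, labels),
                     oracle_roc_auc(scores, labels), tolerance = 1e-9)
      }
    }
    # 200 random instances up to n = 50
    for (i in 1:200) {
      n <- sample(3:50, 1)
      scores <- round(runif(n), sample(1:3, 1))
      labels <- rbinom(n, 1, 0.4)
      if (sum(labels) == 0 || sum(labels) == n) next
      expect_equal(average_precision(scores, labels),
                   oracle_average_precision(scores, labels), tolerance = 1e-9)
      expect_equal(roc_auc(scores, labels),
                   oracle_roc_auc(scores, labels), tolerance = 1e-9)
    }
  })
})

test_that("roc_points integrates to the Mann-Whitney AUC", {
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      scores <- round(runif(n), 1)
      labels <- rbinom(n, 1, 0.5)
      if (sum(labels) %in% c(0, n)) next
      curve <- roc_points(scores, labels)
      trap <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                       utils::tail(curve$tpr, -1)) / 2)
      expect_equal(trap, roc_auc(scores, labels), tolerance = 1e-9)
    }
  })
})

test_that("prediction sets validate probabilities and labels", {
  probs <- matrix(c(0.7, 0.2, 0.1, 0.1, 0.3, 0.6), 2, byrow = TRUE)
  ps <- prediction_set(probs, c(0L, 2L), task = "los")
  expect_s3_class(ps, "prediction_set")
  expect_error(prediction_set(probs * 2, c(0L, 2L), task = "los"), "sum to 1")
  expect_error(prediction_set(probs, c(0L, 3L), task = "los"), "out of range")
})

test_that("per-patient metrics follow the one-positive rank closed forms", {
  # C = 4, true class ranked 3rd -> AUC 1/3, AP 1/3
  probs <- matrix(c(0.4, 0.3, 0.2, 0.1), 1)
  ps <- prediction_set(probs, 2L, task = "diagnosis",
                       class_labels = letters[1:4])
  m <- per_patient_metrics(ps)
  expect_equal(m$mean_auc, 1 / 3)
  expect_equal(m$mean_aps, 1 / 3)
  # always top-ranked -> (1, 1); mixing with AUC 0.5 averages to 0.75
  probs2 <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))
  ps2 <- prediction_set(probs2, c(0L, 0L), task = "diagnosis")
  m2 <- per_patient_metrics(ps2)
  expect_equal(m2$mean_auc, 0.75)
  ps3 <- prediction_set(probs2[1, , drop = FALSE], 0L, task = "diagnosis")
  expect_equal(per_patient_metrics(ps3)$mean_aps, 1)
})

test_that("per-patient AUC equals generic roc_auc on the one-positive instance", {
  withr::with_seed(14, {
    for (C in c(2, 5, 23, 115)) {
      p <- runif(C); p <- p / sum(p)
      for (true in c(0L, as.integer(C %/% 2), C - 1L)) {
        ps <- prediction_set(matrix(p, 1), true, task = "diagnosis")
        labels <- as.integer(seq_len(C) - 1L == true)
        expect_equal(per_patient_metrics(ps)$mean_auc,
                     roc_auc(p, labels), tolerance = 1e-12)
      }
    }
  })
})

test_that("per-class metrics pool patients one-vs-rest and macro-average defined classes", {
  # balanced 3-class toy with perfect predictions -> all AUCs 1
  probs <- diag(3)[c(1, 2, 3, 1, 2, 3), ] * 0.94 + 0.02
  ps <- prediction_set(probs, rep(0:2, 2), task = "los",
                       class_labels = c("a", "b", "c"))
  pc <- per_class_metrics(ps)
  expect_equal(pc$per_class$auc, rep(1, 3))
  expect_equal(pc$macro$macro_auc, 1)
  # a class absent from truth is undefined and excluded
  ps2 <- prediction_set(probs, rep(c(0L, 1L), 3), task = "los")
  pc2 <- per_class_metrics(ps2)
  expect_true(is.na(pc2$per_class$auc[3]))
  expect_equal(pc2$macro$n_classes_auc, 2L)
  expect_equal(pc2$per_class$support, c(3L, 3L, 0L))
})

test_that("per-class macro mean equals a hand-computed fixture", {
  withr::with_seed(3, {
    probs <- matrix(runif(10 * 3), 10)
    probs <- probs / rowSums(probs)
    truth <- sample(0:2, 10, replace = TRUE)
    ps <- prediction_set(probs, truth, task = "los")
    pc <- per_class_metrics(ps)
    by_hand_auc <- vapply(1:3, function(c) {
      oracle_roc_auc(probs[, c], as.integer(truth == c - 1))
    }, 0)
    expect_equal(pc$per_class$auc, by_hand_auc)
    expect_equal(pc$macro$macro_auc, mean(by_hand_auc, na.rm = TRUE))
    expect_equal(sum(pc$per_class$support), 10L)
  })
})

test_that("ranking metrics agree with pROC on pooled one-vs-rest instances", {
  withr::with_seed(21, {
    scores <- runif(60)
    labels <- rbinom(60, 1, 0.3)
    expect_equal(
      roc_auc(scores, labels),
      as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                     direction = "<"))))
  })
})

test_that("cosine summary: unit diagonal, symmetry, canonical angles, zero-norm rejection", {
  emb <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 3), d = c(-1, 0))
  cs <- cosine_similarity_summary(emb)
  S <- cs$similarity
  expect_equal(S["a", "b"], 1)       # identical direction
  expect_equal(S["a", "c"], 0)       # orthogonal
  expect_equal(S["a", "d"], -1)      # antiparallel
  expect_equal(S, t(S))
  expect_equal(diag(S), setNames(rep(1, 4), rownames(emb)))
  expect_equal(cs$summary$min, -1)
  expect_equal(cs$summary$max, 1)
  bad <- rbind(x = c(1, 1), y = c(0, 0))
  expect_error(cosine_similarity_summary(bad), "y")
})

test_that("t-SNE projection: shape, seeded determinism, cluster preservation", {
  withr::with_seed(2, {
    centers <- rbind(c(8, 0, 0), c(0, 8, 0), c(0, 0, 8))
    X <- centers[rep(1:3, each = 10), ] + matrix(rnorm(90, sd = 0.3), 30)
    rownames(X) <- sprintf("t%02d", 1:30)
  })
  p1 <- project_embeddings_2d(X, seed = 7, perplexity = 5)
  p2 <- project_embeddings_2d(X, seed = 7, perplexity = 5)
  expect_equal(dim(p1), c(30L, 3L))
  expect_identical(p1, p2)
  cl <- rep(1:3, each = 10)
  D <- as.matrix(dist(cbind(p1$x, p1$y)))
  same <- outer(cl, cl, "==") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[!same & upper.tri(D)]))
  expect_error(project_embeddings_2d(X, perplexity = 20), "perplexity <= 9")
  expect_error(project_embeddings_2d(X[1:3, ]), "at least 4")
})

test_that("Fisher's exact test equals enumeration and the stats oracle", {
  expect_equal(fishers_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fishers_exact(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1)
  expect_error(fishers_exact(matrix(c(-1, 0, 0, 2), 2)), "nonnegative")
  withr::with_seed(6, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 4), 2)
      expect_equal(fishers_exact(tab),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-10)
    }
  })
})

test_that("identical predictions give identical subgroup metrics; supports conserve", {
  withr::with_seed(10, {
    probs <- matrix(runif(40 * 3), 40)
    probs <- probs / rowSums(probs)
    truth <- sample(0:2, 40, replace = TRUE)
    grp <- tibble::tibble(site = rep(c("east", "west"), 20))
    # both subgroups receive exactly the same predictions and truths
    probs2 <- probs[rep(1:20, 2), ]
    truth2 <- truth[rep(1:20, 2)]
    grp2 <- tibble::tibble(site = rep(c("east", "west"), each = 20))
    ps <- prediction_set(probs2, truth2, task = "los", subgroups = grp2)
    fr <- fairness_report(ps, attributes = "site", min_support = 5)
    expect_equal(fr$mean_auc[1], fr$mean_auc[2])
    expect_equal(fr$macro_auc[1], fr$macro_auc[2])
    expect_equal(sum(fr$support), 40L)

    ps_all <- prediction_set(probs, truth, task = "los", subgroups = grp)
    expect_error(fairness_report(ps_all, attributes = "nope"), "Available")
  })
})

test_that("age and visit-count fairness bins follow the audit scheme", {
  withr::with_seed(11, {
    probs <- matrix(runif(30 * 3), 30); probs <- probs / rowSums(probs)
    grp <- tibble::tibble(patient_age = c(rep(1, 10), rep(10, 10), rep(20, 10)),
                          visit_count = c(rep(3, 10), rep(5, 10), rep(9, 10)))
    ps <- prediction_set(probs, sample(0:2, 30, TRUE), task = "los",
                         subgroups = grp)
    fr <- fairness_report(ps, attributes = c("patient_age", "visit_count"),
                          min_support = 5)
    expect_setequal(fr$level[fr$attribute == "patient_age"],
                    c("0-2", "3-17", "17+"))
    expect_setequal(fr$level[fr$attribute == "visit_count"], c("3", "4-6", "7+"))
    expect_true(all(fr$support == 10L))
    # region lookup attaches a derived attribute
    grp$birth_county <- rep(c("c01", "c02", "c03"), each = 10)
    ps2 <- prediction_set(probs, sample(0:2, 30, TRUE), task = "los",
                          subgroups = grp)
    lk <- tibble::tibble(county = c("c01", "c02", "c03"),
                         region = c("north", "north", "south"))
    fr2 <- fairness_report(ps2, attributes = "region", region_lookup = lk,
                           min_support = 5)
    expect_setequal(fr2$level, c("north", "south"))
    expect_equal(fr2$support[fr2$level == "north"], 20L)
  })
})
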