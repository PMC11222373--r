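# Shared fixtures and independent oracles, all built in code.

# ---- tiny visit-table builders -------------------------------------------

# Minimal hand-written visit table: one patient, explicit codes per visit.
visits_from_codes <- function(code_lists, patient_id = "p1", los = NULL) {
  T_ <- length(code_lists)
  if (is.null(los)) los <- rep(0L, T_)
  tibble::tibble(
    patient_id = patient_id,
    visit_ordinal = seq_len(T_),
    dx1 = vapply(code_lists, `[`, "", 1),
    dx2 = vapply(code_lists, function(x) if (length(x) >= 2) x[2] else NA_character_, ""),
    dx3 = vapply(code_lists, function(x) if (length(x) >= 3) x[3] else NA_character_, ""),
    age_years = seq_len(T_) - 1,
    county = "c01",
    zip = "01000",
    los_days = as.integer(los)
  )
}

# Corpus in which code "20" deterministically co-occurs with code "10":
# every visit is either the pair ("10","20") or two random other codes.
make_pair_visits <- function(n_patients, seed, pair_prob = 0.5) {
  withr::with_seed(seed, {
    other <- setdiff(default_code_set(30), c("10", "20"))
    n_vis <- sample(3:5, n_patients, replace = TRUE)
    pid <- rep(sprintf("p%05d", seq_len(n_patients)), n_vis)
    ord <- unlist(lapply(n_vis, seq_len))
    nv <- length(pid)
    is_pair <- runif(nv) < pair_prob
    dx1 <- ifelse(is_pair, "10", sample(other, nv, replace = TRUE))
    dx2 <- ifelse(is_pair, "20", sample(other, nv, replace = TRUE))
    dx2[!is_pair & dx2 == dx1] <- NA
    tibble::tibble(patient_id = pid, visit_ordinal = ord, dx1 = dx1, dx2 = dx2,
                   dx3 = NA_character_, age_years = ord - 1, county = "c01",
                   zip = "01000", los_days = 0L)
  })
}

# Row subset of a token corpus.
sub_corpus <- function(corp, idx) {
  out <- corp
  for (f in c("ids", "vis", "age", "cnty", "zip", "mask", "input_ids", "labels"))
    if (!is.null(out[[f]])) out[[f]] <- corp[[f]][idx, , drop = FALSE]
  out$patient_id <- corp$patient_id[idx]
  out
}

# Desk-scale encoder: 2 layers, 2 heads, 32-dim, 24-token histories.
small_encoder <- function(vocab, ...) {
  encoder_config(d_model = 32L, n_layers = 2L, n_heads = 2L, ffn_hidden = 32L,
                 vocab_size = vocab$size, max_len = 24L, ...)
}

# Cluster-structured generator: 3 latent clusters, mostly 3-code visits,
# sticky cluster chain; used for the embedding-geometry and gender
# diagnostics.
cluster_sim <- function(n_patients, seed, gender_skew = c("01" = 3, "74" = 3),
                        n_clusters = 3L) {
  stay <- 0.9
  P <- matrix((1 - stay) / (n_clusters - 1), n_clusters, n_clusters)
  diag(P) <- stay
  ehr_sim_config(
    n_patients = n_patients, n_codes = 30L, n_clusters = n_clusters,
    cluster_transition = P, within_visit_extra_code_prob = 0.9,
    gender_skew = gender_skew, n_counties = 4L, seed = seed
  )
}

# Generator in which the latent cluster (sticky chain) sharply determines
# the LoS class: cluster 1 -> same-day, cluster 2 -> 1-3 days,
# cluster 3 -> > 3 days.
los_sim <- function(n_patients, seed) {
  ehr_sim_config(
    n_patients = n_patients, n_codes = 30L, n_clusters = 3L,
    cluster_transition = matrix(c(.85, .075, .075,
                                  .075, .85, .075,
                                  .075, .075, .85), 3, byrow = TRUE),
    los_params = tibble::tibble(p_zero = c(0.95, 0.05, 0.05),
                                lambda = c(0.5, 0.8, 8)),
    n_counties = 4L, seed = seed
  )
}

# Long-history generator for the masking-contract checks: 8-12 visits with
# mostly multi-code visits, so tokenized histories sit near the 40-token
# cap and the per-sequence max(1, round(rate * n)) selection rule is not
# dominated by integer rounding on short sequences.
long_history_sim <- function(n_patients, seed) {
  ehr_sim_config(
    n_patients = n_patients,
    visits_dist = c(rep(0, 7), 0.2, 0.2, 0.2, 0.2, 0.2),
    within_visit_extra_code_prob = 0.8,
    seed = seed
  )
}

split_roles <- function(visits, fractions, seed) {
  assign_splits(unique(visits$patient_id), fractions, seed = seed)
}

role_visits <- function(visits, roles, role) {
  visits[visits$patient_id %in% roles$patient_id[roles$role == role], ,
         drop = FALSE]
}

# ---- independent metric oracles ------------------------------------------

# Average precision straight from its definition: loop over descending
# unique thresholds, accumulate (delta recall) x precision.
oracle_average_precision <- function(scores, labels) {
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thr) {
    pred_pos <- scores >= t
    tp <- sum(labels == 1 & pred_pos)
    precision <- tp / sum(pred_pos)
    recall <- tp / npos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# AUC as the explicit pair statistic P(s_pos > s_neg) + 0.5 P(tie).
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Fisher's two-sided p by direct enumeration with table probabilities from
# factorials (no dhyper).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  tab_prob <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, tab_prob, 0)
  sum(ps[ps <= tab_prob(a) * (1 + 1e-7)])
}
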