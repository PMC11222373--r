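# From-scratch transformer engine: embeddings, multi-head self-attention
# (bidirectional or causal), post-layer-norm residual blocks, MLM and
# classification heads, manual backpropagation, and AdamW.
#
# Layout convention: a batch of B sequences of length L is flattened to an
# N x d matrix with N = B * L and row n = (b - 1) * L + i, so per-example
# blocks are contiguous. Ids are 0-based everywhere; embedding tables are
# indexed with id + 1.

NEG_INF <- -1e30

#' Transformer encoder configuration
#'
#' Defaults follow the reference architecture for diagnosis-history
#' modeling: a 120-row, 128-dimensional input embedding matrix, histories
#' of at most 40 tokens, 6 encoder layers with 12 attention heads and a
#' 128-unit feed-forward sublayer, and dropout 0.1. Because 128 is not
#' divisible by 12, each head has width `floor(d_model / n_heads)` and the
#' concatenated head outputs are linearly projected back to `d_model`.
#'
#' @param d_model Embedding / hidden width.
#' @param n_layers Number of encoder layers (0 = embeddings + pooling only,
#'   the random-embedding comparator).
#' @param n_heads Attention heads per layer.
#' @param ffn_hidden Feed-forward sublayer width.
#' @param dropout Dropout rate in the two sublayers.
#' @param vocab_size Token vocabulary size (codes + 5 special tokens).
#' @param max_len Maximum token-sequence length.
#' @param embedding_spec One of `"base"`, `"base+age"`, `"base+cnty"`,
#'   `"base+age+cnty"`, `"base+zip"`; `base` is the sum of diagnosis and
#'   visit-position embeddings.
#' @param attention_mode `"bidirectional"` (encoder) or `"causal"`
#'   (left-context decoder comparator).
#' @param pooling `"cls"` (final-layer vector at the `[CLS]` position) or
#'   `"mean"` (mean over real tokens). Models with `n_layers = 0` should
#'   use `"mean"`, since without an encoder the `[CLS]` slot is a constant.
#' @param n_counties,n_zips Sizes of the county / zip id spaces (excluding
#'   the reserved "none" id 0).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(d_model = 128L, n_layers = 6L, n_heads = 12L,
                           ffn_hidden = 128L, dropout = 0.1,
                           vocab_size = 120L, max_len = 40L,
                           embedding_spec = "base",
                           attention_mode = c("bidirectional", "causal"),
                           pooling = c("cls", "mean"),
                           n_counties = 64L, n_zips = 64L) {
  attention_mode <- match.arg(attention_mode)
  pooling <- match.arg(pooling)
  embedding_spec <- match.arg(
    embedding_spec, c("base", "base+age", "base+cnty", "base+age+cnty", "base+zip"))
  stopifnot(d_model >= 1, n_layers >= 0, n_heads >= 1, ffn_hidden >= 1,
            vocab_size >= 6, max_len >= 3, dropout >= 0, dropout < 1)
  d_head <- max(1L, d_model %/% n_heads)
  structure(
    list(d_model = as.integer(d_model), n_layers = as.integer(n_layers),
         n_heads = as.integer(n_heads), d_head = as.integer(d_head),
         ffn_hidden = as.integer(ffn_hidden), dropout = dropout,
         vocab_size = as.integer(vocab_size), max_len = as.integer(max_len),
         embedding_spec = embedding_spec, attention_mode = attention_mode,
         pooling = pooling,
         use_age = embedding_spec %in% c("base+age", "base+age+cnty"),
         use_cnty = embedding_spec %in% c("base+cnty", "base+age+cnty"),
         use_zip = embedding_spec == "base+zip",
         n_counties = as.integer(n_counties), n_zips = as.integer(n_zips)),
    class = "encoder_config"
  )
}

#' Training configuration
#'
#' Pre-training defaults: 15 epochs, Adam with learning rate 3e-5 and
#' decoupled weight decay 0.01. Fine-tuning defaults: 100 epochs, Adam
#' 3e-4, head dropout 0.3, early stopping on validation loss (patience 5).
#'
#' @param phase `"pretrain"` or `"finetune"`.
#' @param epochs,learning_rate,weight_decay,batch_size Optimizer settings.
#' @param head_dropout Dropout on the fine-tuning head's hidden layer.
#' @param patience,min_delta Early-stopping settings (fine-tuning).
#' @param n_runs Number of independent runs to average in experiment
#'   drivers.
#' @param seed RNG seed for initialization, shuffling, masking and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(phase = c("pretrain", "finetune"),
                         epochs = NULL, learning_rate = NULL,
                         weight_decay = NULL, batch_size = 64L,
                         head_dropout = 0.3, patience = 5L, min_delta = 0,
                         n_runs = 5L, seed = 1L) {
  phase <- match.arg(phase)
  if (is.null(epochs)) epochs <- if (phase == "pretrain") 15L else 100L
  if (is.null(learning_rate)) learning_rate <- if (phase == "pretrain") 3e-5 else 3e-4
  if (is.null(weight_decay)) weight_decay <- if (phase == "pretrain") 0.01 else 0
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(
    list(phase = phase, epochs = as.integer(epochs),
         learning_rate = learning_rate, weight_decay = weight_decay,
         batch_size = as.integer(batch_size), head_dropout = head_dropout,
         patience = as.integer(patience), min_delta = min_delta,
         n_runs = as.integer(n_runs), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Classification-head configuration
#'
#' @param hidden_units Width of the single hidden layer (default 64).
#' @param n_classes 115 (diagnosis) or 3 (LoS).
#' @param mother_fusion Concatenate mother features to the pooled
#'   representation before the hidden layer.
#' @return A list of class `head_config`.
#' @export
head_config <- function(hidden_units = 64L, n_classes = 115L,
                        mother_fusion = FALSE) {
  stopifnot(hidden_units >= 1, n_classes >= 2)
  structure(list(hidden_units = as.integer(hidden_units),
                 n_classes = as.integer(n_classes),
                 mother_fusion = isTRUE(mother_fusion)),
            class = "head_config")
}

# ---- parameters ----------------------------------------------------------

rmat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)

init_encoder_params <- function(cfg) {
  d <- cfg$d_model; H <- cfg$d_head * cfg$n_heads
  P <- list(
    tok = rmat(cfg$vocab_size, d),
    vis = rmat(VISIT_BINS + 1L, d),
    ageE = rmat(AGE_BINS + 1L, d),
    cntyE = rmat(cfg$n_counties + 1L, d),
    zipE = rmat(cfg$n_zips + 1L, d)
  )
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("L", l, ".")
    P[[paste0(pre, "Wq")]] <- rmat(d, H); P[[paste0(pre, "bq")]] <- numeric(H)
    P[[paste0(pre, "Wk")]] <- rmat(d, H); P[[paste0(pre, "bk")]] <- numeric(H)
    P[[paste0(pre, "Wv")]] <- rmat(d, H); P[[paste0(pre, "bv")]] <- numeric(H)
    P[[paste0(pre, "Wo")]] <- rmat(H, d); P[[paste0(pre, "bo")]] <- numeric(d)
    P[[paste0(pre, "g1")]] <- rep(1, d);  P[[paste0(pre, "c1")]] <- numeric(d)
    P[[paste0(pre, "W1")]] <- rmat(d, cfg$ffn_hidden)
    P[[paste0(pre, "b1")]] <- numeric(cfg$ffn_hidden)
    P[[paste0(pre, "W2")]] <- rmat(cfg$ffn_hidden, d)
    P[[paste0(pre, "b2")]] <- numeric(d)
    P[[paste0(pre, "g2")]] <- rep(1, d);  P[[paste0(pre, "c2")]] <- numeric(d)
  }
  P
}

init_mlm_head <- function(cfg) {
  list(mlm.W = rmat(cfg$d_model, cfg$vocab_size),
       mlm.b = numeric(cfg$vocab_size))
}

init_cls_head <- function(cfg, hcfg, n_mother = 0L) {
  d_in <- cfg$d_model + n_mother
  list(head.W1 = rmat(d_in, hcfg$hidden_units),
       head.b1 = numeric(hcfg$hidden_units),
       head.W2 = rmat(hcfg$hidden_units, hcfg$n_classes),
       head.b2 = numeric(hcfg$n_classes))
}

zeros_like <- function(P) lapply(P, function(p) array(0, dim = dim(p) %||% length(p)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- primitive layers ----------------------------------------------------

addb <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

bcast <- function(g, N) matrix(g, N, length(g), byrow = TRUE)

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  istd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * istd
  list(y = xhat * bcast(g, nrow(x)) + bcast(b, nrow(x)), xhat = xhat, istd = istd)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * bcast(g, nrow(dy))
  dx <- cache$istd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

drop_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, m = NULL))
  m <- matrix(rbinom(length(x), 1L, 1 - p), nrow(x), ncol(x)) / (1 - p)
  list(y = x * m, m = m)
}

drop_bwd <- function(dy, m) if (is.null(m)) dy else dy * m

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- embeddings ----------------------------------------------------------

# batch: list of integer matrices ids, vis, age, cnty, zip (B x L), mask.
flatten_batch <- function(batch) {
  lapply(batch, function(m) if (is.matrix(m)) as.vector(t(m)) else m)
}

embed_fwd <- function(P, cfg, fb) {
  X <- P$tok[fb$ids + 1L, , drop = FALSE] + P$vis[fb$vis + 1L, , drop = FALSE]
  if (cfg$use_age) X <- X + P$ageE[fb$age + 1L, , drop = FALSE]
  if (cfg$use_cnty) X <- X + P$cntyE[fb$cnty + 1L, , drop = FALSE]
  if (cfg$use_zip) X <- X + P$zipE[fb$zip + 1L, , drop = FALSE]
  X
}

scatter_rows <- function(dX, idx, nrow_out, ncol_out) {
  rs <- rowsum(dX, idx)
  out <- matrix(0, nrow_out, ncol_out)
  grp <- as.integer(rownames(rs))
  out[grp + 1L, ] <- rs
  out
}

embed_bwd <- function(G, cfg, fb, dX) {
  d <- ncol(dX)
  G$tok <- G$tok + scatter_rows(dX, fb$ids, nrow(G$tok), d)
  G$vis <- G$vis + scatter_rows(dX, fb$vis, nrow(G$vis), d)
  if (cfg$use_age) G$ageE <- G$ageE + scatter_rows(dX, fb$age, nrow(G$ageE), d)
  if (cfg$use_cnty) G$cntyE <- G$cntyE + scatter_rows(dX, fb$cnty, nrow(G$cntyE), d)
  if (cfg$use_zip) G$zipE <- G$zipE + scatter_rows(dX, fb$zip, nrow(G$zipE), d)
  G
}

# ---- encoder forward / backward ------------------------------------------

# mask: B x L 0/1 matrix. Returns final representations (N x d) plus caches
# for the backward pass.
encoder_fwd <- function(P, cfg, fb, mask, train = FALSE) {
  B <- nrow(mask); L <- ncol(mask)
  N <- B * L
  X <- embed_fwd(P, cfg, fb)
  caches <- vector("list", cfg$n_layers)
  causal <- cfg$attention_mode == "causal"
  scale <- 1 / sqrt(cfg$d_head)
  nh <- cfg$n_heads; dh <- cfg$d_head
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("L", l, ".")
    Q <- addb(X %*% P[[paste0(pre, "Wq")]], P[[paste0(pre, "bq")]])
    K <- addb(X %*% P[[paste0(pre, "Wk")]], P[[paste0(pre, "bk")]])
    V <- addb(X %*% P[[paste0(pre, "Wv")]], P[[paste0(pre, "bv")]])
    O <- matrix(0, N, nh * dh)
    A_cache <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      kb <- ifelse(mask[b, ] == 1L, 0, NEG_INF)
      Ab <- vector("list", nh)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) * scale
        S <- S + matrix(kb, L, L, byrow = TRUE)
        if (causal) S[upper.tri(S)] <- NEG_INF
        A <- softmax_rows(S)
        O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
        Ab[[h]] <- A
      }
      A_cache[[b]] <- Ab
    }
    AOp <- addb(O %*% P[[paste0(pre, "Wo")]], P[[paste0(pre, "bo")]])
    dr1 <- drop_fwd(AOp, cfg$dropout, train)
    ln1 <- ln_fwd(X + dr1$y, P[[paste0(pre, "g1")]], P[[paste0(pre, "c1")]])
    X1 <- ln1$y
    pre_act <- addb(X1 %*% P[[paste0(pre, "W1")]], P[[paste0(pre, "b1")]])
    Hff <- pmax(pre_act, 0)
    F2 <- addb(Hff %*% P[[paste0(pre, "W2")]], P[[paste0(pre, "b2")]])
    dr2 <- drop_fwd(F2, cfg$dropout, train)
    ln2 <- ln_fwd(X1 + dr2$y, P[[paste0(pre, "g2")]], P[[paste0(pre, "c2")]])
    caches[[l]] <- list(Xin = X, Q = Q, K = K, V = V, A = A_cache, O = O,
                        m1 = dr1$m, ln1 = ln1, X1 = X1, act = pre_act > 0,
                        Hff = Hff, m2 = dr2$m, ln2 = ln2)
    X <- ln2$y
  }
  list(out = X, caches = caches, B = B, L = L)
}

encoder_bwd <- function(P, G, cfg, fb, mask, fwd, dOut) {
  B <- fwd$B; L <- fwd$L
  nh <- cfg$n_heads; dh <- cfg$d_head
  scale <- 1 / sqrt(cfg$d_head)
  dX <- dOut
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("L", l, ".")
    cc <- fwd$caches[[l]]
    b2 <- ln_bwd(dX, cc$ln2, P[[paste0(pre, "g2")]])
    G[[paste0(pre, "g2")]] <- G[[paste0(pre, "g2")]] + b2$dg
    G[[paste0(pre, "c2")]] <- G[[paste0(pre, "c2")]] + b2$db
    dX1 <- b2$dx
    dF2 <- drop_bwd(b2$dx, cc$m2)
    G[[paste0(pre, "W2")]] <- G[[paste0(pre, "W2")]] + crossprod(cc$Hff, dF2)
    G[[paste0(pre, "b2")]] <- G[[paste0(pre, "b2")]] + colSums(dF2)
    dHff <- dF2 %*% t(P[[paste0(pre, "W2")]])
    dpre <- dHff * cc$act
    G[[paste0(pre, "W1")]] <- G[[paste0(pre, "W1")]] + crossprod(cc$X1, dpre)
    G[[paste0(pre, "b1")]] <- G[[paste0(pre, "b1")]] + colSums(dpre)
    dX1 <- dX1 + dpre %*% t(P[[paste0(pre, "W1")]])
    b1 <- ln_bwd(dX1, cc$ln1, P[[paste0(pre, "g1")]])
    G[[paste0(pre, "g1")]] <- G[[paste0(pre, "g1")]] + b1$dg
    G[[paste0(pre, "c1")]] <- G[[paste0(pre, "c1")]] + b1$db
    dXin <- b1$dx
    dAOp <- drop_bwd(b1$dx, cc$m1)
    G[[paste0(pre, "Wo")]] <- G[[paste0(pre, "Wo")]] + crossprod(cc$O, dAOp)
    G[[paste0(pre, "bo")]] <- G[[paste0(pre, "bo")]] + colSums(dAOp)
    dO <- dAOp %*% t(P[[paste0(pre, "Wo")]])
    dQ <- matrix(0, nrow(dO), nh * dh)
    dK <- matrix(0, nrow(dO), nh * dh)
    dV <- matrix(0, nrow(dO), nh * dh)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- cc$A[[b]][[h]]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- cc$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dV[rows, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] * scale
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE]) * scale
      }
    }
    G[[paste0(pre, "Wq")]] <- G[[paste0(pre, "Wq")]] + crossprod(cc$Xin, dQ)
    G[[paste0(pre, "bq")]] <- G[[paste0(pre, "bq")]] + colSums(dQ)
    G[[paste0(pre, "Wk")]] <- G[[paste0(pre, "Wk")]] + crossprod(cc$Xin, dK)
    G[[paste0(pre, "bk")]] <- G[[paste0(pre, "bk")]] + colSums(dK)
    G[[paste0(pre, "Wv")]] <- G[[paste0(pre, "Wv")]] + crossprod(cc$Xin, dV)
    G[[paste0(pre, "bv")]] <- G[[paste0(pre, "bv")]] + colSums(dV)
    dXin <- dXin + dQ %*% t(P[[paste0(pre, "Wq")]]) +
      dK %*% t(P[[paste0(pre, "Wk")]]) + dV %*% t(P[[paste0(pre, "Wv")]])
    dX <- dXin
  }
  embed_bwd(G, cfg, fb, dX)
}

# ---- pooling -------------------------------------------------------------

pool_fwd <- function(out, mask, pooling) {
  B <- nrow(mask); L <- ncol(mask)
  if (pooling == "cls") {
    idx <- (seq_len(B) - 1L) * L + 1L
    list(pooled = out[idx, , drop = FALSE], idx = idx)
  } else {
    grp <- rep(seq_len(B), each = L)
    w <- as.vector(t(mask))
    cnt <- rowsum(w, grp)[, 1]
    pooled <- rowsum(out * w, grp) / cnt
    list(pooled = pooled, w = w, grp = grp, cnt = cnt)
  }
}

pool_bwd <- function(dPooled, pool, mask, N) {
  B <- nrow(mask); L <- ncol(mask)
  dOut <- matrix(0, N, ncol(dPooled))
  if (!is.null(pool$idx)) {
    dOut[pool$idx, ] <- dPooled
  } else {
    per_row <- dPooled[rep(seq_len(B), each = L), , drop = FALSE]
    dOut <- per_row * (pool$w / pool$cnt[rep(seq_len(B), each = L)])
  }
  dOut
}

# ---- AdamW ---------------------------------------------------------------

adam_init <- function(P) list(m = zeros_like(P), v = zeros_like(P), t = 0L)

# Decoupled weight decay; decay is not applied to biases, layer-norm
# parameters, or embedding tables' pad rows (kept simple: applied to all
# matrices, not to vectors).
adam_step <- function(P, G, st, lr, wd = 0, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  b1c <- 1 - beta1^st$t
  b2c <- 1 - beta2^st$t
  for (nm in names(P)) {
    g <- G[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    upd <- (st$m[[nm]] / b1c) / (sqrt(st$v[[nm]] / b2c) + eps)
    decay <- if (is.matrix(P[[nm]])) wd * P[[nm]] else 0
    P[[nm]] <- P[[nm]] - lr * (upd + decay)
  }
  list(P = P, st = st)
}

# ---- losses --------------------------------------------------------------

# Cross-entropy over rows of `logits` with 0-based integer `truth`.
# Returns loss and dlogits (already divided by the number of rows).
ce_loss <- function(logits, truth) {
  probs <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), truth + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}
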