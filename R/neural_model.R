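# The relation classifier.
#
# Architecture: token features -> BiLSTM -> two parallel branches:
#   (a) self-attention over the BiLSTM states (additive / general /
#       scaled dot-product / multihead), max-pooled to h_att;
#   (b) a stack of graph convolutions over the document-level dependency
#       graph, from which the sentence vector h_sent and the two entity
#       vectors h_c, h_d are max-pooled (h_GCN = [h_sent; h_c; h_d]);
# h_final = [h_GCN; h_att] -> 2-layer rectified perceptron -> softmax over
# {no relation, CID relation}.
#
# Everything, including backpropagation, is implemented directly with
# dense matrix algebra: at desk scale (hidden sizes ~32, sequences ~40
# tokens) this trains in seconds per epoch and keeps the arithmetic
# auditable against the naive oracles used in the tests.

#' Model configuration
#'
#' @param profile `"paper"` mirrors the full-scale settings (BiLSTM output
#'   and GCN and perceptron widths 500, 5 attention heads, dropout 0.5);
#'   `"test"` is the desk-scale profile (widths 32, 2 heads).
#' @param ... Named overrides: `lstm_dim` (per direction), `gcn_dim`,
#'   `gcn_layers`, `attention_kind` (`"none"`, `"additive"`, `"general"`,
#'   `"scaled_dot"`, `"multihead"`), `n_heads`, `mlp_dim`, `dropout`,
#'   `use_gcn`, `seed`.
#' @return A validated `model_config` list.
#' @export
model_config <- function(profile = c("test", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(lstm_dim = 250L, gcn_dim = 500L, gcn_layers = 2L,
         attention_kind = "multihead", n_heads = 5L, mlp_dim = 500L,
         dropout = 0.5, use_gcn = TRUE, seed = 1L)
  } else {
    list(lstm_dim = 16L, gcn_dim = 32L, gcn_layers = 2L,
         attention_kind = "multihead", n_heads = 2L, mlp_dim = 32L,
         dropout = 0.2, use_gcn = TRUE, seed = 1L)
  }
  cfg <- utils::modifyList(cfg, list(...))
  kinds <- c("none", "additive", "general", "scaled_dot", "multihead")
  if (!cfg$attention_kind %in% kinds) {
    stopf("unknown attention kind '%s'", cfg$attention_kind)
  }
  D <- 2L * cfg$lstm_dim
  if (cfg$attention_kind == "multihead" && D %% cfg$n_heads != 0L) {
    stopf("BiLSTM output dim %d not divisible by n_heads %d", D, cfg$n_heads)
  }
  if (cfg$gcn_layers < 1L) stopf("gcn_layers must be >= 1")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stopf("dropout must be in [0,1)")
  if (!cfg$use_gcn && cfg$attention_kind == "none") {
    stopf("at least one of the GCN and attention branches must be enabled")
  }
  structure(cfg, class = "model_config")
}

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

#' Initialise model parameters
#'
#' All weights are Glorot-scaled Gaussians drawn deterministically from the
#' configuration seed; LSTM forget-gate biases start at 1 (standard
#' initialisation aiding gradient flow), all other biases at 0.
#'
#' @param config A [model_config()].
#' @param input_dim Width of the token feature matrix.
#' @return A `cid_model` with `$config`, `$input_dim`, `$params`.
#' @export
init_model <- function(config, input_dim) {
  Hd <- config$lstm_dim
  D <- 2L * Hd
  params <- with_local_seed(derive_seed(config$seed, "init"), {
    lstm_init <- function() {
      b <- numeric(4L * Hd)
      b[(Hd + 1L):(2L * Hd)] <- 1  # forget gate bias
      list(W = t(glorot(input_dim, 4L * Hd)), U = t(glorot(Hd, 4L * Hd)), b = b)
    }
    p <- list(lstm_f = lstm_init(), lstm_b = lstm_init())
    p$att <- switch(config$attention_kind,
      none = NULL,
      scaled_dot = list(),
      general = list(Ws = glorot(D, D)),
      additive = list(W1 = glorot(D, D), W2 = glorot(D, D),
                      s = numeric(D), v = stats::rnorm(D, sd = 1 / sqrt(D))),
      multihead = list(Wq = glorot(D, D), Wk = glorot(D, D),
                       Wv = glorot(D, D), Wo = glorot(D, D)))
    if (config$use_gcn) {
      p$gcn <- vector("list", config$gcn_layers)
      d_in <- D
      for (l in seq_len(config$gcn_layers)) {
        p$gcn[[l]] <- list(W = glorot(d_in, config$gcn_dim),
                           b = numeric(config$gcn_dim))
        d_in <- config$gcn_dim
      }
    }
    pool_dim <- if (config$use_gcn) config$gcn_dim else D
    width <- 3L * pool_dim + if (config$attention_kind == "none") 0L else D
    p$cls <- list(W1 = t(glorot(width, config$mlp_dim)), b1 = numeric(config$mlp_dim),
                  W2 = t(glorot(config$mlp_dim, config$mlp_dim)),
                  b2 = numeric(config$mlp_dim),
                  Wo = t(glorot(config$mlp_dim, 2L)), bo = numeric(2L))
    p
  })
  structure(list(config = config, input_dim = as.integer(input_dim),
                 params = params), class = "cid_model")
}

#' @export
print.cid_model <- function(x, ...) {
  cat(sprintf("<cid_model: input %d, BiLSTM %d, attention %s (%d heads), GCN %s, mlp %d>\n",
              x$input_dim, 2L * x$config$lstm_dim, x$config$attention_kind,
              x$config$n_heads,
              if (x$config$use_gcn) sprintf("%dx%d", x$config$gcn_layers, x$config$gcn_dim) else "off",
              x$config$mlp_dim))
  invisible(x)
}

# ---------------------------------------------------------------------------
# BiLSTM

# One-directional LSTM pass.  Gate layout in the stacked weight matrices is
# [input; forget; cell; output] blocks of lstm_dim rows each.
lstm_dir_forward <- function(X, W, U, b) {
  n <- nrow(X)
  Hd <- ncol(U)
  G <- X %*% t(W)
  G <- sweep(G, 2L, b, "+")
  ii <- 1:Hd; ff <- (Hd + 1L):(2L * Hd)
  gg <- (2L * Hd + 1L):(3L * Hd); oo <- (3L * Hd + 1L):(4L * Hd)
  I <- F_ <- Gg <- O <- C <- TC <- Hm <- matrix(0, n, Hd)
  h <- numeric(Hd); cc <- numeric(Hd)
  for (t in seq_len(n)) {
    a <- G[t, ] + as.vector(U %*% h)
    i_t <- sigmoid(a[ii]); f_t <- sigmoid(a[ff])
    g_t <- tanh(a[gg]); o_t <- sigmoid(a[oo])
    cc <- f_t * cc + i_t * g_t
    tc <- tanh(cc)
    h <- o_t * tc
    I[t, ] <- i_t; F_[t, ] <- f_t; Gg[t, ] <- g_t; O[t, ] <- o_t
    C[t, ] <- cc; TC[t, ] <- tc; Hm[t, ] <- h
  }
  list(H = Hm, I = I, F = F_, G = Gg, O = O, C = C, TC = TC, X = X)
}

lstm_dir_backward <- function(cache, W, U, dH) {
  n <- nrow(dH); Hd <- ncol(dH)
  DA <- matrix(0, n, 4L * Hd)
  ii <- 1:Hd; ff <- (Hd + 1L):(2L * Hd)
  gg <- (2L * Hd + 1L):(3L * Hd); oo <- (3L * Hd + 1L):(4L * Hd)
  dh_next <- numeric(Hd); dc_next <- numeric(Hd)
  for (t in n:1) {
    dh <- dH[t, ] + dh_next
    o_t <- cache$O[t, ]; tc <- cache$TC[t, ]
    dc <- dc_next + dh * o_t * (1 - tc^2)
    do_ <- dh * tc
    c_prev <- if (t > 1L) cache$C[t - 1L, ] else numeric(Hd)
    i_t <- cache$I[t, ]; f_t <- cache$F[t, ]; g_t <- cache$G[t, ]
    di <- dc * g_t; df <- dc * c_prev; dg <- dc * i_t
    dc_next <- dc * f_t
    da <- numeric(4L * Hd)
    da[ii] <- di * i_t * (1 - i_t)
    da[ff] <- df * f_t * (1 - f_t)
    da[gg] <- dg * (1 - g_t^2)
    da[oo] <- do_ * o_t * (1 - o_t)
    DA[t, ] <- da
    dh_next <- as.vector(crossprod(U, da))
  }
  Hprev <- rbind(numeric(Hd), cache$H[-n, , drop = FALSE])
  list(dW = crossprod(DA, cache$X), dU = crossprod(DA, Hprev),
       db = colSums(DA), dX = DA %*% W)
}

#' BiLSTM forward pass
#'
#' Runs a forward LSTM over the rows of `X` and a backward LSTM over the
#' reversed rows; the per-token output is the concatenation
#' `[h_forward; h_backward]`.
#'
#' @param X Token feature matrix (n x input_dim), n >= 1.
#' @param params Parameter list with `lstm_f` and `lstm_b`, each holding
#'   stacked gate weights `W` (4h x input_dim), recurrent weights `U`
#'   (4h x h), and bias `b` (gate order: input, forget, cell, output).
#' @return List: `H` (n x 2h concatenated states) plus the per-direction
#'   caches (`fwd`, `bwd`) with gate activations and cell states.
#' @export
bilstm_forward <- function(X, params) {
  if (!is.matrix(X) || nrow(X) < 1L) stopf("bilstm_forward: X must be a non-empty matrix")
  if (ncol(X) != ncol(params$lstm_f$W)) {
    stopf("bilstm_forward: input width %d does not match parameters (%d)",
          ncol(X), ncol(params$lstm_f$W))
  }
  fwd <- lstm_dir_forward(X, params$lstm_f$W, params$lstm_f$U, params$lstm_f$b)
  n <- nrow(X)
  Xr <- X[n:1, , drop = FALSE]
  bwd <- lstm_dir_forward(Xr, params$lstm_b$W, params$lstm_b$U, params$lstm_b$b)
  H <- cbind(fwd$H, bwd$H[n:1, , drop = FALSE])
  list(H = H, fwd = fwd, bwd = bwd)
}

bilstm_backward <- function(cache, params, dH) {
  n <- nrow(dH); Hd <- ncol(dH) / 2L
  gf <- lstm_dir_backward(cache$fwd, params$lstm_f$W, params$lstm_f$U,
                          dH[, 1:Hd, drop = FALSE])
  dHb <- dH[n:1, (Hd + 1L):(2L * Hd), drop = FALSE]
  gb <- lstm_dir_backward(cache$bwd, params$lstm_b$W, params$lstm_b$U, dHb)
  dX <- gf$dX + gb$dX[n:1, , drop = FALSE]
  list(lstm_f = list(W = gf$dW, U = gf$dU, b = gf$db),
       lstm_b = list(W = gb$dW, U = gb$dU, b = gb$db),
       dX = dX)
}

# ---------------------------------------------------------------------------
# Attention

#' Self-attention over BiLSTM states
#'
#' Four interchangeable kinds, all producing an n x d output whose rows are
#' convex combinations of value rows:
#' * `scaled_dot`: `softmax(H H' / sqrt(d)) H` (no parameters);
#' * `general`: scores `h_i' Ws h_j`;
#' * `additive`: scores `v' tanh(W1 h_i + W2 h_j + s)`;
#' * `multihead`: scaled dot-product attention on `n_heads` learned
#'   subspace projections of `H`, heads concatenated and re-projected by
#'   `Wo`.
#'
#' @param H BiLSTM output matrix (n x d).
#' @param kind One of `"additive"`, `"general"`, `"scaled_dot"`,
#'   `"multihead"`.
#' @param params Parameter list for the chosen kind (see [init_model()]).
#' @param n_heads Number of heads (multihead only; must divide d).
#' @return List: `output` (n x d), `weights` (list of per-head n x n
#'   row-stochastic matrices), and an internal cache for backpropagation.
#' @export
attention <- function(H, kind, params = list(), n_heads = 1L) {
  n <- nrow(H); D <- ncol(H)
  switch(kind,
    scaled_dot = {
      S <- tcrossprod(H) / sqrt(D)
      P <- softmax_rows(S)
      list(output = P %*% H, weights = list(P), cache = list(P = P, H = H))
    },
    general = {
      M <- H %*% params$Ws
      P <- softmax_rows(tcrossprod(M, H))
      list(output = P %*% H, weights = list(P), cache = list(P = P, H = H, M = M))
    },
    additive = {
      A1 <- H %*% params$W1
      A2 <- H %*% params$W2
      E <- matrix(0, n, n)
      Ts <- vector("list", n)
      for (j in seq_len(n)) {
        Tj <- tanh(sweep(A1, 2L, A2[j, ] + params$s, "+"))
        E[, j] <- Tj %*% params$v
        Ts[[j]] <- Tj
      }
      P <- softmax_rows(E)
      list(output = P %*% H, weights = list(P),
           cache = list(P = P, H = H, Ts = Ts))
    },
    multihead = {
      if (D %% n_heads != 0L) stopf("n_heads %d does not divide d %d", n_heads, D)
      dh <- D %/% n_heads
      Q <- H %*% params$Wq; K <- H %*% params$Wk; V <- H %*% params$Wv
      O <- matrix(0, n, D)
      Ps <- vector("list", n_heads)
      for (k in seq_len(n_heads)) {
        ck <- ((k - 1L) * dh + 1L):(k * dh)
        S <- tcrossprod(Q[, ck, drop = FALSE], K[, ck, drop = FALSE]) / sqrt(dh)
        Ps[[k]] <- softmax_rows(S)
        O[, ck] <- Ps[[k]] %*% V[, ck, drop = FALSE]
      }
      list(output = O %*% params$Wo, weights = Ps,
           cache = list(Ps = Ps, H = H, Q = Q, K = K, V = V, O = O))
    },
    stopf("unknown attention kind '%s'", kind))
}

softmax_rows_backward <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

attention_backward <- function(out, kind, params, n_heads, dZ) {
  cc <- out$cache
  H <- cc$H
  D <- ncol(H)
  switch(kind,
    scaled_dot = {
      P <- cc$P
      dP <- tcrossprod(dZ, H)          # output = P H
      dH <- crossprod(P, dZ)
      dS <- softmax_rows_backward(P, dP)
      dH <- dH + (dS + t(dS)) %*% H / sqrt(D)
      list(grads = list(), dH = dH)
    },
    general = {
      P <- cc$P; M <- cc$M
      dP <- tcrossprod(dZ, H)
      dH <- crossprod(P, dZ)
      dS <- softmax_rows_backward(P, dP)  # S = M H'
      dM <- dS %*% H
      dH <- dH + t(dS) %*% M + dM %*% t(params$Ws)
      list(grads = list(Ws = crossprod(H, dM)), dH = dH)
    },
    additive = {
      P <- cc$P; Ts <- cc$Ts
      n <- nrow(H)
      dP <- tcrossprod(dZ, H)
      dH <- crossprod(P, dZ)
      dE <- softmax_rows_backward(P, dP)
      dv <- numeric(length(params$v)); ds <- numeric(length(params$s))
      dA1 <- matrix(0, n, D); dA2 <- matrix(0, n, D)
      for (j in seq_len(n)) {
        Tj <- Ts[[j]]
        dv <- dv + as.vector(crossprod(Tj, dE[, j]))
        dTj <- (dE[, j] %o% params$v) * (1 - Tj^2)
        dA1 <- dA1 + dTj
        cs <- colSums(dTj)
        dA2[j, ] <- cs
        ds <- ds + cs
      }
      dH <- dH + dA1 %*% t(params$W1) + dA2 %*% t(params$W2)
      list(grads = list(W1 = crossprod(H, dA1), W2 = crossprod(H, dA2),
                        s = ds, v = dv), dH = dH)
    },
    multihead = {
      dh <- D %/% n_heads
      dWo <- crossprod(cc$O, dZ)
      dO <- tcrossprod(dZ, params$Wo)
      dQ <- matrix(0, nrow(H), D); dK <- dQ; dV <- dQ
      for (k in seq_len(n_heads)) {
        ck <- ((k - 1L) * dh + 1L):(k * dh)
        P <- cc$Ps[[k]]
        Vk <- cc$V[, ck, drop = FALSE]
        dOk <- dO[, ck, drop = FALSE]
        dP <- tcrossprod(dOk, Vk)
        dV[, ck] <- crossprod(P, dOk)
        dS <- softmax_rows_backward(P, dP)
        dQ[, ck] <- dS %*% cc$K[, ck, drop = FALSE] / sqrt(dh)
        dK[, ck] <- crossprod(dS, cc$Q[, ck, drop = FALSE]) / sqrt(dh)
      }
      dH <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
      list(grads = list(Wq = crossprod(H, dQ), Wk = crossprod(H, dK),
                        Wv = crossprod(H, dV), Wo = dWo), dH = dH)
    })
}

# ---------------------------------------------------------------------------
# GCN

#' One graph convolution layer
#'
#' `h_i_out = rho( (1/d_i) sum_j A_ij W' h_j + b )`, i.e. the degree-
#' normalised neighbour average of linearly transformed inputs.  `A` must
#' be the binary symmetric adjacency with unit diagonal, so `d_i >= 1`.
#'
#' @param H_in Node representations (n x d_in).
#' @param A Adjacency matrix (dense or `Matrix` sparse, n x n).
#' @param W Weight matrix (d_in x d_out).
#' @param b Bias vector (d_out).
#' @param activation Elementwise nonlinearity (default rectifier).
#' @return Matrix n x d_out.
#' @export
gcn_layer <- function(H_in, A, W, b, activation = relu) {
  if (nrow(H_in) != nrow(A)) stopf("gcn_layer: H_in rows != A dimension")
  d <- Matrix::rowSums(A)
  AH <- as.matrix(A %*% H_in) / d
  activation(sweep(AH %*% W, 2L, b, "+"))
}

#' Stacked graph convolutions
#'
#' @param H0 Input node representations (the BiLSTM output).
#' @param A Adjacency matrix.
#' @param params List of `gcn_layers` layer parameter lists (`W`, `b`).
#' @param L Number of layers to apply (default all).
#' @return Output representations after `L` rectified layers.
#' @export
gcn_stack <- function(H0, A, params, L = length(params)) {
  if (L < 1L) stopf("gcn_stack: L must be >= 1")
  H <- H0
  for (l in seq_len(L)) {
    H <- gcn_layer(H, A, params[[l]]$W, params[[l]]$b)
  }
  H
}

# Forward with cache for training.  Anorm is the precomputed D^{-1} A.
gcn_forward_cached <- function(H0, Anorm, params, drop_masks = NULL) {
  L <- length(params)
  inputs <- vector("list", L)   # AH per layer (pre-weight)
  preact <- vector("list", L)
  outs <- vector("list", L)
  H <- H0
  for (l in seq_len(L)) {
    AH <- as.matrix(Anorm %*% H)
    Z <- sweep(AH %*% params[[l]]$W, 2L, params[[l]]$b, "+")
    H <- relu(Z)
    if (!is.null(drop_masks)) H <- H * drop_masks[[l]]
    inputs[[l]] <- AH; preact[[l]] <- Z; outs[[l]] <- H
  }
  list(H_L = H, inputs = inputs, preact = preact, outs = outs)
}

gcn_backward <- function(cache, Anorm, params, dH_L, drop_masks = NULL) {
  L <- length(params)
  grads <- vector("list", L)
  dH <- dH_L
  for (l in L:1) {
    if (!is.null(drop_masks)) dH <- dH * drop_masks[[l]]
    dZ <- dH * (cache$preact[[l]] > 0)
    grads[[l]] <- list(W = crossprod(cache$inputs[[l]], dZ), b = colSums(dZ))
    dAH <- tcrossprod(dZ, params[[l]]$W)
    dH <- as.matrix(Matrix::crossprod(Anorm, dAH))
  }
  list(grads = grads, dH0 = dH)
}

# ---------------------------------------------------------------------------
# Pooling and classification

colmax_pool <- function(M) {
  idx <- max.col(t(M), ties.method = "first")
  list(v = M[cbind(idx, seq_len(ncol(M)))], idx = idx)
}

#' Pool node representations into the instance representation
#'
#' `h_sent` is the columnwise max over all window tokens of `H_L`; `h_c`
#' and `h_d` are columnwise maxima over the chemical and disease mention
#' spans; `h_att` is the columnwise max over the attention output.
#' `h_GCN = [h_sent; h_c; h_d]`, `h_final = [h_GCN; h_att]`.
#'
#' @param H_L Node representations pooled for the graph branch.
#' @param H_att Attention output matrix, or `NULL` when the attention
#'   branch is ablated.
#' @param chem_span,dis_span Window-relative inclusive token spans.
#' @return List with `h_sent`, `h_c`, `h_d`, `h_gcn`, `h_att`, `h_final`.
#' @export
pool_and_represent <- function(H_L, H_att, chem_span, dis_span) {
  n <- nrow(H_L)
  if (anyNA(chem_span) || chem_span[1] < 1L || chem_span[2] > n ||
        chem_span[2] < chem_span[1]) stopf("invalid chemical span")
  if (anyNA(dis_span) || dis_span[1] < 1L || dis_span[2] > n ||
        dis_span[2] < dis_span[1]) stopf("invalid disease span")
  p_sent <- colmax_pool(H_L)
  p_c <- colmax_pool(H_L[chem_span[1]:chem_span[2], , drop = FALSE])
  p_d <- colmax_pool(H_L[dis_span[1]:dis_span[2], , drop = FALSE])
  h_att <- NULL; p_att <- NULL
  if (!is.null(H_att)) {
    p_att <- colmax_pool(H_att)
    h_att <- p_att$v
  }
  h_gcn <- c(p_sent$v, p_c$v, p_d$v)
  list(h_sent = p_sent$v, h_c = p_c$v, h_d = p_d$v, h_gcn = h_gcn,
       h_att = h_att, h_final = c(h_gcn, h_att),
       pool_idx = list(sent = p_sent$idx, c = p_c$idx, d = p_d$idx,
                       att = if (is.null(p_att)) NULL else p_att$idx))
}

#' Classify an instance representation
#'
#' Two rectified affine layers followed by a softmax over the two classes
#' (index 1: no relation, index 2: CID relation).
#'
#' @param h_final Instance representation vector.
#' @param params Classifier parameters (`W1`, `b1`, `W2`, `b2`, `Wo`, `bo`).
#' @return List: `o` (probability 2-vector), hidden layers `h1`, `h2`.
#' @export
classify <- function(h_final, params) {
  if (length(h_final) != ncol(params$W1)) {
    stopf("classify: representation width %d does not match parameters (%d)",
          length(h_final), ncol(params$W1))
  }
  z1 <- as.vector(params$W1 %*% h_final) + params$b1
  h1 <- relu(z1)
  z2 <- as.vector(params$W2 %*% h1) + params$b2
  h2 <- relu(z2)
  logits <- as.vector(params$Wo %*% h2) + params$bo
  list(o = softmax_vec(logits), h1 = h1, h2 = h2, z1 = z1, z2 = z2,
       logits = logits)
}

# ---------------------------------------------------------------------------
# Full forward / backward over one instance

#' Forward pass of the full model on one prepared instance
#'
#' @param model A `cid_model`.
#' @param prep A prepared instance: list with `X` (token features), `Anorm`
#'   (window-restricted normalised adjacency), `chem_span`, `dis_span`
#'   (window-relative).
#' @param train Logical; when `TRUE`, dropout masks are sampled from the
#'   current RNG stream and applied to the BiLSTM output and each GCN
#'   layer output.
#' @return List with class probabilities `o` and the full cache.
#' @export
model_forward <- function(model, prep, train = FALSE) {
  cfg <- model$config
  p <- model$params
  enc <- bilstm_forward(prep$X, p)
  H <- enc$H
  n <- nrow(H)
  mask_H <- NULL; masks_g <- NULL
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask_H <- matrix((stats::runif(n * ncol(H)) < keep) / keep, n, ncol(H))
    H <- H * mask_H
    if (cfg$use_gcn) {
      masks_g <- lapply(seq_len(cfg$gcn_layers), function(l) {
        matrix((stats::runif(n * cfg$gcn_dim) < keep) / keep, n, cfg$gcn_dim)
      })
    }
  }
  att_out <- NULL
  if (cfg$attention_kind != "none") {
    att_out <- attention(H, cfg$attention_kind, p$att, cfg$n_heads)
  }
  gcn_cache <- NULL
  pool_src <- H
  if (cfg$use_gcn) {
    gcn_cache <- gcn_forward_cached(H, prep$Anorm, p$gcn, masks_g)
    pool_src <- gcn_cache$H_L
  }
  rep_ <- pool_and_represent(pool_src, if (is.null(att_out)) NULL else att_out$output,
                             prep$chem_span, prep$dis_span)
  cls <- classify(rep_$h_final, p$cls)
  list(o = cls$o, cache = list(enc = enc, H = H, mask_H = mask_H,
                               masks_g = masks_g, att_out = att_out,
                               gcn_cache = gcn_cache, rep = rep_, cls = cls,
                               prep = prep))
}

# Backward pass; label is 0/1.  Returns gradients in the same nested shape
# as model$params, plus the cross-entropy loss.
model_backward <- function(model, fwd, label) {
  cfg <- model$config
  p <- model$params
  cc <- fwd$cache
  o <- fwd$o
  loss <- -log(max(o[label + 1L], 1e-12))
  dlogits <- o
  dlogits[label + 1L] <- dlogits[label + 1L] - 1
  cls <- cc$cls
  g_cls <- list()
  g_cls$Wo <- dlogits %o% cls$h2
  g_cls$bo <- dlogits
  dh2 <- as.vector(crossprod(p$cls$Wo, dlogits)) * (cls$z2 > 0)
  g_cls$W2 <- dh2 %o% cls$h1
  g_cls$b2 <- dh2
  dh1 <- as.vector(crossprod(p$cls$W2, dh2)) * (cls$z1 > 0)
  g_cls$W1 <- dh1 %o% cc$rep$h_final
  g_cls$b1 <- dh1
  dfinal <- as.vector(crossprod(p$cls$W1, dh1))

  pool_dim <- if (cfg$use_gcn) cfg$gcn_dim else 2L * cfg$lstm_dim
  d_sent <- dfinal[1:pool_dim]
  d_c <- dfinal[(pool_dim + 1L):(2L * pool_dim)]
  d_d <- dfinal[(2L * pool_dim + 1L):(3L * pool_dim)]
  idx <- cc$rep$pool_idx
  prep <- cc$prep
  n <- nrow(cc$H)
  dPool <- matrix(0, n, pool_dim)
  cols <- seq_len(pool_dim)
  dPool[cbind(idx$sent, cols)] <- dPool[cbind(idx$sent, cols)] + d_sent
  rows_c <- prep$chem_span[1] - 1L + idx$c
  dPool[cbind(rows_c, cols)] <- dPool[cbind(rows_c, cols)] + d_c
  rows_d <- prep$dis_span[1] - 1L + idx$d
  dPool[cbind(rows_d, cols)] <- dPool[cbind(rows_d, cols)] + d_d

  dH <- matrix(0, n, 2L * cfg$lstm_dim)
  grads <- list()
  if (cfg$use_gcn) {
    gb <- gcn_backward(cc$gcn_cache, prep$Anorm, p$gcn, dPool, cc$masks_g)
    grads$gcn <- gb$grads
    dH <- dH + gb$dH0
  } else {
    dH <- dH + dPool
  }
  if (cfg$attention_kind != "none") {
    D_att <- 2L * cfg$lstm_dim
    d_att <- dfinal[(3L * pool_dim + 1L):(3L * pool_dim + D_att)]
    dZ <- matrix(0, n, D_att)
    dZ[cbind(idx$att, seq_len(D_att))] <- d_att
    ab <- attention_backward(cc$att_out, cfg$attention_kind, p$att,
                             cfg$n_heads, dZ)
    grads$att <- ab$grads
    dH <- dH + ab$dH
  }
  if (!is.null(cc$mask_H)) dH <- dH * cc$mask_H
  bb <- bilstm_backward(cc$enc, p, dH)
  grads$lstm_f <- bb$lstm_f
  grads$lstm_b <- bb$lstm_b
  grads$cls <- g_cls
  list(grads = grads, loss = loss)
}
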