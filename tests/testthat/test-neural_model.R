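zero_lstm_params <- function(p_dim, h_dim) {
  z <- list(W = matrix(0, 4 * h_dim, p_dim), U = matrix(0, 4 * h_dim, h_dim),
            b = numeric(4 * h_dim))
  list(lstm_f = z, lstm_b = z)
}

test_that("BiLSTM with zero parameters yields all-zero hidden states", {
  X <- matrix(rnorm(15), 5, 3)
  out <- bilstm_forward(X, zero_lstm_params(3, 4))
  expect_equal(out$H, matrix(0, 5, 8))
  # gates: sigmoid(0) = 0.5, tanh(0) = 0, so c_t = 0.5 c_{t-1} = 0
  expect_equal(out$fwd$I, matrix(0.5, 5, 4))
  expect_equal(out$fwd$F, matrix(0.5, 5, 4))
  expect_equal(out$fwd$O, matrix(0.5, 5, 4))
  expect_equal(out$fwd$G, matrix(0, 5, 4))
  expect_equal(out$fwd$C, matrix(0, 5, 4))
})

test_that("LSTM matches the scalar step oracle", {
  set.seed(42)
  p <- 4L; h <- 3L; n <- 6L
  prm <- list(W = matrix(rnorm(4 * h * p, sd = 0.3), 4 * h, p),
              U = matrix(rnorm(4 * h * h, sd = 0.3), 4 * h, h),
              b = rnorm(4 * h, sd = 0.1))
  X <- matrix(rnorm(n * p), n, p)
  out <- bilstm_forward(X, list(lstm_f = prm, lstm_b = prm))
  expect_equal(out$H[, 1:h], oracle_lstm(X, prm$W, prm$U, prm$b),
               tolerance = 1e-6, ignore_attr = TRUE)
  # single-step case
  out1 <- bilstm_forward(X[1, , drop = FALSE], list(lstm_f = prm, lstm_b = prm))
  expect_equal(out1$H[, 1:h],
               oracle_lstm(X[1, , drop = FALSE], prm$W, prm$U, prm$b),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("backward LSTM equals forward LSTM on the reversed sequence", {
  set.seed(7)
  p <- 4L; h <- 3L; n <- 5L
  mk <- function() list(W = matrix(rnorm(4 * h * p, sd = 0.3), 4 * h, p),
                        U = matrix(rnorm(4 * h * h, sd = 0.3), 4 * h, h),
                        b = rnorm(4 * h, sd = 0.1))
  prm <- list(lstm_f = mk(), lstm_b = mk())
  X <- matrix(rnorm(n * p), n, p)
  H_bwd <- bilstm_forward(X, prm)$H[, (h + 1):(2 * h)]
  swapped <- list(lstm_f = prm$lstm_b, lstm_b = prm$lstm_f)
  H_fwd_rev <- bilstm_forward(X[n:1, ], swapped)$H[, 1:h]
  expect_equal(H_bwd, H_fwd_rev[n:1, ], tolerance = 1e-10)
})

test_that("attention weights are row-stochastic for all four kinds", {
  set.seed(11)
  H <- matrix(rnorm(6 * 8), 6, 8)
  model <- init_model(model_config("test", lstm_dim = 4L, n_heads = 2L,
                                   attention_kind = "multihead"), 5L)
  for (kind in c("scaled_dot", "general", "additive", "multihead")) {
    prm <- init_model(model_config("test", lstm_dim = 4L, n_heads = 2L,
                                   attention_kind = kind), 5L)$params$att
    out <- attention(H, kind, prm, n_heads = 2L)
    for (P in out$weights) {
      expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-6, ignore_attr = TRUE)
      expect_true(all(P >= 0))
    }
    expect_equal(dim(out$output), c(6L, 8L))
  }
})

test_that("degenerate attention inputs: identical rows", {
  v <- rnorm(8)
  H <- matrix(v, 6, 8, byrow = TRUE)  # all rows (keys and values) identical
  for (kind in c("scaled_dot", "general", "additive")) {
    prm <- init_model(model_config("test", lstm_dim = 4L, attention_kind = kind),
                      5L)$params$att
    out <- attention(H, kind, prm)
    expect_equal(out$weights[[1]], matrix(1 / 6, 6, 6), tolerance = 1e-9)
    for (i in 1:6) expect_equal(out$output[i, ], v, tolerance = 1e-9,
                                ignore_attr = TRUE)
  }
  # multihead: uniform weights; output rows constant (projected value)
  prm <- init_model(model_config("test", lstm_dim = 4L, n_heads = 2L), 5L)$params$att
  out <- attention(H, "multihead", prm, n_heads = 2L)
  for (P in out$weights) expect_equal(P, matrix(1 / 6, 6, 6), tolerance = 1e-9)
  expect_equal(out$output, matrix(out$output[1, ], 6, 8, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("multihead with one head and identity projections is scaled dot-product", {
  set.seed(13)
  H <- matrix(rnorm(5 * 6), 5, 6)
  I6 <- diag(6)
  mh <- attention(H, "multihead", list(Wq = I6, Wk = I6, Wv = I6, Wo = I6),
                  n_heads = 1L)
  sd_ <- attention(H, "scaled_dot")
  expect_equal(mh$output, sd_$output, tolerance = 1e-6)
  expect_equal(mh$weights[[1]], sd_$weights[[1]], tolerance = 1e-6)
})

test_that("attention rejects heads not dividing the dimension", {
  H <- matrix(rnorm(20), 4, 5)
  expect_error(attention(H, "multihead", list(), n_heads = 2L), "divide")
  expect_error(model_config("test", lstm_dim = 16L, n_heads = 5L), "divisible")
})

test_that("gcn_layer degenerate cases and oracle equivalence", {
  # single node, self loop, identity weights: output = input
  H1 <- matrix(c(1.5, -2), 1, 2)
  expect_equal(gcn_layer(H1, matrix(1, 1, 1), diag(2), c(0, 0),
                         activation = identity), H1)
  # two fully connected nodes: both outputs are the average
  H2 <- rbind(c(1, 2), c(3, 6))
  out2 <- gcn_layer(H2, matrix(1, 2, 2), diag(2), c(0, 0), activation = identity)
  expect_equal(out2, rbind(c(2, 4), c(2, 4)))

  set.seed(21)
  for (trial in 1:20) {
    n <- sample(2:8, 1)
    A <- diag(n)
    for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
    extra <- which(upper.tri(A) & A == 0)
    if (length(extra)) {
      on <- sample(extra, min(2, length(extra)))
      A[on] <- 1
      A <- pmax(A, t(A))
    }
    H <- matrix(rnorm(n * 3), n, 3)
    W <- matrix(rnorm(12, sd = 0.5), 3, 4)
    b <- rnorm(4, sd = 0.2)
    expect_equal(gcn_layer(H, A, W, b), oracle_gcn_layer(H, A, W, b),
                 tolerance = 1e-6)
  }
})

test_that("gcn_stack: L=1 reduction, identity graph, L-hop locality", {
  set.seed(5)
  n <- 6L
  A <- diag(n); for (i in 1:(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1  # chain
  H0 <- matrix(rnorm(n * 4), n, 4)
  prm <- list(list(W = matrix(rnorm(16, sd = 0.5), 4, 4), b = rnorm(4, sd = .1)),
              list(W = matrix(rnorm(16, sd = 0.5), 4, 4), b = rnorm(4, sd = .1)))
  expect_equal(gcn_stack(H0, A, prm, L = 1L),
               gcn_layer(H0, A, prm[[1]]$W, prm[[1]]$b))
  expect_error(gcn_stack(H0, A, prm, L = 0L), "L")
  # identity adjacency: no mixing; each node is an independent MLP
  I_ <- diag(n)
  out_I <- gcn_stack(H0, I_, prm, L = 2L)
  for (i in seq_len(n)) {
    expect_equal(out_I[i, ], gcn_stack(H0[i, , drop = FALSE],
                                       matrix(1, 1, 1), prm, L = 2L)[1, ])
  }
  # locality: perturbing node 1 cannot affect nodes at graph distance > L
  H0b <- H0; H0b[1, ] <- H0b[1, ] + 5
  out_a <- gcn_stack(H0, A, prm, L = 2L)
  out_b <- gcn_stack(H0b, A, prm, L = 2L)
  expect_equal(out_a[4:6, ], out_b[4:6, ])        # distance 3,4,5 from node 1
  expect_false(isTRUE(all.equal(out_a[2, ], out_b[2, ])))
})

test_that("pooling and classification contracts", {
  set.seed(3)
  H_L <- matrix(rnorm(5 * 4), 5, 4)
  H_att <- matrix(rnorm(5 * 6), 5, 6)
  rep_ <- pool_and_represent(H_L, H_att, c(2L, 3L), c(5L, 5L))
  expect_equal(length(rep_$h_final), 3L * 4L + 6L)
  expect_equal(rep_$h_sent, apply(H_L, 2, max), ignore_attr = TRUE)
  expect_equal(rep_$h_c, apply(H_L[2:3, ], 2, max), ignore_attr = TRUE)
  expect_equal(rep_$h_d, H_L[5, ], ignore_attr = TRUE)
  # permutation invariance of the sentence pool
  perm <- sample(5)
  rep_p <- pool_and_represent(H_L[perm, ], H_att[perm, ],
                              c(1L, 5L), c(1L, 5L))
  expect_equal(rep_p$h_sent, rep_$h_sent)
  expect_error(pool_and_represent(H_L, H_att, c(2L, 1L), c(5L, 5L)), "span")

  # single-token document: sentence pool is that row
  r1 <- pool_and_represent(H_L[1, , drop = FALSE], NULL, c(1L, 1L), c(1L, 1L))
  expect_equal(r1$h_sent, H_L[1, ], ignore_attr = TRUE)
  expect_equal(r1$h_final, rep(H_L[1, ], 3), ignore_attr = TRUE)

  prm <- list(W1 = matrix(0, 3, 18), b1 = numeric(3),
              W2 = matrix(0, 3, 3), b2 = numeric(3),
              Wo = matrix(0, 2, 3), bo = numeric(2))
  cls0 <- classify(rep_$h_final, prm)
  expect_equal(cls0$o, c(0.5, 0.5))
  prm2 <- init_model(model_config("test", lstm_dim = 2L, gcn_dim = 4L,
                                  mlp_dim = 3L, n_heads = 1L), 5L)$params$cls
  # monotonicity: raising the positive-class logit raises o[2]
  h <- rnorm(ncol(prm2$W1))
  o1 <- classify(h, prm2)$o
  prm3 <- prm2; prm3$bo[2] <- prm3$bo[2] + 1
  o2 <- classify(h, prm3)$o
  expect_gt(o2[2], o1[2])
  expect_equal(sum(o1), 1)
  expect_true(all(o1 > 0 & o1 < 1))
})

test_that("full forward pass is deterministic given config and seed", {
  cfg <- model_config("test", seed = 77L)
  docs <- generate_corpus(small_spec(2L, seed = 31L))
  inst <- build_all(docs)
  rc <- repr_config("test")
  preps <- prepare_instances(inst, docs, hash_embedder(rc$dim_ctx, rc$seed),
                             embedding_tables(rc))
  m1 <- init_model(cfg, ncol(preps[[1]]$X))
  m2 <- init_model(cfg, ncol(preps[[1]]$X))
  expect_identical(m1$params, m2$params)
  o1 <- model_forward(m1, preps[[1]])$o
  o2 <- model_forward(m2, preps[[1]])$o
  expect_identical(o1, o2)
})
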