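test_that("position_index: inside, signed, clipped, monotone", {
  expect_equal(position_index(3L, c(2L, 4L), 50L), 0L)
  expect_equal(position_index(5L, c(2L, 3L), 50L), 2L)
  expect_equal(position_index(0L, c(60L, 61L), 50L), -50L)
  expect_error(position_index(1L, c(5L, 3L), 50L), "span")
  idx <- position_index(1:100, c(40L, 42L), 10L)
  expect_true(all(diff(idx) >= 0))
  expect_true(all(idx >= -10L & idx <= 10L))
  expect_true(all(idx[40:42] == 0L))
})

test_that("hash embedder is deterministic and context-sensitive", {
  emb <- hash_embedder(32L, seed = 4L)
  a <- embed_tokens(emb, c("alpha", "beta", "gamma"))
  b <- embed_tokens(emb, c("alpha", "beta", "gamma"))
  expect_identical(a, b)
  expect_equal(rowSums(a^2), rep(1, 3), tolerance = 1e-12)
  # different left neighbour changes the middle vector
  c_ <- embed_tokens(emb, c("delta", "beta", "gamma"))
  expect_false(isTRUE(all.equal(a[2, ], c_[2, ])))
  # a fresh embedder with the same seed agrees
  expect_identical(embed_tokens(hash_embedder(32L, seed = 4L),
                                c("alpha", "beta", "gamma")), a)
})

test_that("same word in different contexts stays closer than different words", {
  emb <- hash_embedder(32L, seed = 9L)
  words <- sprintf("w%02d", 1:40)
  set.seed(31)
  cos_same <- replicate(200, {
    w <- sample(words, 1)
    ctx1 <- c(sample(words, 1), w, sample(words, 1))
    ctx2 <- c(sample(words, 1), w, sample(words, 1))
    sum(embed_tokens(emb, ctx1)[2, ] * embed_tokens(emb, ctx2)[2, ])
  })
  cos_diff <- replicate(200, {
    ws <- sample(words, 2)
    ctx1 <- c(sample(words, 1), ws[1], sample(words, 1))
    ctx2 <- c(sample(words, 1), ws[2], sample(words, 1))
    sum(embed_tokens(emb, ctx1)[2, ] * embed_tokens(emb, ctx2)[2, ])
  })
  expect_gt(mean(cos_same), mean(cos_diff) + 0.2)
})

test_that("featurize obeys the concatenation contract", {
  cfg <- repr_config("test")
  tables <- embedding_tables(cfg)
  emb <- hash_embedder(cfg$dim_ctx, cfg$seed)
  doc <- make_fig1_doc()
  inst <- build_all(doc)
  X <- featurize(inst[1, ], doc, emb, tables)
  n <- nrow(doc$tokens)
  expect_equal(dim(X), c(n, cfg$dim_ctx + cfg$dim_pos + 2L * cfg$dim_dist),
               ignore_attr = TRUE)
  # sub-block recovery: POS block equals the table row for the token's tag
  i <- 3L
  pos_block <- X[i, (cfg$dim_ctx + 1L):(cfg$dim_ctx + cfg$dim_pos)]
  expect_equal(pos_block, tables$M_p[doc$tokens$pos_tag[i], ],
               ignore_attr = TRUE)
  # distance blocks equal the M_d rows at the clipped distances
  dch <- position_index(i, attr(X, "chem_span"), cfg$clip)
  off <- cfg$dim_ctx + cfg$dim_pos
  expect_equal(X[i, (off + 1L):(off + cfg$dim_dist)],
               tables$M_d[as.character(dch), ], ignore_attr = TRUE)
  # rebuilding bit-identically
  X2 <- featurize(inst[1, ], doc, hash_embedder(cfg$dim_ctx, cfg$seed),
                  embedding_tables(cfg))
  expect_identical(unclass(X), unclass(X2))
})

test_that("unknown POS tags fall back to the UNK row with a log message", {
  cfg <- repr_config("test")
  tables <- embedding_tables(cfg)
  emb <- hash_embedder(cfg$dim_ctx)
  doc <- make_doc(
    list(list(surface = c("chemA", "x", "disB"), head = c(0L, 1L, 2L),
              pos = c("WEIRD", "NOUN", "NOUN"))),
    list(list(type = "Chemical", concept = "D000001", sentence = 1, tok = 1),
         list(type = "Disease", concept = "D000002", sentence = 1, tok = 3)))
  inst <- build_all(doc)
  withr::with_options(list(docgraphre.verbose = TRUE),
                      expect_message(X <- featurize(inst[1, ], doc, emb, tables),
                                     "UNK"))
  pos_block <- X[1, (cfg$dim_ctx + 1L):(cfg$dim_ctx + cfg$dim_pos)]
  expect_equal(pos_block, tables$M_p["<UNK>", ], ignore_attr = TRUE)
})

test_that("long documents are truncated around the mention pair", {
  cfg <- repr_config("test", max_len = 12L)
  tables <- embedding_tables(cfg)
  emb <- hash_embedder(cfg$dim_ctx)
  words <- sprintf("t%02d", 1:30)
  doc <- make_doc(
    list(list(surface = words, head = c(0L, rep(1L, 29L)))),
    list(list(type = "Chemical", concept = "D000001", sentence = 1, tok = 14),
         list(type = "Disease", concept = "D000002", sentence = 1, tok = 18)))
  inst <- build_all(doc)
  X <- featurize(inst[1, ], doc, emb, tables)
  expect_equal(nrow(X), 12L)
  w <- attr(X, "window")
  expect_lte(w[1], 14L); expect_gte(w[2], 18L)
  cs <- attr(X, "chem_span")
  expect_equal(doc$tokens$surface[w[1] + cs[1] - 1L], "t14")
})
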