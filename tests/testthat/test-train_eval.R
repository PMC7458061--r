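test_that("evaluation formulas match the counting oracle", {
  # TP=5, FP=5, FN=5 forced: 10 predictions, 5 correct, 10 gold
  gold <- data.frame(doc_id = as.character(1:10), chemical_id = "C",
                     disease_id = "D", stringsAsFactors = FALSE)
  pred <- data.frame(doc_id = as.character(c(1:5, 11:15)), chemical_id = "C",
                     disease_id = "D", level = "intra", stringsAsFactors = FALSE)
  inst <- data.frame(doc_id = as.character(1:15), level = "intra",
                     chemical_id = "C", disease_id = "D",
                     stringsAsFactors = FALSE)
  rep_ <- evaluate(pred, gold, inst)
  m <- rep_[rep_$level == "merged", ]
  expect_equal(c(m$tp, m$fp, m$fn), c(5, 5, 5))
  expect_equal(c(m$precision, m$recall, m$f_measure), c(0.5, 0.5, 0.5))

  # perfect predictions
  rep_p <- evaluate(cbind(gold, level = "intra"), gold, inst)
  expect_true(all(rep_p[rep_p$level != "inter",
                        c("precision", "recall", "f_measure")] == 1))
})

test_that("evaluation matches the oracle on random prediction/gold sets", {
  set.seed(55)
  for (trial in 1:20) {
    docs <- as.character(1:8)
    univ <- expand.grid(doc_id = docs, chemical_id = c("C1", "C2"),
                        disease_id = c("D1", "D2"), stringsAsFactors = FALSE)
    inst <- cbind(univ, level = sample(c("intra", "inter"), nrow(univ),
                                       replace = TRUE))
    gold <- univ[sample(nrow(univ), 10), ]
    pred_rows <- inst[sample(nrow(inst), 12), ]
    rep_ <- evaluate(pred_rows, gold, inst)
    key <- function(df) paste(df$doc_id, df$chemical_id, df$disease_id)
    gl <- ifelse(key(gold) %in% key(inst[inst$level == "intra", ]),
                 "intra", "inter")
    for (lv in c("intra", "inter", "merged")) {
      gk <- if (lv == "merged") key(gold) else key(gold)[gl == lv]
      pk <- if (lv == "merged") key(pred_rows) else
        key(pred_rows)[pred_rows$level == lv]
      o <- oracle_prf(pk, gk)
      r <- rep_[rep_$level == lv, ]
      expect_equal(c(r$tp, r$fp, r$fn), c(o$tp, o$fp, o$fn))
      expect_equal(c(r$precision, r$recall, r$f_measure), c(o$p, o$r, o$f))
    }
    # conservation of gold at the merged level
    m <- rep_[rep_$level == "merged", ]
    expect_equal(m$tp + m$fn, nrow(gold))
  }
})

test_that("gold pairs dropped by the distance filter count as false negatives", {
  far <- make_doc(
    list(chain_sentence(c("a", "chemX", "b", "c", "d")),
         chain_sentence(c("f", "g", "h", "i", "j")),
         chain_sentence(c("k", "l", "m", "n", "o")),
         chain_sentence(c("p", "q", "r", "s", "t")),
         chain_sentence(c("u", "disY", "v", "w", "x"))),
    list(list(type = "Chemical", concept = "D000001", sentence = 1, tok = 2),
         list(type = "Disease", concept = "D000002", sentence = 5, tok = 2)),
    data.frame(chemical_id = "D000001", disease_id = "D000002",
               stringsAsFactors = FALSE))
  inst <- build_all(far, 3L)
  expect_equal(nrow(inst), 0L)
  rep_ <- evaluate(inst[0, c("doc_id", "chemical_id", "disease_id", "level")],
                   gold_pairs(list(far)), inst)
  expect_equal(rep_$fn[rep_$level == "merged"], 1L)
  expect_equal(rep_$fn[rep_$level == "inter"], 1L)
})

test_that("training decreases the loss and is seed-reproducible", {
  docs <- generate_corpus(small_spec(40L, seed = 61L))
  inst <- build_all(docs)
  cfg <- model_config("test", seed = 1L)
  tc <- training_config("test", max_epochs = 5L, patience = 5L, seed = 1L)
  ck <- train(inst, docs, cfg, tc)
  h <- ck$history
  expect_true(all(is.finite(h$loss)))
  expect_lt(h$loss[nrow(h)], h$loss[1])
  ck2 <- train(inst, docs, cfg, training_config("test", max_epochs = 1L,
                                                patience = 1L, seed = 1L))
  expect_equal(ck2$history$loss[1], h$loss[1], tolerance = 1e-12)

  # degenerate set: no positives
  neg <- inst[inst$label == 0L, ]
  expect_error(train(neg, docs, cfg, tc), "positive")
})

test_that("prediction lifts instance decisions to concept pairs", {
  docs <- generate_corpus(small_spec(40L, seed = 61L))
  inst <- build_all(docs)
  ck <- train(inst, docs, model_config("test", seed = 1L),
              training_config("test", max_epochs = 4L, seed = 1L))
  # empty instance list
  p0 <- predict_relations(ck, inst[0, ], docs)
  expect_equal(nrow(p0), 0L)
  preds <- predict_relations(ck, inst, docs)
  # predictions are a subset of candidate pairs
  expect_true(all(paste(preds$doc_id, preds$chemical_id, preds$disease_id) %in%
                    paste(inst$doc_id, inst$chemical_id, inst$disease_id)))
  # threshold at 0.5 equals argmax of the two-class softmax
  expect_true(all(preds$prob > 0.5))
  # checkpoint round trip preserves predictions
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  expect_true(file.exists(paste0(f, ".json")))
  ck2 <- load_checkpoint(f)
  preds2 <- predict_relations(ck2, inst, docs)
  expect_equal(preds, preds2)
})

test_that("ablation grid: single cell, head sweep rows, infeasible cells", {
  corpus <- list(train = generate_corpus(small_spec(24L, seed = 71L)),
                 test = generate_corpus(small_spec(8L, seed = 72L)))
  tc <- training_config("test", max_epochs = 2L, patience = 1L, seed = 1L)
  one <- ablate(list(base = list()), corpus, train_cfg = tc)
  expect_equal(unique(one$cell), "base")
  expect_setequal(one$level, c("intra", "inter", "merged"))

  # head sweep {2,4,5,8,10}: one row set per cell; 5 and 10 do not divide
  # the desk-scale BiLSTM output (32) and are recorded as skipped
  grid <- lapply(c(2L, 4L, 5L, 8L, 10L), function(h) list(n_heads = h))
  names(grid) <- paste0("heads", c(2, 4, 5, 8, 10))
  sweep_ <- ablate(grid, corpus, train_cfg = tc)
  expect_equal(length(unique(sweep_$cell)), 5L)
  expect_equal(sort(unique(sweep_$cell[sweep_$level == "skipped"])),
               c("heads10", "heads5"))
})
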