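# Training loop (Adam on minibatch cross-entropy), prediction, the
# intra/inter/merged evaluation, ablation sweeps, and a bag-of-words
# logistic baseline used as a negative control for the graph branch.

#' Training configuration
#'
#' @param profile `"paper"` mirrors the full-scale optimiser settings
#'   (Adam, learning rate 0.001, minibatch 32); `"test"` uses a smaller
#'   batch and a slightly larger step, suited to the desk-scale nets.
#' @param ... Overrides: `learning_rate`, `batch_size`, `max_epochs`,
#'   `patience` (early stopping on development merged F), `dev_fraction`
#'   (document-level split used when no explicit development set is given),
#'   `seed`.
#' @return A validated list.
#' @export
training_config <- function(profile = c("test", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(learning_rate = 0.001, batch_size = 32L, max_epochs = 30L,
         patience = 5L, dev_fraction = 0.1, seed = 1L)
  } else {
    # patience 5: desk-scale runs can sit at dev F = 0 for the first few
    # epochs before the graph signal emerges; stopping earlier aborts
    # otherwise-converging runs
    list(learning_rate = 0.002, batch_size = 8L, max_epochs = 20L,
         patience = 5L, dev_fraction = 0.1, seed = 1L)
  }
  cfg <- utils::modifyList(cfg, list(...))
  stopifnot(cfg$learning_rate > 0, cfg$batch_size >= 1, cfg$max_epochs >= 1,
            cfg$patience >= 1)
  cfg
}

# -- nested parameter-list arithmetic ---------------------------------------

nested_map <- function(f, x) {
  if (is.list(x)) return(lapply(x, function(e) nested_map(f, e)))
  if (is.null(x)) return(NULL)
  f(x)
}

# Recurse by NAME where available: gradient lists are assembled in a
# different order than the parameter list, so positional matching would
# silently misalign.
nested_map2 <- function(f, a, b) {
  if (is.list(a)) {
    nm <- names(a)
    if (!is.null(nm) && all(nzchar(nm))) {
      out <- lapply(nm, function(k) nested_map2(f, a[[k]], b[[k]]))
      names(out) <- nm
      return(out)
    }
    return(mapply(function(x, y) nested_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  if (is.null(a)) return(NULL)
  f(a, b)
}

adam_init <- function(params) {
  list(m = nested_map(function(x) x * 0, params),
       v = nested_map(function(x) x * 0, params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nested_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- nested_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- nested_map(function(m) m / bc1, state$m)
  vh <- nested_map(function(v) v / bc2, state$v)
  upd <- nested_map2(function(m, v) lr * m / (sqrt(v) + eps), mh, vh)
  params <- nested_map2(`-`, params, upd)
  list(params = params, state = state)
}

# -- instance preparation ----------------------------------------------------

#' Prepare instances for the model
#'
#' Featurises each candidate instance and restricts the document's
#' normalised adjacency to the instance's token window.  The per-document
#' graph and adjacency are computed once and shared across the document's
#' instances.
#'
#' @param instances Output of [build_all()].
#' @param docs List of parsed, aligned `cdr_document`s.
#' @param embedder A `contextual_embedder`.
#' @param tables [embedding_tables()] output.
#' @return List of prepared instances (`X`, `Anorm`, spans, label, ids).
#' @export
prepare_instances <- function(instances, docs, embedder, tables) {
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  adj <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, ]
    doc <- docs[[inst$doc_id]]
    if (is.null(doc)) stopf("instance references unknown document %s", inst$doc_id)
    A <- adj[[inst$doc_id]]
    if (is.null(A)) {
      A <- to_adjacency(build_document_graph(doc))
      adj[[inst$doc_id]] <- A
    }
    X <- featurize(inst, doc, embedder, tables)
    window <- attr(X, "window")
    Anorm <- normalize_adjacency(window_adjacency(A, window))
    list(X = unclass(X), Anorm = Anorm,
         chem_span = attr(X, "chem_span"), dis_span = attr(X, "dis_span"),
         label = inst$label, doc_id = inst$doc_id, level = inst$level,
         chemical_id = inst$chemical_id, disease_id = inst$disease_id)
  })
}

# -- training ----------------------------------------------------------------

#' Train the relation classifier
#'
#' Minimises minibatch cross-entropy over instance labels with Adam.
#' When no explicit development set is given, a document-level fraction of
#' the training documents is held out; the checkpoint with the best
#' development merged F-measure is retained and training stops early after
#' `patience` epochs without improvement.  Fully deterministic given the
#' seeds (single-threaded).
#'
#' @param instances Labelled instances from [build_all()].
#' @param docs Their documents (parsed and aligned).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [training_config()].
#' @param repr_cfg A [repr_config()]; must have `dim_ctx` matching the
#'   embedder.
#' @param embedder Contextual embedder (default: hash embedder from
#'   `repr_cfg`).
#' @param tables Embedding tables (default: from `repr_cfg`).
#' @param dev_instances,dev_docs Optional explicit development split.
#' @return A `cid_checkpoint`: best model, configurations, training history.
#' @export
train <- function(instances, docs, model_cfg = model_config(),
                  train_cfg = training_config(), repr_cfg = repr_config(),
                  embedder = hash_embedder(repr_cfg$dim_ctx, repr_cfg$seed),
                  tables = embedding_tables(repr_cfg),
                  dev_instances = NULL, dev_docs = NULL) {
  if (!nrow(instances)) stopf("no training instances")
  if (!any(instances$label == 1L)) stopf("degenerate training set: no positive instances")
  if (is.null(dev_instances)) {
    ids <- sort(unique(instances$doc_id))
    n_dev <- max(1L, round(length(ids) * train_cfg$dev_fraction))
    dev_ids <- with_local_seed(derive_seed(train_cfg$seed, "devsplit"),
                               sample(ids, n_dev))
    dev_instances <- instances[instances$doc_id %in% dev_ids, , drop = FALSE]
    instances <- instances[!instances$doc_id %in% dev_ids, , drop = FALSE]
    dev_docs <- docs[vapply(docs, `[[`, "", "doc_id") %in% dev_ids]
  }
  preps <- prepare_instances(instances, docs, embedder, tables)
  dev_preps <- prepare_instances(dev_instances, dev_docs, embedder, tables)
  model <- init_model(model_cfg, ncol(preps[[1]]$X))
  gold_dev <- gold_pairs(dev_docs)
  st <- adam_init(model$params)
  best <- list(f = -1, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(), dev_f = numeric())
  with_local_seed(derive_seed(train_cfg$seed, "trainloop"), {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample(length(preps))
      total_loss <- 0
      for (b0 in seq(1L, length(ord), by = train_cfg$batch_size)) {
        batch <- ord[b0:min(b0 + train_cfg$batch_size - 1L, length(ord))]
        gsum <- NULL
        for (k in batch) {
          fwd <- model_forward(model, preps[[k]], train = TRUE)
          bk <- model_backward(model, fwd, preps[[k]]$label)
          total_loss <- total_loss + bk$loss
          gsum <- if (is.null(gsum)) bk$grads else nested_map2(`+`, gsum, bk$grads)
        }
        gavg <- nested_map(function(g) g / length(batch), gsum)
        res <- adam_step(model$params, gavg, st, train_cfg$learning_rate)
        model$params <- res$params
        st <- res$state
      }
      preds <- predict_prepared(model, dev_preps)
      rep_dev <- evaluate(preds, gold_dev, dev_instances)
      dev_f <- rep_dev$f_measure[rep_dev$level == "merged"]
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss = total_loss / length(preps),
                                           dev_f = dev_f))
      log_msg(sprintf("epoch %d: mean loss %.4f, dev merged F %.3f",
                      epoch, total_loss / length(preps), dev_f))
      if (dev_f > best$f + 1e-9) {
        best <- list(f = dev_f, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= train_cfg$patience) {
        log_msg(sprintf("early stop at epoch %d (best dev F %.3f at epoch %d)",
                        epoch, best$f, best$epoch))
        break
      }
    }
  })
  model$params <- best$params
  structure(list(model = model, model_cfg = model_cfg, train_cfg = train_cfg,
                 repr_cfg = tables$config, tables = tables,
                 embedder_spec = embedder_spec(embedder),
                 history = history, best_dev_f = best$f),
            class = "cid_checkpoint")
}

embedder_spec <- function(embedder) {
  if (inherits(embedder, "hash_embedder")) {
    list(kind = "hash", dim = embedder$dim, seed = embedder$seed)
  } else {
    list(kind = class(embedder)[1])
  }
}

rebuild_embedder <- function(spec, fallback = NULL) {
  if (identical(spec$kind, "hash")) return(hash_embedder(spec$dim, spec$seed))
  if (!is.null(fallback)) return(fallback)
  stopf("cannot rebuild embedder of kind '%s'; pass one explicitly", spec$kind)
}

predict_prepared <- function(model, preps) {
  rows <- lapply(preps, function(pr) {
    o <- model_forward(model, pr, train = FALSE)$o
    data.frame(doc_id = pr$doc_id, chemical_id = pr$chemical_id,
               disease_id = pr$disease_id, level = pr$level,
               prob = o[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(doc_id = character(), chemical_id = character(),
                                      disease_id = character(), level = character(),
                                      prob = numeric(), stringsAsFactors = FALSE))
  out[out$prob > 0.5, , drop = FALSE]
}

#' Predict CID relations for candidate instances
#'
#' An instance is predicted positive when its softmax CID probability
#' exceeds 0.5 (equivalently, the argmax of the two-class output); the
#' decision lifts to the concept pair since instance construction emits one
#' instance per pair.
#'
#' @param checkpoint A `cid_checkpoint` from [train()].
#' @param instances Candidate instances from [build_all()].
#' @param docs Their documents.
#' @param embedder Optional embedder override (needed when the checkpoint
#'   was trained with a non-reconstructible embedder).
#' @return `data.frame` of predicted pairs: `doc_id`, `chemical_id`,
#'   `disease_id`, `level`, `prob`.
#' @export
predict_relations <- function(checkpoint, instances, docs, embedder = NULL) {
  if (!nrow(instances)) {
    return(data.frame(doc_id = character(), chemical_id = character(),
                      disease_id = character(), level = character(),
                      prob = numeric(), stringsAsFactors = FALSE))
  }
  emb <- rebuild_embedder(checkpoint$embedder_spec, embedder)
  preps <- prepare_instances(instances, docs, emb, checkpoint$tables)
  predict_prepared(checkpoint$model, preps)
}

#' Gold relation pairs of a corpus as one table
#' @param docs List of `cdr_document`s.
#' @return `data.frame` with `doc_id`, `chemical_id`, `disease_id`.
#' @export
gold_pairs <- function(docs) {
  rows <- lapply(docs, function(d) {
    if (!nrow(d$relations)) return(NULL)
    cbind(doc_id = d$doc_id, d$relations, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), chemical_id = character(),
                      disease_id = character(), stringsAsFactors = FALSE)
  }
  out
}

# -- evaluation --------------------------------------------------------------

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f_measure = f)
}

pair_key <- function(df) paste(df$doc_id, df$chemical_id, df$disease_id, sep = "\r")

#' Evaluate predictions at the intra, inter, and merged levels
#'
#' Each gold pair is assigned to the intrasentence level when its document
#' has an intrasentence instance for it, otherwise to the intersentence
#' level (gold pairs unreachable by instance construction — e.g. removed by
#' the sentence-distance filter — therefore count as false negatives at the
#' intersentence and merged levels).  The merged level scores the union of
#' predictions against all gold pairs.  Micro-averaged precision, recall
#' and F-measure.
#'
#' @param predictions `data.frame` with `doc_id`, `chemical_id`,
#'   `disease_id`, `level`.
#' @param gold `data.frame` with `doc_id`, `chemical_id`, `disease_id`.
#' @param instances The candidate instances (used to assign gold pairs to
#'   levels).
#' @return `data.frame` with one row per level: counts `tp`, `fp`, `fn`
#'   and `precision`, `recall`, `f_measure`.
#' @export
evaluate <- function(predictions, gold, instances) {
  gold <- unique(gold[, c("doc_id", "chemical_id", "disease_id")])
  gk <- pair_key(gold)
  intra_keys <- pair_key(instances[instances$level == "intra", , drop = FALSE])
  gold_level <- ifelse(gk %in% intra_keys, "intra", "inter")
  pred <- unique(predictions[, c("doc_id", "chemical_id", "disease_id", "level")])
  pk <- pair_key(pred)
  rows <- lapply(c("intra", "inter", "merged"), function(lv) {
    if (lv == "merged") {
      g <- gk; p <- pk
    } else {
      g <- gk[gold_level == lv]
      p <- pk[pred$level == lv]
    }
    tp <- sum(p %in% g)
    fp <- length(p) - tp
    fn <- length(g) - tp
    data.frame(level = lv, tp = tp, fp = fp, fn = fn,
               t(prf(tp, fp, fn)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# -- ablation ----------------------------------------------------------------

#' Run an ablation grid
#'
#' Trains and evaluates one model per named cell of the grid, sharing the
#' training seed across cells so differences come from the configuration
#' delta alone.  Infeasible cells (configuration errors) are recorded as
#' skipped.
#'
#' @param grid Named list; each element is a list of [model_config()]
#'   overrides (e.g. `list(n_heads = 4)`, `list(use_gcn = FALSE)`).
#' @param corpus List with `train`, `test` (and optionally `dev`) document
#'   lists.
#' @param base_profile Profile for the shared base configuration.
#' @param train_cfg A [training_config()].
#' @param repr_cfg A [repr_config()].
#' @param max_sentence_distance Passed to instance construction.
#' @return `data.frame`: one row per (cell, level) with metrics, or a
#'   single `skipped` row per infeasible cell.
#' @export
ablate <- function(grid, corpus, base_profile = "test",
                   train_cfg = training_config(), repr_cfg = repr_config(),
                   max_sentence_distance = 3L) {
  train_inst <- build_all(corpus$train, max_sentence_distance)
  test_inst <- build_all(corpus$test, max_sentence_distance)
  dev_inst <- if (!is.null(corpus$dev)) build_all(corpus$dev, max_sentence_distance)
  gold_test <- gold_pairs(corpus$test)
  rows <- lapply(names(grid), function(cell) {
    cfg <- tryCatch(do.call(model_config, c(list(profile = base_profile), grid[[cell]])),
                    error = function(e) e)
    if (inherits(cfg, "error")) {
      log_msg(sprintf("ablation cell '%s' skipped: %s", cell, conditionMessage(cfg)),
              level = "WARN")
      return(data.frame(cell = cell, level = "skipped", tp = NA, fp = NA, fn = NA,
                        precision = NA, recall = NA, f_measure = NA,
                        stringsAsFactors = FALSE))
    }
    ck <- train(train_inst, corpus$train, cfg, train_cfg, repr_cfg,
                dev_instances = dev_inst, dev_docs = corpus$dev)
    preds <- predict_relations(ck, test_inst, corpus$test)
    rep_ <- evaluate(preds, gold_test, test_inst)
    cbind(cell = cell, rep_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# -- bag-of-words logistic baseline -----------------------------------------

#' Bag-of-words logistic-regression baseline
#'
#' Represents each candidate instance by the token counts of its whole
#' document (plus the level flag) and fits a ridge-penalised logistic
#' regression.  By design this baseline cannot see the dependency graph,
#' so on corpora whose labels are decidable only through graph structure it
#' bounds what lexical signal alone achieves.
#'
#' @param train_instances,train_docs Training instances and documents.
#' @param test_instances,test_docs Held-out instances and documents.
#' @param lambda Ridge penalty (default 0.01).
#' @return Predicted-positive pairs, same shape as [predict_relations()].
#' @export
bow_baseline <- function(train_instances, train_docs, test_instances,
                         test_docs, lambda = 0.01) {
  vocab <- sort(unique(unlist(lapply(train_docs, function(d) d$tokens$surface))))
  featurise <- function(instances, docs) {
    names(docs) <- vapply(docs, `[[`, "", "doc_id")
    bags <- lapply(docs, function(d) {
      tab <- table(factor(d$tokens$surface, levels = vocab))
      as.numeric(tab)
    })
    m <- do.call(rbind, bags[instances$doc_id])
    cbind(m, level_inter = as.numeric(instances$level == "inter"))
  }
  x_tr <- featurise(train_instances, train_docs)
  y_tr <- train_instances$label
  fit <- glmnet::glmnet(x_tr, y_tr, family = "binomial", alpha = 0,
                        lambda = lambda)
  x_te <- featurise(test_instances, test_docs)
  prob <- as.numeric(stats::predict(fit, x_te, type = "response"))
  out <- cbind(test_instances[, c("doc_id", "chemical_id", "disease_id", "level")],
               prob = prob)
  out[out$prob > 0.5, , drop = FALSE]
}

# -- checkpoint IO -----------------------------------------------------------

#' Save / load a checkpoint
#'
#' The parameter archive is a single RDS file with a human-readable JSON
#' configuration sidecar (`<path>.json`).
#'
#' @param checkpoint A `cid_checkpoint`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  cfg <- checkpoint$model_cfg
  jsonlite::write_json(
    list(model = unclass(cfg), train = checkpoint$train_cfg,
         repr = checkpoint$repr_cfg, embedder = checkpoint$embedder_spec),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "cid_checkpoint"))
  ck
}
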