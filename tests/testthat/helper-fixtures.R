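# Fixtures are built in code; oracles here are deliberately independent,
# naive re-implementations (loops, traversals, enumerations) of the
# contracts they check.

# Build a document from sentence structures and mention slots, mirroring
# what an external tokenizer + parser would deliver.
make_doc <- function(sentences, mentions = list(), relations = NULL,
                     doc_id = "T1") {
  surf_all <- unlist(lapply(sentences, `[[`, "surface"))
  sizes <- vapply(sentences, function(s) length(s$surface), 1L)
  offsets <- c(0L, cumsum(sizes))
  starts <- integer(length(surf_all))
  pos <- 0L
  for (i in seq_along(surf_all)) {
    starts[i] <- pos
    pos <- pos + nchar(surf_all[i]) + 1L
  }
  ends <- starts + nchar(surf_all)
  title <- paste(sentences[[1]]$surface, collapse = " ")
  abstract <- if (length(sentences) > 1L) {
    paste(unlist(lapply(sentences[-1], `[[`, "surface")), collapse = " ")
  } else ""
  mdf <- do.call(rbind, lapply(mentions, function(m) {
    gi <- offsets[m$sentence] + m$tok
    data.frame(entity_type = m$type, concept_id = m$concept,
               char_start = starts[min(gi)], char_end = ends[max(gi)],
               text = paste(surf_all[gi], collapse = " "),
               sentence_index = NA_integer_, tok_start = NA_integer_,
               tok_end = NA_integer_, stringsAsFactors = FALSE)
  }))
  if (is.null(mdf)) mdf <- docgraphre:::empty_mentions()
  if (is.null(relations)) relations <- docgraphre:::empty_relations()
  doc <- new_document(doc_id, title, abstract, mdf, relations)
  doc$tokens <- data.frame(
    surface = surf_all, char_start = starts, char_end = ends,
    sentence_index = rep(seq_along(sizes) - 1L, sizes),
    pos_tag = unlist(lapply(sentences, function(s) {
      s$pos %||% rep("NOUN", length(s$surface))
    })), stringsAsFactors = FALSE)
  doc$parses <- lapply(sentences, function(s) {
    dr <- s$deprel %||% ifelse(s$head == 0L, "root", "dep")
    list(head = s$head, deprel = dr)
  })
  align_mentions(doc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chain_sentence <- function(words, pos = NULL) {
  list(surface = words, head = c(0L, seq_len(length(words) - 1L)), pos = pos)
}

# The worked instance-construction scenario: chemical D007545 mentioned in
# sentences 1, 2 and 4; disease D006332 in sentences 1-2; disease D006984
# in sentences 4-5; disease D006965 in sentence 5; one gold relation
# (D007545, D006332).
make_fig1_doc <- function() {
  sentences <- list(
    chain_sentence(c("use", "chemA", "causes", "severe", "disB", "often")),
    chain_sentence(c("more", "chemA", "was", "linked", "then", "disB")),
    chain_sentence(c("patients", "were", "observed", "daily", "here")),
    chain_sentence(c("after", "dosing", "chemA", "with", "disC", "signs")),
    chain_sentence(c("later", "disC", "and", "disD", "appeared", "too")))
  mentions <- list(
    list(type = "Chemical", concept = "D007545", sentence = 1, tok = 2),
    list(type = "Disease", concept = "D006332", sentence = 1, tok = 5),
    list(type = "Chemical", concept = "D007545", sentence = 2, tok = 2),
    list(type = "Disease", concept = "D006332", sentence = 2, tok = 6),
    list(type = "Chemical", concept = "D007545", sentence = 4, tok = 3),
    list(type = "Disease", concept = "D006984", sentence = 4, tok = 5),
    list(type = "Disease", concept = "D006984", sentence = 5, tok = 2),
    list(type = "Disease", concept = "D006965", sentence = 5, tok = 4))
  relations <- data.frame(chemical_id = "D007545", disease_id = "D006332",
                          stringsAsFactors = FALSE)
  make_doc(sentences, mentions, relations, doc_id = "6203632")
}

small_spec <- function(n_docs = 20L, seed = 1L, ...) {
  synthetic_spec(n_docs = n_docs, seed = seed, ...)
}

# --- independent oracles ----------------------------------------------------

# Brute-force instance construction over all mention pairs.
oracle_instances <- function(doc, max_sentence_distance = 3L) {
  m <- doc$mentions
  chem <- which(m$entity_type == "Chemical")
  dis <- which(m$entity_type == "Disease")
  out <- list()
  for (cid in unique(m$concept_id[chem])) {
    for (did in unique(m$concept_id[dis])) {
      cms <- chem[m$concept_id[chem] == cid]
      dms <- dis[m$concept_id[dis] == did]
      lex_better <- function(key, best) {
        if (is.null(best)) return(TRUE)
        for (k in seq_along(key)) {
          if (key[k] < best$key[k]) return(TRUE)
          if (key[k] > best$key[k]) return(FALSE)
        }
        FALSE
      }
      best <- NULL
      co_sent <- FALSE
      for (ci in cms) for (di in dms) {
        sd_ <- abs(m$sentence_index[ci] - m$sentence_index[di])
        td <- abs((m$tok_start[ci] + m$tok_end[ci]) / 2 -
                    (m$tok_start[di] + m$tok_end[di]) / 2)
        if (sd_ == 0) co_sent <- TRUE
        key <- c(sd_, td, m$tok_start[ci], m$tok_start[di])
        if (lex_better(key, best)) best <- list(key = key, ci = ci, di = di)
      }
      if (co_sent) {
        # redo restricted to co-sentential pairs, token distance primary
        best <- NULL
        for (ci in cms) for (di in dms) {
          if (m$sentence_index[ci] != m$sentence_index[di]) next
          td <- abs((m$tok_start[ci] + m$tok_end[ci]) / 2 -
                      (m$tok_start[di] + m$tok_end[di]) / 2)
          key <- c(td, m$tok_start[ci], m$tok_start[di])
          if (lex_better(key, best)) best <- list(key = key, ci = ci, di = di)
        }
        level <- "intra"
      } else {
        if (best$key[1] > max_sentence_distance) next
        level <- "inter"
      }
      lab <- as.integer(any(doc$relations$chemical_id == cid &
                              doc$relations$disease_id == did))
      out[[length(out) + 1L]] <- data.frame(
        doc_id = doc$doc_id, level = level, chemical_id = cid,
        disease_id = did, chem_tok_start = m$tok_start[best$ci],
        dis_tok_start = m$tok_start[best$di], label = lab,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(df)
  df[order(df$level, df$chemical_id, df$disease_id), ]
}

# BFS reachability over an edge list.
oracle_connected <- function(n, edges_i, edges_j) {
  adj <- vector("list", n)
  for (k in seq_along(edges_i)) {
    adj[[edges_i[k]]] <- c(adj[[edges_i[k]]], edges_j[k])
    adj[[edges_j[k]]] <- c(adj[[edges_j[k]]], edges_i[k])
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
  }
  all(seen)
}

# Tree check by traversal from the root.
oracle_is_tree <- function(head) {
  n <- length(head)
  if (sum(head == 0L) != 1L) return(FALSE)
  children <- vector("list", n)
  for (i in seq_len(n)) if (head[i] != 0L) {
    children[[head[i]]] <- c(children[[head[i]]], i)
  }
  root <- which(head == 0L)
  seen <- logical(n)
  stack <- root
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[u]) return(FALSE)
    seen[u] <- TRUE
    stack <- c(stack, children[[u]])
  }
  all(seen)
}

# Naive per-node GCN layer (double loop).
oracle_gcn_layer <- function(H_in, A, W, b) {
  n <- nrow(A)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    acc <- numeric(ncol(W))
    d <- 0
    for (j in seq_len(n)) {
      if (A[i, j] != 0) {
        acc <- acc + as.vector(t(W) %*% H_in[j, ])
        d <- d + 1
      }
    }
    out[i, ] <- pmax(acc / d + b, 0)
  }
  out
}

# Scalar re-implementation of the LSTM step equations.
oracle_lstm <- function(X, W, U, b) {
  Hd <- ncol(U)
  n <- nrow(X)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(Hd); cc <- numeric(Hd)
  out <- matrix(0, n, Hd)
  for (t in seq_len(n)) {
    a <- as.vector(W %*% X[t, ]) + as.vector(U %*% h) + b
    i_t <- sig(a[1:Hd])
    f_t <- sig(a[(Hd + 1):(2 * Hd)])
    g_t <- tanh(a[(2 * Hd + 1):(3 * Hd)])
    o_t <- sig(a[(3 * Hd + 1):(4 * Hd)])
    cc <- f_t * cc + i_t * g_t
    h <- o_t * tanh(cc)
    out[t, ] <- h
  }
  out
}

# Independent confusion counting.
oracle_prf <- function(pred_keys, gold_keys) {
  tp <- 0
  for (k in pred_keys) if (k %in% gold_keys) tp <- tp + 1
  fp <- length(pred_keys) - tp
  fn <- length(gold_keys) - tp
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, p = p, r = r, f = f)
}

# Shared end-to-end corpus for the acceptance tests (generated once).
e2e_env <- new.env(parent = emptyenv())
get_e2e_corpus <- function() {
  if (is.null(e2e_env$corpus)) {
    e2e_env$corpus <- list(
      train = generate_corpus(synthetic_spec(n_docs = 300L, seed = 101L)),
      test = generate_corpus(synthetic_spec(n_docs = 100L, seed = 102L)))
  }
  e2e_env$corpus
}
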