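# Synthetic desk-scale corpora.
#
# Emulates the shape of a PubTator-distributed CID corpus: multi-sentence
# abstracts with random single-rooted dependency trees, single-token
# chemical/disease mentions carrying MeSH-style concept ids, and gold
# relations decided by a planted rule:
#   lexical          a trigger token linearly adjacent to the instance's
#                    chemical mention;
#   dependency_path  a trigger token on the (unique) document-graph path
#                    between the instance's mention pair.
# Every candidate instance receives exactly one trigger token: positives on
# the path (as close to the disease mention as possible), negatives at an
# off-path decoy position matched in linear proximity to the disease.  The
# per-document trigger count is therefore independent of the labels, so a
# bag-of-words model cannot read the labels off token counts — only the
# graph (or adjacency) structure separates the classes.  Labels are finally
# RE-DERIVED from the rule on the finished document, so the stated rule is
# the ground truth even in rare collision cases.

#' Specification of a synthetic corpus
#'
#' @param n_docs Number of documents.
#' @param sentences_range Inclusive range of sentences per document (min
#'   must be >= 2 when `inter_fraction > 0`).
#' @param tokens_range Inclusive range of tokens per sentence (min 5).
#' @param n_chemicals,n_diseases Concepts per document.
#' @param mentions_per_concept Inclusive range of mentions per concept
#'   (extra mentions exercise the nearest-mention heuristics).
#' @param p_positive Target probability that a candidate pair is positive.
#' @param inter_fraction Share of disease concepts realised only
#'   cross-sentence.
#' @param max_inter_distance Largest planted sentence distance for
#'   cross-sentence pairs.
#' @param trigger_rule `"dependency_path"` (default; solvable only through
#'   the graph) or `"lexical"` (solvable from linear adjacency).
#' @param seed Integer seed; the generator is bitwise reproducible.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_docs = 50L, sentences_range = c(3L, 6L),
                           tokens_range = c(6L, 10L), n_chemicals = 1L,
                           n_diseases = 2L, mentions_per_concept = c(1L, 2L),
                           p_positive = 0.35, inter_fraction = 0.4,
                           max_inter_distance = 3L,
                           trigger_rule = c("dependency_path", "lexical"),
                           seed = 1L) {
  trigger_rule <- match.arg(trigger_rule)
  if (p_positive < 0 || p_positive > 1 || inter_fraction < 0 || inter_fraction > 1) {
    stopf("probabilities must lie in [0,1]")
  }
  if (sentences_range[1] > sentences_range[2] || tokens_range[1] > tokens_range[2]) {
    stopf("empty range")
  }
  if (inter_fraction > 0 && sentences_range[1] < 2L) {
    stopf("inter_fraction > 0 requires at least 2 sentences per document")
  }
  if (tokens_range[1] < 5L) stopf("tokens_range minimum must be >= 5")
  structure(list(n_docs = as.integer(n_docs),
                 sentences_range = as.integer(sentences_range),
                 tokens_range = as.integer(tokens_range),
                 n_chemicals = as.integer(n_chemicals),
                 n_diseases = as.integer(n_diseases),
                 mentions_per_concept = as.integer(mentions_per_concept),
                 p_positive = p_positive, inter_fraction = inter_fraction,
                 max_inter_distance = as.integer(max_inter_distance),
                 trigger_rule = trigger_rule, seed = as.integer(seed)),
            class = "synthetic_spec")
}

trigger_word <- function() "induceX"

synthetic_lexicon <- function() {
  c(sprintf("w%03d", 1:180),
    "the", "a", "of", "in", "with", "was", "were", "and", "after", "during",
    "patient", "doses", "mg", "daily", "observed", "reported", "case",
    "treatment", "therapy", "onset")
}

deprel_set <- function() {
  c("nsubj", "obj", "obl", "amod", "advmod", "nmod", "det", "case", "conj", "dep")
}

# Random recursive tree on m nodes rooted at node 1, resampled until it has
# at least `min_leaves` leaves (mention slots must be leaves).
random_tree <- function(m, min_leaves = 4L) {
  for (try in 1:200) {
    head <- integer(m)
    if (m > 1L) head[2:m] <- vapply(2:m, function(k) sample.int(k - 1L, 1L), 1L)
    leaves <- setdiff(which(!(seq_len(m) %in% head)), 1L)
    if (length(leaves) >= min_leaves) {
      return(list(head = head, leaves = leaves))
    }
  }
  stopf("could not sample a tree with %d leaves on %d nodes", min_leaves, m)
}

# Document-level parent vector: dependency heads within sentences, roots of
# sentence k>1 attached to the root of sentence k-1 (0 for the first root).
# This is exactly the spanning structure of the document graph minus self
# loops, so paths in it are the unique document-graph paths.
doc_parents <- function(doc) {
  n_sent <- length(doc$parses)
  sizes <- vapply(doc$parses, function(p) length(p$head), 1L)
  offsets <- c(0L, cumsum(sizes))
  parents <- integer(sum(sizes))
  prev_root <- 0L
  for (s in seq_len(n_sent)) {
    h <- doc$parses[[s]]$head
    root <- which(h == 0L)
    parents[offsets[s] + seq_along(h)] <- ifelse(h == 0L, 0L, offsets[s] + h)
    parents[offsets[s] + root] <- prev_root
    prev_root <- offsets[s] + root
  }
  parents
}

# Unique path (inclusive) between two nodes of the parent tree.
tree_path <- function(parents, u, v) {
  anc_u <- u
  j <- u
  while (parents[j] != 0L) { j <- parents[j]; anc_u <- c(anc_u, j) }
  anc_u <- c(anc_u, 0L)
  path_v <- v
  j <- v
  while (!(j %in% anc_u)) { j <- parents[j]; path_v <- c(path_v, j) }
  meet <- j
  up_u <- anc_u[seq_len(match(meet, anc_u))]
  c(up_u, rev(path_v[-length(path_v)]))
}

#' Evaluate the planted decision rule on a finished document
#'
#' @param doc A generated, aligned `cdr_document`.
#' @param instance One instance row (from [build_all()]).
#' @param rule `"dependency_path"` or `"lexical"`.
#' @return 0/1 label.
#' @export
trigger_label <- function(doc, instance, rule) {
  surf <- doc$tokens$surface
  if (rule == "lexical") {
    nb <- c(instance$chem_tok_start - 1L, instance$chem_tok_end + 1L)
    nb <- nb[nb >= 1L & nb <= length(surf)]
    return(as.integer(any(surf[nb] == trigger_word())))
  }
  parents <- doc_parents(doc)
  path <- tree_path(parents, instance$chem_tok_start, instance$dis_tok_start)
  as.integer(any(surf[path] == trigger_word()))
}

# Materialise sentence structures into a cdr_document.
materialize_doc <- function(doc_id, sentences, mention_slots, relations) {
  surf_all <- unlist(lapply(sentences, `[[`, "surface"))
  sizes <- vapply(sentences, function(s) length(s$surface), 1L)
  offsets <- c(0L, cumsum(sizes))
  starts <- integer(length(surf_all))
  pos <- 0L
  for (i in seq_along(surf_all)) {
    starts[i] <- pos
    pos <- pos + nchar(surf_all[i]) + 1L  # single joining space
  }
  ends <- starts + nchar(surf_all)
  sent_idx <- rep(seq_along(sizes) - 1L, sizes)
  title <- paste(sentences[[1]]$surface, collapse = " ")
  abstract <- if (length(sentences) > 1L) {
    paste(unlist(lapply(sentences[-1], `[[`, "surface")), collapse = " ")
  } else ""
  mentions <- empty_mentions()
  for (ms in mention_slots) {
    gi <- offsets[ms$sentence] + ms$tok
    mentions <- rbind(mentions, data.frame(
      entity_type = ms$entity_type, concept_id = ms$concept_id,
      char_start = starts[gi], char_end = ends[gi], text = surf_all[gi],
      sentence_index = NA_integer_, tok_start = NA_integer_,
      tok_end = NA_integer_, stringsAsFactors = FALSE))
  }
  if (nrow(mentions)) {
    # canonical order (matches write_pubtator output)
    mentions <- mentions[order(mentions$char_start, mentions$char_end,
                               mentions$entity_type, mentions$concept_id), ]
    rownames(mentions) <- NULL
  }
  doc <- new_document(doc_id, title, abstract, mentions, relations)
  doc$tokens <- data.frame(surface = surf_all, char_start = starts,
                           char_end = ends, sentence_index = sent_idx,
                           pos_tag = unlist(lapply(sentences, `[[`, "pos")),
                           stringsAsFactors = FALSE)
  doc$parses <- lapply(sentences, function(s) list(head = s$head, deprel = s$deprel))
  align_mentions(doc)
}

generate_document <- function(spec, d) {
  with_local_seed(derive_seed(spec$seed, paste0("doc", d)), {
    # Labels are drawn once per document and held fixed across structure
    # retries: rejecting structures (not labels) keeps the realised
    # positive rate an unbiased Bernoulli(p_positive) sample.
    planted_flags <- stats::runif(spec$n_chemicals * spec$n_diseases) < spec$p_positive
    for (attempt in 1:50) {
      doc <- try(generate_document_once(spec, d, planted_flags), silent = TRUE)
      if (!inherits(doc, "try-error")) return(doc)
    }
    stopf("document generation failed repeatedly: %s",
          attr(doc, "condition")$message)
  })
}

generate_document_once <- function(spec, d, planted_flags) {
  S <- sample(spec$sentences_range[1]:spec$sentences_range[2], 1L)
  lex <- synthetic_lexicon()
  pos_tags <- upos_subset()
  sentences <- lapply(seq_len(S), function(s) {
    m <- sample(spec$tokens_range[1]:spec$tokens_range[2], 1L)
    tr <- random_tree(m)
    dr <- sample(deprel_set(), m, replace = TRUE)
    dr[tr$head == 0L] <- "root"
    list(surface = sample(lex, m, replace = TRUE),
         pos = sample(pos_tags, m, replace = TRUE),
         head = tr$head, deprel = dr,
         leaves = tr$leaves, free_leaves = tr$leaves)
  })

  concept_ids <- sprintf("D%06d", sample.int(999999L, spec$n_chemicals + spec$n_diseases))
  chem_ids <- concept_ids[seq_len(spec$n_chemicals)]
  dis_ids <- concept_ids[spec$n_chemicals + seq_len(spec$n_diseases)]

  take_slot <- function(s) {
    free <- sentences[[s]]$free_leaves
    if (!length(free)) return(NA_integer_)
    tok <- if (length(free) == 1L) free else sample(free, 1L)
    sentences[[s]]$free_leaves <<- setdiff(free, tok)
    tok
  }
  mention_slots <- list()
  add_mention <- function(type, id, s) {
    tok <- take_slot(s)
    if (is.na(tok)) stopf("no free leaf slot in sentence %d", s)
    surfid <- paste0(if (type == "Chemical") "chem" else "dis", substr(id, 2L, 7L))
    sentences[[s]]$surface[tok] <<- surfid
    sentences[[s]]$pos[tok] <<- "PROPN"
    mention_slots[[length(mention_slots) + 1L]] <<-
      list(entity_type = type, concept_id = id, sentence = s, tok = tok)
    invisible(s)
  }

  n_mentions <- function() sample(spec$mentions_per_concept[1]:spec$mentions_per_concept[2], 1L)
  chem_sents <- integer()
  for (id in chem_ids) {
    for (k in seq_len(n_mentions())) {
      s <- sample.int(S, 1L)
      add_mention("Chemical", id, s)
      chem_sents <- union(chem_sents, s)
    }
  }
  inter_sents <- integer()
  for (id in dis_ids) {
    inter <- stats::runif(1) < spec$inter_fraction
    if (inter) {
      cand <- setdiff(seq_len(S), chem_sents)
      cand <- cand[vapply(cand, function(s) min(abs(s - chem_sents)), 1) <=
                     spec$max_inter_distance]
      if (!length(cand)) stopf("no sentence available for cross-sentence disease")
      s <- if (length(cand) == 1L) cand else sample(cand, 1L)
      add_mention("Disease", id, s)
      inter_sents <- union(inter_sents, s)
    } else {
      s <- if (length(chem_sents) == 1L) chem_sents else sample(chem_sents, 1L)
      add_mention("Disease", id, s)
      for (k in seq_len(n_mentions() - 1L)) {
        cand <- setdiff(seq_len(S), inter_sents)
        s2 <- if (length(cand) == 1L) cand else sample(cand, 1L)
        ok <- try(add_mention("Disease", id, s2), silent = TRUE)
      }
    }
  }

  # Provisional document (labels unknown): instance selection only depends
  # on token indices, which trigger planting does not move.
  doc0 <- materialize_doc(as.character(d), sentences, mention_slots,
                          empty_relations())
  inst <- build_all(doc0, spec$max_inter_distance)
  parents <- doc_parents(doc0)
  sizes <- vapply(sentences, function(s) length(s$surface), 1L)
  offsets <- c(0L, cumsum(sizes))
  glob2loc <- function(g) {
    s <- findInterval(g - 1L, offsets[-length(offsets)], rightmost.closed = FALSE)
    c(s, g - offsets[s])
  }
  mention_tokens <- offsets[vapply(mention_slots, `[[`, 1L, "sentence")] +
    vapply(mention_slots, `[[`, 1L, "tok")
  roots <- vapply(seq_len(S), function(s) {
    offsets[s] + which(sentences[[s]]$head == 0L)
  }, 1L)
  all_paths <- lapply(seq_len(nrow(inst)), function(i) {
    tree_path(parents, inst$chem_tok_start[i], inst$dis_tok_start[i])
  })
  set_trigger <- function(g) {
    loc <- glob2loc(g)
    sentences[[loc[1]]]$surface[loc[2]] <<- trigger_word()
    sentences[[loc[1]]]$pos[loc[2]] <<- "VERB"
  }
  protected <- unique(c(mention_tokens, unlist(all_paths), roots))
  if (length(planted_flags) != nrow(inst)) {
    stopf("instance count %d != expected pair count %d", nrow(inst),
          length(planted_flags))
  }
  # A positive's trigger is steered away from the paths of negative-
  # designated pairs so the drawn labels are realised exactly.
  neg_union <- unique(unlist(all_paths[!planted_flags]))
  for (i in seq_len(nrow(inst))) {
    planted <- planted_flags[i]
    if (spec$trigger_rule == "dependency_path") {
      if (planted) {
        interior <- setdiff(all_paths[[i]],
                            c(inst$chem_tok_start[i], inst$dis_tok_start[i]))
        if (!length(interior)) stopf("degenerate path for instance %d", i)
        pref <- setdiff(interior, c(neg_union, mention_tokens))
        cand <- if (length(pref)) pref else setdiff(interior, mention_tokens)
        # closest to the disease end of the path
        ord <- match(cand, rev(all_paths[[i]]))
        set_trigger(cand[which.min(ord)])
      } else {
        dsent <- doc0$tokens$sentence_index[inst$dis_tok_start[i]] + 1L
        cand <- (offsets[dsent] + 1L):offsets[dsent + 1L]
        cand <- setdiff(cand, protected)
        if (!length(cand)) cand <- setdiff(seq_len(sum(sizes)), protected)
        if (!length(cand)) stopf("no decoy position available")
        g <- if (length(cand) == 1L) cand else sample(cand, 1L)
        set_trigger(g)
        protected <- c(protected, g)  # decoys must not stack on one token
      }
    } else {  # lexical: trigger next to the chemical mention
      if (planted) {
        nb <- c(inst$chem_tok_start[i] - 1L, inst$chem_tok_end[i] + 1L)
        nb <- setdiff(nb[nb >= 1L & nb <= sum(sizes)], mention_tokens)
        if (!length(nb)) stopf("no linear neighbour available")
        set_trigger(nb[1])
      } else {
        chem_nb <- unique(c(mention_tokens - 1L, mention_tokens + 1L))
        cand <- setdiff(seq_len(sum(sizes)), c(protected, chem_nb))
        if (!length(cand)) stopf("no decoy position available")
        g <- if (length(cand) == 1L) cand else sample(cand, 1L)
        set_trigger(g)
        protected <- c(protected, g)
      }
    }
  }

  # Final labels come from the rule itself, evaluated on the finished text.
  doc1 <- materialize_doc(as.character(d), sentences, mention_slots,
                          empty_relations())
  labels <- vapply(seq_len(nrow(inst)), function(i) {
    trigger_label(doc1, inst[i, ], spec$trigger_rule)
  }, 1L)
  if (spec$trigger_rule == "dependency_path" &&
        !all(labels == as.integer(planted_flags))) {
    # A positive's trigger unavoidably fell on a negative pair's path (the
    # negative's path can swallow the whole positive path).  Reject and
    # regenerate so the realised positive rate stays at p_positive.
    stopf("planting collision; rejecting document")
  }
  rel <- inst[labels == 1L, c("chemical_id", "disease_id"), drop = FALSE]
  rownames(rel) <- NULL
  materialize_doc(as.character(d), sentences, mention_slots, rel)
}

#' Generate a synthetic corpus
#'
#' Deterministic given the spec (same spec and seed produce byte-identical
#' PubTator and CoNLL-U serialisations).  Documents come with tokens,
#' parses, aligned mentions and gold relations attached.
#'
#' @param spec A [synthetic_spec()].
#' @return List of `cdr_document`s.
#' @export
generate_corpus <- function(spec) {
  lapply(seq_len(spec$n_docs), function(d) generate_document(spec, d))
}

#' Summary statistics of a corpus
#'
#' Counts documents, mentions, gold relations, and intra/inter candidate
#' instances (with the positive rate among instances).  Invariant to
#' document order.
#'
#' @param docs List of `cdr_document`s.
#' @param max_sentence_distance Passed to instance construction.
#' @return One-row `data.frame`.
#' @export
corpus_stats <- function(docs, max_sentence_distance = 3L) {
  if (!length(docs)) {
    return(data.frame(n_docs = 0L, n_mentions = 0L, n_relations = 0L,
                      n_intra = 0L, n_inter = 0L, n_instances = 0L,
                      positive_rate = NA_real_))
  }
  inst <- build_all(docs, max_sentence_distance)
  data.frame(
    n_docs = length(docs),
    n_mentions = sum(vapply(docs, function(d) nrow(d$mentions), 1L)),
    n_relations = sum(vapply(docs, function(d) nrow(d$relations), 1L)),
    n_intra = sum(inst$level == "intra"),
    n_inter = sum(inst$level == "inter"),
    n_instances = nrow(inst),
    positive_rate = if (nrow(inst)) mean(inst$label) else NA_real_)
}
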