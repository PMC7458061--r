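# Candidate-instance construction.
#
# A candidate instance is one (chemical concept, disease concept) pair per
# document, realised by a single representative mention pair:
#   * intrasentence: the concepts co-occur in >=1 sentence; the co-sentential
#     mention pair with the smallest token distance (between span midpoints)
#     represents the pair;
#   * intersentence: the concepts never co-occur in a sentence; the mention
#     pair with the smallest sentence distance (ties: token distance, then
#     earliest chemical, then earliest disease mention) represents the pair,
#     and pairs farther apart than `max_sentence_distance` sentences are
#     dropped entirely.
# An instance is positive iff its concept pair is a gold CID relation.

instance_columns <- function() {
  data.frame(doc_id = character(), level = character(),
             chemical_id = character(), disease_id = character(),
             chem_tok_start = integer(), chem_tok_end = integer(),
             dis_tok_start = integer(), dis_tok_end = integer(),
             chem_sentence = integer(), dis_sentence = integer(),
             sentence_distance = integer(), token_distance = numeric(),
             label = integer(), stringsAsFactors = FALSE)
}

mention_pairs <- function(doc) {
  m <- doc$mentions
  if (any(is.na(m$tok_start))) {
    stopf("document %s: mentions not aligned (call align_mentions first)", doc$doc_id)
  }
  chem <- which(m$entity_type == "Chemical")
  dis <- which(m$entity_type == "Disease")
  if (!length(chem) || !length(dis)) return(NULL)
  g <- expand.grid(ci = chem, di = dis)
  mid <- (m$tok_start + m$tok_end) / 2
  data.frame(
    chemical_id = m$concept_id[g$ci], disease_id = m$concept_id[g$di],
    chem_tok_start = m$tok_start[g$ci], chem_tok_end = m$tok_end[g$ci],
    dis_tok_start = m$tok_start[g$di], dis_tok_end = m$tok_end[g$di],
    chem_sentence = m$sentence_index[g$ci], dis_sentence = m$sentence_index[g$di],
    sentence_distance = abs(m$sentence_index[g$ci] - m$sentence_index[g$di]),
    token_distance = abs(mid[g$ci] - mid[g$di]),
    stringsAsFactors = FALSE)
}

# Deterministic nearest-pair selection within one concept pair's rows.
pick_nearest <- function(rows, by_sentence) {
  keys <- if (by_sentence) {
    order(rows$sentence_distance, rows$token_distance,
          rows$chem_tok_start, rows$dis_tok_start)
  } else {
    order(rows$token_distance, rows$chem_tok_start, rows$dis_tok_start)
  }
  rows[keys[1], , drop = FALSE]
}

label_pairs <- function(rows, relations) {
  if (!nrow(rows)) return(integer())
  key <- paste(rows$chemical_id, rows$disease_id, sep = "\r")
  gold <- paste(relations$chemical_id, relations$disease_id, sep = "\r")
  as.integer(key %in% gold)
}

#' Build intrasentence candidate instances for one document
#'
#' One instance per chemical/disease concept pair that co-occurs in at
#' least one sentence, realised by the co-sentential mention pair with the
#' smallest token distance.
#'
#' @param doc An aligned `cdr_document`.
#' @return A `data.frame` of instances (possibly empty), one row per pair.
#' @export
construct_intra <- function(doc) {
  pairs <- mention_pairs(doc)
  out <- instance_columns()
  if (is.null(pairs)) return(out)
  co <- pairs[pairs$sentence_distance == 0L, , drop = FALSE]
  if (!nrow(co)) return(out)
  for (key in unique(paste(co$chemical_id, co$disease_id, sep = "\r"))) {
    rows <- co[paste(co$chemical_id, co$disease_id, sep = "\r") == key, , drop = FALSE]
    best <- pick_nearest(rows, by_sentence = FALSE)
    out <- rbind(out, cbind(doc_id = doc$doc_id, level = "intra", best,
                            label = NA_integer_, stringsAsFactors = FALSE))
  }
  out$label <- label_pairs(out, doc$relations)
  rownames(out) <- NULL
  out[order(out$chemical_id, out$disease_id), c(names(instance_columns()))]
}

#' Build intersentence candidate instances for one document
#'
#' Considers only concept pairs with no sentential co-occurrence anywhere
#' in the document; each is realised by the mention pair minimising
#' sentence distance (ties broken by token distance, then earliest
#' chemical, then earliest disease mention).  Pairs whose minimal sentence
#' distance exceeds `max_sentence_distance` are dropped — the same filter
#' the method applies to bound cross-sentence candidates.
#'
#' @param doc An aligned `cdr_document`.
#' @param max_sentence_distance Maximum allowed sentence separation
#'   (default 3).
#' @return A `data.frame` of instances, one row per surviving pair.
#' @export
construct_inter <- function(doc, max_sentence_distance = 3L) {
  pairs <- mention_pairs(doc)
  out <- instance_columns()
  if (is.null(pairs)) return(out)
  key <- paste(pairs$chemical_id, pairs$disease_id, sep = "\r")
  co_keys <- unique(key[pairs$sentence_distance == 0L])
  cross <- pairs[!(key %in% co_keys), , drop = FALSE]
  if (!nrow(cross)) return(out)
  for (k in unique(paste(cross$chemical_id, cross$disease_id, sep = "\r"))) {
    rows <- cross[paste(cross$chemical_id, cross$disease_id, sep = "\r") == k, , drop = FALSE]
    best <- pick_nearest(rows, by_sentence = TRUE)
    if (best$sentence_distance > max_sentence_distance) next
    out <- rbind(out, cbind(doc_id = doc$doc_id, level = "inter", best,
                            label = NA_integer_, stringsAsFactors = FALSE))
  }
  if (!nrow(out)) return(instance_columns())
  out$label <- label_pairs(out, doc$relations)
  rownames(out) <- NULL
  out[order(out$chemical_id, out$disease_id), c(names(instance_columns()))]
}

#' Build all candidate instances for a corpus
#'
#' Concatenates per-document intrasentence and intersentence instances in
#' a deterministic order (document id, level, concept pair).
#'
#' @param docs List of aligned `cdr_document`s.
#' @param max_sentence_distance Passed to [construct_inter()].
#' @return A `data.frame` of candidate instances.
#' @export
build_all <- function(docs, max_sentence_distance = 3L) {
  if (inherits(docs, "cdr_document")) docs <- list(docs)
  parts <- lapply(docs, function(d) {
    rbind(construct_intra(d), construct_inter(d, max_sentence_distance))
  })
  out <- do.call(rbind, c(list(instance_columns()), parts))
  out <- out[order(out$doc_id, out$level, out$chemical_id, out$disease_id), ]
  rownames(out) <- NULL
  out
}

#' Serialise instances as TSV
#'
#' @param instances Output of [build_all()].
#' @param path Optional file path.
#' @return TSV text, invisibly when `path` is given.
#' @export
instances_to_tsv <- function(instances, path = NULL) {
  con <- textConnection("tsv", "w", local = TRUE)
  utils::write.table(instances, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  txt <- paste0(paste(tsv, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
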