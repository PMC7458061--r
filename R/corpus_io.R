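# PubTator / CoNLL-U corpus IO and mention-token alignment.
#
# Conventions (stated once, used everywhere):
#   * character offsets are 0-based, end-exclusive, indexing the joined
#     "title + single space + abstract" document text (PubTator convention);
#   * token spans are inclusive intervals of 1-based document-level token
#     indices (R convention);
#   * sentence indices are 0-based to match the CoNLL-U block order.

#' Construct a document object
#'
#' A `cdr_document` bundles one abstract: its raw text, tokenization and
#' part-of-speech tags (attached from CoNLL-U), typed entity mentions with
#' MeSH concept identifiers, gold chemical-induced-disease (CID) relations,
#' and one dependency parse per sentence.
#'
#' @param doc_id Document identifier (PMID for real corpora).
#' @param title,abstract Title and abstract text; the document text is their
#'   concatenation with a single separating space.
#' @param mentions `data.frame` with columns `entity_type` ("Chemical" or
#'   "Disease"), `concept_id`, `char_start`, `char_end` (0-based,
#'   end-exclusive), `text`.
#' @param relations `data.frame` with columns `chemical_id`, `disease_id`.
#' @param tokens Optional token table (usually attached by [read_conllu()]).
#' @param parses Optional list of per-sentence dependency parses.
#' @return An object of class `cdr_document`.
#' @export
new_document <- function(doc_id, title, abstract = "",
                         mentions = empty_mentions(),
                         relations = empty_relations(),
                         tokens = NULL, parses = NULL) {
  text <- if (nzchar(abstract)) paste(title, abstract) else title
  doc <- structure(
    list(doc_id = as.character(doc_id), title = title, abstract = abstract,
         text = text, mentions = mentions, relations = relations,
         tokens = tokens, parses = parses),
    class = "cdr_document")
  validate_document(doc)
}

empty_mentions <- function() {
  data.frame(entity_type = character(), concept_id = character(),
             char_start = integer(), char_end = integer(),
             text = character(), sentence_index = integer(),
             tok_start = integer(), tok_end = integer(),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(chemical_id = character(), disease_id = character(),
             stringsAsFactors = FALSE)
}

#' Validate a document's internal invariants
#'
#' Checks mention offsets against the text, relation uniqueness, and (when
#' parses are attached) the per-sentence tree property.
#'
#' @param doc A `cdr_document`.
#' @return The document, invisibly usable in pipelines; errors on violation.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "cdr_document"))
  m <- doc$mentions
  if (nrow(m)) {
    if (any(m$char_start < 0 | m$char_end > nchar(doc$text) |
              m$char_start >= m$char_end)) {
      stopf("document %s: mention offsets outside text", doc$doc_id)
    }
    if (!all(m$entity_type %in% c("Chemical", "Disease"))) {
      stopf("document %s: unknown entity type", doc$doc_id)
    }
    if (any(!nzchar(m$concept_id))) {
      stopf("document %s: empty concept id", doc$doc_id)
    }
  }
  r <- doc$relations
  if (nrow(r) && anyDuplicated(paste(r$chemical_id, r$disease_id))) {
    stopf("document %s: duplicate gold relation", doc$doc_id)
  }
  if (!is.null(doc$parses)) {
    for (k in seq_along(doc$parses)) check_tree(doc$parses[[k]]$head, doc$doc_id, k)
  }
  doc
}

#' @export
print.cdr_document <- function(x, ...) {
  cat(sprintf("<cdr_document %s: %d chars, %s sentences, %d mentions, %d relations>\n",
              x$doc_id, nchar(x$text),
              if (is.null(x$tokens)) "?" else length(unique(x$tokens$sentence_index)),
              nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

n_sentences <- function(doc) {
  if (is.null(doc$tokens)) 0L else length(unique(doc$tokens$sentence_index))
}

# Verify that a 1-based head vector (0 = root) encodes a single-rooted tree:
# exactly one root, every node reaches the root, no cycles.
check_tree <- function(head, doc_id = "?", sent = NA) {
  n <- length(head)
  if (sum(head == 0L) != 1L) {
    stopf("document %s sentence %s: expected exactly one root", doc_id, sent)
  }
  if (any(head < 0L | head > n)) {
    stopf("document %s sentence %s: head index out of range", doc_id, sent)
  }
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (head[j] != 0L) {
      if (seen[j]) stopf("document %s sentence %s: cycle in dependency heads",
                         doc_id, sent)
      seen[j] <- TRUE
      j <- head[j]
    }
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# PubTator

#' Read a PubTator-format corpus
#'
#' Parses the plain-text dialect used to distribute the BioCreative V CDR
#' corpus: per document a `PMID|t|title` line, a `PMID|a|abstract` line,
#' tab-separated mention lines (`PMID start end text type conceptID`) and
#' relation lines (`PMID CID chemicalID diseaseID`), with documents
#' separated by blank lines.  Mentions whose concept is `-1` (unnormalised)
#' are dropped; composite concept fields (`D1|D2` or `D1+D2`) are expanded
#' into one mention per concept; duplicate relation lines are deduplicated
#' with a logged warning.
#'
#' @param stream A character scalar holding the whole file, a character
#'   vector of lines, or a file path.
#' @return A list of [new_document()] objects.
#' @export
read_pubtator <- function(stream) {
  lines <- as_lines(stream)
  docs <- list()
  block <- character()
  block_start <- 1L
  flush <- function(block, first_line) {
    if (length(block)) docs[[length(docs) + 1L]] <<- parse_pubtator_block(block, first_line)
  }
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      flush(block, block_start)
      block <- character()
      block_start <- i + 1L
    } else {
      block <- c(block, lines[i])
    }
  }
  flush(block, block_start)
  docs
}

parse_pubtator_block <- function(block, first_line) {
  lineno <- function(k) first_line + k - 1L
  if (!grepl("^[^|\t]+\\|t\\|", block[1])) {
    stopf("line %d: expected 'PMID|t|title' line", lineno(1L))
  }
  doc_id <- sub("\\|.*$", "", block[1])
  title <- sub("^[^|]+\\|t\\|", "", block[1])
  abstract <- ""
  k <- 2L
  if (length(block) >= 2 && startsWith(block[2], paste0(doc_id, "|a|"))) {
    abstract <- sub("^[^|]+\\|a\\|", "", block[2])
    k <- 3L
  }
  mentions <- empty_mentions()
  relations <- empty_relations()
  if (length(block) >= k) {
    for (j in k:length(block)) {
      f <- strsplit(block[j], "\t", fixed = TRUE)[[1]]
      if (length(f) == 4L && f[2] == "CID") {
        relations <- rbind(relations, data.frame(
          chemical_id = f[3], disease_id = f[4], stringsAsFactors = FALSE))
      } else if (length(f) == 6L) {
        if (f[1] != doc_id) stopf("line %d: PMID mismatch in mention line", lineno(j))
        st <- suppressWarnings(as.integer(f[2])); en <- suppressWarnings(as.integer(f[3]))
        if (is.na(st) || is.na(en)) stopf("line %d: non-numeric mention offsets", lineno(j))
        ids <- unlist(strsplit(f[6], "[|+]"))
        ids <- ids[nzchar(ids) & ids != "-1"]
        for (id in ids) {
          mentions <- rbind(mentions, data.frame(
            entity_type = f[5], concept_id = id, char_start = st, char_end = en,
            text = f[4], sentence_index = NA_integer_,
            tok_start = NA_integer_, tok_end = NA_integer_,
            stringsAsFactors = FALSE))
        }
      } else {
        stopf("line %d: malformed PubTator line", lineno(j))
      }
    }
  }
  dup <- duplicated(paste(relations$chemical_id, relations$disease_id))
  if (any(dup)) {
    log_msg(sprintf("document %s: %d duplicate relation line(s) dropped",
                    doc_id, sum(dup)), level = "WARN")
    relations <- relations[!dup, , drop = FALSE]
    rownames(relations) <- NULL
  }
  new_document(doc_id, title, abstract, mentions, relations)
}

#' Write documents in PubTator format
#'
#' Inverse of [read_pubtator()]: emits the same dialect with mention lines
#' sorted by start offset and relation lines sorted lexicographically, so
#' output is deterministic and round-trips losslessly.
#'
#' @param docs A list of `cdr_document` objects (or a single one).
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The PubTator text, invisibly when `path` is given.
#' @export
write_pubtator <- function(docs, path = NULL) {
  if (inherits(docs, "cdr_document")) docs <- list(docs)
  blocks <- vapply(docs, function(doc) {
    validate_document(doc)
    out <- c(sprintf("%s|t|%s", doc$doc_id, doc$title),
             sprintf("%s|a|%s", doc$doc_id, doc$abstract))
    m <- doc$mentions
    if (nrow(m)) {
      m <- m[order(m$char_start, m$char_end, m$entity_type, m$concept_id), ]
      out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s\t%s", doc$doc_id,
                            m$char_start, m$char_end, m$text, m$entity_type,
                            m$concept_id))
    }
    r <- doc$relations
    if (nrow(r)) {
      r <- r[order(r$chemical_id, r$disease_id), ]
      out <- c(out, sprintf("%s\tCID\t%s\t%s", doc$doc_id, r$chemical_id,
                            r$disease_id))
    }
    paste0(paste(out, collapse = "\n"), "\n")
  }, character(1))
  txt <- paste(blocks, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

# ---------------------------------------------------------------------------
# CoNLL-U

#' Attach CoNLL-U tokenization and dependency parses to a document
#'
#' Reads 10-column CoNLL-U blocks (one block per document sentence, in
#' order; `#` comment lines ignored) and attaches tokens (surface, UPOS,
#' character offsets recovered by matching surfaces against the document
#' text) and one dependency parse per sentence.  Each parse must be a
#' single-rooted tree.
#'
#' @param stream CoNLL-U text (scalar, lines, or file path).
#' @param doc The `cdr_document` the parses belong to.
#' @return The document with `$tokens` and `$parses` populated.
#' @export
read_conllu <- function(stream, doc) {
  lines <- as_lines(stream)
  lines <- lines[!startsWith(lines, "#")]
  blocks <- split_blocks(lines)
  if (!length(blocks)) stopf("document %s: no CoNLL-U sentences", doc$doc_id)
  tokens <- data.frame(surface = character(), char_start = integer(),
                       char_end = integer(), sentence_index = integer(),
                       pos_tag = character(), stringsAsFactors = FALSE)
  parses <- vector("list", length(blocks))
  cursor <- 0L  # 0-based offset into doc$text
  text <- doc$text
  nch <- nchar(text)
  for (s in seq_along(blocks)) {
    bl <- blocks[[s]]
    fields <- strsplit(bl, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) != 10L)
    if (length(bad)) stopf("document %s sentence %d: expected 10 columns",
                           doc$doc_id, s)
    ids <- vapply(fields, `[[`, "", 1L)
    if (any(grepl("[-.]", ids))) {
      stopf("document %s sentence %d: multiword/empty-node ids unsupported",
            doc$doc_id, s)
    }
    if (!identical(as.integer(ids), seq_along(ids))) {
      stopf("document %s sentence %d: token ids not sequential", doc$doc_id, s)
    }
    form <- vapply(fields, `[[`, "", 2L)
    upos <- vapply(fields, `[[`, "", 4L)
    head <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 7L)))
    deprel <- vapply(fields, `[[`, "", 8L)
    if (anyNA(head)) stopf("document %s sentence %d: non-numeric HEAD",
                           doc$doc_id, s)
    check_tree(head, doc$doc_id, s)
    for (t in seq_along(form)) {
      while (cursor < nch && substr(text, cursor + 1L, cursor + 1L) == " ") {
        cursor <- cursor + 1L
      }
      w <- form[t]
      if (substr(text, cursor + 1L, cursor + nchar(w)) != w) {
        stopf("document %s sentence %d token %d: surface '%s' does not match text at offset %d",
              doc$doc_id, s, t, w, cursor)
      }
      tokens <- rbind(tokens, data.frame(
        surface = w, char_start = cursor, char_end = cursor + nchar(w),
        sentence_index = s - 1L, pos_tag = upos[t], stringsAsFactors = FALSE))
      cursor <- cursor + nchar(w)
    }
    parses[[s]] <- list(head = head, deprel = deprel)
  }
  if (trimws(substr(text, cursor + 1L, nch)) != "") {
    stopf("document %s: CoNLL-U tokens cover only %d of %d characters",
          doc$doc_id, cursor, nch)
  }
  doc$tokens <- tokens
  doc$parses <- parses
  doc
}

#' Write a document's tokenization and parses as CoNLL-U
#'
#' Emits one `# newdoc id = <doc_id>` comment followed by one 10-column
#' block per sentence.  Deterministic; round-trips through [read_conllu()].
#'
#' @param docs A `cdr_document` or list of them (tokens and parses present).
#' @param path Optional file path.
#' @return CoNLL-U text, invisibly when `path` is given.
#' @export
write_conllu <- function(docs, path = NULL) {
  if (inherits(docs, "cdr_document")) docs <- list(docs)
  out <- character()
  for (doc in docs) {
    if (is.null(doc$tokens) || is.null(doc$parses)) {
      stopf("document %s: tokens/parses missing", doc$doc_id)
    }
    out <- c(out, sprintf("# newdoc id = %s", doc$doc_id))
    for (s in seq_along(doc$parses)) {
      tok <- doc$tokens[doc$tokens$sentence_index == s - 1L, , drop = FALSE]
      p <- doc$parses[[s]]
      out <- c(out, sprintf("%d\t%s\t_\t%s\t_\t_\t%d\t%s\t_\t_",
                            seq_len(nrow(tok)), tok$surface, tok$pos_tag,
                            p$head, p$deprel), "")
    }
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Attach parses to a whole corpus from one CoNLL-U stream
#'
#' Splits the stream on `# newdoc id = <id>` markers and dispatches each
#' chunk to [read_conllu()] by document id.
#'
#' @param docs List of `cdr_document`s.
#' @param stream CoNLL-U text containing `newdoc` markers.
#' @return The documents with tokens and parses attached, same order.
#' @export
attach_parses <- function(docs, stream) {
  lines <- as_lines(stream)
  marks <- grep("^# newdoc id = ", lines)
  if (!length(marks)) stopf("no '# newdoc id' markers in CoNLL-U stream")
  ids <- sub("^# newdoc id = ", "", lines[marks])
  ends <- c(marks[-1] - 1L, length(lines))
  chunks <- Map(function(a, b) lines[a:b], marks, ends)
  names(chunks) <- ids
  lapply(docs, function(doc) {
    ch <- chunks[[doc$doc_id]]
    if (is.null(ch)) stopf("no CoNLL-U block for document %s", doc$doc_id)
    read_conllu(ch, doc)
  })
}

#' Align entity mentions to token spans
#'
#' Fills each mention's inclusive token interval with the minimal set of
#' tokens overlapping its character interval, and assigns the mention to
#' the sentence of its first token.  Mentions crossing a sentence boundary
#' are kept (with a logged warning); mentions matching no token are an
#' error.
#'
#' @param doc A `cdr_document` with tokens attached.
#' @return The document with `sentence_index`, `tok_start`, `tok_end`
#'   filled on every mention.
#' @export
align_mentions <- function(doc) {
  if (is.null(doc$tokens)) stopf("document %s: tokens missing (read CoNLL-U first)",
                                 doc$doc_id)
  tok <- doc$tokens
  m <- doc$mentions
  for (i in seq_len(nrow(m))) {
    hit <- which(tok$char_start < m$char_end[i] & tok$char_end > m$char_start[i])
    if (!length(hit)) {
      stopf("document %s: mention '%s' [%d,%d) matches no token",
            doc$doc_id, m$text[i], m$char_start[i], m$char_end[i])
    }
    m$tok_start[i] <- min(hit)
    m$tok_end[i] <- max(hit)
    sents <- unique(tok$sentence_index[hit])
    if (length(sents) > 1L) {
      log_msg(sprintf("document %s: mention '%s' crosses a sentence boundary; assigned to sentence %d",
                      doc$doc_id, m$text[i], sents[1]), level = "WARN")
    }
    m$sentence_index[i] <- sents[1]
  }
  doc$mentions <- m
  doc
}

# -- small shared parsing helpers -------------------------------------------

as_lines <- function(stream) {
  if (length(stream) == 1L && !grepl("\n", stream) && file.exists(stream)) {
    return(readLines(stream, warn = FALSE))
  }
  if (length(stream) == 1L) return(strsplit(stream, "\n", fixed = TRUE)[[1]])
  stream
}

split_blocks <- function(lines) {
  blocks <- list()
  cur <- character()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- character()
    } else {
      cur <- c(cur, ln)
    }
  }
  if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
  blocks
}
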