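# Per-token input representation: contextual word vector (+) POS embedding
# (+) two position embeddings (signed clipped distance to the chemical and
# to the disease mention of the candidate pair).  The contextual embedder
# is a pluggable interface; a deterministic hash embedder stands in for a
# pretrained deep language model at desk scale.

#' Representation configuration
#'
#' @param profile `"paper"` (contextual dim 1024, POS/position dims 100,
#'   clip radius 50) mirroring the full-scale method, or `"test"`
#'   (desk-scale dims for fast synthetic experiments).
#' @param ... Named overrides of individual fields.
#' @return A list with fields `dim_ctx`, `dim_pos`, `dim_dist`, `clip`,
#'   `max_len`, `seed`.
#' @export
repr_config <- function(profile = c("test", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(dim_ctx = 1024L, dim_pos = 100L, dim_dist = 100L, clip = 50L,
         max_len = 384L, seed = 1L)
  } else {
    list(dim_ctx = 32L, dim_pos = 8L, dim_dist = 8L, clip = 10L,
         max_len = 128L, seed = 1L)
  }
  utils::modifyList(cfg, list(...))
}

#' POS tag vocabulary used by the synthetic generator (UPOS subset)
#' @export
upos_subset <- function() {
  c("NOUN", "VERB", "ADJ", "ADV", "ADP", "DET", "PRON", "PROPN", "NUM", "PUNCT")
}

#' Build fixed embedding lookup tables
#'
#' The POS table `M_p` has one row per tag plus an `<UNK>` row; the
#' distance table `M_d` has one row per clipped signed distance in
#' `[-clip, clip]`.  Rows are Gaussian with scale `1/sqrt(dim)`,
#' deterministic given the seed; both target-entity distances share `M_d`.
#'
#' @param config A [repr_config()].
#' @param pos_vocab Character vector of known POS tags.
#' @return List with matrices `M_p`, `M_d` and the configuration.
#' @export
embedding_tables <- function(config = repr_config(), pos_vocab = upos_subset()) {
  M_p <- with_local_seed(derive_seed(config$seed, "M_p"), {
    m <- matrix(stats::rnorm((length(pos_vocab) + 1L) * config$dim_pos,
                             sd = 1 / sqrt(config$dim_pos)),
                nrow = length(pos_vocab) + 1L)
    rownames(m) <- c(pos_vocab, "<UNK>")
    m
  })
  M_d <- with_local_seed(derive_seed(config$seed, "M_d"), {
    m <- matrix(stats::rnorm((2L * config$clip + 1L) * config$dim_dist,
                             sd = 1 / sqrt(config$dim_dist)),
                nrow = 2L * config$clip + 1L)
    rownames(m) <- as.character(seq(-config$clip, config$clip))
    m
  })
  list(M_p = M_p, M_d = M_d, config = config)
}

#' Signed clipped distance from a token to a mention span
#'
#' Zero inside the span; otherwise the signed distance to the nearest span
#' boundary, clipped to `[-max_dist, max_dist]`.  Monotone non-decreasing
#' in `token_index` on either side of the span.
#'
#' @param token_index Token index (vectorised), same indexing base as `span`.
#' @param span Inclusive `c(start, end)` token interval of the mention.
#' @param max_dist Clip radius (>= 1).
#' @return Integer vector of clipped signed distances.
#' @export
position_index <- function(token_index, span, max_dist) {
  if (length(span) != 2L || anyNA(span) || span[2] < span[1]) {
    stopf("position_index: empty or invalid span")
  }
  if (max_dist < 1L) stopf("position_index: max_dist must be >= 1")
  d <- ifelse(token_index < span[1], token_index - span[1],
              ifelse(token_index > span[2], token_index - span[2], 0L))
  as.integer(pmax(-max_dist, pmin(max_dist, d)))
}

# ---------------------------------------------------------------------------
# Contextual embedder interface

#' Deterministic hash-based contextual embedder
#'
#' A desk-scale substitute for a pretrained deep contextual language model:
#' each token's vector is a pseudo-random function of its surface form and
#' the embedder seed, plus smaller additive contributions from the left and
#' right neighbouring surfaces, making it weakly context-sensitive.  Rows
#' are unit-norm.  The same (surface, neighbours, seed) always yields the
#' same vector; no global RNG state is consumed.
#'
#' @param dim Output dimension (>= 1).
#' @param seed Integer seed.
#' @return An object of class `hash_embedder` (also `contextual_embedder`).
#' @export
hash_embedder <- function(dim, seed = 1L) {
  stopifnot(dim >= 1L)
  structure(list(dim = as.integer(dim), seed = as.integer(seed),
                 cache = new.env(parent = emptyenv())),
            class = c("hash_embedder", "contextual_embedder"))
}

#' Embed a token sequence
#' @param embedder A `contextual_embedder`.
#' @param surfaces Character vector of token surface forms (one document or
#'   window, in order).
#' @return Matrix `length(surfaces) x dim`.
#' @export
embed_tokens <- function(embedder, surfaces) UseMethod("embed_tokens")

hash_base_vec <- function(embedder, key) {
  v <- embedder$cache[[key]]
  if (is.null(v)) {
    v <- with_local_seed(derive_seed(embedder$seed, key),
                         stats::rnorm(embedder$dim))
    embedder$cache[[key]] <- v
  }
  v
}

#' @export
embed_tokens.hash_embedder <- function(embedder, surfaces) {
  n <- length(surfaces)
  left <- c("<BOS>", surfaces[-n])
  right <- c(surfaces[-1], "<EOS>")
  out <- matrix(0, n, embedder$dim)
  for (i in seq_len(n)) {
    v <- hash_base_vec(embedder, paste0("T\r", surfaces[i])) +
      0.3 * hash_base_vec(embedder, paste0("L\r", left[i])) +
      0.3 * hash_base_vec(embedder, paste0("R\r", right[i]))
    out[i, ] <- v / sqrt(sum(v^2))
  }
  out
}

#' Precomputed-vector embedder
#'
#' Reads per-token vectors from a TSV sidecar (one row per token of each
#' document, first column the document id), for plugging in externally
#' computed contextual representations.
#'
#' @param path TSV file: `doc_id` column then `dim` numeric columns.
#' @return A `contextual_embedder` keyed by document id; its
#'   `embed_tokens` method requires `attr(surfaces, "doc_id")`.
#' @export
precomputed_embedder <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  structure(list(dim = ncol(tab) - 1L,
                 by_doc = split(as.matrix(tab[, -1, drop = FALSE]), tab[[1]])),
            class = c("precomputed_embedder", "contextual_embedder"))
}

#' @export
embed_tokens.precomputed_embedder <- function(embedder, surfaces) {
  doc_id <- attr(surfaces, "doc_id")
  if (is.null(doc_id)) stopf("precomputed_embedder requires attr(surfaces, 'doc_id')")
  v <- embedder$by_doc[[doc_id]]
  if (is.null(v)) stopf("no precomputed vectors for document %s", doc_id)
  m <- matrix(v, ncol = embedder$dim)
  idx <- attr(surfaces, "token_range") %||% seq_along(surfaces)
  m[idx, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Featurisation

#' Build the token feature matrix for one candidate instance
#'
#' Concatenates, per token of the input window, the contextual vector, the
#' POS embedding, and the two distance embeddings (relative to the chemical
#' and to the disease mention), in that fixed order.  The window is the
#' whole document, truncated symmetrically around the two mention spans to
#' `max_len` tokens when the document is longer (both spans are always
#' retained).
#'
#' @param instance One row of [build_all()] output.
#' @param doc The instance's `cdr_document`.
#' @param embedder A `contextual_embedder`.
#' @param tables Output of [embedding_tables()].
#' @return Matrix `n x (dim_ctx + dim_pos + 2 dim_dist)` with attributes
#'   `window` (document-level token range), `chem_span`, `dis_span`
#'   (window-relative inclusive spans).
#' @export
featurize <- function(instance, doc, embedder, tables) {
  cfg <- tables$config
  tok <- doc$tokens
  n <- nrow(tok)
  span_lo <- min(instance$chem_tok_start, instance$dis_tok_start)
  span_hi <- max(instance$chem_tok_end, instance$dis_tok_end)
  if (n > cfg$max_len) {
    if (span_hi - span_lo + 1L > cfg$max_len) {
      stopf("document %s: mention spans farther apart than max_len=%d",
            doc$doc_id, cfg$max_len)
    }
    center <- floor((span_lo + span_hi) / 2)
    w_start <- center - floor(cfg$max_len / 2) + 1L
    w_start <- max(1L, min(w_start, n - cfg$max_len + 1L))
    w_start <- min(w_start, span_lo)
    w_end <- w_start + cfg$max_len - 1L
    if (w_end < span_hi) {
      w_end <- span_hi
      w_start <- w_end - cfg$max_len + 1L
    }
  } else {
    w_start <- 1L
    w_end <- n
  }
  idx <- w_start:w_end
  surfaces <- tok$surface[idx]
  attr(surfaces, "doc_id") <- doc$doc_id
  attr(surfaces, "token_range") <- idx
  ctx <- embed_tokens(embedder, surfaces)
  if (ncol(ctx) != cfg$dim_ctx) {
    stopf("embedder dimension %d does not match config dim_ctx %d",
          ncol(ctx), cfg$dim_ctx)
  }
  pos_tags <- tok$pos_tag[idx]
  unknown <- !(pos_tags %in% rownames(tables$M_p))
  if (any(unknown)) {
    log_msg(sprintf("document %s: %d token(s) with unknown POS mapped to <UNK>",
                    doc$doc_id, sum(unknown)), level = "WARN")
    pos_tags[unknown] <- "<UNK>"
  }
  pos_part <- tables$M_p[pos_tags, , drop = FALSE]
  chem_span <- c(instance$chem_tok_start, instance$chem_tok_end) - w_start + 1L
  dis_span <- c(instance$dis_tok_start, instance$dis_tok_end) - w_start + 1L
  wpos <- seq_along(idx)
  d_chem <- position_index(wpos, chem_span, cfg$clip)
  d_dis <- position_index(wpos, dis_span, cfg$clip)
  dist_part_c <- tables$M_d[as.character(d_chem), , drop = FALSE]
  dist_part_d <- tables$M_d[as.character(d_dis), , drop = FALSE]
  X <- cbind(ctx, pos_part, dist_part_c, dist_part_d)
  dimnames(X) <- NULL
  attr(X, "window") <- c(w_start, w_end)
  attr(X, "chem_span") <- chem_span
  attr(X, "dis_span") <- dis_span
  class(X) <- c("token_feature_matrix", class(X))
  X
}
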