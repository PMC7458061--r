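# Document-level dependency graph.
#
# Nodes are the document's tokens (1-based document-level indices).  Three
# edge types:
#   syntactic          one per dependency arc, within a sentence;
#   adjacent_sentence  between the dependency roots of consecutive sentences;
#   self               one self-loop per token.
# For the GCN the typed, directed edge list collapses to a binary symmetric
# adjacency matrix with unit diagonal, so every node has degree >= 1 and the
# degree normalisation never divides by zero.

#' Build the document-level dependency graph
#'
#' @param doc A `cdr_document` with tokens and one parse per sentence.
#' @return A `doc_graph` object: `n_nodes`, a typed edge `data.frame`
#'   (`i`, `j`, `type`), the node-to-sentence map, and the per-sentence
#'   root token indices.
#' @export
build_document_graph <- function(doc) {
  if (is.null(doc$tokens)) stopf("document %s: tokens missing", doc$doc_id)
  if (is.null(doc$parses)) stopf("document %s: parses missing", doc$doc_id)
  sent_of <- doc$tokens$sentence_index
  n <- nrow(doc$tokens)
  n_sent <- length(doc$parses)
  offsets <- c(0L, cumsum(tabulate(sent_of + 1L, nbins = n_sent)))
  edges_i <- integer(); edges_j <- integer(); edges_t <- character()
  roots <- integer(n_sent)
  for (s in seq_len(n_sent)) {
    p <- doc$parses[[s]]
    if (is.null(p)) stopf("document %s: missing parse for sentence %d", doc$doc_id, s - 1L)
    m <- length(p$head)
    if (m != sum(sent_of == s - 1L)) {
      stopf("document %s sentence %d: parse length %d != token count %d",
            doc$doc_id, s - 1L, m, sum(sent_of == s - 1L))
    }
    dep <- which(p$head != 0L)
    edges_i <- c(edges_i, offsets[s] + dep)
    edges_j <- c(edges_j, offsets[s] + p$head[dep])
    edges_t <- c(edges_t, rep("syntactic", length(dep)))
    roots[s] <- offsets[s] + which(p$head == 0L)
  }
  if (n_sent > 1L) {
    edges_i <- c(edges_i, roots[-n_sent])
    edges_j <- c(edges_j, roots[-1L])
    edges_t <- c(edges_t, rep("adjacent_sentence", n_sent - 1L))
  }
  edges_i <- c(edges_i, seq_len(n))
  edges_j <- c(edges_j, seq_len(n))
  edges_t <- c(edges_t, rep("self", n))
  structure(list(
    n_nodes = n,
    edges = data.frame(i = edges_i, j = edges_j, type = edges_t,
                       stringsAsFactors = FALSE),
    node_sentence = sent_of,
    roots = roots), class = "doc_graph")
}

#' @export
print.doc_graph <- function(x, ...) {
  tab <- table(x$edges$type)
  cat(sprintf("<doc_graph: %d nodes; %s>\n", x$n_nodes,
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Convert a document graph to its symmetric binary adjacency matrix
#'
#' Edge direction and type are discarded: `A[i,j] = A[j,i] = 1` for every
#' edge, and `A[i,i] = 1` from the self-loops.
#'
#' @param graph A `doc_graph`.
#' @return A sparse symmetric 0/1 `Matrix::dgCMatrix` with unit diagonal.
#' @export
to_adjacency <- function(graph) {
  e <- graph$edges
  A <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = 1, dims = rep(graph$n_nodes, 2L))
  A@x[] <- 1  # collapse duplicate (i,j) entries to weight 1
  A
}

#' Degree-normalised adjacency `D^{-1} A` used by the graph convolution.
#' @param A Output of [to_adjacency()].
#' @return Sparse row-normalised matrix.
#' @export
normalize_adjacency <- function(A) {
  d <- Matrix::rowSums(A)
  Matrix::Diagonal(x = 1 / d) %*% A
}

#' Restrict an adjacency matrix to a token window
#' @param A Full-document adjacency.
#' @param window Integer vector `c(first, last)` of 1-based token indices.
#' @return The sub-adjacency over `window` (diagonal preserved).
#' @export
window_adjacency <- function(A, window) {
  idx <- window[1]:window[2]
  A[idx, idx, drop = FALSE]
}

#' Export the typed edge list as TSV (debugging aid)
#' @param graph A `doc_graph`.
#' @param path Optional file path.
#' @return TSV text.
#' @export
graph_to_tsv <- function(graph, path = NULL) {
  e <- graph$edges
  txt <- paste0("i\tj\ttype\n",
                paste(sprintf("%d\t%d\t%s", e$i, e$j, e$type), collapse = "\n"),
                "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Export an adjacency matrix in MatrixMarket coordinate format
#' @param A Adjacency matrix.
#' @param path File path to write to.
#' @export
adjacency_to_mtx <- function(A, path) {
  Matrix::writeMM(A, path)
  invisible(path)
}
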