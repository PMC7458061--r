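#' @keywords internal
"_PACKAGE"

# Internal numerical and RNG helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-wise softmax of a matrix (numerically stabilised).
#' @noRd
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Evaluate `expr` under a temporary RNG state seeded with `seed`,
#' restoring the caller's RNG stream afterwards.  All deterministic
#' components (hash embedder, embedding tables, parameter init, corpus
#' generation) go through this so they never perturb user code.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' FNV-1a style 32-bit string hash, kept below 2^31 so it is a valid
#' `set.seed` argument.  Pure integer arithmetic on doubles to avoid
#' overflow (R has no native uint32).
#' @noRd
hash_string <- function(s) {
  codes <- utf8ToInt(s)
  # polynomial rolling hash mod a Mersenne prime; products stay < 2^53 so
  # double arithmetic is exact
  h <- 5381
  for (cc in codes) {
    h <- (h * 1048573 + cc) %% 2147483647
  }
  as.integer(h)
}

#' Combine a base seed with a string salt into a reproducible sub-seed.
#' @noRd
derive_seed <- function(seed, salt) {
  hash_string(paste0(salt, "\r", format(seed, scientific = FALSE)))
}

#' Internal logger: writes to stderr, silenced via
#' `options(docgraphre.verbose = FALSE)`.
#' @noRd
log_msg <- function(..., level = "INFO") {
  if (isFALSE(getOption("docgraphre.verbose", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
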