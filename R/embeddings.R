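# Embedding table construction and token-sequence lookup.

# Stable per-word random row: seeded from the table seed and the word
# string, so initialization is independent of vocabulary iteration order
# and unseen prediction-time tokens get the same vector on every run.
random_embedding_row <- function(seed, word, d, a) {
  set.seed(derive_seed(seed, paste0("emb:", word)))
  stats::runif(d, -a, a)
}

#' Build the vocabulary-to-vector embedding table
#'
#' Rows for words found in `pretrained` take the pretrained vector
#' (provenance `"pretrained"`); all other words are drawn i.i.d. uniform
#' from `[-a, a]` (provenance `"random"`). When a pretrained file is
#' supplied, `a` is set to the standard deviation of all its entries —
#' the spread of the pretrained embedding — so random rows live on the
#' same scale as the pretrained ones; without one, `a` is the `a`
#' argument (default 0.25). The reserved `PADDING` row is all zeros,
#' flagged `"reserved"`, and never receives gradient. `Protein1` and
#' `Protein2` are ordinary random rows.
#'
#' Dependency-relation labels (`nsubj`, `prep-of`, ...) are deliberately
#' ordinary vocabulary entries: they are words to the network. They will
#' essentially never appear in a pretrained word2vec file and therefore
#' get random rows — a known error source for path pairs that differ
#' only in their relation labels.
#'
#' @param vocab_tokens character vector of every token occurring in the
#'   corpus (the reserved symbols are added automatically).
#' @param d embedding dimension.
#' @param seed integer seed for the random rows.
#' @param pretrained optional `w2v_embeddings` from [read_word2vec()].
#' @param a half-range of the uniform initialization when no pretrained
#'   embeddings are given.
#' @param trainable logical: may training update this table's rows?
#' @return A list of class `embedding_table`: `$words`, `$D` (|V| x d
#'   matrix), `$d`, `$a`, `$seed`, `$provenance`, `$trainable`.
#' @export
build_embedding_table <- function(vocab_tokens, d, seed, pretrained = NULL,
                                  a = 0.25, trainable = FALSE) {
  d <- as.integer(d)
  stopifnot(d >= 1L, a >= 0)
  words <- c(reserved_tokens(),
             sort(unique(setdiff(vocab_tokens, reserved_tokens()))))
  if (!is.null(pretrained)) {
    if (ncol(pretrained$vectors) != d)
      stop("pretrained embedding dimension ", ncol(pretrained$vectors),
           " does not match d = ", d)
    a <- stats::sd(as.vector(pretrained$vectors))
  }
  D <- matrix(0, length(words), d)
  provenance <- rep("random", length(words))
  provenance[words == "PADDING"] <- "reserved"
  for (i in seq_along(words)) {
    w <- words[i]
    if (w == "PADDING") next
    j <- if (!is.null(pretrained)) match(w, pretrained$words) else NA_integer_
    if (!is.na(j)) {
      D[i, ] <- pretrained$vectors[j, ]
      provenance[i] <- "pretrained"
    } else {
      D[i, ] <- random_embedding_row(seed, w, d, a)
    }
  }
  structure(list(words = words, D = D, d = d, a = a, seed = seed,
                 provenance = provenance, trainable = trainable),
            class = "embedding_table")
}

#' Map a fixed-length token sequence to its path matrix
#'
#' Row i of the result is the embedding of token i; `PADDING` rows are
#' zero. Tokens absent from the vocabulary (possible only at prediction
#' time, on sequences the table was not built from) are assigned a
#' stable random vector derived from the token string, and a message
#' reports how many such tokens were seen.
#'
#' @param seq an `sdp_sequence`, or a plain character vector of tokens.
#' @param table an `embedding_table`.
#' @return A list of class `path_matrix`: `$P` (N x d matrix), `$tokens`,
#'   `$rows` (row index into `table$D` per token, `NA` for
#'   out-of-vocabulary tokens).
#' @export
embed_lookup <- function(seq, table) {
  tokens <- if (inherits(seq, "sdp_sequence")) seq$tokens else as.character(seq)
  rows <- match(tokens, table$words)
  P <- matrix(0, length(tokens), table$d)
  seen <- !is.na(rows)
  P[seen, ] <- table$D[rows[seen], , drop = FALSE]
  if (any(!seen)) {
    for (i in which(!seen))
      P[i, ] <- random_embedding_row(table$seed, paste0("unseen:", tokens[i]),
                                     table$d, table$a)
    message(sum(!seen), " out-of-vocabulary token(s) assigned stable ",
            "random vectors")
  }
  structure(list(P = P, tokens = tokens, rows = rows),
            class = "path_matrix")
}
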