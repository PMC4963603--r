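# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (loops, closed forms) and shares
# no code with the package internals it checks.

# --- Floyd-Warshall all-pairs shortest hop counts ------------------------

floyd_warshall_dist <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (v in seq_len(n)) for (w in adj[[v]]) D[v, w] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Random connected graph: a random tree plus optional extra edges.
random_connected_graph <- function(n, extra_edges = 0L) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  add_edge <- function(a, b) {
    adj[[a]] <<- unique(c(adj[[a]], b))
    adj[[b]] <<- unique(c(adj[[b]], a))
  }
  for (i in seq_len(n)[-1L]) add_edge(i, sample.int(i - 1L, 1L))
  for (e in seq_len(extra_edges)) {
    ab <- sample.int(n, 2L)
    if (ab[1L] != ab[2L]) add_edge(ab[1L], ab[2L])
  }
  adj
}

# Random dependency tree as a dep_parse: node i > 1 attaches to a random
# earlier node.
random_tree_parse <- function(n, id = "t") {
  head <- c(0L, vapply(seq_len(n)[-1L], function(i)
    sample.int(i - 1L, 1L), 0L))
  tokens <- data.frame(
    index = seq_len(n),
    form = paste0("w", seq_len(n)),
    head = head,
    deprel = c("root", sample(c("nsubj", "dobj", "amod", "conj", "prep-of"),
                              n - 1L, replace = TRUE)),
    stringsAsFactors = FALSE)
  sdpcnn:::validate_parse(sdpcnn:::new_dep_parse(id, tokens))
}

# --- Naive convolution (explicit double loop over window entries) --------

naive_feature_map <- function(P, W_k, b, f = tanh) {
  N <- nrow(P); h <- nrow(W_k); d <- ncol(P)
  out <- numeric(N - h + 1L)
  for (i in seq_len(N - h + 1L)) {
    acc <- 0
    for (r in seq_len(h)) for (c in seq_len(d))
      acc <- acc + W_k[r, c] * P[i + r - 1L, c]
    out[i] <- f(acc + b)
  }
  out
}

# --- Finite-difference gradient check ------------------------------------

# Flatten the trainable parameters (and optionally given embedding rows)
# into one vector; `set` writes a vector back.
flatten_theta <- function(params, tables = NULL, rows = NULL) {
  th <- unlist(lapply(sdpcnn:::PARAM_NAMES, function(nm) as.vector(params[[nm]])))
  if (!is.null(tables))
    for (ch in seq_along(tables))
      th <- c(th, as.vector(tables[[ch]]$D[rows[[ch]], , drop = FALSE]))
  th
}

unflatten_theta <- function(theta, params, tables = NULL, rows = NULL) {
  pos <- 0L
  for (nm in sdpcnn:::PARAM_NAMES) {
    k <- length(params[[nm]])
    params[[nm]][] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  if (!is.null(tables)) {
    for (ch in seq_along(tables)) {
      k <- length(rows[[ch]]) * tables[[ch]]$d
      tables[[ch]]$D[rows[[ch]], ] <-
        matrix(theta[pos + seq_len(k)], length(rows[[ch]]), tables[[ch]]$d)
      pos <- pos + k
    }
  }
  list(params = params, tables = tables)
}

# Loss of one (tokens, y) example as a function of the flat parameter
# vector; recomputes the path matrices from the (possibly perturbed)
# embedding tables.
theta_loss <- function(theta, params, tables, tokens, y,
                       trainable_rows = NULL) {
  st <- unflatten_theta(theta, params, tables, trainable_rows)
  Ps <- lapply(st$tables, function(tb)
    suppressMessages(embed_lookup(tokens, tb))$P)
  trace <- sdpcnn_forward(if (length(Ps) == 1L) Ps[[1L]] else Ps, st$params)
  nll(trace$S, y)
}

# Central finite differences vs analytic gradient; returns the max
# relative error over all coordinates.
gradient_check <- function(params, tables, tokens, y,
                           trainable_embeddings = FALSE, step = 1e-5) {
  trainable_rows <- NULL
  if (trainable_embeddings) {
    trainable_rows <- lapply(tables, function(tb) {
      r <- match(tokens, tb$words)
      sort(unique(r[tb$words[r] != "PADDING"]))
    })
  }
  Ps <- lapply(tables, function(tb)
    suppressMessages(embed_lookup(tokens, tb))$P)
  trace <- sdpcnn_forward(if (length(Ps) == 1L) Ps[[1L]] else Ps, params)
  grads <- sdpcnn_backward(trace, y, params,
                           trainable_embeddings = trainable_embeddings)
  g_analytic <- unlist(lapply(sdpcnn:::PARAM_NAMES, function(nm)
    as.vector(grads[[nm]])))
  if (trainable_embeddings) {
    for (ch in seq_along(tables)) {
      rows_seq <- match(tokens, tables[[ch]]$words)
      dD <- matrix(0, length(tables[[ch]]$words), tables[[ch]]$d)
      for (i in seq_along(rows_seq)) {
        r <- rows_seq[i]
        if (tables[[ch]]$words[r] != "PADDING")
          dD[r, ] <- dD[r, ] + grads$P[[ch]][i, ]
      }
      g_analytic <- c(g_analytic,
                      as.vector(dD[trainable_rows[[ch]], , drop = FALSE]))
    }
  }
  theta <- flatten_theta(params, if (trainable_embeddings) tables,
                         trainable_rows)
  g_fd <- vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + step
    tm <- theta; tm[j] <- tm[j] - step
    (theta_loss(tp, params, tables, tokens, y, trainable_rows) -
       theta_loss(tm, params, tables, tokens, y, trainable_rows)) / (2 * step)
  }, 0)
  max(abs(g_analytic - g_fd) / pmax(abs(g_analytic), abs(g_fd), 1e-3))
}

# --- Tiny model fixtures -------------------------------------------------

tiny_pretrained <- function(d, seed = 42L) {
  set.seed(seed)
  words <- c("affects", "properties", "binds", "levels")
  structure(list(words = words,
                 vectors = matrix(rnorm(length(words) * d, sd = 0.3),
                                  length(words), d)),
            class = "w2v_embeddings")
}

# A tiny model + tables + one example sequence for the given variant.
tiny_setup <- function(variant = "random_update", seed = 7L,
                       N = 5L, d = 3L, h = 3L, M = 2L, H = 4L) {
  tokens_raw <- c("Protein1", "nsubj", "affects", "dobj", "Protein2")
  vocab <- unique(c(tokens_raw, "PADDING"))
  channels <- if (variant == "combined") 2L else 1L
  pre <- if (variant %in% c("pretrained", "combined")) tiny_pretrained(d)
  tables <- switch(variant,
    random = ,
    random_update = list(main = build_embedding_table(vocab, d, seed)),
    pretrained = list(main = build_embedding_table(vocab, d, seed,
                                                   pretrained = pre)),
    combined = list(pre = build_embedding_table(vocab, d, seed,
                                                pretrained = pre),
                    rand = build_embedding_table(vocab, d, seed + 1L)))
  params <- suppressWarnings(
    init_model_params(N, d, h, M, H, seed = seed, channels = channels))
  tokens <- sdp_fit_length(
    structure(list(tokens = tokens_raw, raw_length = 5L,
                   n_fixed = NA_integer_), class = "sdp_sequence"),
    N)$tokens
  list(params = params, tables = tables, tokens = tokens,
       variant = variant)
}

# Synthetic-experiment model configuration used across the evaluation
# and acceptance tests (desk-scale counterpart of the benchmark
# settings).
synth_model_config <- function(seed = 1L, epochs = 40L, ...) {
  sdpcnn_config(N = 11L, d = 50L, h = 3L, M = 16L, H = 16L,
                epochs = epochs, seed = seed, ...)
}
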