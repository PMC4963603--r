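# Shortest-dependency-path extraction: entity head selection, BFS over the
# undirected dependency graph, entity blinding, serialization, and
# padding/truncation to a fixed input length.

#' Syntactic head of an entity mention span
#'
#' Returns the token inside the span whose governor lies outside the span
#' (0 = root counts as outside); that token carries the dependency edge
#' connecting the mention to the rest of the sentence. When the span has
#' several such tokens or none, the last token of the span is used as a
#' fallback, with a warning.
#'
#' @param parse a `dep_parse` object.
#' @param span inclusive 1-based token range `c(start, end)`.
#' @return A single token index.
#' @export
entity_head <- function(parse, span) {
  n <- nrow(parse$tokens)
  span <- as.integer(span)
  if (length(span) != 2L || span[1L] > span[2L] || span[1L] < 1L || span[2L] > n)
    stop("invalid entity span [", paste(span, collapse = ", "),
         "] in sentence ", parse$sentence_id)
  idx <- span[1L]:span[2L]
  if (length(idx) == 1L) return(idx)
  outside <- !(parse$tokens$head[idx] %in% idx)
  cand <- idx[outside]
  if (length(cand) == 1L) return(cand)
  warning("span [", span[1L], ", ", span[2L], "] in sentence ",
          parse$sentence_id, " has ", length(cand),
          " tokens headed outside the span; using the last span token")
  span[2L]
}

#' Breadth-first shortest path over an adjacency list
#'
#' Minimum-hop path between two vertices of an undirected graph given as
#' an adjacency list. Neighbours are explored in ascending vertex index,
#' which makes the returned path deterministic when several shortest
#' paths exist.
#'
#' @param adjacency list; `adjacency[[v]]` holds the neighbours of `v`.
#' @param from,to vertex indices.
#' @return Integer vector of vertices from `from` to `to`, or `NULL` if
#'   `to` is unreachable.
#' @export
bfs_shortest_path <- function(adjacency, from, to) {
  n <- length(adjacency)
  stopifnot(from >= 1L, from <= n, to >= 1L, to <= n)
  if (from == to) return(as.integer(from))
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  queue <- as.integer(from)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (nb in sort(adjacency[[v]])) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        prev[nb] <- v
        if (nb == to) {
          path <- nb
          while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
          return(as.integer(path))
        }
        queue <- c(queue, nb)
      }
    }
  }
  NULL
}

#' Shortest dependency path between two tokens
#'
#' Finds the minimum-hop path between tokens `u` and `v` over the
#' sentence's head/dependent edge set viewed as an undirected graph
#' (interaction-relevant paths routinely traverse edges against their
#' syntactic direction, e.g. upward through `nsubj`). Edge labels along
#' the path are the dependency relations of the traversed edges; edge
#' direction is not encoded.
#'
#' @param parse a `dep_parse` object.
#' @param u,v distinct token indices.
#' @return A list of class `sdp_path` with `$node_indices` (token indices
#'   from `u` to `v`) and `$edge_labels` (length `length(node_indices) - 1`).
#' @export
sdp_path <- function(parse, u, v) {
  n <- nrow(parse$tokens)
  u <- as.integer(u); v <- as.integer(v)
  stopifnot(u >= 1L, u <= n, v >= 1L, v <= n)
  if (u == v) stop("degenerate pair: both entities resolve to token ", u)
  adj <- parse_adjacency(parse)
  nodes <- bfs_shortest_path(adj, u, v)
  if (is.null(nodes))  # cannot happen after read-time connectivity check
    stop("token ", v, " unreachable from token ", u, " in sentence ",
         parse$sentence_id)
  heads <- parse$tokens$head
  deprel <- parse$tokens$deprel
  edges <- vapply(seq_len(length(nodes) - 1L), function(i) {
    a <- nodes[i]; b <- nodes[i + 1L]
    if (heads[a] == b) deprel[a] else deprel[b]
  }, "")
  structure(list(node_indices = nodes, edge_labels = edges),
            class = "sdp_path")
}

#' Serialize a dependency path as a blinded token sequence
#'
#' Produces the interleaved word/relation sequence fed to the network:
#' `[Protein1, rel1, w2, rel2, ..., Protein2]`. The two entity endpoints
#' are blinded to the reserved symbols `Protein1`/`Protein2` (this
#' prevents memorisation of specific protein names and reduces
#' sparsity); interior words are lowercased surface forms; relation
#' labels are inserted verbatim between consecutive path nodes and are
#' treated as ordinary words downstream. A path of k nodes serializes to
#' `2k - 1` tokens.
#'
#' @param path_result an `sdp_path` object.
#' @param parse the parse the path was extracted from.
#' @return A list of class `sdp_sequence` with `$tokens`, `$raw_length`
#'   (token count before padding/truncation) and `$n_fixed` (`NA` until
#'   [sdp_fit_length()] is applied).
#' @export
sdp_serialize <- function(path_result, parse) {
  nodes <- path_result$node_indices
  k <- length(nodes)
  words <- tolower(parse$tokens$form[nodes])
  words[1L] <- "Protein1"
  words[k] <- "Protein2"
  tokens <- character(2L * k - 1L)
  tokens[seq(1L, 2L * k - 1L, by = 2L)] <- words
  if (k > 1L)
    tokens[seq(2L, 2L * k - 2L, by = 2L)] <- path_result$edge_labels
  structure(list(tokens = tokens, raw_length = length(tokens),
                 n_fixed = NA_integer_),
            class = "sdp_sequence")
}

#' Pad or truncate a serialized path to a fixed length
#'
#' The network consumes fixed-length inputs. Shorter sequences are padded
#' with the reserved `PADDING` symbol (which embeds to the zero vector);
#' longer sequences are truncated. With `truncate = "middle"` (default) a
#' block of interior tokens centred on the path midpoint is removed, so
#' both entity anchors and their nearby context survive; with
#' `truncate = "tail"` the first `n_fixed - 1` tokens and the final
#' `Protein2` token are kept.
#'
#' @param seq an `sdp_sequence`.
#' @param n_fixed target length N, at least 3.
#' @param truncate `"middle"` or `"tail"`.
#' @return An `sdp_sequence` whose `$tokens` has exactly `n_fixed`
#'   entries, still starting with `Protein1` and whose last non-`PADDING`
#'   token is `Protein2`.
#' @export
sdp_fit_length <- function(seq, n_fixed, truncate = c("middle", "tail")) {
  truncate <- match.arg(truncate)
  n_fixed <- as.integer(n_fixed)
  if (is.na(n_fixed) || n_fixed < 3L)
    stop("fixed path length N must be an integer >= 3, got ", n_fixed)
  tokens <- seq$tokens
  L <- length(tokens)
  if (L <= n_fixed) {
    tokens <- c(tokens, rep("PADDING", n_fixed - L))
  } else if (truncate == "middle") {
    m <- L - n_fixed
    start <- (L - m) %/% 2L + 1L
    tokens <- tokens[-(start:(start + m - 1L))]
  } else {
    tokens <- c(tokens[seq_len(n_fixed - 1L)], tokens[L])
  }
  structure(list(tokens = tokens, raw_length = seq$raw_length,
                 n_fixed = n_fixed),
            class = "sdp_sequence")
}

#' Extract the blinded shortest-dependency-path sequence for an instance
#'
#' Convenience wrapper: resolves the syntactic head of each entity span,
#' finds the shortest dependency path between the two heads, serializes
#' it with entity blinding, and (optionally) fits it to a fixed length.
#'
#' @param parse the `dep_parse` of the instance's sentence.
#' @param instance a `ppi_instance`.
#' @param n_fixed optional fixed length N; `NULL` leaves the raw sequence.
#' @param truncate truncation strategy, see [sdp_fit_length()].
#' @return An `sdp_sequence`.
#' @export
#' @examples
#' we <- worked_example()
#' extract_sdp(we$parse, we$instance)$tokens
extract_sdp <- function(parse, instance, n_fixed = NULL,
                        truncate = c("middle", "tail")) {
  truncate <- match.arg(truncate)
  h1 <- entity_head(parse, instance$e1)
  h2 <- entity_head(parse, instance$e2)
  if (h1 == h2)
    stop("degenerate pair: entity spans of instance ", instance$instance_id,
         " share the syntactic head token ", h1)
  seq <- sdp_serialize(sdp_path(parse, h1, h2), parse)
  if (!is.null(n_fixed)) seq <- sdp_fit_length(seq, n_fixed, truncate)
  seq
}
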