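# Readers and writers for dependency parses (CoNLL-style), instance
# annotations (JSON-lines) and word2vec embedding files.

new_dep_parse <- function(sentence_id, tokens) {
  structure(list(sentence_id = sentence_id, tokens = tokens),
            class = "dep_parse")
}

# Validates token indexing, head range and undirected connectivity.
validate_parse <- function(parse) {
  tok <- parse$tokens
  n <- nrow(tok)
  sid <- parse$sentence_id
  if (n == 0L) stop("empty sentence: ", sid)
  if (!identical(tok$index, seq_len(n)))
    stop("token indices are not contiguous 1..n in sentence ", sid)
  if (any(tok$head < 0L) || any(tok$head > n))
    stop("head index out of range in sentence ", sid)
  if (any(tok$head == tok$index))
    stop("token is its own head in sentence ", sid)
  if (any(!nzchar(tok$deprel)))
    stop("empty dependency relation in sentence ", sid)
  adj <- parse_adjacency(parse)
  visited <- rep(FALSE, n)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!visited[nb]]
    visited[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(visited))
    stop("disconnected dependency parse in sentence ", sid)
  invisible(parse)
}

# Undirected adjacency list of the head/dependent edge set, neighbours in
# ascending token index (the BFS tie-break relies on this ordering).
parse_adjacency <- function(parse) {
  tok <- parse$tokens
  n <- nrow(tok)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    h <- tok$head[i]
    if (h > 0L) {
      adj[[i]] <- c(adj[[i]], h)
      adj[[h]] <- c(adj[[h]], i)
    }
  }
  lapply(adj, function(x) sort(unique(x)))
}

#' Read dependency parses from a CoNLL-style file
#'
#' One token per line, blank line between sentences, `#` comment lines
#' allowed. Two column layouts are recognised: the compact 4-column
#' `ID FORM HEAD DEPREL` layout, and the 10-column CoNLL-U layout (of
#' which columns ID, FORM, HEAD and DEPREL are used; LEMMA, POS etc. are
#' ignored). Multi-word-token and empty-node lines (IDs containing `-` or
#' `.`) are skipped. A `# sent_id = ...` comment names the sentence;
#' otherwise sentences are numbered `s1`, `s2`, ... in file order.
#'
#' Relation labels are kept verbatim: collapsed-preposition labels such
#' as `prep-of` or `prep_of` are opaque strings, never normalised.
#'
#' Every parse is validated on read: token indices must be contiguous
#' from 1, heads must point at existing tokens (0 = root), and the
#' head/dependent edge set, viewed undirected, must connect the whole
#' sentence. Disconnected parses are rejected.
#'
#' @param path path to the parse file.
#' @return A list of parse objects (class `dep_parse`), each with
#'   `$sentence_id` and a `$tokens` data frame with columns `index`,
#'   `form`, `head`, `deprel`.
#' @seealso [write_parses()], [read_instances()]
#' @export
read_parses <- function(path) {
  if (!file.exists(path)) stop("parse file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parses <- list()
  rows <- list()
  sent_id <- NULL
  n_sent <- 0L

  flush_sentence <- function() {
    if (!length(rows)) return(invisible(NULL))
    n_sent <<- n_sent + 1L
    id <- sent_id %||% paste0("s", n_sent)
    tok <- do.call(rbind, rows)
    tok <- data.frame(index = as.integer(tok[, 1L]),
                      form = tok[, 2L],
                      head = as.integer(tok[, 3L]),
                      deprel = tok[, 4L],
                      stringsAsFactors = FALSE)
    parse <- validate_parse(new_dep_parse(id, tok))
    parses[[length(parses) + 1L]] <<- parse
    rows <<- list()
    sent_id <<- NULL
    invisible(NULL)
  }

  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) { flush_sentence(); next }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*sent_id\\s*=\\s*(\\S+)", line))[[1L]]
      if (length(m) == 2L) sent_id <- m[2L]
      next
    }
    fields <- strsplit(trimws(line), "[ \t]+")[[1L]]
    if (length(fields) >= 10L) {
      id <- fields[1L]; form <- fields[2L]
      head <- fields[7L]; deprel <- fields[8L]
    } else if (length(fields) >= 4L) {
      id <- fields[1L]; form <- fields[2L]
      head <- fields[3L]; deprel <- fields[4L]
    } else {
      stop("malformed parse line ", ln, ": expected at least 4 columns")
    }
    if (grepl("[-.]", id)) next  # multi-word token / empty node lines
    if (!grepl("^[0-9]+$", id) || !grepl("^[0-9]+$", head))
      stop("malformed parse line ", ln, ": non-integer ID or HEAD")
    rows[[length(rows) + 1L]] <- c(id, form, head, deprel)
  }
  flush_sentence()
  parses
}

#' Write dependency parses in the compact 4-column CoNLL-style layout
#'
#' The inverse of [read_parses()]: emits `# sent_id = ...` followed by
#' tab-separated `ID FORM HEAD DEPREL` lines and a blank line per
#' sentence.
#'
#' @param parses list of `dep_parse` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parses <- function(parses, path) {
  out <- character(0)
  for (p in parses) {
    tok <- p$tokens
    out <- c(out,
             paste0("# sent_id = ", p$sentence_id),
             paste(tok$index, tok$form, tok$head, tok$deprel, sep = "\t"),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

new_instance <- function(instance_id, sentence_id, e1, e2, label) {
  structure(list(instance_id = instance_id, sentence_id = sentence_id,
                 e1 = as.integer(e1), e2 = as.integer(e2),
                 label = as.integer(label)),
            class = "ppi_instance")
}

#' Read candidate-pair instances from a JSON-lines file
#'
#' Each line is a JSON object with fields `instance_id`, `sentence_id`,
#' `e1`, `e2` (inclusive 1-based token ranges `[start, end]` of the two
#' protein mentions) and `label` (0 = no interaction, 1 = interaction).
#' When `parses` is supplied, every instance is cross-checked against it:
#' the sentence must exist and both spans must lie inside it.
#'
#' Identical `e1`/`e2` spans (a self-pair) are rejected: a mention cannot
#' interact with itself in this representation.
#'
#' @param path path to the JSON-lines instance file.
#' @param parses optional list of parses from [read_parses()] for
#'   cross-validation of sentence ids and spans.
#' @return A list of instance objects (class `ppi_instance`).
#' @export
read_instances <- function(path, parses = NULL) {
  if (!file.exists(path)) stop("instance file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  by_id <- if (!is.null(parses))
    stats::setNames(parses, vapply(parses, `[[`, "", "sentence_id"))
  instances <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i])
    for (f in c("instance_id", "sentence_id", "e1", "e2", "label"))
      if (is.null(rec[[f]]))
        stop("instance line ", i, ": missing field '", f, "'")
    e1 <- as.integer(rec$e1); e2 <- as.integer(rec$e2)
    if (length(e1) != 2L || length(e2) != 2L || e1[1L] > e1[2L] || e2[1L] > e2[2L])
      stop("instance line ", i, ": spans must be [start, end] with start <= end")
    if (!(rec$label %in% c(0, 1)))
      stop("instance line ", i, ": label must be 0 or 1, got ", rec$label)
    if (identical(e1, e2))
      stop("instance line ", i, ": e1 and e2 spans are identical")
    if (!is.null(parses)) {
      p <- by_id[[as.character(rec$sentence_id)]]
      if (is.null(p))
        stop("instance line ", i, ": unknown sentence_id '", rec$sentence_id, "'")
      n <- nrow(p$tokens)
      if (e1[1L] < 1L || e1[2L] > n || e2[1L] < 1L || e2[2L] > n)
        stop("instance line ", i, ": entity span outside sentence '",
             rec$sentence_id, "'")
    }
    instances[[i]] <- new_instance(rec$instance_id, rec$sentence_id,
                                   e1, e2, rec$label)
  }
  instances
}

#' Write instances as JSON-lines
#'
#' Inverse of [read_instances()].
#'
#' @param instances list of `ppi_instance` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path) {
  lines <- vapply(instances, function(ins) {
    jsonlite::toJSON(list(instance_id = ins$instance_id,
                          sentence_id = ins$sentence_id,
                          e1 = ins$e1, e2 = ins$e2, label = ins$label),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a word2vec embedding file
#'
#' Supports the two standard word2vec layouts. Text: a header line
#' `"<count> <dim>"` followed by `"word v1 ... vd"` lines. Binary: the
#' same ASCII header, then for each word its bytes up to a space followed
#' by `dim` little-endian float32 values (a trailing newline per record,
#' as written by the reference implementation, is tolerated).
#'
#' Duplicate words keep their first occurrence, with a warning. All
#' vectors must share one dimension.
#'
#' @param path path to the embedding file.
#' @param format `"text"` or `"binary"`.
#' @return A list with `$words` (character) and `$vectors` (numeric
#'   matrix, one row per word), class `w2v_embeddings`.
#' @export
read_word2vec <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("embedding file not found: ", path)
  if (format == "text") {
    lines <- readLines(path, warn = FALSE)
    hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
    if (length(hdr) != 2L || anyNA(hdr))
      stop("malformed word2vec header: ", lines[1L])
    count <- hdr[1L]; d <- hdr[2L]
    body <- lines[-1L]
    body <- body[nzchar(body)]
    if (length(body) != count)
      stop("word2vec header declares ", count, " words but file has ",
           length(body))
    words <- character(count)
    vectors <- matrix(NA_real_, count, d)
    for (i in seq_len(count)) {
      parts <- strsplit(body[i], " ", fixed = TRUE)[[1L]]
      v <- suppressWarnings(as.numeric(parts[-1L]))
      if (length(v) != d || anyNA(v))
        stop("word2vec record ", i, ": expected ", d, " values")
      words[i] <- parts[1L]
      vectors[i, ] <- v
    }
  } else {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    read_ascii_until <- function(stop_bytes) {
      bytes <- raw(0)
      repeat {
        b <- readBin(con, "raw", n = 1L)
        if (!length(b)) break
        if (as.integer(b) %in% stop_bytes) break
        bytes <- c(bytes, b)
      }
      rawToChar(bytes)
    }
    hdr <- strsplit(trimws(read_ascii_until(0x0a)), "\\s+")[[1L]]
    count <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
    if (anyNA(c(count, d))) stop("malformed word2vec binary header")
    words <- character(count)
    vectors <- matrix(NA_real_, count, d)
    for (i in seq_len(count)) {
      w <- ""
      repeat {  # skip record-separating newlines before the word
        w <- read_ascii_until(0x20)
        w <- gsub("\n", "", w, fixed = TRUE)
        if (nzchar(w)) break
      }
      v <- readBin(con, "numeric", n = d, size = 4L, endian = "little")
      if (length(v) != d)
        stop("truncated word2vec binary file at record ", i)
      words[i] <- w
      vectors[i, ] <- v
    }
  }
  dup <- duplicated(words)
  if (any(dup)) {
    warning("duplicate words in embedding file (first occurrence kept): ",
            paste(unique(words[dup]), collapse = ", "))
    words <- words[!dup]
    vectors <- vectors[!dup, , drop = FALSE]
  }
  structure(list(words = words, vectors = vectors),
            class = "w2v_embeddings")
}

#' Write embeddings in word2vec text or binary format
#'
#' Text vectors are printed with `%.17g`, so a write/read round trip
#' reproduces double-precision values exactly. The binary layout stores
#' float32 (the format's native width), so binary round trips are exact
#' only to single precision.
#'
#' @param embeddings a `w2v_embeddings` object, or any list with
#'   `$words` and `$vectors`.
#' @param path output path.
#' @param format `"text"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(embeddings, path, format = c("text", "binary")) {
  format <- match.arg(format)
  words <- embeddings$words
  vectors <- embeddings$vectors
  stopifnot(length(words) == nrow(vectors))
  if (format == "text") {
    lines <- c(paste(length(words), ncol(vectors)),
               vapply(seq_along(words), function(i) {
                 paste(words[i],
                       paste(sprintf("%.17g", vectors[i, ]), collapse = " "))
               }, ""))
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(charToRaw(paste0(length(words), " ", ncol(vectors), "\n")), con)
    for (i in seq_along(words)) {
      writeBin(charToRaw(paste0(words[i], " ")), con)
      writeBin(vectors[i, ], con, size = 4L, endian = "little")
      writeBin(charToRaw("\n"), con)
    }
  }
  invisible(path)
}
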