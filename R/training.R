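# Training: negative log-likelihood, exact backpropagation (including
# optional embedding-row gradients), Adadelta updates, and the
# per-example training loop.

#' Negative log-likelihood of the gold class
#'
#' `-log S[y]`, with S clamped at 1e-12 before the log so a saturated
#' softmax cannot produce an infinite loss.
#'
#' @param S length-2 softmax output.
#' @param y gold label, 0 or 1.
#' @return Non-negative scalar loss.
#' @export
nll <- function(S, y) {
  stopifnot(length(S) == 2L, y %in% c(0L, 1L))
  -log(max(S[y + 1L], 1e-12))
}

#' Backpropagation through the path CNN
#'
#' Exact gradient of the negative log-likelihood with respect to every
#' parameter, by the chain rule: softmax+NLL gives `S - onehot(y)` at
#' the confidence layer; the hidden tanh contributes `1 - O^2`;
#' max-pooling routes gradient only into each filter's argmax window;
#' the convolution gradient for filter k is the argmax window scaled by
#' the upstream signal. With `trainable_embeddings = TRUE` the gradient
#' with respect to each input path matrix is also returned (`$P`, one
#' N x d matrix per channel) so embedding rows can be updated.
#'
#' @param trace an `sdpcnn_trace` from [sdpcnn_forward()].
#' @param y gold label, 0 or 1.
#' @param params the `sdpcnn_params` used for the forward pass.
#' @param trainable_embeddings compute input-matrix gradients?
#' @return A list with components `W`, `b1`, `W2`, `b2`, `W3` shaped
#'   like the parameters, plus `P` (list of per-channel input gradients,
#'   or `NULL`).
#' @export
sdpcnn_backward <- function(trace, y, params, trainable_embeddings = FALSE) {
  hy <- params$hyper
  act <- get_activation(params$activation)
  Mt <- hy$M * hy$channels

  dI <- trace$S
  dI[y + 1L] <- dI[y + 1L] - 1
  dW3 <- outer(dI, trace$O)
  dO <- as.vector(t(params$W3) %*% dI)
  dZ2 <- dO * act$deriv_from_output(trace$O)
  dW2 <- outer(dZ2, trace$pooled)
  db2 <- dZ2
  dr <- as.vector(t(params$W2) %*% dZ2)
  # gradient reaches only the argmax entry of each feature map
  dA_pool <- dr * act$deriv_from_output(trace$pooled)

  Wmat <- matrix(params$W, hy$h * hy$d, Mt)
  dWmat <- matrix(0, hy$h * hy$d, Mt)
  dPs <- if (trainable_embeddings)
    lapply(seq_len(hy$channels), function(i) matrix(0, hy$N, hy$d))
  for (k in seq_len(Mt)) {
    ch <- (k - 1L) %/% hy$M + 1L
    pos <- trace$argmax[k]
    dWmat[, k] <- trace$X[[ch]][pos, ] * dA_pool[k]
    if (trainable_embeddings) {
      g <- matrix(Wmat[, k] * dA_pool[k], hy$h, hy$d)
      rows <- pos:(pos + hy$h - 1L)
      dPs[[ch]][rows, ] <- dPs[[ch]][rows, ] + g
    }
  }
  list(W = array(dWmat, dim = dim(params$W)), b1 = dA_pool,
       W2 = dW2, b2 = db2, W3 = dW3, P = dPs)
}

#' Initialize Adadelta accumulator state
#'
#' One pair of running averages, E[g^2] and E[delta^2], per parameter
#' array, both starting at zero.
#'
#' @param params named list of numeric arrays (for the network, the
#'   five weight arrays of an `sdpcnn_params`).
#' @return A list with `$Eg` and `$Ed`, shaped like `params`.
#' @export
adadelta_init <- function(params) {
  zeros_like <- function(x) {
    z <- x
    z[] <- 0
    z
  }
  acc <- lapply(params, zeros_like)
  list(Eg = acc, Ed = acc)
}

#' One Adadelta update
#'
#' Zeiler's rule, per coordinate:
#' `E[g^2] <- rho E[g^2] + (1 - rho) g^2`;
#' `delta  <- -sqrt(E[d^2] + eps) / sqrt(E[g^2] + eps) * g`;
#' `E[d^2] <- rho E[d^2] + (1 - rho) delta^2`;
#' `theta  <- theta + delta`.
#' The ratio of running RMS update to running RMS gradient replaces a
#' fixed learning rate, which plain gradient descent needs and which
#' makes its loss unstable.
#'
#' @param params named list of numeric arrays.
#' @param grads gradients, same names and shapes as `params`.
#' @param state accumulator state from [adadelta_init()].
#' @param rho decay rate in (0, 1), default 0.95.
#' @param eps conditioning constant, default 1e-6 (Zeiler's published
#'   defaults; no values are standard in the PPI literature).
#' @return `list(params, state)` with updated values.
#' @export
adadelta_step <- function(params, grads, state, rho = 0.95, eps = 1e-6) {
  stopifnot(rho > 0, rho < 1, eps > 0)
  for (nm in names(state$Eg)) {
    g <- grads[[nm]]
    state$Eg[[nm]] <- rho * state$Eg[[nm]] + (1 - rho) * g^2
    delta <- -sqrt(state$Ed[[nm]] + eps) / sqrt(state$Eg[[nm]] + eps) * g
    state$Ed[[nm]] <- rho * state$Ed[[nm]] + (1 - rho) * delta^2
    params[[nm]] <- params[[nm]] + delta
  }
  list(params = params, state = state)
}

#' Assemble a training/run configuration
#'
#' Defaults mirror the hyperparameter settings used on the benchmark
#' corpora (N = 20, d = 300, h = 3, M = 100, H = 500); desk-scale
#' experiments on synthetic corpora typically pass much smaller values.
#'
#' Variants: `"random"` — randomly initialized embeddings, frozen;
#' `"random_update"` — randomly initialized, fine-tuned during training;
#' `"pretrained"` — pretrained vectors where available (random
#' elsewhere), frozen; `"combined"` — two input channels, one pretrained
#' and one random table, pooled features concatenated, both frozen.
#' `trainable_embeddings` overrides the variant's default.
#'
#' @param variant one of `"random_update"`, `"random"`, `"pretrained"`,
#'   `"combined"`.
#' @param N,d,h,M,H model hyperparameters (fixed path length, embedding
#'   dimension, filter width, filter count per channel, hidden width).
#' @param epochs full passes over the training set.
#' @param seed integer run seed; all stage seeds derive from it.
#' @param rho,eps Adadelta decay and epsilon.
#' @param a uniform half-range for random embedding rows (overridden by
#'   the pretrained spread when a pretrained file is given).
#' @param truncate path truncation strategy, see [sdp_fit_length()].
#' @param shuffle reshuffle instance order each epoch?
#' @param trainable_embeddings `NULL` for the variant default, or a
#'   logical override.
#' @param pretrained `w2v_embeddings`, required for the `pretrained`
#'   and `combined` variants.
#' @param activation activation function name.
#' @return A list of class `sdpcnn_config`.
#' @export
sdpcnn_config <- function(variant = c("random_update", "random",
                                      "pretrained", "combined"),
                          N = 20L, d = 300L, h = 3L, M = 100L, H = 500L,
                          epochs = 100L, seed = 1L, rho = 0.95, eps = 1e-6,
                          a = 0.25, truncate = "middle", shuffle = TRUE,
                          trainable_embeddings = NULL, pretrained = NULL,
                          activation = "tanh") {
  variant <- match.arg(variant)
  stopifnot(epochs >= 1L, rho > 0, rho < 1, eps > 0)
  if (variant %in% c("pretrained", "combined") && is.null(pretrained))
    stop("variant '", variant, "' requires a pretrained embedding file")
  if (is.null(trainable_embeddings))
    trainable_embeddings <- identical(variant, "random_update")
  structure(list(variant = variant, N = as.integer(N), d = as.integer(d),
                 h = as.integer(h), M = as.integer(M), H = as.integer(H),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 rho = rho, eps = eps, a = a, truncate = truncate,
                 shuffle = shuffle,
                 trainable_embeddings = trainable_embeddings,
                 pretrained = pretrained, activation = activation),
            class = "sdpcnn_config")
}

index_parses <- function(parses) {
  stats::setNames(parses, vapply(parses, `[[`, "", "sentence_id"))
}

# Build the embedding table(s) a config calls for, from training
# vocabulary only.
build_tables <- function(vocab, config) {
  es <- derive_seed(config$seed, "embeddings")
  switch(config$variant,
    random = ,
    random_update = list(
      main = build_embedding_table(vocab, config$d, es, a = config$a,
                                   trainable = config$trainable_embeddings)),
    pretrained = list(
      main = build_embedding_table(vocab, config$d, es,
                                   pretrained = config$pretrained,
                                   trainable = config$trainable_embeddings)),
    combined = list(
      pre = build_embedding_table(vocab, config$d, es,
                                  pretrained = config$pretrained,
                                  trainable = config$trainable_embeddings),
      rand = build_embedding_table(vocab, config$d,
                                   derive_seed(config$seed, "embeddings2"),
                                   a = config$a,
                                   trainable = config$trainable_embeddings))
  )
}

# Adadelta row update for the embedding matrix of one table. `rows` maps
# sequence positions to table rows; the PADDING row and out-of-vocabulary
# positions are frozen.
update_embedding_rows <- function(table, estate, dP, rows, rho, eps) {
  ok <- !is.na(rows) & table$words[rows] != "PADDING"
  if (!any(ok)) return(list(table = table, estate = estate))
  G <- rowsum(dP[ok, , drop = FALSE], group = rows[ok])
  idx <- as.integer(rownames(G))
  estate$Eg[idx, ] <- rho * estate$Eg[idx, ] + (1 - rho) * G^2
  delta <- -sqrt(estate$Ed[idx, , drop = FALSE] + eps) /
    sqrt(estate$Eg[idx, , drop = FALSE] + eps) * G
  estate$Ed[idx, ] <- rho * estate$Ed[idx, ] + (1 - rho) * delta^2
  table$D[idx, ] <- table$D[idx, , drop = FALSE] + delta
  list(table = table, estate = estate)
}

# Row indices of one instance's sequence in each channel's table, plus
# the tokens themselves.
instance_lookup <- function(seqs, tables) {
  lapply(seqs, function(s)
    lapply(tables, function(tb) match(s$tokens, tb$words)))
}

#' Train a path-CNN model
#'
#' Extracts and length-fits the blinded shortest-path sequence of every
#' instance, builds the embedding table(s) from the training vocabulary,
#' initializes the network, and performs per-example stochastic updates:
#' one forward pass, one exact backward pass and one Adadelta step per
#' instance, with the epoch order reshuffled under a seed derived from
#' `config$seed`. Runs are bit-reproducible given the seed.
#'
#' @param instances list of `ppi_instance` objects (the training set).
#' @param parses list of `dep_parse` objects covering the instances.
#' @param config an `sdpcnn_config`.
#' @return A list of class `sdpcnn_model`: `$params`, `$tables`,
#'   `$config`, `$hyper`, `$loss_log` (data frame with per-epoch mean
#'   loss and training accuracy), `$vocab`.
#' @export
train_sdpcnn <- function(instances, parses, config) {
  stopifnot(inherits(config, "sdpcnn_config"), length(instances) >= 1L)
  by_id <- index_parses(parses)
  seqs <- lapply(instances, function(ins) {
    p <- by_id[[ins$sentence_id]]
    if (is.null(p)) stop("no parse for sentence '", ins$sentence_id, "'")
    extract_sdp(p, ins, n_fixed = config$N, truncate = config$truncate)
  })
  labels <- vapply(instances, function(ins) ins$label, 0L)
  if (length(unique(labels)) < 2L)
    warning("training set contains a single class")

  vocab <- unique(unlist(lapply(seqs, `[[`, "tokens")))
  tables <- build_tables(vocab, config)
  channels <- if (config$variant == "combined") 2L else 1L
  params <- init_model_params(config$N, config$d, config$h, config$M,
                              config$H, seed = config$seed,
                              channels = channels,
                              activation = config$activation)
  state <- adadelta_init(params[PARAM_NAMES])
  trainable <- config$trainable_embeddings
  estates <- if (trainable)
    lapply(tables, function(tb) adadelta_init(list(D = tb$D))) # reuse shapes
  rows_by_inst <- lapply(seqs, function(s)
    lapply(tables, function(tb) match(s$tokens, tb$words)))

  n <- length(instances)
  log_loss <- numeric(config$epochs)
  log_acc <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle) {
      set.seed(derive_seed(config$seed, paste0("shuffle:", epoch)))
      sample.int(n)
    } else seq_len(n)
    losses <- numeric(n)
    correct <- logical(n)
    for (i in ord) {
      rows <- rows_by_inst[[i]]
      Ps <- lapply(seq_along(tables), function(ch)
        tables[[ch]]$D[rows[[ch]], , drop = FALSE])
      trace <- sdpcnn_forward(if (channels == 1L) Ps[[1L]] else Ps, params)
      y <- labels[i]
      losses[i] <- nll(trace$S, y)
      correct[i] <- (which.max(trace$S) - 1L) == y
      grads <- sdpcnn_backward(trace, y, params, trainable_embeddings = trainable)
      upd <- adadelta_step(params[PARAM_NAMES], grads[PARAM_NAMES], state,
                           rho = config$rho, eps = config$eps)
      params[PARAM_NAMES] <- upd$params
      state <- upd$state
      if (trainable) {
        for (ch in seq_along(tables)) {
          res <- update_embedding_rows(tables[[ch]],
                                       list(Eg = estates[[ch]]$Eg$D,
                                            Ed = estates[[ch]]$Ed$D),
                                       grads$P[[ch]], rows[[ch]],
                                       config$rho, config$eps)
          tables[[ch]] <- res$table
          estates[[ch]]$Eg$D <- res$estate$Eg
          estates[[ch]]$Ed$D <- res$estate$Ed
        }
      }
    }
    log_loss[epoch] <- mean(losses)
    log_acc[epoch] <- mean(correct)
  }
  structure(list(params = params, tables = tables, config = config,
                 hyper = params$hyper,
                 loss_log = data.frame(epoch = seq_len(config$epochs),
                                       loss = log_loss,
                                       accuracy = log_acc),
                 vocab = vocab),
            class = "sdpcnn_model")
}

#' Predict interactions for instances with a trained model
#'
#' Extracts each instance's path sequence with the training-time length
#' and truncation settings, embeds it against the trained table(s)
#' (out-of-vocabulary tokens get stable random vectors), and runs the
#' forward pass. The predicted label is the argmax class; an exact
#' probability tie resolves to 0 (no interaction).
#'
#' @param object an `sdpcnn_model`.
#' @param parses list of parses covering the instances.
#' @param instances list of `ppi_instance` objects.
#' @param type `"response"` for a data frame of labels and
#'   probabilities, `"trace"` to also return forward traces and
#'   sequences (needed for key-word attribution).
#' @param ... unused.
#' @return For `type = "response"`, a data frame with columns
#'   `instance_id`, `prob_interaction`, `label`. For `"trace"`, a list
#'   with that data frame plus `$traces` and `$seqs`.
#' @export
predict.sdpcnn_model <- function(object, parses, instances,
                                 type = c("response", "trace"), ...) {
  type <- match.arg(type)
  by_id <- index_parses(parses)
  config <- object$config
  n <- length(instances)
  probs <- numeric(n)
  traces <- if (type == "trace") vector("list", n)
  seqs <- if (type == "trace") vector("list", n)
  for (i in seq_len(n)) {
    ins <- instances[[i]]
    p <- by_id[[ins$sentence_id]]
    if (is.null(p)) stop("no parse for sentence '", ins$sentence_id, "'")
    s <- extract_sdp(p, ins, n_fixed = config$N, truncate = config$truncate)
    Ps <- lapply(object$tables, function(tb)
      suppressMessages(embed_lookup(s, tb))$P)
    trace <- sdpcnn_forward(if (length(Ps) == 1L) Ps[[1L]] else Ps,
                            object$params)
    probs[i] <- trace$S[2L]
    if (type == "trace") {
      traces[[i]] <- trace
      seqs[[i]] <- s
    }
  }
  out <- data.frame(
    instance_id = vapply(instances, `[[`, "", "instance_id"),
    prob_interaction = probs,
    label = as.integer(probs > 0.5),
    stringsAsFactors = FALSE)
  if (type == "response") out
  else list(predictions = out, traces = traces, seqs = seqs)
}
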