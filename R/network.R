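# The path-CNN itself: convolution over the path matrix, max-over-time
# pooling, one hidden full-connection layer, softmax; plus the key-word
# attribution operation and the dual-channel "combined" variant.

PARAM_NAMES <- c("W", "b1", "W2", "b2", "W3")

#' Initialize network parameters
#'
#' The model is parameterised by theta = (W, W2, W3, b1, b2): M
#' convolution filters of shape h x d with biases b1, a hidden
#' full-connection layer W2 (H x M) with biases b2, and the confidence
#' transform W3 (C x H, C = 2, no bias). All weights are drawn uniform
#' from [-0.05, 0.05] under a sub-seed derived from `seed`. With
#' `channels = 2` (the combined variant) a second, independent filter
#' bank is appended and W2 widens to H x 2M.
#'
#' @param N fixed input path length.
#' @param d embedding dimension.
#' @param h filter width in tokens (default 3; odd widths give the
#'   key-word a well-defined middle token — for even h the token left of
#'   centre is used, with a warning here).
#' @param M number of filters per channel.
#' @param H hidden layer width.
#' @param seed integer run seed.
#' @param channels 1, or 2 for the dual-channel combined variant.
#' @param activation activation name for the convolution and hidden
#'   layers (`"tanh"`, the default, or `"relu"`).
#' @return A list of class `sdpcnn_params` with the weight arrays and
#'   `$hyper = list(N, d, h, M, H, C, channels)`.
#' @export
init_model_params <- function(N, d, h = 3L, M, H, seed = 1L, channels = 1L,
                              activation = "tanh") {
  N <- as.integer(N); d <- as.integer(d); h <- as.integer(h)
  M <- as.integer(M); H <- as.integer(H); channels <- as.integer(channels)
  stopifnot(N >= 3L, d >= 1L, M >= 1L, H >= 1L, channels %in% c(1L, 2L))
  if (h > N) stop("filter width h = ", h, " exceeds input length N = ", N)
  if (h %% 2L == 0L)
    warning("even filter width h = ", h,
            ": key-words use the token left of the window centre")
  get_activation(activation)  # validate name
  Mt <- M * channels
  set.seed(derive_seed(seed, "weights"))
  runi <- function(n) stats::runif(n, -0.05, 0.05)
  structure(list(
    W = array(runi(h * d * Mt), dim = c(h, d, Mt)),
    b1 = numeric(Mt),  # zero-init: a positive bias would make the all-zero
    # PADDING window the argmax of a fresh filter, which convolution
    # weights can never escape (the window contributes no W gradient)
    W2 = matrix(runi(H * Mt), H, Mt),
    b2 = runi(H),
    W3 = matrix(runi(2L * H), 2L, H),
    hyper = list(N = N, d = d, h = h, M = M, H = H, C = 2L,
                 channels = channels),
    activation = activation
  ), class = "sdpcnn_params")
}

# Stack the h-row sliding windows of P as rows of an (N-h+1) x (h*d)
# matrix (column-major flattening, matching matrix(W_k) below).
conv_windows <- function(P, h) {
  N <- nrow(P)
  L <- N - h + 1L
  X <- matrix(0, L, h * ncol(P))
  for (i in seq_len(L))
    X[i, ] <- as.vector(P[i:(i + h - 1L), , drop = FALSE])
  X
}

#' Apply one convolution filter to a path matrix
#'
#' Slides the h x d filter over all h-token windows of P with stride 1;
#' each feature is `f(<W_k, P[i..i+h-1, ]> + b)` where `<.,.>` sums the
#' elementwise product over all h*d window entries (the only reading of
#' an elementwise product that yields a scalar feature). Returns the
#' feature map of length `nrow(P) - h + 1`.
#'
#' @param P N x d path matrix.
#' @param W_k h x d filter.
#' @param b scalar bias.
#' @param f activation function (default [tanh]).
#' @return Numeric feature map of length N - h + 1.
#' @export
convolve_filter <- function(P, W_k, b, f = tanh) {
  h <- nrow(W_k)
  if (h > nrow(P))
    stop("filter width h = ", h, " exceeds input length N = ", nrow(P))
  as.vector(f(conv_windows(P, h) %*% as.vector(W_k) + b))
}

#' Max-over-time pooling of a feature map
#'
#' Takes the maximum over all window positions, reducing each filter's
#' response to one scalar regardless of path length. Ties resolve to the
#' first (smallest-index) maximum.
#'
#' @param feature_map non-empty numeric vector.
#' @return `list(value, index)`.
#' @export
max_pool <- function(feature_map) {
  if (!length(feature_map)) stop("empty feature map")
  i <- which.max(feature_map)
  list(value = feature_map[[i]], index = as.integer(i))
}

as_path_matrix_list <- function(P, hyper) {
  Ps <- if (inherits(P, "path_matrix")) list(P$P)
        else if (is.matrix(P)) list(P)
        else lapply(P, function(x) if (inherits(x, "path_matrix")) x$P else x)
  if (length(Ps) != hyper$channels)
    stop("model has ", hyper$channels, " input channel(s) but ",
         length(Ps), " path matrices were supplied")
  for (Pm in Ps)
    if (!is.matrix(Pm) || nrow(Pm) != hyper$N || ncol(Pm) != hyper$d)
      stop("path matrix must be ", hyper$N, " x ", hyper$d, ", got ",
           nrow(Pm), " x ", ncol(Pm))
  Ps
}

check_finite <- function(x, layer) {
  if (!all(is.finite(x)))
    stop("non-finite values in layer '", layer, "'")
  x
}

#' Forward pass of the path CNN
#'
#' Computes, and retains for backpropagation and attribution, every
#' intermediate: the windowed inputs, all M feature maps, the pooled
#' vector r with the argmax position per filter, the hidden layer
#' `O = f(W2 r + b2)`, the class confidences `I = W3 O` (no bias term),
#' and the softmax probabilities S (computed with max-subtraction for
#' numerical stability).
#'
#' For a combined (two-channel) model, pass a list of two path matrices
#' — typically one from a pretrained table and one from a random table —
#' whose pooled vectors are concatenated before the hidden layer.
#'
#' @param P an N x d matrix, a `path_matrix`, or a list of them for the
#'   two-channel variant.
#' @param params an `sdpcnn_params` object.
#' @return A list of class `sdpcnn_trace` holding `P`, `X`,
#'   `feature_maps` (an (N-h+1) x (M*channels) matrix), `pooled`,
#'   `argmax`, `O`, `I`, `S`.
#' @export
sdpcnn_forward <- function(P, params) {
  hy <- params$hyper
  act <- get_activation(params$activation)
  Ps <- as_path_matrix_list(P, hy)
  L <- hy$N - hy$h + 1L
  Mt <- hy$M * hy$channels
  Wmat <- matrix(params$W, hy$h * hy$d, Mt)
  fmap <- matrix(0, L, Mt)
  Xs <- vector("list", hy$channels)
  for (ch in seq_len(hy$channels)) {
    cols <- ((ch - 1L) * hy$M + 1L):(ch * hy$M)
    X <- conv_windows(Ps[[ch]], hy$h)
    A <- check_finite(X %*% Wmat[, cols, drop = FALSE] +
      matrix(params$b1[cols], L, hy$M, byrow = TRUE), "convolution")
    fmap[, cols] <- act$f(A)
    Xs[[ch]] <- X
  }
  check_finite(fmap, "convolution")
  argmax <- apply(fmap, 2L, which.max)
  pooled <- fmap[cbind(argmax, seq_len(Mt))]
  O <- check_finite(as.vector(act$f(params$W2 %*% pooled + params$b2)),
                    "full-connection")
  I <- check_finite(as.vector(params$W3 %*% O), "confidence")
  S <- softmax_stable(I)
  structure(list(P = Ps, X = Xs, feature_maps = fmap, pooled = pooled,
                 argmax = as.integer(argmax), O = O, I = I, S = S),
            class = "sdpcnn_trace")
}

#' Key-words: which token each filter responded to
#'
#' Follows each filter's pooled maximum back to the window that produced
#' it and reports the token in the middle of that window — an
#' attribution device identifying what the filter detected. In practice
#' interaction verbs (and the relation labels flanking them) dominate
#' these positions on predicted-positive instances. `PADDING` key-words
#' are reported as-is.
#'
#' @param trace an `sdpcnn_trace` produced from `seq`.
#' @param seq the `sdp_sequence` (or character token vector) the trace
#'   was computed from.
#' @param params the model parameters used.
#' @return Character vector of `M * channels` key-words, one per filter.
#' @export
sdpcnn_keywords <- function(trace, seq, params) {
  tokens <- if (inherits(seq, "sdp_sequence")) seq$tokens
            else as.character(seq)
  offset <- (params$hyper$h - 1L) %/% 2L
  tokens[trace$argmax + offset]
}
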