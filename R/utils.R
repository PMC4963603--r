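# Shared internal helpers: reserved symbols, seed derivation, softmax.

reserved_tokens <- function() c("PADDING", "Protein1", "Protein2")

#' Derive a named sub-seed from a run seed
#'
#' Every source of randomness in the package (embedding initialization,
#' network weight initialization, epoch shuffling, fold assignment, corpus
#' synthesis) draws from its own sub-seed, derived deterministically from
#' the single run seed and a short stage tag. This keeps a whole run
#' reproducible from one integer while letting each stage be re-run in
#' isolation.
#'
#' @param seed single integer run seed.
#' @param tag character stage name, e.g. `"weights"` or `"folds"`.
#' @return An integer in `[0, 2^31)` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "weights")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(tag), length(tag) == 1L)
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 1000003
  # all intermediates stay well below 2^53, so double arithmetic is exact
  as.integer(((abs(seed) %% 2146483647) * 7919 + h * 104729) %% 2147483629)
}

# Numerically stable softmax (max-subtraction; the textbook form overflows
# for large confidences).
softmax_stable <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Activation functions usable in the network; value and derivative
# expressed in terms of the activation *output* (enough for tanh/relu).
get_activation <- function(name) {
  switch(name,
    tanh = list(f = tanh, deriv_from_output = function(y) 1 - y^2),
    relu = list(f = function(x) pmax(x, 0),
                deriv_from_output = function(y) as.numeric(y > 0)),
    stop("unknown activation: ", name)
  )
}
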