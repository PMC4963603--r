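# Versioned JSON model container: self-describing, full double
# precision, validated on load.

MODEL_FORMAT <- "sdpcnn-model"
MODEL_VERSION <- 1L

# Numbers are stored as %.17g strings: 17 significant digits round-trip
# IEEE doubles exactly, which JSON number emitters do not guarantee.
ser_array <- function(a) {
  list(dim = as.integer(dim(a) %||% length(a)),
       data = sprintf("%.17g", as.vector(a)))
}

deser_array <- function(rec, what) {
  dims <- as.integer(rec$dim)
  data <- as.numeric(unlist(rec$data))
  if (length(data) != prod(dims))
    stop("corrupt model container: '", what, "' declares dim [",
         paste(dims, collapse = " x "), "] but holds ", length(data),
         " values")
  if (length(dims) == 1L) data else array(data, dim = dims)
}

ser_table <- function(tb) {
  list(words = tb$words, D = ser_array(tb$D), d = tb$d, a = tb$a,
       seed = tb$seed, provenance = tb$provenance, trainable = tb$trainable)
}

deser_table <- function(rec) {
  D <- deser_array(rec$D, "embedding matrix")
  if (!is.matrix(D)) D <- matrix(D, ncol = rec$d)
  if (nrow(D) != length(rec$words) || ncol(D) != rec$d)
    stop("corrupt model container: embedding matrix is ", nrow(D), " x ",
         ncol(D), " for ", length(rec$words), " words of dimension ", rec$d)
  structure(list(words = rec$words, D = D, d = as.integer(rec$d),
                 a = rec$a, seed = as.integer(rec$seed),
                 provenance = rec$provenance, trainable = rec$trainable),
            class = "embedding_table")
}

#' Save a trained model to a versioned JSON container
#'
#' Everything needed to reproduce predictions is stored: hyperparameters,
#' the resolved training configuration (minus any in-memory pretrained
#' records), all weight arrays at full double precision, the embedding
#' table(s), and the training loss log. [load_model()] on the result
#' reproduces forward passes bit-exactly.
#'
#' @param model an `sdpcnn_model`.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sdpcnn_model"))
  cfg <- unclass(model$config)
  cfg$pretrained <- NULL
  obj <- list(
    format = MODEL_FORMAT,
    version = MODEL_VERSION,
    hyper = model$hyper,
    config = cfg,
    activation = model$params$activation,
    params = lapply(model$params[PARAM_NAMES], ser_array),
    tables = lapply(model$tables, ser_table),
    loss_log = as.list(model$loss_log),
    vocab = model$vocab
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' Validates the container: format tag and version must match, every
#' stored array must agree with its declared dimensions, and the weight
#' shapes must be consistent with the stored hyperparameters (a tampered
#' dimension is an error, never a silent reshape).
#'
#' @param path path to the JSON container.
#' @return An `sdpcnn_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$format, MODEL_FORMAT))
    stop("not a model container: format tag is '", obj$format, "'")
  if (!identical(as.integer(obj$version), MODEL_VERSION))
    stop("unsupported model container version ", obj$version,
         " (this build reads version ", MODEL_VERSION, ")")
  hy <- obj$hyper
  hy[c("N", "d", "h", "M", "H", "C", "channels")] <-
    lapply(hy[c("N", "d", "h", "M", "H", "C", "channels")], as.integer)
  Mt <- hy$M * hy$channels
  params <- lapply(stats::setNames(PARAM_NAMES, PARAM_NAMES), function(nm)
    deser_array(obj$params[[nm]], nm))
  expected <- list(W = c(hy$h, hy$d, Mt), b1 = Mt, W2 = c(hy$H, Mt),
                   b2 = hy$H, W3 = c(hy$C, hy$H))
  for (nm in PARAM_NAMES) {
    got <- dim(params[[nm]]) %||% length(params[[nm]])
    if (!identical(as.integer(got), as.integer(expected[[nm]])))
      stop("model container shape mismatch: '", nm, "' is [",
           paste(got, collapse = " x "), "] but hyperparameters require [",
           paste(expected[[nm]], collapse = " x "), "]")
  }
  params$hyper <- hy
  params$activation <- obj$activation
  class(params) <- "sdpcnn_params"
  cfg <- obj$config
  cfg[c("N", "d", "h", "M", "H", "epochs", "seed")] <-
    lapply(cfg[c("N", "d", "h", "M", "H", "epochs", "seed")], as.integer)
  class(cfg) <- "sdpcnn_config"
  loss_log <- as.data.frame(lapply(obj$loss_log, unlist))
  structure(list(params = params,
                 tables = lapply(obj$tables, deser_table),
                 config = cfg,
                 hyper = hy,
                 loss_log = loss_log,
                 vocab = unlist(obj$vocab)),
            class = "sdpcnn_model")
}
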