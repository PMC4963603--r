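# Evaluation: precision/recall/F, stratified k-fold cross-validation,
# learning curves, key-word frequency reporting.

#' Precision, recall and F-score of binary predictions
#'
#' Positive class is 1 (interaction). `F = 2PR / (P + R)`, the harmonic
#' mean of precision and recall. Zero-denominator conventions: a metric
#' whose denominator is zero is defined as 0.
#'
#' @param predictions,golds equal-length vectors over \{0, 1\}.
#' @return A list of class `ppi_metrics` with `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f`.
#' @export
ppi_score <- function(predictions, golds) {
  if (length(predictions) != length(golds))
    stop("predictions and golds differ in length")
  stopifnot(all(predictions %in% c(0, 1)), all(golds %in% c(0, 1)))
  tp <- sum(predictions == 1 & golds == 1)
  fp <- sum(predictions == 1 & golds == 0)
  fn <- sum(predictions == 0 & golds == 1)
  tn <- sum(predictions == 0 & golds == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f = f),
            class = "ppi_metrics")
}

#' @export
print.ppi_metrics <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F = %.4f  (tp %d, fp %d, fn %d, tn %d)\n",
              x$precision, x$recall, x$f, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Assigns each instance to one of `k` folds so that class proportions
#' are preserved per fold and overall fold sizes differ by at most one
#' (the second class continues the cyclic assignment where the first
#' left off).
#'
#' @param labels vector of 0/1 labels.
#' @param k number of folds.
#' @param seed integer seed for the within-class shuffles.
#' @return Integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  stopifnot(k >= 2L, n >= k)
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cls in sort(unique(labels))) {
    ids <- which(labels == cls)
    ids <- ids[sample.int(length(ids))]
    fold[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
    offset <- offset + length(ids)
  }
  fold
}

#' k-fold cross-validation of the path CNN
#'
#' Stratified instance-level folds (seeded from the config seed): for
#' each fold, a model is trained from scratch on the other k-1 folds —
#' vocabulary and embedding tables are rebuilt from that training data
#' only, so held-out surface forms never leak into the table — and
#' scored on the held-out fold. Reports per-fold and mean metrics and
#' the fold assignment.
#'
#' @param instances list of `ppi_instance` objects.
#' @param parses list of parses covering them.
#' @param config an `sdpcnn_config`.
#' @param k number of folds, default 10.
#' @return A list of class `cv_report`: `$per_fold` (list of
#'   `ppi_metrics`), `$mean_precision`, `$mean_recall`, `$mean_f`,
#'   `$assignment` (data frame instance_id/fold), `$models` omitted to
#'   keep the object small.
#' @export
cross_validate <- function(instances, parses, config, k = 10L) {
  n <- length(instances)
  if (n < k) stop("need at least k = ", k, " instances, got ", n)
  labels <- vapply(instances, function(ins) ins$label, 0L)
  fold <- make_folds(labels, k, derive_seed(config$seed, "folds"))
  per_fold <- vector("list", k)
  for (j in seq_len(k)) {
    train_set <- instances[fold != j]
    test_set <- instances[fold == j]
    gold <- labels[fold == j]
    if (!any(gold == 1))
      warning("fold ", j, " holds no positive instance")
    model <- train_sdpcnn(train_set, parses, config)
    preds <- predict(model, parses, test_set)
    per_fold[[j]] <- ppi_score(preds$label, gold)
  }
  structure(list(
    per_fold = per_fold,
    mean_precision = mean(vapply(per_fold, `[[`, 0, "precision")),
    mean_recall = mean(vapply(per_fold, `[[`, 0, "recall")),
    mean_f = mean(vapply(per_fold, `[[`, 0, "f")),
    assignment = data.frame(
      instance_id = vapply(instances, `[[`, "", "instance_id"),
      fold = fold, stringsAsFactors = FALSE)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean P = %.4f  R = %.4f  F = %.4f\n",
              length(x$per_fold), x$mean_precision, x$mean_recall, x$mean_f))
  invisible(x)
}

#' Learning curve over held-out test fractions
#'
#' For each test fraction, makes one stratified train/test split per
#' seed, trains on the remainder and scores on the test portion,
#' averaging metrics over seeds. Fractions leaving fewer than 10
#' training instances are skipped with a warning. Larger test fractions
#' mean smaller training sets, so the F-score declines as the fraction
#' grows.
#'
#' @param instances,parses,config as in [cross_validate()].
#' @param test_fractions fractions in (0, 1) of the data held out for
#'   testing; default 0.1 to 0.9.
#' @param seeds integer vector of run seeds to average over; default the
#'   config seed alone.
#' @return A data frame with one row per fraction: `fraction`,
#'   `n_train`, `n_test`, `precision`, `recall`, `f` (seed means).
#' @export
learning_curve <- function(instances, parses, config,
                           test_fractions = seq(0.1, 0.9, by = 0.1),
                           seeds = NULL) {
  stopifnot(all(test_fractions > 0), all(test_fractions < 1))
  if (is.null(seeds)) seeds <- config$seed
  labels <- vapply(instances, function(ins) ins$label, 0L)
  rows <- list()
  for (frac in test_fractions) {
    ms <- list()
    n_train <- n_test <- NA_integer_
    for (s in seeds) {
      set.seed(derive_seed(s, paste0("curve:", frac)))
      test_idx <- unlist(lapply(sort(unique(labels)), function(cls) {
        ids <- which(labels == cls)
        sample(ids, round(length(ids) * frac))
      }))
      train_idx <- setdiff(seq_along(instances), test_idx)
      if (length(train_idx) < 10L) {
        warning("test fraction ", frac, " leaves only ", length(train_idx),
                " training instances; skipped")
        ms <- list()
        break
      }
      cfg <- config
      cfg$seed <- as.integer(s)
      model <- train_sdpcnn(instances[train_idx], parses, cfg)
      preds <- predict(model, parses, instances[test_idx])
      ms[[length(ms) + 1L]] <- ppi_score(preds$label, labels[test_idx])
      n_train <- length(train_idx); n_test <- length(test_idx)
    }
    if (!length(ms)) next
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = frac, n_train = n_train, n_test = n_test,
      precision = mean(vapply(ms, `[[`, 0, "precision")),
      recall = mean(vapply(ms, `[[`, 0, "recall")),
      f = mean(vapply(ms, `[[`, 0, "f")))
  }
  if (!length(rows))
    return(data.frame(fraction = numeric(0), n_train = integer(0),
                      n_test = integer(0), precision = numeric(0),
                      recall = numeric(0), f = numeric(0)))
  do.call(rbind, rows)
}

#' Key-word frequency report over predicted-positive instances
#'
#' Runs the model over the instances, keeps those predicted positive,
#' collects each filter's key-word (the middle token of its maximising
#' window) and tabulates them, ranked by descending count with ties
#' broken by token string. On corpora with genuine interaction signal
#' the top ranks recover interaction verbs — an automatically extracted
#' interaction-verb dictionary.
#'
#' @param model a trained `sdpcnn_model`.
#' @param instances,parses the data to attribute over.
#' @return A data frame with columns `token` and `count`; the total
#'   count equals `M * channels` times the number of predicted-positive
#'   instances.
#' @export
keyword_report <- function(model, instances, parses) {
  if (!length(instances))
    return(data.frame(token = character(0), count = integer(0)))
  res <- predict(model, parses, instances, type = "trace")
  pos <- which(res$predictions$label == 1L)
  if (!length(pos))
    return(data.frame(token = character(0), count = integer(0)))
  kws <- unlist(lapply(pos, function(i)
    sdpcnn_keywords(res$traces[[i]], res$seqs[[i]], model$params)))
  tab <- table(kws)
  out <- data.frame(token = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$token), , drop = FALSE]
}
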