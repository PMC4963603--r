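# Convolution, pooling, forward pass, attribution, dual channel.

test_that("feature maps have length N-h+1 and match the naive double loop", {
  set.seed(501)
  for (rep in seq_len(30)) {
    N <- sample(5:12, 1); d <- sample(2:6, 1)
    h <- sample(seq(3, min(N, 5), by = 2), 1)
    P <- matrix(rnorm(N * d), N, d)
    W_k <- matrix(rnorm(h * d), h, d)
    b <- rnorm(1)
    fm <- convolve_filter(P, W_k, b)
    expect_length(fm, N - h + 1)
    expect_lt(max(abs(fm - naive_feature_map(P, W_k, b))), 1e-10)
  }
})

test_that("a zero filter with zero bias yields an all-zero feature map", {
  P <- matrix(rnorm(21), 7, 3)
  expect_identical(convolve_filter(P, matrix(0, 3, 3), 0), rep(0, 5))
  expect_error(convolve_filter(matrix(0, 2, 3), matrix(0, 3, 3), 0),
               "exceeds input length")
})

test_that("max pooling takes the first maximum", {
  expect_identical(max_pool(c(0.1, 0.9, 0.9)), list(value = 0.9, index = 2L))
  expect_identical(max_pool(rep(0.3, 4))$index, 1L)
  expect_error(max_pool(numeric(0)), "empty")
  set.seed(88)
  for (rep in seq_len(50)) {
    fm <- rnorm(sample(1:20, 1))
    mp <- max_pool(fm)
    srt <- sort(fm, decreasing = TRUE)  # sort-based oracle
    expect_identical(mp$value, srt[1])
    expect_identical(mp$index, which(fm == srt[1])[1])
  }
})

test_that("softmax output is normalized, in (0,1), and shift-invariant", {
  setup <- tiny_setup("random")
  P <- suppressMessages(embed_lookup(setup$tokens, setup$tables$main))$P
  tr <- sdpcnn_forward(P, setup$params)
  expect_equal(sum(tr$S), 1, tolerance = 1e-12)
  expect_true(all(tr$S > 0 & tr$S < 1))
  expect_true(all(tr$pooled == apply(tr$feature_maps, 2, max)))

  # zero confidence transform: uniform output
  p0 <- setup$params
  p0$W3[] <- 0
  expect_equal(sdpcnn_forward(P, p0)$S, c(0.5, 0.5))

  # adding a constant to both confidences leaves S unchanged
  set.seed(91)
  for (kappa in c(1e3, -50, 7)) {
    I <- rnorm(2)
    expect_equal(sdpcnn:::softmax_stable(I + kappa),
                 sdpcnn:::softmax_stable(I), tolerance = 1e-12)
  }
  # the textbook form would overflow here; the stable form must not
  expect_equal(sum(sdpcnn:::softmax_stable(c(1e4, 1e4 - 2))), 1)
})

test_that("increasing a feature-map entry never decreases the pooled value", {
  set.seed(92)
  fm <- rnorm(9)
  base <- max_pool(fm)$value
  for (j in seq_along(fm)) {
    bumped <- fm
    bumped[j] <- bumped[j] + abs(rnorm(1))
    expect_gte(max_pool(bumped)$value, base)
  }
})

test_that("permuting filters together with W2 columns leaves S unchanged", {
  setup <- tiny_setup("random", M = 4L)
  P <- suppressMessages(embed_lookup(setup$tokens, setup$tables$main))$P
  tr <- sdpcnn_forward(P, setup$params)
  perm <- c(3L, 1L, 4L, 2L)
  pp <- setup$params
  pp$W <- pp$W[, , perm, drop = FALSE]
  pp$b1 <- pp$b1[perm]
  pp$W2 <- pp$W2[, perm, drop = FALSE]
  tr2 <- sdpcnn_forward(P, pp)
  expect_equal(tr2$pooled, tr$pooled[perm], tolerance = 1e-14)
  expect_equal(tr2$S, tr$S, tolerance = 1e-14)
})

test_that("zero-padding suffix never alters windows inside the prefix", {
  set.seed(93)
  d <- 4L; h <- 3L
  P_short <- matrix(rnorm(6 * d), 6, d)
  P_padded <- rbind(P_short, matrix(0, 4, d))
  W_k <- matrix(rnorm(h * d), h, d)
  fm_short <- convolve_filter(P_short, W_k, 0.2)
  fm_padded <- convolve_filter(P_padded, W_k, 0.2)
  expect_equal(fm_padded[seq_along(fm_short)], fm_short)
})

test_that("key-words are the middle tokens of the maximising windows", {
  setup <- tiny_setup("random", M = 3L)
  P <- suppressMessages(embed_lookup(setup$tokens, setup$tables$main))$P
  tr <- sdpcnn_forward(P, setup$params)
  kw <- sdpcnn_keywords(tr, setup$tokens, setup$params)
  expect_identical(kw, setup$tokens[tr$argmax + 1L])  # (h-1)/2 = 1

  # N = h: a single window; the key-word is the middle of the sequence
  one <- tiny_setup("random", N = 3L, M = 2L)
  toks <- c("Protein1", "nsubj", "Protein2")
  P1 <- suppressMessages(embed_lookup(toks, one$tables$main))$P
  tr1 <- sdpcnn_forward(P1, one$params)
  expect_identical(sdpcnn_keywords(tr1, toks, one$params),
                   rep("nsubj", 2L))
})

test_that("the combined forward concatenates per-channel pooled vectors", {
  setup <- tiny_setup("combined", M = 2L)
  Ps <- lapply(setup$tables, function(tb)
    suppressMessages(embed_lookup(setup$tokens, tb))$P)
  tr <- sdpcnn_forward(Ps, setup$params)
  expect_length(tr$pooled, 4L)

  # identical channels with duplicated filters: pooled repeats twice
  pp <- setup$params
  pp$W[, , 3:4] <- pp$W[, , 1:2]
  pp$b1[3:4] <- pp$b1[1:2]
  tr_dup <- sdpcnn_forward(list(Ps[[1]], Ps[[1]]), pp)
  expect_equal(tr_dup$pooled[1:2], tr_dup$pooled[3:4], tolerance = 1e-14)

  # zero second-channel filters: its pooled values are tanh(b1)
  pz <- setup$params
  pz$W[, , 3:4] <- 0
  trz <- sdpcnn_forward(Ps, pz)
  expect_equal(trz$pooled[3:4], tanh(pz$b1[3:4]), tolerance = 1e-14)

  expect_error(sdpcnn_forward(Ps[[1]], setup$params), "2 input channel")
})

test_that("non-finite inputs are reported with the failing layer", {
  setup <- tiny_setup("random")
  P <- suppressMessages(embed_lookup(setup$tokens, setup$tables$main))$P
  P[2, 1] <- Inf
  expect_error(sdpcnn_forward(P, setup$params), "convolution")
})

test_that("even filter widths warn at build time", {
  expect_warning(init_model_params(6L, 4L, h = 2L, M = 2L, H = 3L, seed = 1L),
                 "even filter width")
})
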