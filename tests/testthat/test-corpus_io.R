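# Readers/writers: CoNLL-style parses, JSON-lines instances, word2vec
# files, model container.

write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("the worked-example sentence reads back from a CoNLL file", {
  we <- worked_example()
  path <- withr::local_tempfile()
  write_parses(list(we$parse), path)
  parses <- read_parses(path)
  expect_length(parses, 1L)
  expect_equal(nrow(parses[[1]]$tokens), 8L)
  expect_identical(parses[[1]]$sentence_id, "fig2")
  expect_identical(parses[[1]]$tokens, we$parse$tokens)
})

test_that("10-column CoNLL-U rows are accepted, extra columns ignored", {
  path <- write_tmp(c(
    "# sent_id = u1",
    "1\tProfilin\tprofilin\tNOUN\tNN\t_\t2\tnsubj\t_\t_",
    "2\tbinds\tbind\tVERB\tVBZ\t_\t0\troot\t_\t_",
    "3\tactin\tactin\tNOUN\tNN\t_\t2\tdobj\t_\t_"))
  parses <- read_parses(path)
  expect_identical(parses[[1]]$tokens$form, c("Profilin", "binds", "actin"))
  expect_identical(parses[[1]]$tokens$head, c(2L, 0L, 2L))
  expect_identical(parses[[1]]$tokens$deprel, c("nsubj", "root", "dobj"))
})

test_that("malformed, out-of-range and disconnected parses are rejected", {
  expect_error(read_parses(write_tmp(c("1 only-two"))), "malformed.*line 1")
  expect_error(read_parses(write_tmp(c("1 w1 99 dep",
                                       "2 w2 0 root",
                                       "3 w3 2 dobj",
                                       "4 w4 2 dobj",
                                       "5 w5 2 dobj"))),
               "head index out of range")
  # two islands: {1,2} and {3,4}
  expect_error(read_parses(write_tmp(c("1 a 2 amod", "2 b 0 root",
                                       "3 c 4 amod", "4 d 3 conj"))),
               "own head|disconnected")
  expect_error(read_parses(write_tmp(c("1 a 2 amod", "2 b 0 root",
                                       "3 c 4 conj", "4 d 0 root"))),
               "disconnected")
  expect_error(read_parses(write_tmp(c("1 a 2 ", "2 b 0 root"))),
               "malformed")
})

test_that("an empty parse file yields an empty list", {
  expect_identical(read_parses(write_tmp(character(0))), list())
})

test_that("instances round-trip and are cross-checked against parses", {
  we <- worked_example()
  ipath <- withr::local_tempfile()
  write_instances(list(we$instance), ipath)
  back <- read_instances(ipath, parses = list(we$parse))
  expect_identical(back[[1]]$e1, c(1L, 2L))
  expect_identical(back[[1]]$e2, c(8L, 8L))
  expect_identical(back[[1]]$label, 1L)

  bad_label <- '{"instance_id":"x","sentence_id":"fig2","e1":[1,2],"e2":[8,8],"label":2}'
  expect_error(read_instances(write_tmp(bad_label)), "label")
  same_span <- '{"instance_id":"x","sentence_id":"fig2","e1":[1,2],"e2":[1,2],"label":1}'
  expect_error(read_instances(write_tmp(same_span)), "identical")
  bad_sent <- '{"instance_id":"x","sentence_id":"nope","e1":[1,1],"e2":[2,2],"label":0}'
  expect_error(read_instances(write_tmp(bad_sent), parses = list(we$parse)),
               "unknown sentence_id")
  out_of_range <- '{"instance_id":"x","sentence_id":"fig2","e1":[1,1],"e2":[9,9],"label":0}'
  expect_error(read_instances(write_tmp(out_of_range),
                              parses = list(we$parse)),
               "outside sentence")
})

test_that("word2vec text files round-trip to full double precision", {
  set.seed(31)
  emb <- structure(list(words = c("affects", "binds", "prep-of"),
                        vectors = matrix(rnorm(12), 3, 4)),
                   class = "w2v_embeddings")
  path <- withr::local_tempfile()
  write_word2vec(emb, path, "text")
  back <- read_word2vec(path, "text")
  expect_identical(back$words, emb$words)
  expect_identical(back$vectors, emb$vectors)
})

test_that("word2vec binary files round-trip at float32 precision", {
  set.seed(32)
  emb <- structure(list(words = c("alpha", "beta"),
                        vectors = matrix(rnorm(10), 2, 5)),
                   class = "w2v_embeddings")
  path <- withr::local_tempfile()
  write_word2vec(emb, path, "binary")
  back <- read_word2vec(path, "binary")
  expect_identical(back$words, emb$words)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-7)
})

test_that("word2vec header mismatch, bad dimension and duplicates are handled", {
  expect_error(read_word2vec(write_tmp(c("5 4",
                                         "a 1 2 3 4", "b 1 2 3 4",
                                         "c 1 2 3 4", "d 1 2 3 4"))),
               "declares 5 words")
  expect_error(read_word2vec(write_tmp(c("2 4", "a 1 2 3 4", "b 1 2 3"))),
               "expected 4 values")
  dup <- write_tmp(c("3 2", "a 1 2", "b 3 4", "a 9 9"))
  expect_warning(back <- read_word2vec(dup), "duplicate")
  expect_identical(back$words, c("a", "b"))
  expect_equal(back$vectors[1, ], c(1, 2))  # first occurrence wins
})

test_that("a truncated binary embedding file is an error", {
  emb <- structure(list(words = c("aa", "bb"),
                        vectors = matrix(1:8 / 8, 2, 4)),
                   class = "w2v_embeddings")
  path <- withr::local_tempfile()
  write_word2vec(emb, path, "binary")
  bytes <- readBin(path, "raw", file.size(path))
  writeBin(bytes[seq_len(length(bytes) - 10L)], path)
  expect_error(read_word2vec(path, "binary"), "truncated")
})

test_that("model save/load reproduces forward passes bit-exactly", {
  cfg <- synth_config(n_instances = 16L, seed = 5L)
  corpus <- generate_corpus(cfg)
  tcfg <- sdpcnn_config(N = 9L, d = 6L, M = 3L, H = 4L, epochs = 2L,
                        seed = 9L)
  model <- train_sdpcnn(corpus$instances, corpus$parses, tcfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params$W, model$params$W)
  expect_identical(back$tables$main$D, model$tables$main$D)
  p1 <- predict(model, corpus$parses, corpus$instances)
  p2 <- predict(back, corpus$parses, corpus$instances)
  expect_identical(p1$prob_interaction, p2$prob_interaction)
})

test_that("tampered model containers are rejected, never reshaped", {
  cfg <- synth_config(n_instances = 12L, seed = 6L)
  corpus <- generate_corpus(cfg)
  tcfg <- sdpcnn_config(N = 9L, d = 5L, M = 2L, H = 3L, epochs = 1L,
                        seed = 2L)
  model <- train_sdpcnn(corpus$instances, corpus$parses, tcfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)

  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  obj$hyper$M <- 100L  # declared filter count no longer matches arrays
  p2 <- withr::local_tempfile()
  jsonlite::write_json(obj, p2, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(p2), "shape mismatch")

  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  obj$params$W$dim[[3]] <- 3L  # dim field no longer matches data length
  p3 <- withr::local_tempfile()
  jsonlite::write_json(obj, p3, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(p3), "corrupt|shape")

  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  obj$version <- 99L
  p4 <- withr::local_tempfile()
  jsonlite::write_json(obj, p4, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(p4), "version")
})

test_that("parse and instance writers invert the readers on random corpora", {
  cfg <- synth_config(n_instances = 25L, seed = 17L)
  corpus <- generate_corpus(cfg)
  pp <- withr::local_tempfile()
  ip <- withr::local_tempfile()
  write_parses(corpus$parses, pp)
  write_instances(corpus$instances, ip)
  parses <- read_parses(pp)
  instances <- read_instances(ip, parses = parses)
  expect_identical(lapply(parses, `[[`, "tokens"),
                   lapply(corpus$parses, `[[`, "tokens"))
  expect_identical(instances, corpus$instances)
})
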