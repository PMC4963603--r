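# Synthetic corpus generator: parsed, labelled PPI-style sentences with
# a controllable planted signal, so every other module is testable
# without external corpora, parsers or embedding downloads.

synth_protein_names <- c("profilin", "actin", "mdm2", "tp53", "rad51",
                         "brca1", "cdk2", "cyclin", "raf1", "mek1")
synth_filler_words <- c("complex", "domain", "levels", "subunit",
                        "pathway", "expression", "terminus", "region")
synth_distractor_words <- c("the", "novel", "human", "recombinant",
                            "putative", "cells", "assay", "vitro")
synth_relations <- c("nsubj", "dobj", "prep-of", "amod", "conj")

#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the structure that makes shortest dependency
#' paths informative in real PPI corpora: short dependency trees in
#' which the path between the two protein mentions passes through a
#' verb — drawn from a positive "interaction verb" lexicon for label-1
#' instances and from a neutral lexicon for label-0 instances — with
#' distractor subtrees branching off the path. The label depends on
#' nothing but the on-path verb's lexicon membership, so any classifier
#' beating chance must be reading path content.
#'
#' @param n_instances number of sentences/instances.
#' @param positive_fraction fraction labelled 1; exactly
#'   `round(n * positive_fraction)` positives are generated.
#' @param trigger_lexicon interaction verbs planted on positive paths.
#' @param neutral_lexicon verbs planted on negative paths; must be
#'   disjoint from the trigger lexicon. The default is deliberately
#'   larger than the trigger lexicon: interaction verbs form a compact
#'   class while non-interaction contexts are diverse, and a neutral
#'   class as compact as the trigger class would be equally learnable,
#'   blurring the planted signal that recovery tests rely on.
#' @param path_lengths odd raw sequence lengths (tokens including
#'   relations) the paths are drawn from; each must be at least 5 so an
#'   interior verb slot exists.
#' @param path_probs sampling probabilities over `path_lengths`.
#' @param distractor_branches off-path distractor tokens per sentence;
#'   distractors never contain lexicon verbs, keeping the planted signal
#'   identifiable.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_instances = 500L, positive_fraction = 0.5,
                         trigger_lexicon = c("activates", "binds",
                                             "inhibits", "phosphorylates",
                                             "regulates"),
                         neutral_lexicon = c("precedes", "follows",
                                             "accompanies", "resembles",
                                             "parallels", "concerns",
                                             "involves", "mentions",
                                             "describes", "includes",
                                             "shows", "contains"),
                         path_lengths = c(5L, 7L, 9L),
                         path_probs = c(0.4, 0.4, 0.2),
                         distractor_branches = 2L,
                         seed = 1L) {
  stopifnot(n_instances >= 1L,
            positive_fraction > 0, positive_fraction < 1,
            length(trigger_lexicon) >= 1L, length(neutral_lexicon) >= 1L,
            length(path_lengths) == length(path_probs),
            distractor_branches >= 0L)
  if (length(intersect(trigger_lexicon, neutral_lexicon)))
    stop("trigger and neutral lexicons must be disjoint")
  if (any(path_lengths %% 2L == 0L))
    stop("raw path lengths must be odd (k nodes + k-1 relations)")
  if (any(path_lengths < 5L))
    stop("raw path lengths must be >= 5 so the path holds a verb")
  structure(list(n_instances = as.integer(n_instances),
                 positive_fraction = positive_fraction,
                 trigger_lexicon = trigger_lexicon,
                 neutral_lexicon = neutral_lexicon,
                 path_lengths = as.integer(path_lengths),
                 path_probs = path_probs / sum(path_probs),
                 distractor_branches = as.integer(distractor_branches),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# One synthetic sentence: a path of k nodes rooted at the verb, entities
# at the two ends, distractors attached off-path.
synth_sentence <- function(config, i, label) {
  set.seed(derive_seed(config$seed, paste0("inst:", i)))
  L <- config$path_lengths[
    sample.int(length(config$path_lengths), 1L, prob = config$path_probs)]
  k <- (L + 1L) %/% 2L  # path nodes
  interior <- 2L:(k - 1L)
  verb_pos <- interior[sample.int(length(interior), 1L)]
  lexicon <- if (label == 1L) config$trigger_lexicon else config$neutral_lexicon
  forms <- character(k)
  forms[1L] <- sample(synth_protein_names, 1L)
  forms[k] <- sample(setdiff(synth_protein_names, forms[1L]), 1L)
  if (k > 2L)
    forms[2L:(k - 1L)] <- sample(synth_filler_words, k - 2L, replace = TRUE)
  forms[verb_pos] <- sample(lexicon, 1L)

  # chain rooted at the verb: nodes left of it head rightward, nodes
  # right of it head leftward; relation labels drawn from the fixed set
  head <- integer(k)
  deprel <- character(k)
  rels <- synth_relations[sample.int(length(synth_relations), k - 1L,
                                     replace = TRUE)]
  for (j in seq_len(k)) {
    if (j < verb_pos) { head[j] <- j + 1L; deprel[j] <- rels[j] }
    else if (j > verb_pos) { head[j] <- j - 1L; deprel[j] <- rels[j - 1L] }
    else { head[j] <- 0L; deprel[j] <- "root" }
  }

  nb <- config$distractor_branches
  if (nb > 0L) {
    for (b in seq_len(nb)) {
      forms <- c(forms, sample(synth_distractor_words, 1L))
      head <- c(head, sample.int(k, 1L))
      deprel <- c(deprel, sample(c("amod", "conj"), 1L))
    }
  }
  tokens <- data.frame(index = seq_along(forms), form = forms,
                       head = head, deprel = deprel,
                       stringsAsFactors = FALSE)
  parse <- validate_parse(new_dep_parse(paste0("s", i), tokens))
  instance <- new_instance(paste0("inst", i), paste0("s", i),
                           c(1L, 1L), c(k, k), label)
  list(parse = parse, instance = instance)
}

#' Generate a synthetic parsed, labelled PPI corpus
#'
#' See [synth_config()] for what the corpus emulates. Output is in
#' exactly the containers [read_parses()] and [read_instances()]
#' produce, so it can be written out with the corpus writers and fed to
#' every other module.
#'
#' @param config a `synth_config`.
#' @return `list(parses, instances)`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_instances
  n_pos <- round(n * config$positive_fraction)
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  set.seed(derive_seed(config$seed, "labels"))
  labels <- labels[sample.int(n)]
  out <- lapply(seq_len(n), function(i) synth_sentence(config, i, labels[i]))
  list(parses = lapply(out, `[[`, "parse"),
       instances = lapply(out, `[[`, "instance"))
}

#' The hand-transcribed worked example
#'
#' The dependency parse (collapsed-preposition representation, 8 tokens)
#' of the sentence "Acanthamoeba profilin affects the mechanical
#' properties of non-filamentous actin." together with its instance:
#' e1 = "Acanthamoeba profilin" (tokens 1-2, syntactic head "profilin"),
#' e2 = "actin" (token 8), label 1. The shortest dependency path between
#' the entity heads serializes to
#' `Protein1 nsubj affects dobj properties prep-of Protein2`
#' (7 tokens).
#'
#' @return `list(parse, instance)`.
#' @export
#' @examples
#' we <- worked_example()
#' extract_sdp(we$parse, we$instance)$tokens
worked_example <- function() {
  tokens <- data.frame(
    index = 1:8,
    form = c("Acanthamoeba", "profilin", "affects", "the", "mechanical",
             "properties", "non-filamentous", "actin"),
    head = c(2L, 3L, 0L, 6L, 6L, 3L, 8L, 6L),
    deprel = c("amod", "nsubj", "root", "det", "amod", "dobj", "amod",
               "prep-of"),
    stringsAsFactors = FALSE)
  parse <- validate_parse(new_dep_parse("fig2", tokens))
  instance <- new_instance("fig2-pair", "fig2", c(1L, 2L), c(8L, 8L), 1L)
  list(parse = parse, instance = instance)
}
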