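#' Synthetic fixture corpora with known gold relations
#'
#' The generator instantiates sentences from templates keyed to the trigger
#' patterns -- active voice ("X projects densely to Y"), passive voice
#' ("Y was strongly innervated by X"), dual-slot ("projections from X to Y",
#' optionally with a conjunction list of agents), a "receive input from"
#' variant, and an "including" enumeration -- each with gold directed
#' relations and deterministic template-derived constituency and dependency
#' parses. Distractor sentences either contain no trigger pattern at all or
#' a trigger with no dictionary region, and carry no gold relations.
#' A fixed seed makes the output bit-exact.
#'
#' @name fixtures
NULL

#' Fixture specification
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences per document.
#' @param regions_per_sentence probability weights for 2, 3 or 4 distinct
#'   regions in a relation sentence.
#' @param distractor_fraction fraction of sentences with no gold relation.
#' @param passive_fraction fraction of two-region sentences using the
#'   passive-voice template.
#' @param seed integer RNG seed; fixes the output bit-exactly.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_docs = 10L, sentences_per_doc = 3L,
                         regions_per_sentence = c(0.5, 0.3, 0.2),
                         distractor_fraction = 0.2,
                         passive_fraction = 0.25, seed = 1L) {
  stopifnot(n_docs >= 1, sentences_per_doc >= 1,
            length(regions_per_sentence) == 3,
            all(regions_per_sentence >= 0), sum(regions_per_sentence) > 0,
            distractor_fraction >= 0, distractor_fraction <= 1,
            passive_fraction >= 0, passive_fraction <= 1)
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 regions_per_sentence = regions_per_sentence /
                   sum(regions_per_sentence),
                 distractor_fraction = distractor_fraction,
                 passive_fraction = passive_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' The example brain-region dictionary shipped with the package
#'
#' A small dictionary (30 entries) covering the regions used by the fixture
#' templates and the worked examples; stands in for a full literature-scale
#' dictionary.
#'
#' @param acronym_case_insensitive see [nc_dictionary()].
#' @return an \code{nc_dictionary}.
#' @export
nc_example_dictionary <- function(acronym_case_insensitive = FALSE) {
  load_dictionary(system.file("extdata", "brain_regions.tsv",
                              package = "neuroconn", mustWork = TRUE),
                  acronym_case_insensitive = acronym_case_insensitive)
}

# join tokens into natural text (no space before closing punctuation)
.nc_detokenize <- function(tokens) {
  out <- tokens[1]
  for (t in tokens[-1]) {
    sep <- if (t %in% c(".", ",", ";", ":", ")", "?", "!")) "" else " "
    if (out == "(" || endsWith(out, " (")) sep <- ""
    out <- paste0(out, sep, t)
  }
  out
}

# bracketed NP over region tokens, with optional determiner
.nc_npb <- function(rtoks, det = NULL) {
  inner <- paste(sprintf("(NN %s)", rtoks), collapse = " ")
  if (is.null(det)) sprintf("(NP %s)", inner)
  else sprintf("(NP (DT %s) %s)", det, inner)
}

# det/nn dependency lines attaching a region's tokens to its head
.nc_region_deps <- function(rtoks, first_pos, det_tok = NULL,
                            det_pos = NULL) {
  head_pos <- first_pos + length(rtoks) - 1L
  head <- rtoks[length(rtoks)]
  out <- character(0)
  if (!is.null(det_tok)) {
    out <- c(out, sprintf("det(%s-%d, %s-%d)", head, head_pos,
                          det_tok, det_pos))
  }
  if (length(rtoks) > 1L) {
    for (k in seq_len(length(rtoks) - 1L)) {
      out <- c(out, sprintf("nn(%s-%d, %s-%d)", head, head_pos,
                            rtoks[k], first_pos + k - 1L))
    }
  }
  out
}

.nc_split_region <- function(name) strsplit(name, " ", fixed = TRUE)[[1]]

# ---- sentence templates ----------------------------------------------------
# each returns list(tokens, tree, deps, pairs); pairs columns:
# agent, target, agent_text, target_text, forward (agent mentioned first?)

.nc_tpl_active <- function(a, b) {
  at <- .nc_split_region(a); bt <- .nc_split_region(b)
  toks <- c("The", at, "projects", "densely", "to", "the", bt, ".")
  ah <- 1L + length(at)
  v <- ah + 1L
  the2 <- v + 3L
  tree <- sprintf(
    "(S %s (VP (VBZ projects) (ADVP (RB densely)) (PP (TO to) %s)) (. .))",
    .nc_npb(at, "The"), .nc_npb(bt, "the"))
  deps <- c(
    sprintf("nsubj(projects-%d, %s-%d)", v, at[length(at)], ah),
    .nc_region_deps(at, 2L, "The", 1L),
    sprintf("prep_to(projects-%d, %s-%d)", v, bt[length(bt)],
            the2 + length(bt)),
    .nc_region_deps(bt, the2 + 1L, "the", the2))
  list(tokens = toks, tree = tree, deps = deps,
       pairs = data.frame(agent = a, target = b, agent_text = a,
                          target_text = b, forward = TRUE,
                          stringsAsFactors = FALSE))
}

.nc_tpl_passive <- function(a, b) {
  at <- .nc_split_region(a); bt <- .nc_split_region(b)
  toks <- c("The", bt, "was", "strongly", "innervated", "by", "the", at, ".")
  bh <- 1L + length(bt)
  v <- bh + 3L           # innervated
  the2 <- v + 2L
  tree <- sprintf(
    paste0("(S %s (VP (VBD was) (ADVP (RB strongly)) (VP (VBN innervated) ",
           "(PP (IN by) %s))) (. .))"),
    .nc_npb(bt, "The"), .nc_npb(at, "the"))
  deps <- c(
    sprintf("nsubjpass(innervated-%d, %s-%d)", v, bt[length(bt)], bh),
    .nc_region_deps(bt, 2L, "The", 1L),
    sprintf("agent(innervated-%d, %s-%d)", v, at[length(at)],
            the2 + length(at)),
    .nc_region_deps(at, the2 + 1L, "the", the2))
  list(tokens = toks, tree = tree, deps = deps,
       pairs = data.frame(agent = a, target = b, agent_text = a,
                          target_text = b, forward = FALSE,
                          stringsAsFactors = FALSE))
}

.nc_tpl_receive <- function(a, b) {
  at <- .nc_split_region(a); bt <- .nc_split_region(b)
  toks <- c("The", bt, "receives", "dense", "input", "from", "the", at, ".")
  bh <- 1L + length(bt)
  v <- bh + 1L
  the2 <- v + 3L
  tree <- sprintf(
    paste0("(S %s (VP (VBZ receives) (NP (JJ dense) (NN input)) ",
           "(PP (IN from) %s)) (. .))"),
    .nc_npb(bt, "The"), .nc_npb(at, "the"))
  deps <- c(
    sprintf("nsubj(receives-%d, %s-%d)", v, bt[length(bt)], bh),
    .nc_region_deps(bt, 2L, "The", 1L),
    sprintf("dobj(receives-%d, input-%d)", v, v + 2L),
    sprintf("amod(input-%d, dense-%d)", v + 2L, v + 1L),
    sprintf("prep_from(receives-%d, %s-%d)", v, at[length(at)],
            the2 + length(at)),
    .nc_region_deps(at, the2 + 1L, "the", the2))
  list(tokens = toks, tree = tree, deps = deps,
       pairs = data.frame(agent = a, target = b, agent_text = a,
                          target_text = b, forward = FALSE,
                          stringsAsFactors = FALSE))
}

.nc_tpl_dual <- function(agents, b) {
  bt <- .nc_split_region(b)
  list_toks <- character(0)
  np_list <- character(0)
  n <- length(agents)
  for (k in seq_len(n)) {
    at <- .nc_split_region(agents[k])
    if (k > 1L) {
      if (n >= 3L) {
        list_toks <- c(list_toks, ",")
        np_list <- c(np_list, "(, ,)")
      }
      if (k == n) {
        if (n == 2L) {
          list_toks <- c(list_toks, "and")
        } else {
          list_toks <- c(list_toks, "and")
        }
        np_list <- c(np_list, "(CC and)")
      }
    }
    list_toks <- c(list_toks, at)
    np_list <- c(np_list, .nc_npb(at))
  }
  toks <- c("These", "experiments", "confirm", "projections", "from",
            list_toks, "to", "the", bt, ".")
  tree <- sprintf(
    paste0("(S (NP (DT These) (NNS experiments)) (VP (VBP confirm) ",
           "(NP (NP (NNS projections)) (PP (IN from) (NP %s)) ",
           "(PP (TO to) %s))) (. .))"),
    paste(np_list, collapse = " "), .nc_npb(bt, "the"))
  deps <- c("nsubj(confirm-3, experiments-2)",
            "det(experiments-2, These-1)",
            "dobj(confirm-3, projections-4)")
  pairs <- do.call(rbind, lapply(agents, function(a) {
    data.frame(agent = a, target = b, agent_text = a, target_text = b,
               forward = TRUE, stringsAsFactors = FALSE)
  }))
  list(tokens = toks, tree = tree, deps = deps, pairs = pairs)
}

.nc_tpl_including <- function(a, b1, b2) {
  at <- .nc_split_region(a)
  b1t <- .nc_split_region(b1); b2t <- .nc_split_region(b2)
  toks <- c("The", at, "projects", "strongly", "to", "limbic", "structures",
            "including", "the", b1t, "and", "the", b2t, ".")
  ah <- 1L + length(at)
  v <- ah + 1L
  tree <- sprintf(
    paste0("(S %s (VP (VBZ projects) (ADVP (RB strongly)) ",
           "(PP (TO to) (NP (JJ limbic) (NNS structures))) ",
           "(PP (VBG including) (NP %s (CC and) %s))) (. .))"),
    .nc_npb(at, "The"), .nc_npb(b1t, "the"), .nc_npb(b2t, "the"))
  deps <- c(
    sprintf("nsubj(projects-%d, %s-%d)", v, at[length(at)], ah),
    .nc_region_deps(at, 2L, "The", 1L))
  pairs <- rbind(
    data.frame(agent = a, target = b1, agent_text = a, target_text = b1,
               forward = TRUE, stringsAsFactors = FALSE),
    data.frame(agent = a, target = b2, agent_text = a, target_text = b2,
               forward = TRUE, stringsAsFactors = FALSE))
  list(tokens = toks, tree = tree, deps = deps, pairs = pairs)
}

.nc_tpl_distractor_plain <- function() {
  list(tokens = c("The", "results", "were", "discussed", "in", "detail", "."),
       tree = paste0("(S (NP (DT The) (NNS results)) (VP (VBD were) ",
                     "(VP (VBN discussed) (PP (IN in) (NP (NN detail))))) ",
                     "(. .))"),
       deps = c("nsubjpass(discussed-4, results-2)",
                "det(results-2, The-1)"),
       pairs = NULL)
}

.nc_tpl_distractor_trigger <- function() {
  list(tokens = c("These", "findings", "project", "directly", "to",
                  "broader", "conclusions", "."),
       tree = paste0("(S (NP (DT These) (NNS findings)) (VP (VBP project) ",
                     "(ADVP (RB directly)) (PP (TO to) ",
                     "(NP (JJR broader) (NNS conclusions)))) (. .))"),
       deps = c("nsubj(project-3, findings-2)",
                "det(findings-2, These-1)"),
       pairs = NULL)
}

# regions usable in templates: plain multi/single-word names >= 3 chars
.nc_fixture_pool <- function(dict) {
  nm <- dict$entries$name
  nm[grepl("^[A-Za-z][A-Za-z ]+$", nm) & nchar(nm) >= 3L]
}

#' Generate a synthetic fixture corpus
#'
#' @param spec a [fixture_spec()].
#' @param dict dictionary supplying region names (defaults to the shipped
#'   example dictionary).
#' @return list with \code{documents} (list of [nc_document()]),
#'   \code{gold} (an \code{nc_gold_corpus}), \code{parses} (named list keyed
#'   \code{"<doc>.s<idx>"}, each \code{list(tree, deps)}), and
#'   \code{relations} (gold tally data.frame: doc_id, sentence_index, agent,
#'   target, forward).
#' @export
generate_fixture_corpus <- function(spec = fixture_spec(),
                                    dict = nc_example_dictionary()) {
  stopifnot(inherits(spec, "fixture_spec"))
  pool <- .nc_fixture_pool(dict)
  if (length(pool) < 4L) stop("dictionary pool too small for templates")

  old_seed <- if (exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(spec$seed)

  documents <- list()
  parses <- list()
  sent_rows <- list(); ent_rows <- list(); pair_rows <- list()
  rel_rows <- list()
  distractor_kind <- 0L

  for (di in seq_len(spec$n_docs)) {
    doc_id <- sprintf("fx.d%03d", di)
    sent_texts <- character(0)
    for (si in seq_len(spec$sentences_per_doc) - 1L) {
      u <- stats::runif(1)
      if (u < spec$distractor_fraction) {
        distractor_kind <- distractor_kind + 1L
        tpl <- if (distractor_kind %% 2L == 0L) .nc_tpl_distractor_plain()
               else .nc_tpl_distractor_trigger()
      } else {
        size <- sample(2:4, 1L, prob = spec$regions_per_sentence)
        # dual-slot lists must keep the between-prepositions gap small
        repeat {
          regions <- sample(pool, size)
          if (size < 3L ||
              sum(lengths(strsplit(regions[-size], " "))) <= 6L) break
        }
        tpl <- if (size == 2L) {
          if (stats::runif(1) < spec$passive_fraction) {
            .nc_tpl_passive(regions[1], regions[2])
          } else if (stats::runif(1) < 0.5) {
            .nc_tpl_active(regions[1], regions[2])
          } else {
            .nc_tpl_receive(regions[1], regions[2])
          }
        } else if (size == 3L) {
          if (stats::runif(1) < 0.5) {
            .nc_tpl_dual(regions[1:2], regions[3])
          } else {
            .nc_tpl_including(regions[1], regions[2], regions[3])
          }
        } else {
          .nc_tpl_dual(regions[1:3], regions[4])
        }
      }
      text <- .nc_detokenize(tpl$tokens)
      sent_texts <- c(sent_texts, text)
      key <- sprintf("%s.s%d", doc_id, si)
      parses[[key]] <- list(tree = tpl$tree, deps = tpl$deps)
      sent_rows[[length(sent_rows) + 1L]] <-
        data.frame(id = key, doc_id = doc_id, index = si, text = text,
                   stringsAsFactors = FALSE)
      if (!is.null(tpl$pairs)) {
        mentions <- unique(c(tpl$pairs$agent_text, tpl$pairs$target_text))
        eids <- sprintf("%s.e%d", key, seq_along(mentions) - 1L)
        names(eids) <- mentions
        for (m in mentions) {
          ent_rows[[length(ent_rows) + 1L]] <-
            data.frame(id = eids[[m]], sentence_id = key, text = m,
                       stringsAsFactors = FALSE)
        }
        for (pi in seq_len(nrow(tpl$pairs))) {
          p <- tpl$pairs[pi, ]
          pair_rows[[length(pair_rows) + 1L]] <-
            data.frame(sentence_id = key, e1 = eids[[p$agent_text]],
                       e2 = eids[[p$target_text]], interaction = TRUE,
                       direction = "e1_to_e2", stringsAsFactors = FALSE)
          rel_rows[[length(rel_rows) + 1L]] <-
            data.frame(doc_id = doc_id, sentence_index = si,
                       agent = p$agent, target = p$target,
                       forward = p$forward, stringsAsFactors = FALSE)
        }
      }
    }
    documents[[length(documents) + 1L]] <-
      nc_document(doc_id, paste(sent_texts, collapse = " "))
  }

  bindrows <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  gold <- nc_gold_corpus(
    sentences = bindrows(sent_rows, data.frame(
      id = character(), doc_id = character(), index = integer(),
      text = character(), stringsAsFactors = FALSE)),
    entities = bindrows(ent_rows, data.frame(
      id = character(), sentence_id = character(), text = character(),
      stringsAsFactors = FALSE)),
    pairs = bindrows(pair_rows, data.frame(
      sentence_id = character(), e1 = character(), e2 = character(),
      interaction = logical(), direction = character(),
      stringsAsFactors = FALSE)))
  relations <- bindrows(rel_rows, data.frame(
    doc_id = character(), sentence_index = integer(), agent = character(),
    target = character(), forward = logical(), stringsAsFactors = FALSE))

  list(documents = documents, gold = gold, parses = parses,
       relations = relations, spec = spec)
}

#' Write a fixture corpus to a directory
#'
#' Emits \code{docs/<id>.txt}, \code{gold.xml} and
#' \code{parses/<doc>.s<idx>.ptb} / \code{.deps}.
#'
#' @param fixture output of [generate_fixture_corpus()].
#' @param dir target directory (created if needed).
#' @export
write_fixture_corpus <- function(fixture, dir) {
  dir.create(file.path(dir, "docs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "parses"), recursive = TRUE,
             showWarnings = FALSE)
  for (d in fixture$documents) {
    writeLines(d$text, file.path(dir, "docs", paste0(d$doc_id, ".txt")),
               useBytes = TRUE)
  }
  write_interaction_xml(fixture$gold, file.path(dir, "gold.xml"))
  for (key in names(fixture$parses)) {
    writeLines(fixture$parses[[key]]$tree,
               file.path(dir, "parses", paste0(key, ".ptb")),
               useBytes = TRUE)
    writeLines(fixture$parses[[key]]$deps,
               file.path(dir, "parses", paste0(key, ".deps")),
               useBytes = TRUE)
  }
  invisible(dir)
}
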