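test_that("role assignment follows the pattern role table and passive flip", {
  expect_equal(assign_direction("receive input from", "active")[["after"]],
               "agent")
  expect_equal(assign_direction("project into", "active")[["after"]],
               "target")
  expect_equal(assign_direction("innervate", "passive")[["after"]], "agent")
  expect_equal(assign_direction("projection from", "active")[["after"]],
               "agent")
  expect_error(assign_direction("no such pattern", "active"), "unknown")
})

test_that("worked examples yield the expected directed pairs", {
  dict <- we_dict()
  ex <- worked_example("scn_pa")
  rel <- extract_from_sentence(ex$sentence, ex$tree, ex$edges, dict)
  expect_equal(rel$agent, "Suprachiasmatic nucleus")
  expect_equal(rel$target, "Pa")

  ex <- worked_example("tracer_injection")
  rel <- extract_from_sentence(ex$sentence, ex$tree, ex$edges, dict)
  expect_setequal(rel$target, c("Nucleus accumbens", "Basal amygdala",
                                "Lateral septum", "Hypothalamus"))
  expect_equal(unique(rel$agent), "Dorsal midline thalamus")
  expect_equal(unique(rel$agent_kind), "partial")
})

test_that("trigger sentences without dictionary regions yield nothing", {
  dict <- we_dict()
  s <- nc_sentence("d", 0L,
                   "These findings project directly to broader conclusions.")
  tree <- parse_bracketed_tree(paste0(
    "(S (NP (DT These) (NNS findings)) (VP (VBP project) ",
    "(ADVP (RB directly)) (PP (TO to) (NP (JJR broader) ",
    "(NNS conclusions)))) (. .))"))
  edges <- parse_dependency_triples(c("nsubj(project-3, findings-2)",
                                      "det(findings-2, These-1)"))
  expect_equal(nrow(extract_from_sentence(s, tree, edges, dict)), 0L)
})

test_that("relations between a region and itself are suppressed", {
  dict <- we_dict()
  s <- nc_sentence("d", 0L,
                   "The PVT projects densely to the paraventricular thalamus.")
  tree <- parse_bracketed_tree(paste0(
    "(S (NP (DT The) (NN PVT)) (VP (VBZ projects) (ADVP (RB densely)) ",
    "(PP (TO to) (NP (DT the) (JJ paraventricular) (NN thalamus)))) (. .))"))
  edges <- parse_dependency_triples(c("nsubj(projects-3, PVT-2)",
                                      "det(PVT-2, The-1)"))
  expect_equal(nrow(extract_from_sentence(s, tree, edges, dict)), 0L)
})

test_that("missing parses for a candidate sentence raise an error", {
  dict <- we_dict()
  s <- nc_sentence("d", 0L, "The PVT projects densely to the amygdala.")
  expect_error(extract_from_sentence(s, NULL, NULL, dict),
               "missing constituency")
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 2, seed = 4))
  expect_error(extract_corpus(fx$documents, list(), dict), "missing parses")
})

test_that("document-level dedup keeps ordered pairs with mention counts", {
  rel <- data.frame(
    doc_id = c("d1", "d1", "d1", "d1"),
    sentence_index = c(0L, 1L, 2L, 3L),
    agent = c("A", "A", "A", "B"), target = c("B", "B", "B", "A"),
    agent_surface = "x", target_surface = "y",
    agent_kind = "full", target_kind = "full", agent_first = TRUE,
    pattern = "project to", sentence_text = "s",
    stringsAsFactors = FALSE)
  dd <- dedup_document(rel)
  expect_equal(nrow(dd), 2L)
  expect_equal(dd$n_mentions[dd$agent == "A"], 3L)
  expect_equal(dd$n_mentions[dd$agent == "B"], 1L)
  expect_equal(dd$sentence_index[dd$agent == "A"], 0L)
  expect_equal(nrow(dedup_document(rel[0, ])), 0L)
})

test_that("sentence order only affects the dedup representative", {
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 10, seed = 31))
  dict <- we_dict()
  rel1 <- extract_corpus(fx$documents, fx$parses, dict)
  rel2 <- extract_corpus(rev(fx$documents), fx$parses, dict)
  k <- function(r) sort(paste(r$doc_id, r$sentence_index, r$agent, r$target))
  expect_identical(k(rel1), k(rel2))
  d1 <- dedup_document(rel1); d2 <- dedup_document(rel2)
  expect_identical(sort(paste(d1$doc_id, d1$agent, d1$target, d1$n_mentions)),
                   sort(paste(d2$doc_id, d2$agent, d2$target, d2$n_mentions)))
})

test_that("every emitted relation has a trigger in its sentence", {
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 12, seed = 13))
  rel <- extract_corpus(fx$documents, fx$parses, we_dict())
  for (i in seq_len(nrow(rel))) {
    expect_gt(nrow(find_pattern_matches(rel$sentence_text[i])), 0L)
    expect_false(identical(rel$agent[i], rel$target[i]))
  }
})

test_that("relations TSV round-trips", {
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 3, seed = 21))
  rel <- extract_corpus(fx$documents, fx$parses, we_dict())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_relations_tsv(rel, f)
  back <- read_relations_tsv(f)
  expect_equal(nrow(back), nrow(rel))
  expect_equal(back$agent, rel$agent)
  expect_equal(back$target, rel$target)
  expect_equal(back$sentence_index, rel$sentence_index)
})
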