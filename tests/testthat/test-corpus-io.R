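test_that("interaction XML reader handles the unified dialect", {
  # the printed two-entity, one-pair fragment (entities under a document)
  xml <- paste0(
    '<corpus source="unseen"><document id="WhiteTextUnseenEval.d5917">',
    '<sentence id="WhiteTextUnseenEval.d5917.s0" ',
    'text="Projections from the spinal trigeminal nucleus to the cochlear nucleus in the rat.">',
    '<entity id="WhiteTextUnseenEval.d5917.s0.e0" text="spinal trigeminal nucleus"/>',
    '<entity id="WhiteTextUnseenEval.d5917.s0.e1" text="cochlear nucleus"/>',
    '<pair interaction="True" e1="WhiteTextUnseenEval.d5917.s0.e1" ',
    'e2="WhiteTextUnseenEval.d5917.s0.e0"/>',
    "</sentence></document></corpus>")
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, f)
  gc <- read_interaction_xml(f)
  expect_equal(nrow(gc$sentences), 1L)
  expect_equal(nrow(gc$entities), 2L)
  expect_equal(n_gold_relations(gc), 1L)
  expect_equal(gc$entities$text[1], "spinal trigeminal nucleus")

  # interaction="False" pairs are not gold relations
  xml_false <- sub('interaction="True"', 'interaction="False"', xml)
  writeLines(xml_false, f)
  expect_equal(n_gold_relations(read_interaction_xml(f)), 0L)

  # dangling entity references are a validation error
  xml_bad <- sub('e2="WhiteTextUnseenEval.d5917.s0.e0"',
                 'e2="WhiteTextUnseenEval.d5917.s0.e9"', xml)
  writeLines(xml_bad, f)
  expect_error(read_interaction_xml(f), "undeclared entity")

  # malformed XML propagates a parse error
  writeLines(substr(xml, 1, 80), f)
  expect_error(read_interaction_xml(f))
})

test_that("gold corpus round-trips through write/read", {
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 4, seed = 11))
  f <- withr::local_tempfile(fileext = ".xml")
  write_interaction_xml(fx$gold, f)
  back <- read_interaction_xml(f)
  expect_equal(back$sentences[order(back$sentences$id), ],
               fx$gold$sentences[order(fx$gold$sentences$id), ],
               ignore_attr = TRUE)
  expect_equal(nrow(back$entities), nrow(fx$gold$entities))
  expect_equal(n_gold_relations(back), n_gold_relations(fx$gold))
  expect_equal(sort(back$pairs$e1), sort(fx$gold$pairs$e1))
})

test_that("dependency triple parsing is exact", {
  e <- parse_dependency_triples("nsubj(projects-17, subnucleus-16)")
  expect_equal(e$label, "nsubj")
  expect_equal(e$gov, "projects")
  expect_equal(e$gov_pos, 17L)
  expect_equal(e$dep, "subnucleus")
  expect_equal(e$dep_pos, 16L)

  e2 <- parse_dependency_triples("prep_into(injection-4, thalamus-9)")
  expect_equal(e2$label, "prep_into")

  # hyphenated surfaces keep their hyphens
  e3 <- parse_dependency_triples("nn(tract-tracing-6, neuronal-5)")
  expect_equal(e3$gov, "tract-tracing")
  expect_equal(e3$gov_pos, 6L)

  expect_equal(nrow(parse_dependency_triples(character(0))), 0L)
  expect_error(parse_dependency_triples("nsubj(projects, subnucleus)"),
               "malformed")
})

test_that("bracketed trees parse with sequential leaf positions", {
  tr <- parse_bracketed_tree(
    "(S (NP (DT The) (NN cat)) (VP (VBZ sits) (PP (IN on) (NP (DT the) (NN mat)))) (. .))")
  lv <- tree_leaves(tr)
  expect_equal(lv$surface, c("The", "cat", "sits", "on", "the", "mat", "."))
  expect_equal(lv$pos, 1:7)
  expect_error(parse_bracketed_tree("(S (NP (DT The)"), "nbalanced|alformed")
})

test_that("fixture generation is deterministic and honours fractions", {
  a <- generate_fixture_corpus(fixture_spec(n_docs = 6, seed = 7))
  b <- generate_fixture_corpus(fixture_spec(n_docs = 6, seed = 7))
  expect_identical(lapply(a$documents, `[[`, "text"),
                   lapply(b$documents, `[[`, "text"))
  expect_identical(a$parses, b$parses)
  expect_identical(a$relations, b$relations)

  none <- generate_fixture_corpus(
    fixture_spec(n_docs = 5, distractor_fraction = 1, seed = 3))
  expect_equal(n_gold_relations(none$gold), 0L)
  expect_equal(nrow(none$relations), 0L)

  # every gold relation's sentence contains a trigger pattern
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 50, seed = 1))
  pat <- compile_patterns()
  for (i in seq_len(nrow(fx$relations))) {
    key <- sprintf("%s.s%d", fx$relations$doc_id[i],
                   fx$relations$sentence_index[i])
    stext <- fx$gold$sentences$text[fx$gold$sentences$id == key]
    expect_gt(nrow(find_pattern_matches(nc_sentence("x", 0L, stext), pat)),
              0L)
  }
})

test_that("fixture corpora write out and load back", {
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_fixture_corpus(fx, dir)
  expect_true(file.exists(file.path(dir, "gold.xml")))
  docs <- list.files(file.path(dir, "docs"))
  expect_length(docs, 3L)
  ptb <- list.files(file.path(dir, "parses"), pattern = "\\.ptb$")
  expect_length(ptb, length(fx$parses))
  tr <- read_bracketed_tree(
    file.path(dir, "parses", ptb[1]))
  expect_s3_class(tr, "nc_ctree")
})
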