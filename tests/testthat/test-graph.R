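make_rel <- function(agents, targets) {
  data.frame(doc_id = "d", sentence_index = seq_along(agents) - 1L,
             agent = agents, target = targets,
             agent_surface = agents, target_surface = targets,
             agent_kind = "full", target_kind = "full", agent_first = TRUE,
             pattern = "project to", sentence_text = "s",
             stringsAsFactors = FALSE)
}

test_that("graph construction counts mentions as parallel edges", {
  g0 <- build_graph(make_rel("A", "B")[0, ])
  expect_equal(igraph::vcount(g0), 0L)
  expect_equal(nrow(top_regions(g0)), 0L)

  g <- build_graph(make_rel(c("A", "A", "B"), c("B", "B", "C")))
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(igraph::degree(g, "A", mode = "out")[[1]], 2)
  tr <- top_regions(g, 10)
  expect_equal(sum(tr$agent), sum(tr$target))
  expect_equal(sum(tr$agent), 3L)
  expect_equal(tr$total, tr$agent + tr$target)
  rr <- top_relations(g, 10)
  expect_equal(rr$n_mentions[rr$agent == "A" & rr$target == "B"], 2L)
})

test_that("degree table matches an independent tally of the fixtures", {
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 15, seed = 23))
  rel <- extract_corpus(fx$documents, fx$parses, we_dict())
  g <- build_graph(rel)
  tr <- top_regions(g, k = igraph::vcount(g))
  # tally straight from the gold table
  for (i in seq_len(nrow(tr))) {
    expect_equal(tr$agent[i], sum(fx$relations$agent == tr$region[i]))
    expect_equal(tr$target[i], sum(fx$relations$target == tr$region[i]))
  }
  expect_true(all(diff(tr$total) <= 0))
})

test_that("edge betweenness matches brute force on canonical graphs", {
  # path graph A - B - C: pairs (A,B), (A,C) cross edge A-B
  g <- build_graph(make_rel(c("A", "B"), c("B", "C")))
  eb <- edge_betweenness_scores(g)
  expect_equal(eb$betweenness[(eb$from == "A" & eb$to == "B") |
                                (eb$from == "B" & eb$to == "A")], 2)
  # single edge: one unordered pair
  g1 <- build_graph(make_rel("A", "B"))
  expect_equal(edge_betweenness_scores(g1)$betweenness, 1)
  # complete graph K4: all edges equal by symmetry
  nodes <- c("A", "B", "C", "D")
  pairs <- t(utils::combn(nodes, 2))
  g4 <- build_graph(make_rel(pairs[, 1], pairs[, 2]))
  eb4 <- edge_betweenness_scores(g4)
  expect_equal(length(unique(round(eb4$betweenness, 10))), 1L)
  # parallel edges collapse for path finding
  gp <- build_graph(make_rel(c("A", "A", "B"), c("B", "B", "C")))
  ebp <- edge_betweenness_scores(gp)
  expect_equal(nrow(ebp), 2L)
})

test_that("edge betweenness agrees with the all-pairs oracle", {
  set.seed(77)
  for (rep in 1:100) {
    edf <- random_simple_graph()
    g <- build_graph(make_rel(edf$from, edf$to))
    eb <- edge_betweenness_scores(g)
    oracle <- oracle_edge_betweenness(edf$from, edf$to,
                                      sort(unique(c(edf$from, edf$to))))
    key <- paste(pmin(eb$from, eb$to), pmax(eb$from, eb$to), sep = "|")
    expect_equal(unname(eb$betweenness), unname(oracle[key]),
                 tolerance = 1e-9)
  }
})

test_that("graph construction is permutation invariant", {
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 8, seed = 29))
  rel <- extract_corpus(fx$documents, fx$parses, we_dict())
  g1 <- build_graph(rel)
  g2 <- build_graph(rel[rev(seq_len(nrow(rel))), ])
  expect_equal(sort(igraph::V(g1)$name), sort(igraph::V(g2)$name))
  e1 <- igraph::ends(g1, igraph::E(g1)); e2 <- igraph::ends(g2, igraph::E(g2))
  expect_equal(sort(paste(e1[, 1], e1[, 2])), sort(paste(e2[, 1], e2[, 2])))
  expect_equal(top_regions(g1, 100), top_regions(g2, 100))
})

test_that("exports cover the four formats and round-trip counts", {
  rel <- make_rel(c("A", "A", "B", "C"), c("B", "C", "C", "D"))
  g <- build_graph(rel)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))

  dot <- withr::local_tempfile(fileext = ".dot")
  export_graph(g, dot, "dot")
  expect_true(any(grepl("digraph", readLines(dot))))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, tsv, "tsv")
  expect_equal(nrow(utils::read.table(tsv, sep = "\t", header = TRUE)),
               nrow(rel))

  js <- withr::local_tempfile(fileext = ".json")
  export_graph(g, js, "json")
  parsed <- jsonlite::read_json(js)
  expect_length(parsed$links, nrow(rel))
  expect_true(all(vapply(parsed$nodes, function(n) n$color, "") %in%
                    c("green", "yellow", "orange", "red")))

  expect_error(export_graph(g, tsv, "xlsx"), "unknown export format")
})
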