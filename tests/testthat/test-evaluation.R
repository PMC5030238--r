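test_that("f_measure is the rounded harmonic mean", {
  expect_equal(f_measure(76.94, 14.59), 24.53)
  expect_equal(f_measure(50, 50), 50)
  expect_equal(f_measure(100, 0), 0)
  expect_equal(f_measure(0, 0), 0)
  # symmetry and bounds
  set.seed(3)
  for (i in 1:50) {
    p <- round(runif(1, 0, 100), 2); r <- round(runif(1, 0, 100), 2)
    f <- f_measure(p, r)
    expect_equal(f, f_measure(r, p))
    if (p + r > 0) {
      expect_gte(f, min(p, r) - 0.005)
      expect_lte(f, max(p, r) + 0.005)
    }
  }
})

test_that("eval_result computes the ratio identities", {
  r <- eval_result(tp = 107, fp = 54, fn = 215, mode = "strict")
  expect_equal(r$recall, 33.23)
  expect_equal(r$precision, 66.46)
  r2 <- eval_result(tp = 122, fp = 39, fn = 200, mode = "lenient")
  expect_equal(r2$precision, 75.78)
  expect_equal(r2$recall, 37.89)
  expect_equal(r2$f, 50.52)
  # zero retrieved: precision reported as 0 with a flag
  r3 <- eval_result(0, 0, 10)
  expect_equal(r3$precision, 0)
  expect_true(r3$undefined_precision)
  expect_equal(r3$f, 0)
})

test_that("score handles identity and degenerate inputs", {
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 6, seed = 17))
  rel <- extract_corpus(fx$documents, fx$parses, we_dict())
  res <- score(rel, fx$gold, "strict")
  expect_equal(res$precision, 100)
  expect_equal(res$recall, 100)
  expect_equal(res$f, 100)
  # empty predictions against non-empty gold
  res0 <- score(rel[0, ], fx$gold, "lenient")
  expect_equal(res0$precision, 0)
  expect_equal(res0$recall, 0)
  expect_equal(res0$f, 0)
  expect_equal(res0$fn, n_gold_relations(fx$gold))
  expect_error(score(rel, fx$gold, "fuzzy"))
})

test_that("lenient accepts partial surfaces that strict rejects", {
  gold <- nc_gold_corpus(
    sentences = data.frame(id = "d1.s0", doc_id = "d1", index = 0L,
                           text = "t", stringsAsFactors = FALSE),
    entities = data.frame(id = c("d1.s0.e0", "d1.s0.e1"),
                          sentence_id = "d1.s0",
                          text = c("dorsal midline thalamus", "SCN"),
                          stringsAsFactors = FALSE),
    pairs = data.frame(sentence_id = "d1.s0", e1 = "d1.s0.e0",
                       e2 = "d1.s0.e1", interaction = TRUE,
                       direction = "e1_to_e2", stringsAsFactors = FALSE))
  pred <- data.frame(doc_id = "d1", sentence_index = 0L,
                     agent_surface = "thalamus", target_surface = "SCN",
                     stringsAsFactors = FALSE)
  expect_equal(score(pred, gold, "strict")$tp, 0L)
  expect_equal(score(pred, gold, "lenient")$tp, 1L)
  # orderless matching: swapped prediction still matches
  swapped <- data.frame(doc_id = "d1", sentence_index = 0L,
                        agent_surface = "SCN",
                        target_surface = "dorsal midline thalamus",
                        stringsAsFactors = FALSE)
  expect_equal(score(swapped, gold, "strict")$tp, 1L)
})

test_that("nlp mode promotes flagged unannotated candidates", {
  gold <- nc_gold_corpus(
    sentences = data.frame(id = "d1.s0", doc_id = "d1", index = 0L,
                           text = "t", stringsAsFactors = FALSE),
    entities = data.frame(id = c("d1.s0.e0", "d1.s0.e1"),
                          sentence_id = "d1.s0", text = c("PVT", "SCN"),
                          stringsAsFactors = FALSE),
    pairs = data.frame(sentence_id = "d1.s0", e1 = "d1.s0.e0",
                       e2 = "d1.s0.e1", interaction = TRUE,
                       direction = NA_character_, stringsAsFactors = FALSE))
  pred <- data.frame(
    doc_id = c("d1", "d1"), sentence_index = c(0L, 1L),
    agent_surface = c("PVT", "PVT"), target_surface = c("SCN", "amygdala"),
    unannotated_candidate = c(FALSE, TRUE), stringsAsFactors = FALSE)
  s <- score(pred, gold, "strict")
  n <- score(pred, gold, "nlp")
  expect_equal(s$tp, 1L); expect_equal(s$fp, 1L)
  expect_equal(n$tp, 2L); expect_equal(n$fp, 0L)
  expect_gte(n$precision, s$precision)
})

test_that("direction accuracy is computed over true positives only", {
  d <- direction_accuracy(rep("f", 122),
                          c(rep("f", 119), rep("b", 3)))
  expect_equal(d$examined, 122L)
  expect_equal(d$correct, 119L)
  expect_equal(d$accuracy, 97.54)
  expect_equal(direction_accuracy("f", "f")$accuracy, 100)
  expect_warning(
    d2 <- direction_accuracy(c("f", "f"), c("f", NA)),
    "without gold direction")
  expect_equal(d2$examined, 1L)
})

test_that("the majority baseline counts forward-reading directions", {
  expect_equal(majority_direction_baseline(
    c(rep(TRUE, 205), rep(FALSE, 72))), 74.01)
  expect_equal(majority_direction_baseline(rep(TRUE, 10)), 100)
  # brute-force recount over a simulated relation set equals the formula
  set.seed(9)
  fwd <- runif(200) < 0.7
  manual <- 0
  for (x in fwd) if (x) manual <- manual + 1
  expect_equal(majority_direction_baseline(fwd),
               floor(100 * manual / length(fwd) * 100 + 0.5) / 100)
})

test_that("flipping the role table flips directions on the fixtures", {
  # role override: post-pattern text of "project to" becomes the agent
  cfg <- do.call(rbind, lapply(compile_patterns(), function(d) {
    data.frame(name = d$name, regex = d$regex,
               role_after = if (d$name == "project to") "agent"
                            else d$role_after,
               slots = d$slots, prep1 = d$prep1, prep2 = d$prep2,
               stem = d$stem, stringsAsFactors = FALSE)
  }))
  flipped <- compile_patterns(cfg)
  dict <- we_dict()
  ex <- worked_example("scn_pa")
  rel <- extract_from_sentence(ex$sentence, ex$tree, ex$edges, dict,
                               patterns = flipped)
  expect_equal(rel$agent, "Pa")
  expect_equal(rel$target, "Suprachiasmatic nucleus")
})
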