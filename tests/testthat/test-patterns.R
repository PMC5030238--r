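test_that("the default pattern table compiles 18 patterns with roles", {
  p <- compile_patterns()
  expect_length(p, 18L)
  for (d in p) {
    expect_true(d$role_after %in% c("agent", "target"))
    expect_false(identical(d$role_after, d$role_other))
  }
  duals <- Filter(function(d) d$slots == "dual", p)
  expect_setequal(vapply(duals, `[[`, "", "name"),
                  c("projection to from", "projection from to",
                    "project from to", "traveling from to"))
})

test_that("pattern regexes tolerate interleaved words and inflections", {
  p <- compile_patterns()
  m <- find_pattern_matches(
    "The suprachiasmatic nucleus is well known to project densely to Pa in rats.",
    p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pattern, "project to")
  s <- nc_sentence("x", 0L,
    "The suprachiasmatic nucleus is well known to project densely to Pa in rats.")
  expect_equal(substring(s$text, m$start, m$end), "project densely to")

  # unanchored keyword: "innervate" fires inside "innervated"
  m2 <- find_pattern_matches(
    "the aPVT was strongly innervated by the ventral subiculum", p)
  expect_equal(m2$pattern, "innervate")

  m3 <- find_pattern_matches("The nucleus projects to the cortex", p)
  expect_equal(m3$pattern, "project to")
  m4 <- find_pattern_matches("It receives a dense orexin input mostly from the hypothalamus", p)
  expect_equal(m4$pattern, "receive input from")
})

test_that("dual-slot matches subsume their single-slot prefixes", {
  m <- find_pattern_matches(
    "These experiments confirm projections from Pa, Pt, and other midline nuclei to the amygdala.")
  expect_equal(nrow(m), 1L)
  expect_equal(m$pattern, "projection from to")
  expect_false(is.na(m$slot1_start))
  s <- "These experiments confirm projections from Pa, Pt, and other midline nuclei to the amygdala."
  expect_equal(trimws(substring(s, m$slot1_start, m$slot1_end)),
               "Pa, Pt, and other midline nuclei")
})

test_that("matching is case-insensitive with identical spans", {
  s <- "The PVT projects densely to the amygdala."
  m1 <- find_pattern_matches(s)
  m2 <- find_pattern_matches(toupper(s))
  expect_equal(m1[, c("pattern", "start", "end")],
               m2[, c("pattern", "start", "end")])
})

test_that("keyword-free sentences yield no matches", {
  expect_equal(nrow(find_pattern_matches(
    "The thalamus and the cortex were compared across species.")), 0L)
})

test_that("candidate selection is the pattern-match filter", {
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 8, seed = 2))
  cands <- select_candidate_sentences(fx$documents)
  all_sents <- unlist(lapply(fx$documents, `[[`, "sentences"),
                      recursive = FALSE)
  manual <- Filter(function(s) nrow(find_pattern_matches(s)) > 0, all_sents)
  expect_equal(vapply(cands, `[[`, "", "text"),
               vapply(manual, `[[`, "", "text"))
  # candidate set covers every gold relation's sentence
  gold_keys <- sprintf("%s.s%d", fx$relations$doc_id,
                       fx$relations$sentence_index)
  cand_keys <- vapply(cands, function(s) {
    sprintf("%s.s%d", s$doc_id, s$index)
  }, "")
  expect_true(all(gold_keys %in% cand_keys))

  none <- generate_fixture_corpus(
    fixture_spec(n_docs = 4, distractor_fraction = 1, seed = 2))
  # distractor-only corpora still contain trigger-bearing distractors but
  # those with no trigger are excluded
  cand_texts <- vapply(select_candidate_sentences(none$documents),
                       `[[`, "", "text")
  expect_false(any(grepl("discussed in detail", cand_texts)))
})

test_that("pattern config validation rejects bad tables", {
  cfg <- data.frame(name = c("a", "a"), regex = c("x", "y"),
                    role_after = c("agent", "target"),
                    stringsAsFactors = FALSE)
  expect_error(compile_patterns(cfg), "duplicate")
  cfg2 <- data.frame(name = "bad", regex = "([", role_after = "agent",
                     stringsAsFactors = FALSE)
  expect_error(compile_patterns(cfg2), "invalid regex")
  cfg3 <- data.frame(name = "r", regex = "x", role_after = "middle",
                     stringsAsFactors = FALSE)
  expect_error(compile_patterns(cfg3), "role_after")
})

test_that("no returned match span is strictly contained in another", {
  m0 <- find_pattern_matches(paste0(
    "The SCN projects densely to the PVT and receives dense input ",
    "from the locus coeruleus."))
  expect_equal(nrow(m0), 2L)
  expect_setequal(m0$pattern, c("project to", "receive input from"))
  fx <- generate_fixture_corpus(fixture_spec(n_docs = 10, seed = 9))
  for (d in fx$documents) {
    for (s in d$sentences) {
      m <- find_pattern_matches(s)
      if (nrow(m) < 2) next
      for (i in seq_len(nrow(m))) {
        for (j in seq_len(nrow(m))) {
          if (i == j) next
          contained <- m$start[j] <= m$start[i] && m$end[j] >= m$end[i] &&
            (m$end[j] - m$start[j]) > (m$end[i] - m$start[i])
          expect_false(contained)
        }
      }
    }
  }
})
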