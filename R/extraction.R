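#' Directed relation extraction
#'
#' Orchestrates patterns, parse-tree rules and the dictionary into directed
#' relations: for each trigger-pattern match in a candidate sentence, the
#' first argument is the first noun phrase after the pattern (extended with a
#' following "including" PP), the second argument comes from the dependency
#' rules (or, for dual-slot patterns such as "projections from X to Y", from
#' the span between the two prepositions). Both argument spans are pushed
#' through the dictionary cascade; every (agent region, target region)
#' combination yields one relation, with the agent side determined by the
#' pattern's role table and flipped under passive voice.
#'
#' @name extraction
NULL

.nc_empty_relations <- function() {
  data.frame(doc_id = character(), sentence_index = integer(),
             agent = character(), target = character(),
             agent_surface = character(), target_surface = character(),
             agent_kind = character(), target_kind = character(),
             agent_first = logical(), pattern = character(),
             sentence_text = character(), stringsAsFactors = FALSE)
}

# candidate span -> its text, using sentence tokens where available
.nc_span_text <- function(span, sentence = NULL) {
  if (nrow(span) == 0L) return("")
  if (!is.null(sentence)) {
    toks <- sentence$tokens
    hit <- match(span$pos, toks$pos)
    if (!anyNA(hit)) return(paste(toks$surface[hit], collapse = " "))
  }
  paste(span$surface, collapse = " ")
}

#' Assign agent/target roles to a pattern's two argument slots
#'
#' @param pattern pattern name (must exist in \code{patterns}).
#' @param voice "active" or "passive"; passive flips the role table
#'   (supports "the aPVT was strongly innervated by the ventral subiculum").
#' @param patterns compiled pattern set.
#' @return named character vector \code{c(after = ..., other = ...)}: the
#'   role of the post-pattern noun phrase and of the dependency-derived
#'   argument. Dual-slot patterns are not voice-flipped (both slots are
#'   anchored to their prepositions); \code{after} is then the role of the
#'   post-pattern slot and \code{other} that of the between-prepositions
#'   slot.
#' @export
assign_direction <- function(pattern, voice = c("active", "passive"),
                             patterns = compile_patterns()) {
  voice <- match.arg(voice)
  def <- NULL
  for (d in patterns) if (identical(d$name, pattern)) { def <- d; break }
  if (is.null(def)) stop("unknown pattern: '", pattern, "'")
  roles <- c(after = def$role_after, other = def$role_other)
  if (voice == "passive" && !identical(def$slots, "dual")) {
    roles <- c(after = def$role_other, other = def$role_after)
  }
  roles
}

#' Extract directed relations from one sentence
#'
#' @param sentence an [nc_sentence()] (or character scalar).
#' @param tree constituency tree (\code{nc_ctree}) for the sentence, or NULL.
#' @param edges dependency edges for the sentence, or NULL.
#' @param dict an \code{nc_dictionary}.
#' @param patterns compiled pattern set.
#' @return relations data.frame: \code{doc_id}, \code{sentence_index},
#'   \code{agent}, \code{target} (canonical names), surfaces, match kinds
#'   ("full"/"partial"), \code{agent_first} (was the agent mentioned before
#'   the target?), \code{pattern}, \code{sentence_text}. Relations whose two
#'   sides normalize to the same canonical region are suppressed.
#' @export
extract_from_sentence <- function(sentence, tree, edges, dict,
                                  patterns = compile_patterns()) {
  if (is.character(sentence)) sentence <- nc_sentence("adhoc", 0L, sentence)
  matches <- find_pattern_matches(sentence, patterns)
  if (nrow(matches) == 0L) return(.nc_empty_relations())

  defs <- stats::setNames(patterns, vapply(patterns, `[[`, "", "name"))
  out <- list()
  for (mi in seq_len(nrow(matches))) {
    m <- matches[mi, , drop = FALSE]
    def <- defs[[m$pattern]]
    dual <- identical(def$slots, "dual")
    if (is.null(tree)) {
      stop("missing constituency parse for sentence ",
           sentence$doc_id, ".s", sentence$index)
    }
    if (!dual && is.null(edges)) {
      stop("missing dependency parse for sentence ",
           sentence$doc_id, ".s", sentence$index)
    }

    np <- first_np_after(tree, m)
    np <- extend_with_including_pp(tree, np)
    after_txt <- .nc_span_text(np, sentence)
    after_pos <- if (nrow(np)) np$pos[1] else NA_integer_

    if (dual) {
      if (is.na(m$slot1_start) || m$slot1_end < m$slot1_start) next
      other_txt <- trimws(substring(sentence$text, m$slot1_start,
                                    m$slot1_end))
      other_pos <- m$first_tok
      roles <- c(after = def$role_after, other = def$role_other)
    } else {
      span2 <- second_dependent(edges, m$keyword_pos)
      other_txt <- .nc_span_text(span2, sentence)
      other_pos <- if (nrow(span2)) span2$pos[1] else NA_integer_
      voice <- if (.nc_is_passive(edges, m$keyword_pos)) "passive"
               else "active"
      roles <- assign_direction(m$pattern, voice, patterns)
    }
    if (!nzchar(after_txt) || !nzchar(other_txt)) next

    after_regions <- match_text(after_txt, dict)
    other_regions <- match_text(other_txt, dict)
    if (nrow(after_regions) == 0L || nrow(other_regions) == 0L) next

    for (ai in seq_len(nrow(after_regions))) {
      for (oi in seq_len(nrow(other_regions))) {
        ra <- after_regions[ai, ]; ro <- other_regions[oi, ]
        if (identical(ra$canonical, ro$canonical)) next
        if (roles[["after"]] == "agent") {
          agent <- ra; target <- ro
          agent_first <- isTRUE(after_pos < other_pos)
        } else {
          agent <- ro; target <- ra
          agent_first <- isTRUE(other_pos < after_pos)
        }
        out[[length(out) + 1L]] <- data.frame(
          doc_id = sentence$doc_id, sentence_index = sentence$index,
          agent = agent$canonical, target = target$canonical,
          agent_surface = agent$surface, target_surface = target$surface,
          agent_kind = agent$kind, target_kind = target$kind,
          agent_first = agent_first, pattern = m$pattern,
          sentence_text = sentence$text, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(.nc_empty_relations())
  rel <- do.call(rbind, out)
  # the same relation found via two patterns in one sentence counts once
  rel <- rel[!duplicated(rel[, c("agent", "target")]), , drop = FALSE]
  rownames(rel) <- NULL
  rel
}

#' Extract relations from a corpus
#'
#' @param documents list of [nc_document()] objects.
#' @param parses named list keyed \code{"<doc_id>.s<index>"}; each element a
#'   \code{list(tree = , deps = )} where \code{tree} is a bracketed string or
#'   \code{nc_ctree} and \code{deps} a character vector of triples or an edge
#'   data.frame. Candidate sentences without parses raise an error.
#' @param dict dictionary.
#' @param patterns pattern set.
#' @param verbose log per-stage counts via [message()].
#' @return combined relations data.frame (sentence-level, pre-deduplication).
#' @export
extract_corpus <- function(documents, parses, dict,
                           patterns = compile_patterns(), verbose = FALSE) {
  sents <- .nc_corpus_sentences(documents)
  cands <- select_candidate_sentences(sents, patterns)
  if (verbose) {
    message("sentences: ", length(sents), "; candidates: ", length(cands))
  }
  out <- list()
  for (s in cands) {
    key <- sprintf("%s.s%d", s$doc_id, s$index)
    p <- parses[[key]]
    if (is.null(p)) stop("missing parses for candidate sentence ", key)
    tree <- p$tree
    if (is.character(tree)) tree <- parse_bracketed_tree(tree)
    edges <- p$deps
    if (is.character(edges)) edges <- parse_dependency_triples(edges)
    rel <- extract_from_sentence(s, tree, edges, dict, patterns)
    if (nrow(rel) > 0L) out[[length(out) + 1L]] <- rel
  }
  rel <- if (length(out)) do.call(rbind, out) else .nc_empty_relations()
  rownames(rel) <- NULL
  if (verbose) message("relations: ", nrow(rel))
  rel
}

#' Deduplicate relations at document level
#'
#' Keeps one relation per ordered (agent, target) pair per document -- the
#' first occurrence -- and records how many mentions were merged in
#' \code{n_mentions} (used as edge weight by the graph module). A -> B and
#' B -> A are distinct pairs.
#'
#' @param relations relations data.frame.
#' @return deduplicated data.frame with an \code{n_mentions} column.
#' @export
dedup_document <- function(relations) {
  if (nrow(relations) == 0L) {
    rel <- .nc_empty_relations()
    rel$n_mentions <- integer()
    return(rel)
  }
  key <- paste(relations$doc_id, relations$agent, relations$target,
               sep = "\r")
  counts <- table(key)
  out <- relations[!duplicated(key), , drop = FALSE]
  out$n_mentions <- as.integer(counts[paste(out$doc_id, out$agent,
                                            out$target, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Write relations as TSV
#'
#' Columns: doc_id, sentence_idx, agent, direction ("->"), target, pattern,
#' agent_match_kind, target_match_kind, sentence_text.
#'
#' @param relations relations data.frame.
#' @param path output path.
#' @export
write_relations_tsv <- function(relations, path) {
  df <- data.frame(doc_id = relations$doc_id,
                   sentence_idx = relations$sentence_index,
                   agent = relations$agent, direction = "->",
                   target = relations$target, pattern = relations$pattern,
                   agent_match_kind = relations$agent_kind,
                   target_match_kind = relations$target_kind,
                   sentence_text = relations$sentence_text,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read relations written by [write_relations_tsv()]
#' @param path TSV path.
#' @return relations data.frame.
#' @export
read_relations_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  data.frame(doc_id = as.character(df$doc_id),
             sentence_index = df$sentence_idx,
             agent = df$agent, target = df$target,
             agent_surface = df$agent, target_surface = df$target,
             agent_kind = df$agent_match_kind,
             target_kind = df$target_match_kind,
             agent_first = NA, pattern = df$pattern,
             sentence_text = df$sentence_text, stringsAsFactors = FALSE)
}
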