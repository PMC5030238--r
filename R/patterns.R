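#' Trigger patterns for connectivity statements
#'
#' The extractor nominates sentences with a fixed set of 18 trigger patterns
#' over connectivity keywords ("project to", "innervate", "receive input
#' from", ...). Each pattern is a case-insensitive regular expression that
#' tolerates a bounded number of interleaved words between its keywords (so
#' "project densely to" matches "project to"), together with role semantics:
#' whether the text following the pattern names the agent (source) or the
#' target (destination) of the projection.
#'
#' Single-slot patterns take their first argument from the first noun phrase
#' after the match and their second argument from dependency rules. Dual-slot
#' patterns ("projection from ... to ...") carry both arguments locally: the
#' span between the two prepositions and the noun phrase after the second
#' one.
#'
#' @name patterns
NULL

# one interleaved word, optionally carrying a trailing comma/semicolon (so
# list-valued slots such as "from Pa, Pt, and other midline nuclei to" match)
.nc_w <- "(?:[[:alnum:]_'-]+[,;]?\\s+)"

.nc_default_pattern_table <- function() {
  w <- .nc_w
  def <- function(name, regex, role_after, slots = "single",
                  prep1 = NA_character_, prep2 = NA_character_,
                  stem = NULL) {
    list(name = name, regex = regex, role_after = role_after, slots = slots,
         prep1 = prep1, prep2 = prep2,
         stem = if (is.null(stem)) sub("[ [].*$", "", name) else stem)
  }
  list(
    def("innervate", "innervat(e|es|ing)", "target", stem = "innervat"),
    def("innervation of", "innervations?\\s+of\\b", "target",
        stem = "innervation"),
    def("projection to", "projections?\\s+to\\b", "target",
        stem = "projection"),
    def("projection to from",
        paste0("projections?\\s+to\\s+", w, "{0,8}from\\b"),
        "agent", slots = "dual", prep1 = "to", prep2 = "from",
        stem = "projection"),
    def("projection of", "projections?\\s+of\\b", "agent",
        stem = "projection"),
    def("projection target of", "projection\\s+targets?\\s+of\\b", "agent",
        stem = "projection"),
    def("projection from", "projections?\\s+from\\b", "agent",
        stem = "projection"),
    def("projection from to",
        paste0("projections?\\s+from\\s+", w, "{0,8}to\\b"),
        "target", slots = "dual", prep1 = "from", prep2 = "to",
        stem = "projection"),
    def("project to",
        paste0("project(ing|s|ed)?\\s+", w, "{0,2}to\\b"),
        "target", stem = "project"),
    def("project into",
        paste0("project(ing|s|ed)?\\s+", w, "{0,2}into\\b"),
        "target", stem = "project"),
    def("project from to",
        paste0("project(s|ed|ing)?\\s+from\\s+", w, "{0,8}to\\b"),
        "target", slots = "dual", prep1 = "from", prep2 = "to",
        stem = "project"),
    def("receive input from",
        paste0("receiv(e|es|ing|ed)\\s+", w, "{0,4}inputs?\\s+",
               w, "{0,3}from\\b"),
        "agent", stem = "receiv"),
    def("receive fiber from",
        paste0("receiv(e|es|ing|ed)\\s+", w, "{0,4}fibers?\\s+",
               w, "{0,3}from\\b"),
        "agent", stem = "receiv"),
    def("receive innervation from",
        paste0("receiv(e|es|ing|ed)\\s+", w, "{0,4}innervations?\\s+",
               w, "{0,3}from\\b"),
        "agent", stem = "receiv"),
    def("receive [ae]fferent from",
        paste0("receiv(e|es|ing|ed)\\s+", w, "{0,4}[ae]fferents?\\s+",
               w, "{0,3}from\\b"),
        "agent", stem = "receiv"),
    def("traveling from to",
        paste0("travel(s|ling|ing)?\\s+", w, "{0,2}from\\s+",
               w, "{0,5}to\\b"),
        "target", slots = "dual", prep1 = "from", prep2 = "to",
        stem = "travel"),
    def("exit through",
        paste0("exit(s|ing)?\\s+", w, "*through\\b"),
        "agent", stem = "exit"),
    def("exit from",
        paste0("exit(s|ing)?\\s+", w, "*from\\b"),
        "agent", stem = "exit")
  )
}

#' Compile the trigger-pattern set
#'
#' @param config optional data.frame overriding or replacing the default
#'   table; columns \code{name}, \code{regex}, \code{role_after}
#'   ("agent"/"target") and optionally \code{slots} ("single"/"dual"),
#'   \code{prep1}, \code{prep2}, \code{stem}. For dual-slot patterns the two
#'   prepositions delimit the in-pattern argument slot (text between them)
#'   and the post-pattern slot; the "from" slot is always the agent.
#' @return an \code{nc_pattern_set}: list of pattern definitions. Each has
#'   \code{name}, \code{regex} (case-insensitive, applied unanchored),
#'   \code{role_after}, \code{role_other}, \code{slots}, \code{prep1},
#'   \code{prep2} and \code{stem} (the keyword stem used to anchor dependency
#'   rules).
#' @export
compile_patterns <- function(config = NULL) {
  defs <- .nc_default_pattern_table()
  if (!is.null(config)) {
    stopifnot(is.data.frame(config),
              all(c("name", "regex", "role_after") %in% names(config)))
    defs <- lapply(seq_len(nrow(config)), function(i) {
      row <- config[i, , drop = FALSE]
      list(name = row$name, regex = row$regex, role_after = row$role_after,
           slots = if ("slots" %in% names(config)) row$slots else "single",
           prep1 = if ("prep1" %in% names(config)) row$prep1 else NA_character_,
           prep2 = if ("prep2" %in% names(config)) row$prep2 else NA_character_,
           stem = if ("stem" %in% names(config)) row$stem
                  else sub("[ [].*$", "", row$name))
    })
  }
  nms <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate pattern names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  for (d in defs) {
    if (!d$role_after %in% c("agent", "target")) {
      stop("pattern '", d$name, "': role_after must be 'agent' or 'target'")
    }
    ok <- tryCatch({ grepl(d$regex, "x", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("pattern '", d$name, "': invalid regex")
  }
  defs <- lapply(defs, function(d) {
    d$role_other <- setdiff(c("agent", "target"), d$role_after)
    d
  })
  structure(defs, class = "nc_pattern_set")
}

#' @export
print.nc_pattern_set <- function(x, ...) {
  cat(sprintf("<pattern set: %d patterns>\n", length(x)))
  for (d in x) {
    cat(sprintf("  %-26s %-6s post-pattern=%s  /%s/\n",
                d$name, d$slots, d$role_after, d$regex))
  }
  invisible(x)
}

#' Locate trigger-pattern matches in a sentence
#'
#' All matches of all patterns are located; a match whose character span is
#' strictly contained in another match's span is dropped, so when a dual-slot
#' pattern ("projection from ... to") and its single-slot prefix ("projection
#' from") both fire on the same stretch of text only the more specific
#' dual-slot match survives.
#'
#' @param sentence an [nc_sentence()] (or character scalar, tokenized on the
#'   fly).
#' @param patterns an [compile_patterns()] set.
#' @return data.frame with one row per match: \code{pattern}, \code{start},
#'   \code{end} (character span), \code{first_tok}, \code{last_tok} (covered
#'   token positions), \code{keyword_pos} (token anchoring dependency rules),
#'   and for dual-slot matches \code{slot1_start}, \code{slot1_end} (span
#'   between the two prepositions).
#' @export
find_pattern_matches <- function(sentence, patterns = compile_patterns()) {
  if (is.character(sentence)) sentence <- nc_sentence("adhoc", 0L, sentence)
  stopifnot(inherits(sentence, "nc_sentence"))
  text <- sentence$text
  toks <- sentence$tokens

  rows <- list()
  for (d in patterns) {
    m <- gregexpr(paste0("(?i)", d$regex), text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    ends <- starts + attr(m, "match.length") - 1L
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- ends[k]
      cov <- which(toks$end >= s & toks$start <= e)
      if (length(cov) == 0L) next
      kw <- cov[grepl(paste0("(?i)^", .nc_rx_escape(d$stem)),
                      toks$surface[cov], perl = TRUE)]
      kw <- if (length(kw)) kw[1] else cov[1]
      row <- data.frame(pattern = d$name, start = s, end = e,
                        first_tok = min(cov), last_tok = max(cov),
                        keyword_pos = kw,
                        slot1_start = NA_integer_, slot1_end = NA_integer_,
                        stringsAsFactors = FALSE)
      if (identical(d$slots, "dual")) {
        span <- substring(text, s, e)
        p1 <- regexpr(paste0("(?i)\\b", d$prep1, "\\b"), span, perl = TRUE)
        # the closing preposition is the last word of the match
        p2 <- gregexpr(paste0("(?i)\\b", d$prep2, "\\b"), span,
                       perl = TRUE)[[1]]
        if (p1[1] > 0 && p2[1] > 0) {
          p2s <- p2[length(p2)]
          row$slot1_start <- s + p1[1] + attr(p1, "match.length") - 1L
          row$slot1_end <- s + as.integer(p2s) - 2L
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pattern = character(), start = integer(),
                      end = integer(), first_tok = integer(),
                      last_tok = integer(), keyword_pos = integer(),
                      slot1_start = integer(), slot1_end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # subsumption: drop matches strictly contained in another match's span
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j) next
      inside <- out$start[j] <= out$start[i] && out$end[j] >= out$end[i] &&
        (out$end[j] - out$start[j]) > (out$end[i] - out$start[i])
      if (inside) { keep[i] <- FALSE; break }
    }
  }
  out <- out[keep, , drop = FALSE]
  # identical spans from two patterns: keep the first listed
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select candidate sentences
#'
#' Filters a corpus down to the sentences containing at least one trigger
#' pattern, in original order. Only these sentences proceed to syntactic
#' analysis.
#'
#' @param corpus a list of [nc_document()] objects, or a list of sentences.
#' @param patterns pattern set.
#' @return list of \code{nc_sentence} objects with >= 1 pattern match.
#' @export
select_candidate_sentences <- function(corpus, patterns = compile_patterns()) {
  sents <- .nc_corpus_sentences(corpus)
  Filter(function(s) nrow(find_pattern_matches(s, patterns)) > 0L, sents)
}

.nc_corpus_sentences <- function(corpus) {
  if (inherits(corpus, "nc_document")) return(corpus$sentences)
  if (inherits(corpus, "nc_sentence")) return(list(corpus))
  out <- list()
  for (el in corpus) {
    if (inherits(el, "nc_document")) out <- c(out, el$sentences)
    else if (inherits(el, "nc_sentence")) out <- c(out, list(el))
    else stop("corpus must contain nc_document or nc_sentence objects")
  }
  out
}
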