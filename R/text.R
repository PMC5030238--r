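#' Tokenize a sentence
#'
#' Splits text into word and punctuation tokens. Token positions are 1-based
#' and count punctuation marks as tokens, matching the position convention of
#' typed dependency triples such as \code{nsubj(projects-17, subnucleus-16)}.
#' Hyphenated and apostrophe-joined words (e.g. "tract-tracing") stay single
#' tokens; commas, periods, parentheses and other punctuation become tokens of
#' their own.
#'
#' @param text character scalar.
#' @return data.frame with columns \code{surface}, \code{pos} (1-based),
#'   \code{start}, \code{end} (character offsets, inclusive).
#' @export
nc_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(surface = character(), pos = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  rx <- "[[:alnum:]_]+(?:['’-][[:alnum:]_]+)*|[^[:space:][:alnum:]_]"
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), pos = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  data.frame(surface = substring(text, starts, ends),
             pos = seq_along(starts),
             start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# Abbreviations that must not terminate a sentence when followed by a period.
.nc_nonfinal_abbrev <- c(
  "al", "e.g", "i.e", "cf", "ca", "vs", "etc", "fig", "figs", "eq", "eqs",
  "dr", "mr", "mrs", "ms", "prof", "st", "no", "approx", "resp", "ref", "refs"
)

#' Split text into sentences
#'
#' A rule-based splitter: a sentence ends at \code{.}, \code{?} or \code{!}
#' followed by whitespace and an upper-case letter, digit or opening
#' quote/parenthesis, unless the period terminates a known abbreviation
#' ("et al.", "e.g.", "Fig.") or a single-letter initial. Parenthesized
#' citations such as "(Krout and Loewy, 1998)." therefore stay inside their
#' sentence.
#'
#' @param text character scalar (may be empty).
#' @param doc_id document identifier attached to each sentence.
#' @return list of \code{nc_sentence} objects (empty list for empty input).
#' @export
split_sentences <- function(text, doc_id = "doc") {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(list())

  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bounds <- integer(0)  # index of last char of each sentence
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "?", "!")) {
      # absorb runs like "..." or ".)"
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "?", "!", "\"", "'", ")")) j <- j + 1L
      rest <- substring(text, j + 1L)
      follows <- grepl('^[[:space:]]+["\'(]?[[:upper:]0-9]', rest) || !nzchar(trimws(rest))
      if (follows && ch == "." && j == i) {
        # inspect the word preceding the period
        prev <- sub(".*?([[:alnum:].-]+)\\.$", "\\1",
                    substring(text, max(1L, i - 20L), i))
        prevl <- tolower(prev)
        if (prevl %in% .nc_nonfinal_abbrev ||
            prevl %in% sub("\\.$", "", .nc_nonfinal_abbrev)) {
          i <- i + 1L
          next
        }
      }
      if (follows) {
        bounds <- c(bounds, j)
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(bounds) == 0L || bounds[length(bounds)] < n) bounds <- c(bounds, n)

  out <- list()
  beg <- 1L
  idx <- 0L
  for (b in bounds) {
    raw <- substring(text, beg, b)
    lead <- nchar(raw) - nchar(sub("^[[:space:]]+", "", raw))
    stxt <- trimws(raw)
    if (nzchar(stxt)) {
      out[[length(out) + 1L]] <- nc_sentence(
        doc_id = doc_id, index = idx, text = stxt,
        char_start = beg + lead)
      idx <- idx + 1L
    }
    beg <- b + 1L
  }
  out
}

#' Sentence constructor
#'
#' @param doc_id document id.
#' @param index 0-based sentence ordinal within the document.
#' @param text sentence text.
#' @param char_start 1-based offset of the sentence within the document text.
#' @return an \code{nc_sentence}: list with \code{doc_id}, \code{index},
#'   \code{text}, \code{char_start} and a \code{tokens} data.frame.
#' @export
nc_sentence <- function(doc_id, index, text, char_start = 1L) {
  structure(list(doc_id = doc_id, index = as.integer(index), text = text,
                 char_start = as.integer(char_start),
                 tokens = nc_tokenize(text)),
            class = "nc_sentence")
}

#' @export
print.nc_sentence <- function(x, ...) {
  cat(sprintf("<sentence %s.s%d, %d tokens> %s\n",
              x$doc_id, x$index, nrow(x$tokens), x$text))
  invisible(x)
}

#' Document constructor
#'
#' @param doc_id opaque id.
#' @param text full UTF-8 text.
#' @param expand run [expand_abbreviations()] before sentence splitting.
#' @return an \code{nc_document}: list with \code{doc_id}, \code{text} and
#'   \code{sentences}.
#' @export
nc_document <- function(doc_id, text, expand = FALSE) {
  if (expand) text <- expand_abbreviations(text)
  structure(list(doc_id = doc_id, text = text,
                 sentences = split_sentences(text, doc_id = doc_id)),
            class = "nc_document")
}

#' @export
print.nc_document <- function(x, ...) {
  cat(sprintf("<document %s: %d sentences, %d chars>\n",
              x$doc_id, length(x$sentences), nchar(x$text)))
  invisible(x)
}

# ---- Schwartz-Hearst abbreviation expansion --------------------------------

# Candidate short form: content of a parenthesis, 2-10 characters, at most two
# words, starts with an alphanumeric character and contains a letter.
.nc_valid_short_form <- function(sf) {
  nc <- nchar(sf)
  if (nc < 2L || nc > 10L) return(FALSE)
  if (length(strsplit(trimws(sf), "[[:space:]]+")[[1]]) > 2L) return(FALSE)
  if (!grepl("^[[:alnum:]]", sf)) return(FALSE)
  grepl("[[:alpha:]]", sf)
}

# Right-to-left character matching: every alphanumeric character of the short
# form must appear, in order, in the long form, and the short form's first
# character must match at the start of a word of the long form.
.nc_best_long_form <- function(sf, lf) {
  s <- tolower(sf); l <- tolower(lf)
  si <- nchar(s); li <- nchar(l)
  while (si >= 1L) {
    ch <- substr(s, si, si)
    if (!grepl("[a-z0-9]", ch)) { si <- si - 1L; next }
    repeat {
      if (li < 1L) return(NULL)
      lc <- substr(l, li, li)
      ok <- identical(lc, ch)
      if (ok && si == 1L && li > 1L &&
          grepl("[a-z0-9]", substr(l, li - 1L, li - 1L))) {
        ok <- FALSE
      }
      if (ok) break
      li <- li - 1L
    }
    si <- si - 1L; li <- li - 1L
  }
  substring(lf, li + 1L)
}

#' Expand abbreviation definitions (Schwartz-Hearst)
#'
#' Finds abbreviation definitions of the shape "long form (SF)" with the
#' classic character-matching criterion (the short form is matched against the
#' long form right to left; its first character must start a word of the long
#' form; the long form may span at most min(|SF| + 5, 2 |SF|) words). Each
#' subsequent free-standing occurrence of a defined short form is replaced by
#' "long form (short form)", so downstream matching sees the spelled-out
#' region name while the acronym is kept right after it. The operation is
#' idempotent: already-parenthesized occurrences are never rewritten.
#'
#' @param text character scalar.
#' @return the text with short forms expanded.
#' @export
expand_abbreviations <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(text)

  m <- gregexpr("\\(([^()]+)\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(text)
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L

  pairs <- list()
  for (k in seq_along(starts)) {
    sf <- substring(text, starts[k] + 1L, ends[k] - 1L)
    sf <- trimws(sf)
    if (!.nc_valid_short_form(sf)) next
    pre <- substring(text, 1L, starts[k] - 1L)
    # restrict the long-form window to the current sentence fragment
    pre <- sub(".*[.!?;]", "", pre)
    words <- strsplit(trimws(pre), "[[:space:]]+")[[1]]
    words <- words[nzchar(words)]
    if (length(words) == 0L) next
    kmax <- min(nchar(sf) + 5L, 2L * nchar(sf))
    lf_window <- paste(utils::tail(words, kmax), collapse = " ")
    lf <- .nc_best_long_form(sf, lf_window)
    if (is.null(lf)) next
    lf <- trimws(lf)
    if (!nzchar(lf)) next
    if (nchar(lf) <= nchar(sf)) next
    if (length(strsplit(lf, "[[:space:]]+")[[1]]) > kmax) next
    if (grepl(paste0("\\b", .nc_rx_escape(sf), "\\b"), lf)) next
    pairs[[length(pairs) + 1L]] <- list(sf = sf, lf = lf, def_end = ends[k])
  }
  if (length(pairs) == 0L) return(text)

  for (p in pairs) {
    head_txt <- substring(text, 1L, p$def_end)
    tail_txt <- substring(text, p$def_end + 1L)
    # free-standing occurrences only: not already inside "( ... )"
    rx <- paste0("(?<!\\()\\b", .nc_rx_escape(p$sf), "\\b(?!\\))")
    tail_txt <- gsub(rx, paste0(p$lf, " (", p$sf, ")"), tail_txt, perl = TRUE)
    text <- paste0(head_txt, tail_txt)
  }
  text
}

# escape regex metacharacters in a literal string
.nc_rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
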