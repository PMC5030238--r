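#' Brain-region dictionaries
#'
#' A dictionary entry is a canonical brain-region name plus its acronyms and
#' synonyms; every surface form indexes back to the canonical entry so that
#' mentions ("SCN", "suprachiasmatic nuclei") normalize to one node name.
#' Direction-qualified regions ("anterior PVT") are separate entries from the
#' base region. Name and synonym lookup is case-insensitive; acronym lookup is
#' case-sensitive by default so that "Pa" (paraventricular nucleus) is not
#' confused with the word "pa".
#'
#' File format: tab- or pipe-delimited, three columns (canonical name,
#' comma-separated acronyms, comma-separated synonyms), \code{#} comments and
#' blank lines ignored. A lone \code{-} marks an empty column.
#'
#' @name lexicon
NULL

.nc_norm_ws <- function(x) tolower(trimws(gsub("[[:space:]]+", " ", x)))

#' Build a dictionary from entries
#'
#' @param entries data.frame with columns \code{name}, \code{acronyms},
#'   \code{synonyms} (list columns or comma-separated strings).
#' @param acronym_case_insensitive treat acronyms like names (default FALSE).
#' @return an \code{nc_dictionary}.
#' @export
nc_dictionary <- function(entries, acronym_case_insensitive = FALSE) {
  stopifnot(is.data.frame(entries), all(c("name") %in% names(entries)))
  split_field <- function(x) {
    if (is.list(x)) return(lapply(x, function(v) v[nzchar(v)]))
    if (length(x) == 0L) return(list())
    lapply(strsplit(ifelse(is.na(x) | x == "-", "", as.character(x)), ","),
           function(v) { v <- trimws(v); v[nzchar(v)] })
  }
  name <- trimws(entries$name)
  if (any(!nzchar(name))) stop("empty canonical names are not allowed")
  if (anyDuplicated(tolower(name))) {
    stop("duplicate canonical names: ",
         paste(unique(name[duplicated(tolower(name))]), collapse = ", "))
  }
  acr <- split_field(if ("acronyms" %in% names(entries)) entries$acronyms
                     else rep("", nrow(entries)))
  syn <- split_field(if ("synonyms" %in% names(entries)) entries$synonyms
                     else rep("", nrow(entries)))

  ci <- new.env(parent = emptyenv())  # case-insensitive surfaces
  cs <- new.env(parent = emptyenv())  # case-sensitive surfaces (acronyms)
  surfaces <- list()
  add <- function(env, key, canonical, surface) {
    if (!nzchar(key)) return(invisible())
    if (!is.null(env[[key]])) {
      if (!identical(env[[key]], canonical)) {
        warning("surface form '", surface, "' maps to both '", env[[key]],
                "' and '", canonical, "'; keeping the first", call. = FALSE)
      }
      return(invisible())
    }
    env[[key]] <- canonical
    surfaces[[length(surfaces) + 1L]] <<-
      list(surface = surface, canonical = canonical,
           case_sensitive = identical(env, cs))
  }
  for (i in seq_along(name)) {
    add(ci, .nc_norm_ws(name[i]), name[i], name[i])
    for (s in syn[[i]]) add(ci, .nc_norm_ws(s), name[i], s)
    for (a in acr[[i]]) {
      if (acronym_case_insensitive) add(ci, .nc_norm_ws(a), name[i], a)
      else add(cs, trimws(gsub("[[:space:]]+", " ", a)), name[i], a)
    }
  }
  surf <- if (length(surfaces)) {
    data.frame(surface = vapply(surfaces, `[[`, "", "surface"),
               canonical = vapply(surfaces, `[[`, "", "canonical"),
               case_sensitive = vapply(surfaces, `[[`, TRUE, "case_sensitive"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(surface = character(), canonical = character(),
               case_sensitive = logical(), stringsAsFactors = FALSE)
  }
  structure(list(entries = data.frame(name = name, stringsAsFactors = FALSE),
                 acronyms = acr, synonyms = syn,
                 ci = ci, cs = cs, surfaces = surf,
                 stop_words = c("of", "the", "area", "part")),
            class = "nc_dictionary")
}

#' Load a brain-region dictionary file
#'
#' @param path delimited text file (tab or pipe), columns: canonical name,
#'   acronyms, synonyms.
#' @param acronym_case_insensitive see [nc_dictionary()].
#' @return an \code{nc_dictionary}.
#' @export
load_dictionary <- function(path, acronym_case_insensitive = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(nc_dictionary(data.frame(name = character(),
                                    acronyms = character(),
                                    synonyms = character(),
                                    stringsAsFactors = FALSE)))
  }
  sep <- if (any(grepl("\t", lines))) "\t" else "|"
  parts <- strsplit(lines, sep, fixed = TRUE)
  entries <- data.frame(
    name = vapply(parts, function(p) trimws(p[1]), ""),
    acronyms = vapply(parts, function(p)
      if (length(p) >= 2) trimws(p[2]) else "", ""),
    synonyms = vapply(parts, function(p)
      if (length(p) >= 3) trimws(p[3]) else "", ""),
    stringsAsFactors = FALSE)
  nc_dictionary(entries, acronym_case_insensitive)
}

#' Write a dictionary back to its file format
#'
#' @param dict an \code{nc_dictionary}.
#' @param path output path (tab-delimited).
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "nc_dictionary"))
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "-"
  lines <- vapply(seq_len(nrow(dict$entries)), function(i) {
    paste(dict$entries$name[i], fmt(dict$acronyms[[i]]),
          fmt(dict$synonyms[[i]]), sep = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.nc_dictionary <- function(x, ...) {
  cat(sprintf("<brain-region dictionary: %d entries, %d surface forms>\n",
              nrow(x$entries), nrow(x$surfaces)))
  invisible(x)
}

# exact lookup of one string: case-sensitive acronyms first, then
# case-insensitive names/synonyms; NULL on miss
.nc_dict_lookup <- function(dict, s) {
  s <- trimws(gsub("[[:space:]]+", " ", s))
  if (!nzchar(s)) return(NULL)
  hit <- dict$cs[[s]]
  if (!is.null(hit)) return(hit)
  dict$ci[[.nc_norm_ws(s)]]
}

#' Match brain-region mentions in a candidate text
#'
#' Implements the staged dictionary-decision cascade used on each candidate
#' argument span:
#' \enumerate{
#'   \item whole-string lookup;
#'   \item split the text on the conjunctions "and"/"or" and on
#'     commas/semicolons, and look up each piece;
#'   \item (a) retry each piece after removing the stop words "of", "the",
#'     "area", "part"; (b) failing that, search every dictionary surface form
#'     (>= 3 characters, at word boundaries) as a substring of the piece, and
#'     look up each remaining token on its own.
#' }
#' Finally only the longest non-overlapping matches are kept, so "midline
#' thalamus" wins over a contained "thalamus". Matches produced by step 3b
#' cover only part of their piece and are flagged \code{kind = "partial"};
#' whole-piece lookups are \code{"full"}.
#'
#' @param candidate_text character scalar (an argument span's text).
#' @param dict an \code{nc_dictionary}.
#' @return data.frame: \code{canonical}, \code{surface}, \code{start},
#'   \code{end} (character span in \code{candidate_text}), \code{kind}
#'   ("full"/"partial"). Zero rows when nothing matches.
#' @export
match_text <- function(candidate_text, dict) {
  stopifnot(inherits(dict, "nc_dictionary"))
  empty <- data.frame(canonical = character(), surface = character(),
                      start = integer(), end = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  if (is.null(candidate_text) || is.na(candidate_text) ||
      !nzchar(trimws(candidate_text))) return(empty)
  text <- candidate_text

  row <- function(canonical, surface, start, end, kind) {
    data.frame(canonical = canonical, surface = surface,
               start = as.integer(start), end = as.integer(end), kind = kind,
               stringsAsFactors = FALSE)
  }

  # Step 1: whole string
  whole <- trimws(text)
  ws <- regexpr("[^[:space:]]", text)
  hit <- .nc_dict_lookup(dict, whole)
  if (!is.null(hit)) {
    return(row(hit, whole, ws, ws + nchar(whole) - 1L, "full"))
  }

  # Step 2: split on conjunctions / punctuation, keeping offsets
  sep_rx <- "(?i)(,|;|\\band\\b|\\bor\\b)"
  seps <- gregexpr(sep_rx, text, perl = TRUE)[[1]]
  cut_from <- 1L
  pieces <- list()
  if (seps[1] != -1L) {
    for (k in seq_along(seps)) {
      s <- as.integer(seps[k])
      pieces[[length(pieces) + 1L]] <- c(cut_from, s - 1L)
      cut_from <- s + attr(seps, "match.length")[k]
    }
  }
  pieces[[length(pieces) + 1L]] <- c(cut_from, nchar(text))

  found <- list()
  for (p in pieces) {
    if (p[2] < p[1]) next
    ptxt <- substring(text, p[1], p[2])
    lead <- regexpr("[^[:space:]]", ptxt)
    if (lead < 0) next
    trail <- nchar(ptxt) - nchar(sub("[[:space:]]+$", "", ptxt))
    pstart <- p[1] + lead - 1L
    pend <- p[2] - trail
    ptrim <- substring(text, pstart, pend)

    hit <- .nc_dict_lookup(dict, ptrim)
    if (!is.null(hit)) {
      found[[length(found) + 1L]] <- row(hit, ptrim, pstart, pend, "full")
      next
    }

    # Step 3a: drop stop words, retry
    ptoks <- nc_tokenize(ptrim)
    keep <- !(tolower(ptoks$surface) %in% dict$stop_words)
    kept <- ptoks[keep, , drop = FALSE]
    if (nrow(kept) > 0L && nrow(kept) < nrow(ptoks)) {
      joined <- paste(kept$surface, collapse = " ")
      hit <- .nc_dict_lookup(dict, joined)
      if (!is.null(hit)) {
        found[[length(found) + 1L]] <-
          row(hit, joined, pstart + kept$start[1] - 1L,
              pstart + kept$end[nrow(kept)] - 1L, "full")
        next
      }
    }

    # Step 3b-i: dictionary surface forms as substrings of the piece
    surf <- dict$surfaces
    for (si in seq_len(nrow(surf))) {
      sform <- surf$surface[si]
      if (nchar(sform) < 3L) next
      rx <- paste0(if (surf$case_sensitive[si]) "" else "(?i)",
                   "\\b", .nc_rx_escape(sform), "\\b")
      mm <- gregexpr(rx, ptrim, perl = TRUE)[[1]]
      if (mm[1] == -1L) next
      for (q in seq_along(mm)) {
        st <- pstart + as.integer(mm[q]) - 1L
        en <- st + attr(mm, "match.length")[q] - 1L
        found[[length(found) + 1L]] <-
          row(surf$canonical[si], substring(text, st, en), st, en, "partial")
      }
    }

    # Step 3b-ii: token-by-token lookup
    for (ti in seq_len(nrow(kept))) {
      tk <- kept$surface[ti]
      hit <- .nc_dict_lookup(dict, tk)
      if (!is.null(hit)) {
        found[[length(found) + 1L]] <-
          row(hit, tk, pstart + kept$start[ti] - 1L,
              pstart + kept$end[ti] - 1L, "partial")
      }
    }
  }
  if (length(found) == 0L) return(empty)
  out <- do.call(rbind, found)
  out <- out[!duplicated(out[, c("canonical", "start", "end")]), ,
             drop = FALSE]
  # longest-match selection over overlapping spans
  out <- out[order(-(out$end - out$start), out$start), , drop = FALSE]
  taken <- logical(nchar(text))
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    span <- seq.int(out$start[i], out$end[i])
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare an extracted region string with a gold mention
#'
#' @param extracted the extracted (matched) surface string.
#' @param gold_mention the annotated mention string.
#' @return "full" on case/whitespace-insensitive equality, "partial" when the
#'   extracted string is a proper word-boundary substring of the gold mention,
#'   "miss" otherwise.
#' @export
classify_against_gold <- function(extracted, gold_mention) {
  stopifnot(nzchar(extracted), nzchar(gold_mention))
  e <- .nc_norm_ws(extracted)
  g <- .nc_norm_ws(gold_mention)
  if (identical(e, g)) return("full")
  if (grepl(paste0("\\b", .nc_rx_escape(e), "\\b"), g, perl = TRUE)) {
    return("partial")
  }
  "miss"
}
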