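#' Parse-tree abstractions and argument-identification rules
#'
#' The extractor consumes two syntactic views of a sentence: a bracketed
#' constituency tree (used to grab the first noun phrase after a trigger
#' pattern) and typed dependency edges in the collapsed-preposition scheme
#' (\code{nsubj}, \code{dobj}, \code{nn}, \code{vmod}, \code{prep_into}, ...)
#' used to locate the second, possibly long-distance argument. Both can be
#' loaded from fixture files or produced by any parser through
#' [map_dependency_labels()]; all rules run parser-free on these internal
#' types.
#'
#' @name syntax
NULL

# ---- constituency trees ----------------------------------------------------

#' Parse a bracketed constituency tree
#'
#' Reads standard Penn-style bracketed notation, e.g.
#' \code{"(S (NP (DT The) (NN nucleus)) (VP (VBZ projects) ...))"}.
#' Leaves are numbered 1..n left to right (punctuation included), aligning
#' with dependency-triple token positions.
#'
#' @param text bracketed tree as a single string.
#' @return an \code{nc_ctree}: nested list of nodes
#'   \code{list(label, children)}; terminals are \code{list(surface, pos)}.
#' @export
parse_bracketed_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  if (length(toks) == 0L) stop("empty tree text")
  pos_counter <- new.env(parent = emptyenv())
  pos_counter$n <- 0L
  i <- 1L
  parse_node <- function() {
    if (toks[i] != "(") stop("malformed tree near token ", i, ": '",
                             toks[i], "'")
    i <<- i + 1L
    label <- toks[i]
    if (label %in% c("(", ")")) stop("missing node label at token ", i)
    i <<- i + 1L
    children <- list()
    while (i <= length(toks) && toks[i] != ")") {
      if (toks[i] == "(") {
        children[[length(children) + 1L]] <- parse_node()
      } else {
        pos_counter$n <- pos_counter$n + 1L
        children[[length(children) + 1L]] <-
          structure(list(surface = toks[i], pos = pos_counter$n),
                    class = "nc_ctree_leaf")
        i <<- i + 1L
      }
    }
    if (i > length(toks)) stop("unbalanced parentheses in tree")
    i <<- i + 1L
    structure(list(label = label, children = children),
              class = "nc_ctree_node")
  }
  root <- parse_node()
  if (i <= length(toks)) stop("trailing text after tree")
  structure(list(root = root, n_leaves = pos_counter$n), class = "nc_ctree")
}

#' @export
print.nc_ctree <- function(x, ...) {
  lv <- tree_leaves(x$root)
  cat(sprintf("<constituency tree: %d leaves> %s\n", x$n_leaves,
              paste(lv$surface, collapse = " ")))
  invisible(x)
}

#' Collect the leaves under a tree node
#'
#' @param node an \code{nc_ctree_node} (or \code{nc_ctree}).
#' @return data.frame \code{surface}, \code{pos}, in left-to-right order.
#' @export
tree_leaves <- function(node) {
  if (inherits(node, "nc_ctree")) node <- node$root
  out <- list()
  walk <- function(n) {
    if (inherits(n, "nc_ctree_leaf")) {
      out[[length(out) + 1L]] <<- n
    } else {
      for (ch in n$children) walk(ch)
    }
  }
  walk(node)
  data.frame(surface = vapply(out, `[[`, "", "surface"),
             pos = vapply(out, `[[`, 1L, "pos"),
             stringsAsFactors = FALSE)
}

# pre-order list of internal nodes (top-down, left-to-right)
.nc_preorder_nodes <- function(tree) {
  out <- list()
  walk <- function(n) {
    if (inherits(n, "nc_ctree_leaf")) return(invisible())
    out[[length(out) + 1L]] <<- n
    for (ch in n$children) walk(ch)
  }
  walk(if (inherits(tree, "nc_ctree")) tree$root else tree)
  out
}

.nc_empty_span <- function() {
  data.frame(surface = character(), pos = integer(), stringsAsFactors = FALSE)
}

#' First noun phrase after a pattern match
#'
#' Walks the tree in pre-order (top-down, left-to-right, i.e. the order of
#' the bracketed notation) and returns the leaves under the first NP node
#' whose first leaf lies strictly after the last token of the pattern match.
#' Pre-order finds the outermost such NP, so "Pa in rats" is returned whole
#' rather than the inner "Pa".
#'
#' @param tree an \code{nc_ctree}.
#' @param pattern_match one row of [find_pattern_matches()] output (uses
#'   \code{last_tok}), or an integer token position.
#' @return candidate span data.frame (\code{surface}, \code{pos});
#'   zero rows when no NP follows the pattern.
#' @export
first_np_after <- function(tree, pattern_match) {
  after <- if (is.numeric(pattern_match)) as.integer(pattern_match)
           else as.integer(pattern_match$last_tok)
  for (node in .nc_preorder_nodes(tree)) {
    if (!grepl("^NP", node$label)) next
    lv <- tree_leaves(node)
    if (nrow(lv) > 0L && lv$pos[1] > after) return(lv)
  }
  .nc_empty_span()
}

#' Extend an NP span with a following "including" PP
#'
#' If the prepositional phrase immediately following the NP (by surface
#' adjacency: its first leaf is the token right after the NP's last leaf)
#' contains the keyword "including", its leaves are appended to the span;
#' otherwise the span is returned unchanged. This picks up enumerations such
#' as "limbic structures including the amygdala and hippocampus".
#'
#' @param tree an \code{nc_ctree}.
#' @param np_span span returned by [first_np_after()].
#' @return possibly extended span.
#' @export
extend_with_including_pp <- function(tree, np_span) {
  if (nrow(np_span) == 0L) return(np_span)
  last <- max(np_span$pos)
  for (node in .nc_preorder_nodes(tree)) {
    if (!grepl("^PP", node$label)) next
    lv <- tree_leaves(node)
    if (nrow(lv) == 0L || lv$pos[1] != last + 1L) next
    if (!any(tolower(lv$surface) == "including")) next
    out <- rbind(np_span, lv)
    out <- out[!duplicated(out$pos), , drop = FALSE]
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  np_span
}

# ---- dependency edges ------------------------------------------------------

.nc_empty_edges <- function() {
  data.frame(label = character(), gov = character(), gov_pos = integer(),
             dep = character(), dep_pos = integer(), stringsAsFactors = FALSE)
}

#' Parse typed dependency triples
#'
#' One triple per line in the printed textual format
#' \code{label(governor-pos1, dependent-pos2)}, e.g.
#' \code{nsubj(projects-17, subnucleus-16)} or
#' \code{prep_into(injection-4, thalamus-9)}. Blank lines and \code{#}
#' comments are ignored.
#'
#' @param lines character vector of triple lines.
#' @return data.frame \code{label}, \code{gov}, \code{gov_pos}, \code{dep},
#'   \code{dep_pos}.
#' @export
parse_dependency_triples <- function(lines) {
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  if (length(lines) == 0L) return(.nc_empty_edges())
  rx <- "^[[:space:]]*([A-Za-z_:]+)\\((.*?)-([0-9]+)['′]?,[[:space:]]*(.*?)-([0-9]+)['′]?\\)[[:space:]]*$"
  bad <- !grepl(rx, lines, perl = TRUE)
  if (any(bad)) {
    stop("malformed dependency triple: '", lines[which(bad)[1]], "'")
  }
  data.frame(
    label = sub(rx, "\\1", lines, perl = TRUE),
    gov = sub(rx, "\\2", lines, perl = TRUE),
    gov_pos = as.integer(sub(rx, "\\3", lines, perl = TRUE)),
    dep = sub(rx, "\\4", lines, perl = TRUE),
    dep_pos = as.integer(sub(rx, "\\5", lines, perl = TRUE)),
    stringsAsFactors = FALSE)
}

#' Map provider dependency labels to the internal label set
#'
#' Modern parsers emit Universal Dependencies labels; the rules here use the
#' older collapsed Stanford-typed scheme. This maps \code{obj} to
#' \code{dobj}, \code{compound} to \code{nn}, \code{acl}/\code{acl:relcl} to
#' \code{vmod}, \code{nsubj:pass} to \code{nsubjpass}, and synthesizes
#' collapsed prepositions: an \code{nmod}/\code{obl} edge whose dependent
#' governs a \code{case} edge with surface "into" becomes \code{prep_into}.
#' Unmapped labels pass through unchanged (and are ignored by the rules).
#'
#' @param edges data.frame of edges as from [parse_dependency_triples()].
#' @return edges with internal labels.
#' @export
map_dependency_labels <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  map <- c(obj = "dobj", compound = "nn", acl = "vmod",
           "acl:relcl" = "vmod", "nsubj:pass" = "nsubjpass",
           "csubj:pass" = "csubjpass")
  lab <- edges$label
  mapped <- unname(map[lab])
  lab[!is.na(mapped)] <- mapped[!is.na(mapped)]
  base <- sub(":.*$", "", lab)
  sub_t <- ifelse(grepl(":", lab), sub("^[^:]+:", "", lab), NA_character_)
  for (i in seq_len(nrow(edges))) {
    if (!base[i] %in% c("nmod", "obl")) next
    if (!is.na(sub_t[i]) && !sub_t[i] %in% c("npmod", "tmod", "poss")) {
      lab[i] <- paste0("prep_", sub_t[i])
      next
    }
    case <- which(edges$label == "case" & edges$gov_pos == edges$dep_pos[i])
    if (length(case) > 0L) {
      lab[i] <- paste0("prep_", tolower(edges$dep[case[1]]))
    }
  }
  edges$label <- lab
  edges
}

# tokens (surface,pos) referenced by a set of edge endpoints
.nc_edge_tokens <- function(edges) {
  data.frame(surface = c(edges$gov, edges$dep),
             pos = c(edges$gov_pos, edges$dep_pos),
             stringsAsFactors = FALSE)
}

.nc_span_from_pos <- function(edges, pos) {
  pos <- sort(unique(pos))
  if (length(pos) == 0L) return(.nc_empty_span())
  toks <- .nc_edge_tokens(edges)
  toks <- toks[!duplicated(toks$pos), , drop = FALSE]
  out <- toks[match(pos, toks$pos), , drop = FALSE]
  out$pos <- pos
  rownames(out) <- NULL
  out
}

#' Subject-group rule (nsubj / nsubjpass / xsubj / nn)
#'
#' When the pattern keyword takes part in a subject or noun-compound
#' relation: with the keyword as governor, the relation's dependent is the
#' candidate head and every word it governs (determiners, adjectival and
#' noun-compound modifiers) is pulled in; with the keyword as dependent, the
#' prepositional dependent of the keyword's governor is the candidate head,
#' extended with its \code{amod}/\code{nn} modifiers.
#'
#' @param edges dependency edges.
#' @param keyword_pos token position of the pattern keyword.
#' @return candidate span sorted by position (zero rows when the rule does
#'   not fire).
#' @export
rule_subject_group <- function(edges, keyword_pos) {
  labs <- c("nsubj", "nsubjpass", "xsubj", "nn")
  hits <- edges[edges$label %in% labs &
                  (edges$gov_pos == keyword_pos |
                     edges$dep_pos == keyword_pos), , drop = FALSE]
  if (nrow(hits) == 0L) return(.nc_empty_span())
  pos <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (hits$gov_pos[i] == keyword_pos) {
      head_pos <- hits$dep_pos[i]
      pos <- c(pos, head_pos,
               edges$dep_pos[edges$gov_pos == head_pos])
    } else {
      gov_pos <- hits$gov_pos[i]
      preps <- edges[grepl("^prep", edges$label) &
                       edges$gov_pos == gov_pos, , drop = FALSE]
      for (j in seq_len(nrow(preps))) {
        d <- preps$dep_pos[j]
        pos <- c(pos, d,
                 edges$dep_pos[edges$label %in% c("amod", "nn") &
                                 edges$gov_pos == d])
      }
    }
  }
  pos <- setdiff(pos, keyword_pos)
  .nc_span_from_pos(edges, pos)
}

#' Direct-object rule (pattern keyword in dobj, subject via sibling nsubj)
#'
#' When the keyword is the dependent of a \code{dobj} edge, the verb
#' governing it is searched as the governor of an \code{nsubj} edge (which
#' need not involve the keyword). The nominal subject is the candidate head;
#' its \code{amod}/\code{nn}/\code{prep} dependents are added, and for each
#' word reached through a \code{prep} edge its own \code{amod}/\code{nn}
#' modifiers as well (one further level).
#'
#' @inheritParams rule_subject_group
#' @return candidate span sorted by position.
#' @export
rule_dobj_nsubj <- function(edges, keyword_pos) {
  dobj <- edges[edges$label == "dobj" & edges$dep_pos == keyword_pos, ,
                drop = FALSE]
  if (nrow(dobj) == 0L) return(.nc_empty_span())
  pos <- integer(0)
  for (i in seq_len(nrow(dobj))) {
    verb <- dobj$gov_pos[i]
    subj <- edges[edges$label == "nsubj" & edges$gov_pos == verb, ,
                  drop = FALSE]
    for (j in seq_len(nrow(subj))) {
      s <- subj$dep_pos[j]
      pos <- c(pos, s)
      mods <- edges[(edges$label %in% c("amod", "nn") |
                       grepl("^prep", edges$label)) &
                      edges$gov_pos == s, , drop = FALSE]
      pos <- c(pos, mods$dep_pos)
      prep_deps <- mods$dep_pos[grepl("^prep", mods$label)]
      for (d in prep_deps) {
        pos <- c(pos, edges$dep_pos[edges$label %in% c("amod", "nn") &
                                      edges$gov_pos == d])
      }
    }
  }
  pos <- setdiff(pos, keyword_pos)
  .nc_span_from_pos(edges, pos)
}

#' Verbal-modifier rule (pattern keyword as vmod dependent)
#'
#' When the keyword is the dependent of a reduced non-finite verbal modifier
#' ("orexin neurons projecting to ..."), the modified noun (the \code{vmod}
#' governor) is the candidate head, extended with its \code{amod}/\code{nn}
#' modifiers.
#'
#' @inheritParams rule_subject_group
#' @return candidate span sorted by position.
#' @export
rule_vmod <- function(edges, keyword_pos) {
  vm <- edges[edges$label == "vmod" & edges$dep_pos == keyword_pos, ,
              drop = FALSE]
  if (nrow(vm) == 0L) return(.nc_empty_span())
  pos <- integer(0)
  for (i in seq_len(nrow(vm))) {
    g <- vm$gov_pos[i]
    pos <- c(pos, g,
             edges$dep_pos[edges$label %in% c("amod", "nn") &
                             edges$gov_pos == g])
  }
  pos <- setdiff(pos, keyword_pos)
  .nc_span_from_pos(edges, pos)
}

#' Second (dependency-derived) argument of a pattern
#'
#' Dispatches the three rule groups in their presentation order --
#' subject group, then the dobj/nsubj special case, then the vmod rule --
#' and returns the first non-empty candidate span.
#'
#' @inheritParams rule_subject_group
#' @return candidate span sorted by position; zero rows when no rule fires.
#' @export
second_dependent <- function(edges, keyword_pos) {
  for (rule in list(rule_subject_group, rule_dobj_nsubj, rule_vmod)) {
    span <- rule(edges, keyword_pos)
    if (nrow(span) > 0L) return(span)
  }
  .nc_empty_span()
}

# is the keyword part of a passive construction?
.nc_is_passive <- function(edges, keyword_pos) {
  any(edges$label == "nsubjpass" &
        (edges$gov_pos == keyword_pos | edges$dep_pos == keyword_pos))
}
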