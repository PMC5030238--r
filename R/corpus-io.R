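#' Gold corpus container
#'
#' Holds an interaction-annotated corpus: sentences, entity mentions and
#' pairwise interaction annotations, as read from the unified interaction XML
#' dialect (\code{<entity id text/>}, \code{<pair e1 e2 interaction/>}).
#' Pairs with \code{interaction="True"} are the gold relations; an optional
#' \code{direction} attribute ("e1_to_e2"/"e2_to_e1") carries gold
#' directionality where annotated.
#'
#' @param sentences data.frame: \code{id}, \code{doc_id}, \code{index},
#'   \code{text}.
#' @param entities data.frame: \code{id}, \code{sentence_id}, \code{text}.
#' @param pairs data.frame: \code{sentence_id}, \code{e1}, \code{e2},
#'   \code{interaction} (logical), \code{direction} (character, NA allowed).
#' @return an \code{nc_gold_corpus}.
#' @export
nc_gold_corpus <- function(sentences, entities, pairs) {
  stopifnot(is.data.frame(sentences), is.data.frame(entities),
            is.data.frame(pairs))
  if (nrow(pairs) > 0L) {
    missing <- setdiff(c(pairs$e1, pairs$e2), entities$id)
    if (length(missing) > 0L) {
      stop("pair references undeclared entity id(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  structure(list(sentences = sentences, entities = entities, pairs = pairs),
            class = "nc_gold_corpus")
}

#' @export
print.nc_gold_corpus <- function(x, ...) {
  cat(sprintf(
    "<gold corpus: %d sentences, %d entities, %d pairs (%d interactions)>\n",
    nrow(x$sentences), nrow(x$entities), nrow(x$pairs),
    sum(x$pairs$interaction)))
  invisible(x)
}

#' Number of gold (interaction = TRUE) relations
#' @param gold an \code{nc_gold_corpus}.
#' @export
n_gold_relations <- function(gold) sum(gold$pairs$interaction)

.nc_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  ifelse(is.na(v), NA_character_, v)
}

#' Read an interaction-annotated corpus (unified interaction XML)
#'
#' Accepts the dialect with \code{corpus/document/sentence} nesting; entities
#' and pairs may also sit directly under a document, in which case the
#' sentence id is recovered from the entity id prefix
#' (\code{"....s0.e0"} belongs to sentence \code{"....s0"}). Only attributes
#' \code{id}, \code{text}, \code{interaction}, \code{e1}, \code{e2} (and the
#' optional \code{direction}) are interpreted; unknown attributes are
#' ignored. Malformed XML propagates the parser error (which names the
#' offending line); a pair referencing an undeclared entity is a validation
#' error.
#'
#' @param path XML file path.
#' @return an \code{nc_gold_corpus}.
#' @export
read_interaction_xml <- function(path) {
  doc <- xml2::read_xml(path)
  sent_nodes <- xml2::xml_find_all(doc, ".//sentence")
  sentences <- data.frame(id = character(), doc_id = character(),
                          index = integer(), text = character(),
                          stringsAsFactors = FALSE)
  if (length(sent_nodes) > 0L) {
    ids <- xml2::xml_attr(sent_nodes, "id")
    docs <- vapply(sent_nodes, function(s) {
      p <- xml2::xml_parent(s)
      if (identical(xml2::xml_name(p), "document")) {
        a <- xml2::xml_attr(p, "id")
        if (!is.na(a)) return(a)
      }
      sub("\\.s[0-9]+$", "", xml2::xml_attr(s, "id"))
    }, "")
    sentences <- data.frame(
      id = ids, doc_id = docs,
      index = as.integer(sub("^.*\\.s([0-9]+)$", "\\1", ids)),
      text = xml2::xml_attr(sent_nodes, "text"),
      stringsAsFactors = FALSE)
  }
  ent_nodes <- xml2::xml_find_all(doc, ".//entity")
  sent_of <- function(nodes) {
    vapply(nodes, function(n) {
      p <- xml2::xml_parent(n)
      if (identical(xml2::xml_name(p), "sentence")) {
        a <- xml2::xml_attr(p, "id")
        if (!is.na(a)) return(a)
      }
      sub("\\.[ep][0-9]+$", "", xml2::xml_attr(n, "id"))
    }, "")
  }
  entities <- if (length(ent_nodes) > 0L) {
    data.frame(id = xml2::xml_attr(ent_nodes, "id"),
               sentence_id = sent_of(ent_nodes),
               text = xml2::xml_attr(ent_nodes, "text"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(), sentence_id = character(),
               text = character(), stringsAsFactors = FALSE)
  }
  pair_nodes <- xml2::xml_find_all(doc, ".//pair")
  pairs <- if (length(pair_nodes) > 0L) {
    e1 <- xml2::xml_attr(pair_nodes, "e1")
    data.frame(
      sentence_id = sub("\\.e[0-9]+$", "", e1),
      e1 = e1,
      e2 = xml2::xml_attr(pair_nodes, "e2"),
      interaction = tolower(xml2::xml_attr(pair_nodes, "interaction")) ==
        "true",
      direction = vapply(pair_nodes, .nc_attr, "", name = "direction"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(sentence_id = character(), e1 = character(),
               e2 = character(), interaction = logical(),
               direction = character(), stringsAsFactors = FALSE)
  }
  nc_gold_corpus(sentences, entities, pairs)
}

#' Write a gold corpus in the unified interaction XML dialect
#'
#' Round-trips with [read_interaction_xml()].
#'
#' @param gold an \code{nc_gold_corpus}.
#' @param path output path.
#' @export
write_interaction_xml <- function(gold, path) {
  stopifnot(inherits(gold, "nc_gold_corpus"))
  root <- xml2::xml_new_root("corpus", source = "neuroconn")
  for (d in unique(gold$sentences$doc_id)) {
    dnode <- xml2::xml_add_child(root, "document", id = d)
    srows <- gold$sentences[gold$sentences$doc_id == d, , drop = FALSE]
    srows <- srows[order(srows$index), , drop = FALSE]
    for (i in seq_len(nrow(srows))) {
      snode <- xml2::xml_add_child(dnode, "sentence",
                                   id = srows$id[i], text = srows$text[i])
      erows <- gold$entities[gold$entities$sentence_id == srows$id[i], ,
                             drop = FALSE]
      for (j in seq_len(nrow(erows))) {
        xml2::xml_add_child(snode, "entity", id = erows$id[j],
                            text = erows$text[j])
      }
      prows <- gold$pairs[gold$pairs$sentence_id == srows$id[i], ,
                          drop = FALSE]
      for (j in seq_len(nrow(prows))) {
        pn <- xml2::xml_add_child(
          snode, "pair", e1 = prows$e1[j], e2 = prows$e2[j],
          interaction = if (prows$interaction[j]) "True" else "False")
        if (!is.na(prows$direction[j]) && nzchar(prows$direction[j])) {
          xml2::xml_set_attr(pn, "direction", prows$direction[j])
        }
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read dependency triples from a .deps file
#' @param path file with one \code{label(gov-i, dep-j)} triple per line.
#' @return edge data.frame (see [parse_dependency_triples()]).
#' @export
read_dependency_triples <- function(path) {
  parse_dependency_triples(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Read a bracketed constituency tree from a .ptb file
#' @param path file holding one bracketed tree (may span lines).
#' @return an \code{nc_ctree} (see [parse_bracketed_tree()]).
#' @export
read_bracketed_tree <- function(path) {
  parse_bracketed_tree(
    paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = " "))
}
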