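#' End-to-end pipeline and command-line interface
#'
#' [run_pipeline()] ties the stages together: sentence splitting (optionally
#' preceded by abbreviation expansion), pattern-based candidate selection,
#' parse loading, argument identification, dictionary decision, direction
#' assignment, deduplication, and output writing. All randomness lives in
#' the fixture generator; extraction itself is deterministic given parses.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param docs directory of plain-text documents (one per file) or a list of
#'   [nc_document()] objects.
#' @param dictionary dictionary file path or an \code{nc_dictionary}.
#' @param parses directory with \code{<doc>.s<idx>.ptb} / \code{.deps}
#'   files, or a named parse list as produced by
#'   [generate_fixture_corpus()].
#' @param patterns optional pattern config data.frame (see
#'   [compile_patterns()]).
#' @param expand_abbreviations run Schwartz-Hearst expansion before sentence
#'   splitting.
#' @param dedup "document" (default) or "sentence": granularity of the
#'   relations table written out.
#' @param out_dir output directory (created); NULL suppresses writing.
#' @param gold optional gold corpus (path or object) to score against.
#' @param eval_mode evaluation mode when \code{gold} is given.
#' @param verbose log per-stage counts.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(docs, dictionary, parses = NULL, patterns = NULL,
                            expand_abbreviations = TRUE,
                            dedup = c("document", "sentence"),
                            out_dir = NULL, gold = NULL,
                            eval_mode = "lenient", verbose = TRUE) {
  dedup <- match.arg(dedup)
  if (is.null(dictionary)) stop("a dictionary is required")
  structure(list(docs = docs, dictionary = dictionary, parses = parses,
                 patterns = patterns,
                 expand_abbreviations = expand_abbreviations,
                 dedup = dedup, out_dir = out_dir, gold = gold,
                 eval_mode = eval_mode, verbose = verbose),
            class = "pipeline_config")
}

.nc_load_docs <- function(docs, expand) {
  if (is.character(docs) && length(docs) == 1L && dir.exists(docs)) {
    files <- sort(list.files(docs, pattern = "\\.txt$", full.names = TRUE))
    return(lapply(files, function(f) {
      nc_document(tools::file_path_sans_ext(basename(f)),
                  paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                        collapse = " "),
                  expand = expand)
    }))
  }
  lapply(.nc_as_doclist(docs), function(d) {
    if (expand) nc_document(d$doc_id, d$text, expand = TRUE) else d
  })
}

.nc_as_doclist <- function(docs) {
  if (inherits(docs, "nc_document")) return(list(docs))
  stopifnot(is.list(docs))
  docs
}

.nc_load_parses <- function(parses) {
  if (is.character(parses) && length(parses) == 1L && dir.exists(parses)) {
    ptb <- list.files(parses, pattern = "\\.ptb$", full.names = TRUE)
    keys <- tools::file_path_sans_ext(basename(ptb))
    out <- stats::setNames(lapply(seq_along(ptb), function(i) {
      dep_file <- file.path(parses, paste0(keys[i], ".deps"))
      list(tree = read_bracketed_tree(ptb[i]),
           deps = if (file.exists(dep_file)) {
             read_dependency_triples(dep_file)
           } else NULL)
    }), keys)
    return(out)
  }
  parses
}

#' Run the extraction pipeline
#'
#' @param config a [pipeline_config()].
#' @return list with \code{relations} (sentence-level), \code{deduped},
#'   \code{graph}, and \code{evaluation} (NULL without gold); side effect:
#'   writes \code{relations.tsv}, \code{graph.graphml} and
#'   \code{metrics.json} under \code{out_dir} when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(...) if (config$verbose) message("[neuroconn] ", ...)

  dict <- config$dictionary
  if (is.character(dict)) dict <- load_dictionary(dict)
  patterns <- if (is.null(config$patterns)) compile_patterns()
              else compile_patterns(config$patterns)

  docs <- .nc_load_docs(config$docs, config$expand_abbreviations)
  log("documents: ", length(docs))
  parses <- .nc_load_parses(config$parses)

  relations <- extract_corpus(docs, parses, dict, patterns,
                              verbose = config$verbose)
  deduped <- dedup_document(relations)
  log("relations: ", nrow(relations), " (", nrow(deduped),
      " unique per document)")
  graph <- build_graph(relations)

  evaluation <- NULL
  if (!is.null(config$gold)) {
    gold <- config$gold
    if (is.character(gold)) gold <- read_interaction_xml(gold)
    evaluation <- score(relations, gold, mode = config$eval_mode)
    log(sprintf("%s: P=%.2f R=%.2f F=%.2f", config$eval_mode,
                evaluation$precision, evaluation$recall, evaluation$f))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out_rel <- if (config$dedup == "document") deduped else relations
    write_relations_tsv(out_rel, file.path(config$out_dir, "relations.tsv"))
    export_graph(graph, file.path(config$out_dir, "graph.graphml"),
                 format = "graphml")
    if (!is.null(evaluation)) {
      jsonlite::write_json(
        evaluation[c("tp", "fp", "fn", "precision", "recall", "f", "mode")],
        file.path(config$out_dir, "metrics.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }
  list(relations = relations, deduped = deduped, graph = graph,
       evaluation = evaluation)
}

# ---- minimal CLI (subcommands: fixtures, extract, evaluate, graph,
#      patterns) -------------------------------------------------------------

.nc_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        out[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      out[["_positional"]] <- c(out[["_positional"]], a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: \code{fixtures --out DIR [--seed N] [--n-docs N]};
#' \code{extract --docs DIR --dict FILE --parses DIR --out DIR};
#' \code{evaluate --pred relations.tsv --gold gold.xml [--mode strict]};
#' \code{graph --relations relations.tsv --out FILE [--format graphml]};
#' \code{patterns} (dump the active pattern table).
#'
#' @param args character vector (defaults to \code{commandArgs(TRUE)}).
#' @return exit status (0 on success), invisibly.
#' @export
nc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: neuroconn <fixtures|extract|evaluate|graph|patterns> ...\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- .nc_cli_args(args[-1])
  switch(
    cmd,
    fixtures = {
      spec <- fixture_spec(
        n_docs = as.integer(opt[["n-docs"]] %||% 10L),
        seed = as.integer(opt[["seed"]] %||% 1L))
      fx <- generate_fixture_corpus(spec)
      write_fixture_corpus(fx, opt[["out"]] %||% "fixture")
      cat("wrote fixture corpus to ", opt[["out"]] %||% "fixture", "\n",
          sep = "")
    },
    extract = {
      cfg <- pipeline_config(
        docs = opt[["docs"]], dictionary = opt[["dict"]],
        parses = opt[["parses"]], out_dir = opt[["out"]] %||% "out",
        expand_abbreviations = !isTRUE(opt[["no-expand"]]))
      run_pipeline(cfg)
    },
    evaluate = {
      pred <- read_relations_tsv(opt[["pred"]])
      gold <- read_interaction_xml(opt[["gold"]])
      res <- score(pred, gold, mode = opt[["mode"]] %||% "strict")
      print(res)
    },
    graph = {
      rel <- read_relations_tsv(opt[["relations"]])
      g <- build_graph(rel)
      export_graph(g, opt[["out"]] %||% "graph.graphml",
                   format = opt[["format"]] %||% "graphml")
    },
    patterns = {
      print(compile_patterns())
    },
    {
      cat("unknown subcommand: ", cmd, "\n", sep = "")
      return(invisible(1L))
    })
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
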