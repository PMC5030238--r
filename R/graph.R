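#' Literature-mined connectivity graphs
#'
#' Extracted relations are assembled into a directed multigraph: brain
#' regions are nodes and every extracted connectivity mention adds one
#' directed edge from agent to target, attributed with its document,
#' sentence and pattern provenance. Node size (mention degree) is the number
#' of incident edges; edge betweenness -- the number of all-pairs shortest
#' paths running along an edge -- highlights bridging connections. Following
#' the Girvan-Newman convention, betweenness is computed on the collapsed
#' simple undirected graph while the stored graph stays a directed
#' multigraph.
#'
#' @name connectivity-graph
NULL

#' Build the connectivity multigraph
#'
#' @param relations relations data.frame with canonical \code{agent} /
#'   \code{target} names, one row per extracted mention (sentence-level,
#'   pre-deduplication: parallel edges encode repeated mentions).
#' @return an \code{nc_graph}: an \code{igraph} directed multigraph with
#'   node attribute \code{mention_degree} and edge attributes \code{doc_id},
#'   \code{sentence_index}, \code{pattern}.
#' @export
build_graph <- function(relations) {
  if (nrow(relations) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    edges <- data.frame(from = relations$agent, to = relations$target,
                        stringsAsFactors = FALSE)
    if ("doc_id" %in% names(relations)) edges$doc_id <- relations$doc_id
    if ("sentence_index" %in% names(relations)) {
      edges$sentence_index <- relations$sentence_index
    }
    if ("pattern" %in% names(relations)) edges$pattern <- relations$pattern
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  }
  igraph::V(g)$mention_degree <- igraph::degree(g, mode = "all")
  class(g) <- c("nc_graph", class(g))
  g
}

#' Edge betweenness of the connectivity graph
#'
#' Parallel edges are collapsed for path finding; the score is attributed to
#' the collapsed region pair. By default shortest paths are counted between
#' unordered node pairs on the undirected view of the graph (the
#' Girvan-Newman convention); \code{directed = TRUE} counts ordered pairs on
#' the directed collapsed graph instead. Equal-length shortest paths split
#' the count fractionally.
#'
#' @param graph an \code{nc_graph} (or any igraph).
#' @param directed count ordered pairs on the directed graph.
#' @return data.frame \code{from}, \code{to}, \code{betweenness}, one row
#'   per collapsed edge.
#' @export
edge_betweenness_scores <- function(graph, directed = FALSE) {
  simple <- igraph::simplify(
    if (directed) graph else igraph::as_undirected(graph, mode = "collapse"),
    remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(simple) == 0L) {
    return(data.frame(from = character(), to = character(),
                      betweenness = numeric(), stringsAsFactors = FALSE))
  }
  eb <- igraph::edge_betweenness(simple, directed = directed)
  ends <- igraph::ends(simple, igraph::E(simple))
  data.frame(from = ends[, 1], to = ends[, 2], betweenness = eb,
             stringsAsFactors = FALSE)
}

#' Region degree table (agent / target mention counts)
#'
#' @param graph an \code{nc_graph}.
#' @param k number of rows (regions) to return; ties broken alphabetically.
#' @return data.frame \code{region}, \code{agent} (out-mentions),
#'   \code{target} (in-mentions), \code{total}, sorted by total descending.
#' @export
top_regions <- function(graph, k = 5L) {
  if (k <= 0L || igraph::vcount(graph) == 0L) {
    return(data.frame(region = character(), agent = integer(),
                      target = integer(), total = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    region = igraph::V(graph)$name,
    agent = as.integer(igraph::degree(graph, mode = "out")),
    target = as.integer(igraph::degree(graph, mode = "in")),
    stringsAsFactors = FALSE)
  out$total <- out$agent + out$target
  out <- out[order(-out$total, out$region), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Most frequently mentioned directed relations
#'
#' @param graph an \code{nc_graph}.
#' @param k number of rows; ties broken alphabetically by agent then target.
#' @return data.frame \code{agent}, \code{target}, \code{n_mentions}.
#' @export
top_relations <- function(graph, k = 5L) {
  if (k <= 0L || igraph::ecount(graph) == 0L) {
    return(data.frame(agent = character(), target = character(),
                      n_mentions = integer(), stringsAsFactors = FALSE))
  }
  ends <- igraph::ends(graph, igraph::E(graph))
  key <- paste(ends[, 1], ends[, 2], sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(agent = vapply(parts, `[`, "", 1),
                    target = vapply(parts, `[`, "", 2),
                    n_mentions = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_mentions, out$agent, out$target), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

# quartile color bins (rendering convention for exported graphs)
.nc_color_bins <- function(x) {
  cols <- c("green", "yellow", "orange", "red")
  if (length(x) == 0L) return(character(0))
  qs <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), na.rm = TRUE,
                        names = FALSE, type = 7)
  cols[findInterval(x, qs, left.open = TRUE) + 1L]
}

#' Export the connectivity graph
#'
#' Writes the directed multigraph with provenance attributes, node
#' \code{mention_degree} and, when betweenness is requested, collapsed-edge
#' \code{betweenness} scores; quartile color bins over the mapped attributes
#' are emitted as \code{color} attributes.
#'
#' @param graph an \code{nc_graph}.
#' @param path output file.
#' @param format one of "graphml", "dot", "tsv", "json".
#' @param betweenness attach edge-betweenness scores before export.
#' @export
export_graph <- function(graph, path,
                         format = c("graphml", "dot", "tsv", "json"),
                         betweenness = TRUE) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown export format: '",
                                              format[1], "'", call. = FALSE))
  g <- graph
  igraph::V(g)$color <- .nc_color_bins(igraph::V(g)$mention_degree)
  if (betweenness && igraph::ecount(g) > 0L) {
    eb <- edge_betweenness_scores(g)
    key <- function(a, b) {
      paste(pmin(a, b), pmax(a, b), sep = "\r")
    }
    lut <- stats::setNames(eb$betweenness, key(eb$from, eb$to))
    ends <- igraph::ends(g, igraph::E(g))
    igraph::E(g)$betweenness <- unname(lut[key(ends[, 1], ends[, 2])])
    igraph::E(g)$color <- .nc_color_bins(igraph::E(g)$betweenness)
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "dot") {
    igraph::write_graph(g, path, format = "dot")
  } else if (format == "tsv") {
    ends <- igraph::ends(g, igraph::E(g))
    df <- data.frame(agent = ends[, 1], target = ends[, 2],
                     stringsAsFactors = FALSE)
    for (a in igraph::edge_attr_names(g)) {
      df[[a]] <- igraph::edge_attr(g, a)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    nodes <- data.frame(id = igraph::V(g)$name,
                        mention_degree = igraph::V(g)$mention_degree,
                        color = igraph::V(g)$color,
                        stringsAsFactors = FALSE)
    ends <- igraph::ends(g, igraph::E(g))
    links <- data.frame(source = ends[, 1], target = ends[, 2],
                        stringsAsFactors = FALSE)
    for (a in igraph::edge_attr_names(g)) {
      links[[a]] <- igraph::edge_attr(g, a)
    }
    jsonlite::write_json(list(directed = TRUE, nodes = nodes,
                              links = links),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
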