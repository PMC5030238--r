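# Independent brute-force oracles used to cross-check the implementation.
# These follow the rule/score definitions naively (explicit loops, no shared
# code with the package internals).

# ---- dependency-rule oracles -----------------------------------------------

oracle_subject_group <- function(edges, k) {
  subj <- c("nsubj", "nsubjpass", "xsubj", "nn")
  cand <- integer(0)
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (!(e$label %in% subj)) next
    if (e$gov_pos == k) {
      cand <- c(cand, e$dep_pos)
      for (j in seq_len(nrow(edges))) {
        if (edges$gov_pos[j] == e$dep_pos) cand <- c(cand, edges$dep_pos[j])
      }
    } else if (e$dep_pos == k) {
      for (j in seq_len(nrow(edges))) {
        f <- edges[j, ]
        if (startsWith(f$label, "prep") && f$gov_pos == e$gov_pos) {
          cand <- c(cand, f$dep_pos)
          for (l in seq_len(nrow(edges))) {
            g <- edges[l, ]
            if (g$label %in% c("amod", "nn") && g$gov_pos == f$dep_pos) {
              cand <- c(cand, g$dep_pos)
            }
          }
        }
      }
    }
  }
  sort(unique(setdiff(cand, k)))
}

oracle_dobj_nsubj <- function(edges, k) {
  cand <- integer(0)
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (e$label != "dobj" || e$dep_pos != k) next
    for (j in seq_len(nrow(edges))) {
      f <- edges[j, ]
      if (f$label != "nsubj" || f$gov_pos != e$gov_pos) next
      cand <- c(cand, f$dep_pos)
      for (l in seq_len(nrow(edges))) {
        g <- edges[l, ]
        if (g$gov_pos != f$dep_pos) next
        if (g$label %in% c("amod", "nn") || startsWith(g$label, "prep")) {
          cand <- c(cand, g$dep_pos)
          if (startsWith(g$label, "prep")) {
            for (q in seq_len(nrow(edges))) {
              h <- edges[q, ]
              if (h$label %in% c("amod", "nn") && h$gov_pos == g$dep_pos) {
                cand <- c(cand, h$dep_pos)
              }
            }
          }
        }
      }
    }
  }
  sort(unique(setdiff(cand, k)))
}

oracle_vmod <- function(edges, k) {
  cand <- integer(0)
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (e$label != "vmod" || e$dep_pos != k) next
    cand <- c(cand, e$gov_pos)
    for (j in seq_len(nrow(edges))) {
      f <- edges[j, ]
      if (f$label %in% c("amod", "nn") && f$gov_pos == e$gov_pos) {
        cand <- c(cand, f$dep_pos)
      }
    }
  }
  sort(unique(setdiff(cand, k)))
}

# random small dependency graph: n_edges edges over positions 1..10
random_dep_edges <- function(n_edges = 8L,
                             labels = c("nsubj", "nsubjpass", "xsubj", "nn",
                                        "dobj", "vmod", "amod", "det",
                                        "prep_to", "prep_from", "prep_into",
                                        "advmod")) {
  lab <- sample(labels, n_edges, replace = TRUE)
  gov <- sample(1:10, n_edges, replace = TRUE)
  dep <- sample(1:10, n_edges, replace = TRUE)
  data.frame(label = lab,
             gov = paste0("w", gov), gov_pos = gov,
             dep = paste0("w", dep), dep_pos = dep,
             stringsAsFactors = FALSE)
}

# ---- edge-betweenness oracle -----------------------------------------------

# brute force over all unordered node pairs of an undirected simple graph:
# enumerate every shortest path (BFS distances + backward DFS), split the
# unit of each pair fractionally across its shortest paths, and accumulate
# on the edges of each path.
oracle_edge_betweenness <- function(from, to, nodes) {
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  keys <- ekey(from, to)
  score <- stats::setNames(numeric(length(keys)), keys)
  nbrs <- stats::setNames(lapply(nodes, function(n) {
    unique(c(to[from == n], from[to == n]))
  }), nodes)
  bfs_dist <- function(src) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[src] <- 0
    queue <- src
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (w in nbrs[[cur]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[cur] + 1
          queue <- c(queue, w)
        }
      }
    }
    d
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      u <- nodes[i]; v <- nodes[j]
      d <- bfs_dist(u)
      if (is.infinite(d[v])) next
      paths <- list()
      walk <- function(cur, acc) {
        if (cur == u) {
          paths[[length(paths) + 1L]] <<- rev(acc)
          return(invisible())
        }
        for (w in nbrs[[cur]]) {
          if (d[w] == d[cur] - 1) walk(w, c(acc, w))
        }
      }
      walk(v, v)
      w <- 1 / length(paths)
      for (p in paths) {
        for (s in seq_len(length(p) - 1L)) {
          score[ekey(p[s], p[s + 1L])] <-
            score[ekey(p[s], p[s + 1L])] + w
        }
      }
    }
  }
  score
}

random_simple_graph <- function(max_nodes = 8L) {
  n <- sample(3:max_nodes, 1L)
  nodes <- paste0("R", seq_len(n))
  all_pairs <- t(utils::combn(nodes, 2))
  m <- sample(seq_len(nrow(all_pairs)), sample(2:min(nrow(all_pairs), 10), 1L))
  data.frame(from = all_pairs[m, 1], to = all_pairs[m, 2],
             stringsAsFactors = FALSE)
}

# ---- misc helpers ----------------------------------------------------------

we_dict <- function() nc_example_dictionary()

edges_pos <- function(span) as.integer(span$pos)
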