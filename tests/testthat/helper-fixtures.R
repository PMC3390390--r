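# Shared fixtures and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal two-class schema used by most hand-built fixtures.
tiny_schema <- function() {
  slap_schema(
    c("Compound", "Target", "GOTerm", "Substructure"),
    list(bind = c("Compound", "Target"),
         express = c("Compound", "Target"),
         hasGO = c("Target", "GOTerm"),
         hasSubstructure = c("Compound", "Substructure"),
         PPI = c("Target", "Target")))
}

tiny_graph <- function(edges, nodes = NULL) {
  if (is.null(nodes)) {
    ids <- unique(c(edges$source, edges$target))
    cls <- ifelse(grepl("^D", ids), "Compound",
           ifelse(grepl("^T", ids), "Target",
           ifelse(grepl("^G", ids), "GOTerm", "Substructure")))
    nodes <- data.frame(id = ids, class = cls, stringsAsFactors = FALSE)
  }
  semantic_graph(nodes, edges, tiny_schema())
}

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], type = m[, 2], target = m[, 3],
             stringsAsFactors = FALSE)
}

# Random typed graph on <= n nodes (two-class for simplicity plus one
# annotation class), built independently of the generator module.
random_typed_graph <- function(seed, n_nodes = 30, n_edges = 60) {
  set.seed(seed)
  n_c <- max(2, round(n_nodes * 0.4))
  n_t <- max(2, round(n_nodes * 0.4))
  n_g <- max(1, n_nodes - n_c - n_t)
  nodes <- data.frame(
    id = c(sprintf("D%02d", 1:n_c), sprintf("T%02d", 1:n_t),
           sprintf("G%02d", 1:n_g)),
    class = rep(c("Compound", "Target", "GOTerm"), c(n_c, n_t, n_g)),
    stringsAsFactors = FALSE)
  mk <- function(ty, A, B, k) {
    data.frame(source = sample(A, k, replace = TRUE), type = ty,
               target = sample(B, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  cs <- nodes$id[nodes$class == "Compound"]
  ts <- nodes$id[nodes$class == "Target"]
  gs <- nodes$id[nodes$class == "GOTerm"]
  edges <- rbind(mk("bind", cs, ts, round(n_edges * 0.4)),
                 mk("express", cs, ts, round(n_edges * 0.2)),
                 mk("hasGO", ts, gs, round(n_edges * 0.3)),
                 mk("PPI", ts, ts, round(n_edges * 0.1)))
  edges <- edges[edges$source != edges$target, ]
  tiny_graph(edges, nodes)
}

# Brute-force simple-path enumeration by plain depth-first search over the
# edge table; independent of the package's adjacency index and enumeration
# order. Returns a character set, one string per path.
oracle_paths <- function(graph, source, target, max_length = 3,
                         excluded_edges = NULL) {
  e <- graph$edges
  excl <- character(0)
  if (!is.null(excluded_edges)) {
    if (!is.list(excluded_edges)) excluded_edges <- list(excluded_edges)
    excl <- vapply(excluded_edges, function(x) {
      paste(min(x[1], x[3]), x[2], max(x[1], x[3]))
    }, character(1))
  }
  nbrs <- function(v) {
    rows <- e[e$source == v | e$target == v, , drop = FALSE]
    if (!nrow(rows)) return(rows[0, ])
    data.frame(other = ifelse(rows$source == v, rows$target, rows$source),
               type = rows$type, stringsAsFactors = FALSE)
  }
  found <- character(0)
  walk <- function(v, visited, trail) {
    if (length(trail) / 2 >= max_length) return()
    nb <- nbrs(v)
    for (i in seq_len(nrow(nb))) {
      w <- nb$other[i]; ty <- nb$type[i]
      if (paste(min(v, w), ty, max(v, w)) %in% excl) next
      if (w == target) {
        found <<- c(found, paste(c(trail, ty, w), collapse = "|"))
      } else if (!(w %in% visited)) {
        walk(w, c(visited, w), c(trail, ty, w))
      }
    }
  }
  walk(source, c(source, target), source)
  sort(found)
}

path_to_string <- function(p) {
  m <- length(p$nodes)
  out <- character(2 * m - 1)
  out[seq(1, 2 * m - 1, by = 2)] <- p$nodes
  out[seq(2, 2 * m - 2, by = 2)] <- p$types
  paste(out, collapse = "|")
}

# Mann-Whitney AUROC by exhaustive pairwise comparison (independent oracle).
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
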