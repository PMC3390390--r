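# Path enumeration between two nodes of a semantic_graph.
#
# A path is a plain list with fields
#   nodes  character vector of m node ids (simple: no repeats)
#   types  character vector of m-1 edge-type labels
# Every consecutive (node, type, node) triple is an edge of the graph.

.canon_edge_key <- function(u, ty, v) {
  paste(pmin(u, v), ty, pmax(u, v), sep = .SEP)
}

# Types joining u and v, minus any excluded edges (set of canonical keys).
.allowed_types <- function(g, u, v, excl) {
  ty <- .edge_types_between(g, u, v)
  if (length(excl) && length(ty)) {
    ty <- ty[!(.canon_edge_key(u, ty, v) %in% excl)]
  }
  ty
}

# Expand a node sequence into one path per combination of edge types along it.
.expand_types <- function(g, nodes, excl) {
  m <- length(nodes)
  ty_opts <- vector("list", m - 1L)
  for (i in seq_len(m - 1L)) {
    ty <- .allowed_types(g, nodes[i], nodes[i + 1L], excl)
    if (!length(ty)) return(list())
    ty_opts[[i]] <- ty
  }
  if (m == 2L) {
    return(lapply(ty_opts[[1L]], function(t1) list(nodes = nodes, types = t1)))
  }
  combos <- expand.grid(ty_opts, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(r) {
    list(nodes = nodes, types = as.character(unlist(combos[r, ],
                                                    use.names = FALSE)))
  })
}

# Node sequences (excluding endpoints' type expansion) of exact length k >= 4
# found by depth-first search; used only when max_length exceeds 3.
.dfs_sequences <- function(g, source, target, max_len) {
  out <- list()
  recurse <- function(seq_nodes, depth_left) {
    cur <- seq_nodes[length(seq_nodes)]
    for (nb in .neighbors(g, cur)) {
      if (nb == target) {
        out[[length(out) + 1L]] <<- c(seq_nodes, nb)
      } else if (depth_left > 1L && !(nb %in% seq_nodes)) {
        recurse(c(seq_nodes, nb), depth_left - 1L)
      }
    }
  }
  recurse(source, max_len)
  out
}

#' Enumerate bounded-length simple paths between two nodes
#'
#' Returns every simple path (no repeated node) from \code{source} to
#' \code{target} with at most \code{max_length} edges, one entry per
#' combination of edge types along the node sequence. Enumeration is complete:
#' all qualifying paths are returned, not only shortest ones. Output order is
#' deterministic (by length, then pattern signature, then node ids) so that
#' downstream floating-point sums are reproducible.
#'
#' @param graph A [semantic_graph].
#' @param source,target Distinct node ids.
#' @param max_length Maximum number of edges per path; default 3, the usual
#'   search horizon for drug-target evidence paths (path counts explode
#'   beyond it).
#' @param excluded_edges Optional edge or edges no path may traverse: a
#'   character vector \code{c(node, type, node)} or a list of such vectors.
#'   Used for direct-link exclusion, where all paths through the known
#'   drug-target edge are removed so a score reflects only neighborhood
#'   evidence.
#' @return A list of paths, each a list with \code{nodes} (node ids) and
#'   \code{types} (edge-type labels, one fewer). If either endpoint is absent
#'   from the graph the result is an empty list with attribute
#'   \code{status = "not_mapped"}, distinguishable from an empty list with
#'   \code{status = "ok"} (nodes present, no connecting path).
#' @export
enumerate_paths <- function(graph, source, target, max_length = 3,
                            excluded_edges = NULL) {
  stopifnot(inherits(graph, "semantic_graph"), max_length >= 1)
  if (source == target) stop("source and target must differ", call. = FALSE)
  if (!has_node(graph, source) || !has_node(graph, target)) {
    return(structure(list(), status = "not_mapped"))
  }
  excl <- character(0)
  if (!is.null(excluded_edges)) {
    if (!is.list(excluded_edges)) excluded_edges <- list(excluded_edges)
    excl <- vapply(excluded_edges, function(e) {
      stopifnot(length(e) == 3L)
      .canon_edge_key(e[1], e[2], e[3])
    }, character(1))
  }

  g <- graph
  seqs <- list()
  # length 1: the direct edge(s)
  nb_s <- .neighbors(g, source)
  nb_t <- .neighbors(g, target)
  if (target %in% nb_s) seqs[[length(seqs) + 1L]] <- c(source, target)
  # length 2: common neighbors
  if (max_length >= 2L) {
    for (m in setdiff(intersect(nb_s, nb_t), c(source, target))) {
      seqs[[length(seqs) + 1L]] <- c(source, m, target)
    }
  }
  # length 3: a in N(source), b in N(a) intersect N(target)
  if (max_length >= 3L) {
    A <- setdiff(nb_s, target)
    for (a in A) {
      B <- setdiff(intersect(.neighbors(g, a), nb_t), c(source, target, a))
      for (b in B) seqs[[length(seqs) + 1L]] <- c(source, a, b, target)
    }
  }
  if (max_length > 3L) {
    longer <- .dfs_sequences(g, source, target, max_length)
    longer <- longer[vapply(longer, length, integer(1)) > 4L]
    seqs <- c(seqs, longer)
  }

  paths <- list()
  for (s in seqs) paths <- c(paths, .expand_types(g, s, excl))
  if (!length(paths)) return(structure(list(), status = "ok"))

  sig <- .path_signatures(g, paths)
  len <- vapply(paths, function(p) length(p$types), integer(1))
  ids <- vapply(paths, function(p) paste(p$nodes, collapse = .SEP),
                character(1))
  ord <- order(len, sig, ids)
  paths <- paths[ord]
  sig <- sig[ord]
  # cache each path's signature; pattern_signature() returns it when present
  for (i in seq_along(paths)) paths[[i]]$sig <- sig[i]
  structure(paths, status = "ok")
}

# Vectorized pattern signatures for a list of paths (grouped by length so
# that paste() runs once per group).
.path_signatures <- function(g, paths) {
  len <- vapply(paths, function(p) length(p$types), integer(1))
  out <- character(length(paths))
  for (L in unique(len)) {
    idx <- which(len == L)
    nod <- matrix(unlist(lapply(paths[idx], `[[`, "nodes")), ncol = L + 1L,
                  byrow = TRUE)
    ty <- matrix(unlist(lapply(paths[idx], `[[`, "types")), ncol = L,
                 byrow = TRUE)
    parts <- vector("list", 2L * L + 1L)
    for (j in seq_len(L + 1L)) {
      parts[[2L * j - 1L]] <- unname(g$nodes[nod[, j]])
    }
    for (j in seq_len(L)) parts[[2L * j]] <- ty[, j]
    out[idx] <- do.call(paste, c(parts, sep = "|"))
  }
  out
}

# Vectorized raw scores + signatures for a list of paths: one typed-degree
# lookup per distinct (node, type) step, then a grouped sum per path.
.score_paths <- function(g, paths) {
  if (!length(paths)) {
    return(data.frame(signature = character(0), length = integer(0),
                      raw = numeric(0), stringsAsFactors = FALSE))
  }
  len <- vapply(paths, function(p) length(p$types), integer(1))
  from <- unlist(lapply(paths, function(p) p$nodes[-length(p$nodes)]),
                 use.names = FALSE)
  to <- unlist(lapply(paths, function(p) p$nodes[-1L]), use.names = FALSE)
  ty <- unlist(lapply(paths, `[[`, "types"), use.names = FALSE)
  pid <- rep(seq_along(paths), len)
  keys <- c(.key(from, ty), .key(to, ty))
  uk <- unique(keys)
  deg <- vapply(uk, function(k) length(g$index$typed[[k]]), integer(1),
                USE.NAMES = FALSE)
  if (any(deg == 0L)) {
    stop("path step with type degree 0: path is not valid in this graph",
         call. = FALSE)
  }
  ldeg <- log(deg)[match(keys, uk)]
  half <- length(from)
  step <- ldeg[seq_len(half)] + ldeg[half + seq_len(half)]
  raw <- -0.5 * as.numeric(rowsum(step, pid))
  cached <- vapply(paths, function(p) if (is.null(p$sig)) NA_character_ else
    p$sig, character(1))
  sig <- if (anyNA(cached)) .path_signatures(g, paths) else cached
  data.frame(signature = sig, length = len, raw = raw,
             stringsAsFactors = FALSE)
}

#' Semantic signature (meta-path) of a path
#'
#' The pattern of a path is the alternating sequence of node-class labels and
#' edge-type labels along it, read from the source end, abstracting away the
#' specific nodes. Paths sharing this sequence are instances of one pattern,
#' e.g. \code{"Compound|bind|Target|bind|Compound|bind|Target"} for the
#' shared-ligand mechanism. Signatures are directional: they are read from
#' the query end and not symmetrized.
#'
#' @param path A path as returned by [enumerate_paths()].
#' @param graph The [semantic_graph] supplying node classes.
#' @return The signature as a single \code{"|"}-delimited string.
#' @export
pattern_signature <- function(path, graph) {
  if (!is.null(path$sig)) return(path$sig)
  cls <- node_class(graph, path$nodes)
  m <- length(cls)
  out <- character(2L * m - 1L)
  out[seq(1L, 2L * m - 1L, by = 2L)] <- cls
  if (m > 1L) out[seq(2L, 2L * m - 2L, by = 2L)] <- path$types
  paste(out, collapse = "|")
}

#' Group paths by their pattern signature
#'
#' @param paths List of paths from [enumerate_paths()].
#' @param graph The [semantic_graph] supplying node classes.
#' @return Named list mapping signature to the sub-list of paths carrying it;
#'   group sizes sum to \code{length(paths)}.
#' @export
group_by_pattern <- function(paths, graph) {
  if (!length(paths)) return(stats::setNames(list(), character(0)))
  sig <- vapply(paths, function(p) pattern_signature(p, graph), character(1))
  split(paths, factor(sig, levels = sort(unique(sig))))
}

#' Reverse a path
#' @param path A path.
#' @return The same path traversed from the other end.
#' @export
reverse_path <- function(path) {
  list(nodes = rev(path$nodes), types = rev(path$types))
}
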