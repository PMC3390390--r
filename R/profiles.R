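# Polypharmacology profiles: drug x target score matrices, significance
# filtering, Pearson profile similarity and drug-similarity networks.

#' Build a drug x target association-score matrix
#'
#' Scores every drug against every target in the panel with the fitted
#' model. A drug's row of scores across the panel is its polypharmacology
#' profile. Unmapped drugs (or targets) yield zero cells flagged
#' \code{"not_mapped"}.
#'
#' @param model A [slap_fit()] model.
#' @param drugs,targets Non-empty character vectors of node ids.
#' @param exclude_direct Remove direct drug-target edges before scoring
#'   (default FALSE: profile cells for known interactions should reflect
#'   them).
#' @param graph Graph override, as in [score_pairs()].
#' @return An object of class \code{slap_score_matrix}: list with
#'   \code{score} (numeric drugs x targets matrix) and \code{status}
#'   (character matrix of \code{"scored"} / \code{"no_paths"} /
#'   \code{"not_mapped"}).
#' @export
build_score_matrix <- function(model, drugs, targets, exclude_direct = FALSE,
                               graph = NULL) {
  stopifnot(inherits(model, "slap_model"))
  if (!length(drugs) || !length(targets)) {
    stop("drugs and targets must be non-empty", call. = FALSE)
  }
  drugs <- as.character(drugs); targets <- as.character(targets)
  pairs <- data.frame(source = rep(drugs, each = length(targets)),
                      target = rep(targets, times = length(drugs)),
                      stringsAsFactors = FALSE)
  sc <- score_pairs(model, pairs, exclude_direct = exclude_direct,
                    graph = graph)
  score <- matrix(sc$score, nrow = length(drugs), ncol = length(targets),
                  byrow = TRUE, dimnames = list(drugs, targets))
  status <- matrix(sc$status, nrow = length(drugs), ncol = length(targets),
                   byrow = TRUE, dimnames = list(drugs, targets))
  structure(list(score = score, status = status),
            class = "slap_score_matrix")
}

#' @export
print.slap_score_matrix <- function(x, ...) {
  cat("Score matrix:", nrow(x$score), "drugs x", ncol(x$score), "targets;",
      sum(x$score > 0), "non-zero cells\n")
  invisible(x)
}

#' Drop insignificant rows/columns from a score matrix
#'
#' Removes every row (drug) and/or column (target) whose maximum association
#' score is below the significance threshold of the null at level
#' \code{alpha}, so each remaining drug has at least one significant target
#' and vice versa. Filtering is repeated to a fixed point, which makes the
#' operation idempotent.
#'
#' @param matrix A \code{slap_score_matrix}.
#' @param null A \code{slap_null} (e.g. \code{model$null}).
#' @param alpha Significance level (default 0.05).
#' @param mode Filter \code{"both"} (default), \code{"rows"} or
#'   \code{"columns"}.
#' @return The filtered \code{slap_score_matrix}, with attributes
#'   \code{threshold}, \code{kept_rows}, \code{kept_cols}.
#' @export
filter_matrix <- function(matrix, null, alpha = 0.05,
                          mode = c("both", "rows", "columns")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "slap_score_matrix"))
  thr <- significance_threshold(null, alpha)
  sc <- matrix$score; st <- matrix$status
  repeat {
    keep_r <- if (mode %in% c("both", "rows")) {
      apply(sc, 1L, max) >= thr
    } else rep(TRUE, nrow(sc))
    keep_c <- if (mode %in% c("both", "columns")) {
      apply(sc, 2L, max) >= thr
    } else rep(TRUE, ncol(sc))
    if (!any(keep_r) || !any(keep_c)) {
      stop("filtering at alpha = ", alpha,
           " removed every row or column (threshold ",
           signif(thr, 4), ", max score ", signif(max(sc), 4), ")",
           call. = FALSE)
    }
    if (all(keep_r) && all(keep_c)) break
    sc <- sc[keep_r, keep_c, drop = FALSE]
    st <- st[keep_r, keep_c, drop = FALSE]
  }
  structure(list(score = sc, status = st), class = "slap_score_matrix",
            threshold = thr, kept_rows = rownames(sc),
            kept_cols = colnames(sc))
}

#' Pearson similarity of polypharmacology profiles
#'
#' Pearson correlation coefficient between every unordered pair of drug
#' profiles (matrix rows). Profiles with zero variance (a drug with a flat
#' score row) have undefined correlation and propagate as \code{NA}, never
#' as 0. The diagonal is 1 and the matrix is symmetric.
#'
#' @param matrix A \code{slap_score_matrix} with at least 2 rows and 2
#'   columns.
#' @return Symmetric numeric matrix of correlations in [-1, 1] (or NA).
#' @export
profile_similarity <- function(matrix) {
  stopifnot(inherits(matrix, "slap_score_matrix"))
  sc <- matrix$score
  if (nrow(sc) < 2L || ncol(sc) < 2L) {
    stop("need at least 2 drugs and 2 targets", call. = FALSE)
  }
  sim <- suppressWarnings(stats::cor(t(sc), method = "pearson"))
  diag(sim) <- 1
  sim
}

#' Build a drug-similarity network from a profile-similarity matrix
#'
#' Two drugs are linked when their profile correlation is at least the
#' threshold. Drugs without any qualifying partner are retained as isolated
#' nodes (flagged by degree 0) so unclustered drugs remain visible.
#'
#' @param similarities Symmetric correlation matrix from
#'   [profile_similarity()].
#' @param threshold Minimum Pearson coefficient for an edge (default 0.75).
#' @param annotations Optional named character vector (names = drug ids)
#'   attached as the \code{annotation} vertex attribute, e.g. therapeutic
#'   indication.
#' @return An \pkg{igraph} undirected graph with edge attribute
#'   \code{weight} (the coefficient) and graph attribute \code{threshold}.
#' @export
build_similarity_network <- function(similarities, threshold = 0.75,
                                     annotations = NULL) {
  stopifnot(is.matrix(similarities),
            nrow(similarities) == ncol(similarities))
  drugs <- rownames(similarities)
  keep <- which(upper.tri(similarities) & !is.na(similarities) &
                  similarities >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = drugs[keep[, 1]], to = drugs[keep[, 2]],
                      weight = similarities[keep], stringsAsFactors = FALSE)
  net <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = drugs))
  if (!is.null(annotations)) {
    igraph::V(net)$annotation <- unname(annotations[drugs])
  }
  net$threshold <- threshold
  net
}

#' Most similar drugs to a query, by profile correlation
#'
#' @param matrix A \code{slap_score_matrix}.
#' @param query_drug Row id of the query; must exist in the matrix.
#' @param top_k Number of neighbors to return; a larger value than the
#'   library size returns the full ranking.
#' @return Data frame with columns \code{drug} and \code{similarity}, sorted
#'   by descending similarity, query excluded; drugs with undefined
#'   similarity (zero-variance profile) are omitted.
#' @export
query_similar <- function(matrix, query_drug, top_k = 10) {
  stopifnot(inherits(matrix, "slap_score_matrix"))
  sc <- matrix$score
  if (!(query_drug %in% rownames(sc))) {
    stop("unknown drug: ", query_drug, call. = FALSE)
  }
  q <- sc[query_drug, ]
  others <- setdiff(rownames(sc), query_drug)
  sim <- suppressWarnings(
    vapply(others, function(d) stats::cor(q, sc[d, ]), numeric(1)))
  sim <- sim[!is.na(sim)]
  ord <- order(sim, names(sim), decreasing = c(TRUE, FALSE), method = "radix")
  top <- utils::head(ord, top_k)
  data.frame(drug = names(sim)[top], similarity = unname(sim[top]),
             stringsAsFactors = FALSE)
}

#' Write a score matrix to TSV
#'
#' Writes the wide form (one row per drug, one column per target) and, when
#' \code{long_path} is given, a long form with one row per cell
#' (\code{drug}, \code{target}, \code{score}, optional \code{p_value},
#' \code{status}).
#'
#' @param matrix A \code{slap_score_matrix}.
#' @param path Output path for the wide TSV.
#' @param long_path Optional output path for the long TSV.
#' @param null Optional \code{slap_null}; adds a \code{p_value} column to the
#'   long form.
#' @return Invisibly, \code{path}.
#' @export
write_score_matrix <- function(matrix, path, long_path = NULL, null = NULL) {
  stopifnot(inherits(matrix, "slap_score_matrix"))
  wide <- data.frame(drug = rownames(matrix$score), matrix$score,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(long_path)) {
    long <- data.frame(
      drug = rep(rownames(matrix$score), times = ncol(matrix$score)),
      target = rep(colnames(matrix$score), each = nrow(matrix$score)),
      score = as.vector(matrix$score),
      status = as.vector(matrix$status),
      stringsAsFactors = FALSE)
    if (!is.null(null)) {
      long$p_value <- p_value(long$score, null)
      long <- long[c("drug", "target", "score", "p_value", "status")]
    }
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Export a drug-similarity network
#'
#' Writes the weighted edge list as TSV (\code{drug1}, \code{drug2},
#' \code{weight}) and optionally the full network (isolated nodes included)
#' as GraphML.
#'
#' @param network An \pkg{igraph} graph from [build_similarity_network()].
#' @param edge_path Output TSV path.
#' @param graphml_path Optional GraphML output path.
#' @return Invisibly, \code{edge_path}.
#' @export
write_similarity_network <- function(network, edge_path,
                                     graphml_path = NULL) {
  el <- igraph::as_data_frame(network, what = "edges")
  names(el)[1:2] <- c("drug1", "drug2")
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}

# Adjusted Rand index between two labelings; used to compare similarity-
# network components with planted drug groups.
.ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, about 0 for independent ones. Used to quantify how
#' well similarity-network components recover known drug groups.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) .ari(a, b)
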