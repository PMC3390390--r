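# Seeded generator of synthetic heterogeneous drug-target networks with
# planted associations, emulating (at toy scale) the structure of a semantic
# drug-target network: compounds, targets, GO terms, pathways, substructures,
# tissues, side effects and diseases joined by typed background edges, plus
# planted positive pairs wired through indirect evidence routes.

#' Configuration for the synthetic-network generator
#'
#' Background edges are drawn per edge type between the two permitted node
#' classes at densities set by \code{mean_degree}: the expected number of
#' edges of that type per node of the first class. Endpoints are sampled
#' with a Zipf-like weight of exponent \code{degree_skew} (default 1.1),
#' giving the heavy-tailed degree distributions of real chem-bio networks;
#' \code{degree_skew = 0} gives uniform Erdos-Renyi backgrounds. The
#' defaults produce a network in which a typical compound-target pair is
#' joined by tens of length-3 paths, so that path counts alone carry little
#' signal and discrimination has to come from path specificity -- the regime
#' the method is designed for.
#'
#' Positive pairs are planted by wiring \code{strength} indirect evidence
#' routes per pair, each instantiating one of three informative mechanisms:
#' shared ligand (D-bind-T'-bind-D'-bind-T), shared GO annotation
#' (D-bind-T'-hasGO-G-hasGO-T) and shared substructure
#' (D-hasSubstructure-S-hasSubstructure-D'-bind-T). By default the direct
#' D-bind-T edge is \emph{not} added, so planted pairs test missing-link
#' recovery; \code{add_direct = TRUE} adds it for direct-link-exclusion
#' tests.
#'
#' @param seed Integer seed (mandatory); generation is byte-reproducible
#'   given it.
#' @param n_compound,n_target,n_go,n_pathway,n_substructure,n_tissue,n_sideeffect,n_disease
#'   Node counts per class.
#' @param mean_degree Named numeric vector of background densities per edge
#'   type (see above); partial overrides are merged with the defaults.
#' @param n_planted Number of planted positive compound-target pairs.
#' @param strength Evidence routes planted per positive pair (0-10).
#' @param mechanisms Named weights for the three planting mechanisms
#'   \code{shared_ligand}, \code{shared_go}, \code{shared_substructure}.
#' @param add_direct Also add the direct bind edge for planted pairs
#'   (default FALSE).
#' @param degree_skew Non-negative exponent for degree-skewed endpoint
#'   sampling (0 = uniform Erdos-Renyi; larger values give heavier-tailed
#'   degrees, as real chem-bio networks have).
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(seed,
                         n_compound = 60, n_target = 60, n_go = 40,
                         n_pathway = 25, n_substructure = 50, n_tissue = 12,
                         n_sideeffect = 30, n_disease = 10,
                         mean_degree = NULL,
                         n_planted = 40, strength = 3,
                         mechanisms = c(shared_ligand = 1, shared_go = 1,
                                        shared_substructure = 1),
                         add_direct = FALSE, degree_skew = 1.1) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  default_deg <- c(bind = 4, express = 1.5, hasGO = 4, hasPathway = 2,
                   hasTissue = 2, PPI = 2.5, hasSubstructure = 4,
                   hasSideEffect = 2, treats = 0.5)
  if (!is.null(mean_degree)) {
    bad <- setdiff(names(mean_degree), names(default_deg))
    if (length(bad)) stop("unknown edge type(s) in mean_degree: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    default_deg[names(mean_degree)] <- mean_degree
  }
  counts <- c(n_compound = n_compound, n_target = n_target, n_go = n_go,
              n_pathway = n_pathway, n_substructure = n_substructure,
              n_tissue = n_tissue, n_sideeffect = n_sideeffect,
              n_disease = n_disease)
  stopifnot(all(counts >= 0), n_planted >= 0, strength >= 0, strength <= 10,
            degree_skew >= 0)
  structure(list(seed = as.integer(seed), counts = counts,
                 mean_degree = default_deg, n_planted = n_planted,
                 strength = strength, mechanisms = mechanisms,
                 add_direct = add_direct, degree_skew = degree_skew),
            class = "synth_config")
}

.synth_ids <- function(prefix, n) {
  if (n == 0) return(character(0))
  sprintf("%s%04d", prefix, seq_len(n))
}

# Sample n_edges distinct (a, b) pairs from A x B (column-major index,
# a fastest), excluding exclude_idx. skew > 0 biases endpoints by a shuffled
# Zipf weight, giving heavy-tailed degrees.
.sample_bipartite <- function(A, B, n_edges, skew = 0, exclude_idx = NULL) {
  nA <- length(A); nB <- length(B)
  if (nA == 0 || nB == 0 || n_edges == 0) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  cand <- seq_len(nA * nB)
  if (length(exclude_idx)) cand <- setdiff(cand, exclude_idx)
  if (n_edges > length(cand)) {
    stop("requested ", n_edges, " edges but only ", length(cand),
         " candidate pairs", call. = FALSE)
  }
  if (skew > 0) {
    wA <- sample(seq_len(nA)^(-skew))
    wB <- sample(seq_len(nB)^(-skew))
    ai <- (cand - 1L) %% nA + 1L
    bi <- (cand - 1L) %/% nA + 1L
    idx <- sample(cand, n_edges, prob = wA[ai] * wB[bi])
  } else {
    idx <- sample(cand, n_edges)
  }
  data.frame(a = A[(idx - 1L) %% nA + 1L],
             b = B[(idx - 1L) %/% nA + 1L], stringsAsFactors = FALSE)
}

# Sample n_edges distinct unordered pairs within one class.
.sample_within <- function(A, n_edges) {
  n <- length(A)
  if (n < 2 || n_edges == 0) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  ut <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  if (n_edges > nrow(ut)) stop("too many within-class edges requested",
                               call. = FALSE)
  sel <- ut[sample(nrow(ut), n_edges), , drop = FALSE]
  data.frame(a = A[sel[, 1]], b = A[sel[, 2]], stringsAsFactors = FALSE)
}

# Background scaffold (nodes + background edge parts) for a given planted
# pair table; bind/express background edges never join a planted pair.
# Must be called inside .with_seed().
.synth_background <- function(config, planted) {
  cn <- config$counts
  ids <- list(
    Compound = .synth_ids("C", cn[["n_compound"]]),
    Target = .synth_ids("T", cn[["n_target"]]),
    GOTerm = .synth_ids("GO", cn[["n_go"]]),
    Pathway = .synth_ids("PW", cn[["n_pathway"]]),
    Substructure = .synth_ids("S", cn[["n_substructure"]]),
    Tissue = .synth_ids("TS", cn[["n_tissue"]]),
    SideEffect = .synth_ids("SE", cn[["n_sideeffect"]]),
    Disease = .synth_ids("DS", cn[["n_disease"]]))
  nodes <- data.frame(
    id = unlist(ids, use.names = FALSE),
    class = rep(names(ids), lengths(ids)), stringsAsFactors = FALSE)

  compounds <- ids$Compound; targets <- ids$Target
  deg <- config$mean_degree
  skew <- config$degree_skew

  # planted pairs as column-major indices into Compound x Target, kept out
  # of the background bind/express samples (missing-link construction)
  planted_idx <- integer(0)
  if (nrow(planted)) {
    planted_idx <- (match(planted$target, targets) - 1L) *
      length(compounds) + match(planted$source, compounds)
  }

  bip <- function(A, B, ty, excl = NULL) {
    e <- .sample_bipartite(A, B, round(length(A) * deg[[ty]]), skew, excl)
    if (!nrow(e)) return(NULL)
    data.frame(source = e$a, type = ty, target = e$b,
               stringsAsFactors = FALSE)
  }
  parts <- list(
    bip(compounds, targets, "bind", planted_idx),
    bip(compounds, targets, "express", planted_idx),
    bip(targets, ids$GOTerm, "hasGO"),
    bip(targets, ids$Pathway, "hasPathway"),
    bip(targets, ids$Tissue, "hasTissue"),
    bip(compounds, ids$Substructure, "hasSubstructure"),
    bip(compounds, ids$SideEffect, "hasSideEffect"),
    bip(compounds, ids$Disease, "treats"))
  ppi <- .sample_within(targets, round(length(targets) * deg[["PPI"]] / 2))
  if (nrow(ppi)) {
    parts <- c(parts, list(data.frame(source = ppi$a, type = "PPI",
                                      target = ppi$b,
                                      stringsAsFactors = FALSE)))
  }

  list(nodes = nodes, parts = parts, ids = ids, compounds = compounds,
       targets = targets)
}

# Per-pair planted evidence routes: `strength` distinct routes per planted
# pair, each instantiating one mechanism; never creates a direct edge
# between any planted pair. Must be called inside .with_seed().
.synth_pair_routes <- function(config, planted, ids) {
  compounds <- ids$Compound; targets <- ids$Target
  parts <- list(); truth <- list()
  mech_names <- names(config$mechanisms)
  planted_key <- paste(planted$source, planted$target)
  forbidden <- function(d, t) paste(d, t) %in% planted_key
  for (i in seq_len(nrow(planted))) {
    D <- planted$source[i]; T1 <- planted$target[i]
    seen <- character(0)
    for (r in seq_len(config$strength)) {
      for (try in 1:25) {
        mech <- sample(mech_names, 1, prob = config$mechanisms)
        if (mech == "shared_ligand") {
          T2 <- sample(targets[targets != T1 & !forbidden(D, targets)], 1)
          D2 <- sample(compounds[compounds != D &
                                   !forbidden(compounds, T1)], 1)
          e <- data.frame(source = c(D, T2, D2), type = "bind",
                          target = c(T2, D2, T1), stringsAsFactors = FALSE)
          route <- c(D, T2, D2, T1)
        } else if (mech == "shared_go") {
          T2 <- sample(targets[targets != T1 & !forbidden(D, targets)], 1)
          G <- sample(ids$GOTerm, 1)
          e <- data.frame(source = c(D, T2, T1),
                          type = c("bind", "hasGO", "hasGO"),
                          target = c(T2, G, G), stringsAsFactors = FALSE)
          route <- c(D, T2, G, T1)
        } else {
          S <- sample(ids$Substructure, 1)
          D2 <- sample(compounds[compounds != D &
                                   !forbidden(compounds, T1)], 1)
          e <- data.frame(source = c(D, D2, D2),
                          type = c("hasSubstructure", "hasSubstructure",
                                   "bind"),
                          target = c(S, S, T1), stringsAsFactors = FALSE)
          route <- c(D, S, D2, T1)
        }
        key <- paste(route, collapse = "-")
        if (!(key %in% seen)) break
      }
      seen <- c(seen, key)
      parts <- c(parts, list(e))
      truth[[length(truth) + 1L]] <- data.frame(
        source = D, target = T1, mechanism = mech, route = key,
        stringsAsFactors = FALSE)
    }
    if (config$add_direct) {
      parts <- c(parts, list(data.frame(source = D, type = "bind",
                                        target = T1,
                                        stringsAsFactors = FALSE)))
    }
  }
  list(parts = parts, truth = truth)
}

# Assemble the final bundle pieces from node table and edge parts.
.synth_finish <- function(nodes, parts, truth) {
  parts <- parts[!vapply(parts, is.null, logical(1))]
  edges <- do.call(rbind, parts)
  graph <- semantic_graph(nodes, edges, default_schema())
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(source = character(0), target = character(0),
               mechanism = character(0), route = character(0),
               stringsAsFactors = FALSE)
  list(graph = graph, truth = truth)
}

#' Generate a synthetic heterogeneous network with planted associations
#'
#' @param config A [synth_config()].
#' @return An object of class \code{slap_synth_bundle}: list with
#'   \code{graph} (a [semantic_graph]), \code{positives} (data frame of
#'   planted pairs with \code{label = 1}), \code{compounds} and
#'   \code{targets} (the decoy candidate pools), \code{truth} (one row per
#'   planted evidence route) and \code{config}.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    compounds <- .synth_ids("C", config$counts[["n_compound"]])
    targets <- .synth_ids("T", config$counts[["n_target"]])
    planted <- .sample_pairs(compounds, targets, config$n_planted,
                             seed = NULL)
    if (config$n_planted == 0) {
      planted <- data.frame(source = character(0), target = character(0),
                            stringsAsFactors = FALSE)
    }
    bg <- .synth_background(config, planted)
    routes <- .synth_pair_routes(config, planted, bg$ids)
    built <- .synth_finish(bg$nodes, c(bg$parts, routes$parts),
                           routes$truth)
    positives <- planted
    positives$label <- rep(1L, nrow(positives))
    structure(list(graph = built$graph, positives = positives,
                   compounds = bg$compounds, targets = bg$targets,
                   truth = built$truth, config = config),
              class = "slap_synth_bundle")
  })
}

#' @export
print.slap_synth_bundle <- function(x, ...) {
  cat("Synthetic network bundle:", length(x$graph$nodes), "nodes,",
      nrow(x$graph$edges), "edges,", nrow(x$positives),
      "planted pairs (strength", x$config$strength, ")\n")
  invisible(x)
}

#' Positive/decoy benchmark from a synthetic bundle
#'
#' Decoys are sampled without replacement from the compound x target cross
#' product, excluding the planted positives, at \code{decoy_multiplier}
#' times the positive count.
#'
#' @param bundle A [synth_generate()] bundle.
#' @param decoy_multiplier Decoys per positive (default 1).
#' @param seed Integer seed for the decoy sample.
#' @return List with \code{positives} and \code{decoys} data frames
#'   (\code{source}, \code{target}, \code{label}).
#' @export
benchmark_from <- function(bundle, decoy_multiplier = 1, seed = 1) {
  stopifnot(inherits(bundle, "slap_synth_bundle"), decoy_multiplier >= 1)
  n <- nrow(bundle$positives) * decoy_multiplier
  decoys <- .sample_pairs(bundle$compounds, bundle$targets, n, seed,
                          exclude_pairs = bundle$positives)
  decoys$label <- rep(0L, nrow(decoys))
  list(positives = bundle$positives, decoys = decoys)
}

#' Synthetic network with group-structured drug-target wiring
#'
#' Builds a background network plus, for each of \code{n_groups} disjoint
#' drug groups, a set of group-shared evidence channels wiring every drug in
#' the group to every target in the group's own disjoint target set. Each
#' channel is one mechanism instantiated through anchors shared by the whole
#' group -- the way a real drug class shares a scaffold, known ligands and
#' target-family annotation:
#' \itemize{
#'   \item shared substructure: every group drug has the group scaffold
#'     substructure, which an anchor ligand compound also has; the anchor
#'     ligand binds every group target.
#'   \item shared ligand: every group drug binds a group anchor target,
#'     which an anchor ligand also binds; the anchor ligand binds every
#'     group target.
#'   \item shared GO: every group drug binds a group anchor target that
#'     shares a GO term with every group target.
#' }
#' \code{strength} channels are created per group (cycling through the three
#' mechanisms), so every within-group (drug, target) pair has
#' \code{strength} evidence routes of length 3 and no direct edge. Drugs in
#' the same group therefore share a polypharmacology profile peaked on the
#' same targets; drugs in different groups peak on disjoint targets.
#'
#' @param seed Integer seed.
#' @param n_groups Number of drug groups (default 2).
#' @param drugs_per_group,targets_per_group Group sizes (defaults 6 and 8).
#' @param strength Evidence channels per group (default 6, two per
#'   mechanism), hence routes per within-group pair; enough shared evidence
#'   that within-class pairs clear a profile significance filter at alpha
#'   0.05.
#' @param config Optional [synth_config()] for the background; defaults to
#'   \code{synth_config(seed = seed)}. Its \code{n_planted} is ignored.
#' @return A \code{slap_synth_bundle} with an extra \code{groups} element: a
#'   named character vector mapping each group drug to its group label.
#' @export
synth_profile_groups <- function(seed, n_groups = 2, drugs_per_group = 6,
                                 targets_per_group = 8, strength = 6,
                                 config = NULL) {
  if (is.null(config)) config <- synth_config(seed = seed)
  config$strength <- strength
  compounds <- .synth_ids("C", config$counts[["n_compound"]])
  targets <- .synth_ids("T", config$counts[["n_target"]])
  need_d <- n_groups * drugs_per_group
  need_t <- n_groups * targets_per_group
  stopifnot(need_d <= length(compounds), need_t <= length(targets),
            need_d + n_groups * strength <= length(compounds),
            need_t + n_groups * strength <= length(targets))
  group_names <- paste0("group", seq_len(n_groups))
  group_of <- rep(group_names, each = drugs_per_group)
  drugs <- compounds[seq_len(need_d)]
  names(group_of) <- drugs
  planted <- do.call(rbind, lapply(seq_len(n_groups), function(gidx) {
    gd <- drugs[group_of == group_names[gidx]]
    gt <- targets[(gidx - 1L) * targets_per_group +
                    seq_len(targets_per_group)]
    data.frame(source = rep(gd, each = length(gt)),
               target = rep(gt, times = length(gd)),
               stringsAsFactors = FALSE)
  }))
  # anchor nodes: taken from outside the group drugs / panel targets
  free_c <- setdiff(compounds, drugs)
  free_t <- targets[-seq_len(need_t)]
  .with_seed(config$seed, {
    bg <- .synth_background(config, planted)
    parts <- bg$parts; truth <- list()
    mechs <- c("shared_substructure", "shared_ligand", "shared_go")
    anchor_c <- sample(free_c, n_groups * strength)
    anchor_t <- sample(free_t, n_groups * strength)
    anchor_s <- sample(bg$ids$Substructure, n_groups * strength)
    anchor_g <- sample(bg$ids$GOTerm, n_groups * strength)
    k <- 0L
    for (gidx in seq_len(n_groups)) {
      gd <- drugs[group_of == group_names[gidx]]
      gt <- unique(planted$target[planted$source %in% gd])
      for (u in seq_len(strength)) {
        k <- k + 1L
        mech <- mechs[(u - 1L) %% 3L + 1L]
        if (mech == "shared_substructure") {
          S <- anchor_s[k]; L <- anchor_c[k]
          e <- rbind(
            data.frame(source = gd, type = "hasSubstructure", target = S,
                       stringsAsFactors = FALSE),
            data.frame(source = L, type = "hasSubstructure", target = S,
                       stringsAsFactors = FALSE),
            data.frame(source = L, type = "bind", target = gt,
                       stringsAsFactors = FALSE))
          route <- paste(S, L, sep = "-")
        } else if (mech == "shared_ligand") {
          Ta <- anchor_t[k]; L <- anchor_c[k]
          e <- rbind(
            data.frame(source = gd, type = "bind", target = Ta,
                       stringsAsFactors = FALSE),
            data.frame(source = L, type = "bind", target = Ta,
                       stringsAsFactors = FALSE),
            data.frame(source = L, type = "bind", target = gt,
                       stringsAsFactors = FALSE))
          route <- paste(Ta, L, sep = "-")
        } else {
          Ta <- anchor_t[k]; G <- anchor_g[k]
          e <- rbind(
            data.frame(source = gd, type = "bind", target = Ta,
                       stringsAsFactors = FALSE),
            data.frame(source = Ta, type = "hasGO", target = G,
                       stringsAsFactors = FALSE),
            data.frame(source = gt, type = "hasGO", target = G,
                       stringsAsFactors = FALSE))
          route <- paste(Ta, G, sep = "-")
        }
        parts <- c(parts, list(e))
        truth[[length(truth) + 1L]] <- data.frame(
          source = group_names[gidx], target = "*", mechanism = mech,
          route = route, stringsAsFactors = FALSE)
      }
    }
    built <- .synth_finish(bg$nodes, parts, truth)
    positives <- planted
    positives$label <- rep(1L, nrow(positives))
    structure(list(graph = built$graph, positives = positives,
                   compounds = bg$compounds, targets = bg$targets,
                   truth = built$truth, config = config,
                   groups = group_of),
              class = "slap_synth_bundle")
  })
}
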