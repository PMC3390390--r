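# Statistical core: raw path scores, per-pattern z-normalization, association
# scores, and the log-normal random-pair null.

# typed degree without the validity checks of type_degree(); hot path
.td <- function(g, n, t) length(g$index$typed[[.key(n, t)]])

# Evaluate and restore the RNG state around a seeded computation so that
# seeded fits do not disturb the caller's random stream.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Raw score of a path: degree-normalized traversal log-probability
#'
#' Traversal is modelled as a walk with an equal chance of moving from a node
#' to each of its neighbors within the same edge type, so each step from node
#' \eqn{v} along an edge of type \eqn{t} has probability
#' \eqn{1/d_t(v)} where \eqn{d_t(v)} is the node's type degree. Step
#' probabilities multiply along the path, and the natural logarithm is taken.
#' Because the graph is undirected, the raw score is the average of the
#' forward (source to target) and backward (target to source)
#' log-probabilities. It is always \eqn{\le 0}, with 0 attained exactly when
#' every step in both directions has type degree 1 (a maximally specific
#' path).
#'
#' @param path A path from [enumerate_paths()].
#' @param graph The [semantic_graph] the path lives in.
#' @return A single non-positive number.
#' @export
raw_path_score <- function(path, graph) {
  n <- path$nodes
  ty <- path$types
  m <- length(n)
  stopifnot(m >= 2L, length(ty) == m - 1L)
  fwd <- numeric(m - 1L)
  bwd <- numeric(m - 1L)
  for (i in seq_len(m - 1L)) {
    fwd[i] <- .td(graph, n[i], ty[i])
    bwd[i] <- .td(graph, n[i + 1L], ty[i])
  }
  if (any(fwd == 0) || any(bwd == 0)) {
    stop("path step with type degree 0: path is not valid in this graph",
         call. = FALSE)
  }
  -0.5 * sum(log(fwd) + log(bwd))
}

#' Fit per-pattern raw-score distributions from random pairs
#'
#' Samples source-target pairs uniformly without replacement from the cross
#' product of the two pools (optionally excluding a list of known positive
#' pairs, so the sample represents "random" pairs), enumerates all paths of
#' length at most \code{max_length} for each pair, scores each path with
#' [raw_path_score()], and fits a normal distribution (sample mean and
#' standard deviation) to the scores of each path pattern. These fits are the
#' reference population against which individual path scores are
#' z-normalized.
#'
#' Patterns observed on fewer than \code{min_n} sampled paths, or with a
#' degenerate spread (\code{sigma <= sigma_tol}), are marked unusable and
#' contribute no z scores downstream.
#'
#' @param graph A [semantic_graph].
#' @param source_pool,target_pool Character vectors of candidate node ids
#'   (typically all compounds and all targets).
#' @param n_pairs Number of pairs to sample (without replacement).
#' @param seed Integer seed; the fit is fully deterministic given it.
#' @param max_length Maximum path length (default 3).
#' @param exclude_pairs Optional data frame with columns \code{source},
#'   \code{target}: pairs never sampled (e.g. known positives).
#' @param min_n Minimum sampled paths for a usable pattern (default 30).
#' @param sigma_tol Minimum usable standard deviation (default 1e-9).
#' @return An object of class \code{slap_pattern_stats}: a data frame with
#'   columns \code{signature}, \code{mu}, \code{sigma}, \code{n},
#'   \code{usable}, plus attributes recording the sampling (\code{n_pairs},
#'   \code{n_pairs_with_paths}, \code{n_paths}, \code{seed},
#'   \code{max_length}).
#' @export
fit_pattern_stats <- function(graph, source_pool, target_pool, n_pairs, seed,
                              max_length = 3, exclude_pairs = NULL,
                              min_n = 30, sigma_tol = 1e-9) {
  stopifnot(length(source_pool) > 0, length(target_pool) > 0, n_pairs >= 1)
  pairs <- .sample_pairs(source_pool, target_pool, n_pairs, seed,
                         exclude_pairs)
  sig_chunks <- vector("list", nrow(pairs))
  raw_chunks <- vector("list", nrow(pairs))
  n_with <- 0L
  for (i in seq_len(nrow(pairs))) {
    paths <- enumerate_paths(graph, pairs$source[i], pairs$target[i],
                             max_length = max_length)
    if (!length(paths)) next
    n_with <- n_with + 1L
    sc <- .score_paths(graph, paths)
    sig_chunks[[i]] <- sc$signature
    raw_chunks[[i]] <- sc$raw
  }
  sig <- unlist(sig_chunks, use.names = FALSE)
  raw <- unlist(raw_chunks, use.names = FALSE)
  if (is.null(sig)) sig <- character(0)
  if (is.null(raw)) raw <- numeric(0)
  f <- factor(sig)
  mu <- as.numeric(tapply(raw, f, mean))
  sigma <- as.numeric(tapply(raw, f, stats::sd))
  n <- as.integer(tapply(raw, f, length))
  sigma[is.na(sigma)] <- 0
  out <- data.frame(signature = levels(f), mu = mu, sigma = sigma, n = n,
                    stringsAsFactors = FALSE)
  out$usable <- out$n >= min_n & out$sigma > sigma_tol
  out <- out[order(out$signature), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("slap_pattern_stats", "data.frame"),
            n_pairs = nrow(pairs), n_pairs_with_paths = n_with,
            n_paths = length(raw), seed = as.integer(seed),
            max_length = max_length, min_n = min_n, sigma_tol = sigma_tol)
}

# Uniform sample without replacement from source_pool x target_pool minus
# exclude_pairs, deterministic given seed (seed = NULL draws from the
# caller's RNG stream). Ordered pairs indexed column-major over
# (source, target).
.sample_pairs <- function(source_pool, target_pool, n_pairs, seed,
                          exclude_pairs = NULL) {
  ns <- length(source_pool); nt <- length(target_pool)
  idx_all <- seq_len(ns * nt)
  if (!is.null(exclude_pairs) && nrow(exclude_pairs)) {
    si <- match(exclude_pairs$source, source_pool)
    ti <- match(exclude_pairs$target, target_pool)
    drop <- (ti[!is.na(si) & !is.na(ti)] - 1L) * ns +
      si[!is.na(si) & !is.na(ti)]
    idx_all <- setdiff(idx_all, drop)
  }
  if (length(idx_all) < n_pairs) {
    stop("pair pool too small: ", length(idx_all), " candidate pairs for ",
         n_pairs, " requested", call. = FALSE)
  }
  idx <- if (is.null(seed)) sample(idx_all, n_pairs) else
    .with_seed(seed, sample(idx_all, n_pairs))
  data.frame(source = source_pool[(idx - 1L) %% ns + 1L],
             target = target_pool[(idx - 1L) %/% ns + 1L],
             stringsAsFactors = FALSE)
}

#' @export
print.slap_pattern_stats <- function(x, ...) {
  cat("Pattern raw-score fits:", nrow(x), "patterns (",
      sum(x$usable), "usable ) from", attr(x, "n_paths"), "paths over",
      attr(x, "n_pairs"), "sampled pairs\n")
  NextMethod()
}

#' z score of a raw path score within its pattern
#'
#' Standardizes a raw path score against the fitted mean and standard
#' deviation of its pattern: \eqn{z = (raw - \mu)/\sigma}. A positive z marks
#' a path that is more probable (more specific) than a typical random-pair
#' path of the same pattern.
#'
#' @param raw Numeric vector of raw scores.
#' @param stats A \code{slap_pattern_stats} object.
#' @param signature Pattern signature the scores belong to; must be a usable
#'   pattern in \code{stats}.
#' @return Numeric vector of z scores.
#' @export
path_z_score <- function(raw, stats, signature) {
  i <- match(signature, stats$signature)
  if (is.na(i)) stop("unknown pattern: ", signature, call. = FALSE)
  if (!stats$usable[i]) {
    stop("pattern not usable (too few samples or zero spread): ", signature,
         call. = FALSE)
  }
  (raw - stats$mu[i]) / stats$sigma[i]
}

#' Association score of a node pair
#'
#' Enumerates all paths of length at most \code{max_length} between the pair,
#' z-normalizes each path's raw score within its pattern, and sums the z
#' scores of the valid paths: those with \eqn{z > 0} whose pattern is both
#' usable and in the informative set. The sum is the association score (0
#' when no valid path exists). With \code{exclude_direct = TRUE} every path
#' traversing a direct edge between the two nodes is removed first, so the
#' score measures neighborhood ("missing link") evidence only.
#'
#' @param graph A [semantic_graph].
#' @param source,target Node ids; a pair with either node absent gets status
#'   \code{"not_mapped"} and score 0 rather than an error.
#' @param stats A \code{slap_pattern_stats} object.
#' @param informative Character vector of informative pattern signatures;
#'   \code{NULL} means every usable pattern counts.
#' @param exclude_direct Remove paths using a direct source-target edge
#'   (default TRUE).
#' @param max_length Maximum path length (default 3).
#' @return An object of class \code{slap_association}: a list with
#'   \code{source}, \code{target}, \code{score}, \code{status} (one of
#'   \code{"scored"}, \code{"not_mapped"}, \code{"no_paths"}),
#'   \code{n_valid}, and \code{paths}, a data frame with one row per
#'   enumerated path (\code{signature}, \code{length}, \code{raw}, \code{z},
#'   \code{valid}).
#' @export
association_score <- function(graph, source, target, stats,
                              informative = NULL, exclude_direct = TRUE,
                              max_length = 3) {
  empty <- data.frame(signature = character(0), length = integer(0),
                      raw = numeric(0), z = numeric(0), valid = logical(0),
                      stringsAsFactors = FALSE)
  res <- list(source = source, target = target, score = 0,
              status = "scored", n_valid = 0L, paths = empty)
  class(res) <- "slap_association"
  if (!has_node(graph, source) || !has_node(graph, target)) {
    res$status <- "not_mapped"
    return(res)
  }
  excl <- NULL
  if (exclude_direct) {
    direct <- .edge_types_between(graph, source, target)
    if (length(direct)) {
      excl <- lapply(direct, function(ty) c(source, ty, target))
    }
  }
  paths <- enumerate_paths(graph, source, target, max_length = max_length,
                           excluded_edges = excl)
  if (!length(paths)) {
    res$status <- "no_paths"
    return(res)
  }
  sc <- .score_paths(graph, paths)
  sig <- sc$signature; raw <- sc$raw; len <- sc$length
  i <- match(sig, stats$signature)
  usable <- !is.na(i) & stats$usable[ifelse(is.na(i), 1L, i)]
  z <- rep(NA_real_, length(raw))
  z[usable] <- (raw[usable] - stats$mu[i[usable]]) / stats$sigma[i[usable]]
  informative_ok <- if (is.null(informative)) usable else sig %in% informative
  valid <- usable & informative_ok & !is.na(z) & z > 0
  res$paths <- data.frame(signature = sig, length = len, raw = raw, z = z,
                          valid = valid, stringsAsFactors = FALSE)
  res$score <- if (any(valid)) sum(z[valid]) else 0
  res$n_valid <- sum(valid)
  res
}

#' @export
print.slap_association <- function(x, ...) {
  cat(sprintf("%s -- %s: association score %.4f (%s; %d/%d valid paths)\n",
              x$source, x$target, x$score, x$status, x$n_valid,
              nrow(x$paths)))
  invisible(x)
}

#' Fit the random-pair null model
#'
#' The natural logarithms of the (strictly positive) association scores of
#' random pairs are fitted to a normal distribution. The fit supplies
#' p-values ([p_value()]) and score thresholds
#' ([significance_threshold()]). Scores of 0 (pairs with no valid path) carry
#' no log and are excluded; their count is recorded.
#'
#' @param scores Numeric vector of association scores of random pairs.
#' @param min_n Minimum number of positive scores required (default 30).
#' @return An object of class \code{slap_null}: list with \code{mu_log},
#'   \code{sigma_log}, \code{n} (positive scores used) and \code{n_zero}
#'   (excluded zero scores).
#' @export
fit_null_model <- function(scores, min_n = 30) {
  scores <- as.numeric(scores)
  pos <- scores[scores > 0]
  n_zero <- sum(scores <= 0)
  if (!length(pos)) stop("all scores are zero: cannot fit a null model",
                         call. = FALSE)
  if (length(pos) < min_n) {
    stop("only ", length(pos), " positive scores; need at least ", min_n,
         call. = FALSE)
  }
  lg <- log(pos)
  s <- stats::sd(lg)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate null: log scores have zero spread", call. = FALSE)
  }
  structure(list(mu_log = mean(lg), sigma_log = s, n = length(pos),
                 n_zero = n_zero),
            class = "slap_null")
}

#' @export
print.slap_null <- function(x, ...) {
  cat(sprintf(
    "Log-normal null: mu_log = %.4f, sigma_log = %.4f (n = %d, %d zero scores excluded)\n",
    x$mu_log, x$sigma_log, x$n, x$n_zero))
  invisible(x)
}

#' p-value of an association score under the random-pair null
#'
#' Upper-tail probability of \code{log(score)} under the fitted normal of
#' [fit_null_model()]: the chance of seeing at least this score for a random
#' pair. Strictly decreasing in the score. Scores \eqn{\le 0} (no valid
#' path) are assigned p-value 1 by convention.
#'
#' @param score Numeric vector of association scores.
#' @param null A \code{slap_null} object.
#' @return Numeric vector of p-values in (0, 1].
#' @export
p_value <- function(score, null) {
  stopifnot(inherits(null, "slap_null"))
  p <- rep(1, length(score))
  pos <- score > 0
  p[pos] <- stats::pnorm(log(score[pos]), mean = null$mu_log,
                         sd = null$sigma_log, lower.tail = FALSE)
  p
}

#' Association score at a given significance level
#'
#' The score whose [p_value()] equals \code{alpha}:
#' \code{exp(mu_log + qnorm(1 - alpha) * sigma_log)}. Inverse of
#' [p_value()]; strictly decreasing in \code{alpha}.
#'
#' @param null A \code{slap_null} object.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Positive score threshold.
#' @export
significance_threshold <- function(null, alpha = 0.05) {
  stopifnot(inherits(null, "slap_null"), alpha > 0, alpha < 1)
  exp(null$mu_log + stats::qnorm(alpha, lower.tail = FALSE) * null$sigma_log)
}
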