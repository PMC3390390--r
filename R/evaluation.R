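# Whole-method benchmarking: ranking metrics, topological baselines, and the
# decoy-ratio experiment.

#' Area under the ROC curve of a score ranking
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive
#' outscores a random negative, with ties counting 1/2. Shared by every
#' ranking evaluation in the package so tie handling is uniform.
#'
#' @param scores Numeric scores, higher = more strongly predicted positive.
#'   \code{-Inf} is allowed; \code{NA} is not.
#' @param labels Binary labels (1/TRUE = positive); both classes must be
#'   present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need both positive and negative labels", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC and precision-recall curves of a scored pair list
#'
#' Sweeps a threshold over the distinct score values (highest first),
#' recording the true/false positive rates and precision/recall at each. The
#' trapezoidal area under the ROC curve equals the Mann-Whitney [auroc()]
#' exactly, ties included.
#'
#' @param scores Numeric scores, higher = predicted positive.
#' @param labels Binary labels; both classes required.
#' @param method Optional method name stored with the run.
#' @return An object of class \code{slap_evaluation}: list with
#'   \code{method}, \code{auroc}, \code{n_pos}, \code{n_neg}, \code{ratio}
#'   (decoys per positive), \code{roc} (data frame \code{threshold},
#'   \code{fpr}, \code{tpr}) and \code{pr} (data frame \code{threshold},
#'   \code{recall}, \code{precision}).
#' @export
roc_pr <- function(scores, labels, method = "slap") {
  labels <- as.logical(labels)
  a <- auroc(scores, labels)    # validates input
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  cum_tp <- cumsum(l)
  cum_fp <- cumsum(!l)
  last <- rev(!duplicated(rev(s)))  # last index of each tie group
  tp <- cum_tp[last]; fp <- cum_fp[last]; thr <- s[last]
  roc <- data.frame(threshold = thr, fpr = fp / n_neg, tpr = tp / n_pos)
  pr <- data.frame(threshold = thr, recall = tp / n_pos,
                   precision = tp / (tp + fp))
  structure(list(method = method, auroc = a, n_pos = n_pos, n_neg = n_neg,
                 ratio = n_neg / n_pos, roc = roc, pr = pr),
            class = "slap_evaluation")
}

#' @export
print.slap_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation [%s]: AUROC %.4f (%d positives, %d decoys)\n",
              x$method, x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Plot ROC and precision-recall curves
#' @param x A \code{slap_evaluation}.
#' @param ... Passed to \code{plot}.
#' @export
plot.slap_evaluation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(c(0, x$roc$fpr, 1), c(0, x$roc$tpr, 1), type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUROC = %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  plot(x$pr$recall, x$pr$precision, type = "l", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "Recall", ylab = "Precision",
       main = sprintf("PR (%d:%d)", x$n_pos, x$n_neg), ...)
  invisible(x)
}

#' Precision at a given recall level
#'
#' Precision at the first threshold (sweeping from the highest score down)
#' whose recall reaches the requested level.
#'
#' @param evaluation A \code{slap_evaluation} from [roc_pr()].
#' @param recall Target recall in (0, 1]; default 0.7.
#' @return Precision in [0, 1].
#' @export
precision_at_recall <- function(evaluation, recall = 0.7) {
  pr <- evaluation$pr
  i <- which(pr$recall >= recall)
  if (!length(i)) return(NA_real_)
  pr$precision[min(i)]
}

#' Association scores for a list of pairs
#'
#' Applies [association_score()] with a fitted model's pattern statistics and
#' informative set to each pair. Pairs with an unmapped node or no path score
#' 0 and are flagged in the \code{status} column, never dropped.
#'
#' @param model A [slap_fit()] model.
#' @param pairs Data frame with columns \code{source}, \code{target}.
#' @param exclude_direct Remove the direct source-target edge(s) from every
#'   path before scoring (default TRUE, the missing-link setting).
#' @param graph Graph to score against; defaults to the graph stored in the
#'   model.
#' @return Data frame with columns \code{source}, \code{target},
#'   \code{score}, \code{p_value}, \code{n_valid}, \code{status}.
#' @export
score_pairs <- function(model, pairs, exclude_direct = TRUE, graph = NULL) {
  stopifnot(inherits(model, "slap_model"))
  g <- if (is.null(graph)) model$graph else graph
  if (is.null(g)) stop("model carries no graph; pass one via 'graph'",
                       call. = FALSE)
  n <- nrow(pairs)
  score <- numeric(n); n_valid <- integer(n); status <- character(n)
  for (i in seq_len(n)) {
    a <- association_score(g, pairs$source[i], pairs$target[i],
                           model$pattern_stats, model$informative,
                           exclude_direct = exclude_direct,
                           max_length = model$config$max_length)
    score[i] <- a$score; n_valid[i] <- a$n_valid; status[i] <- a$status
  }
  data.frame(source = pairs$source, target = pairs$target, score = score,
             p_value = p_value(score, model$null), n_valid = n_valid,
             status = status, stringsAsFactors = FALSE)
}

#' Simple topological baseline scores for a list of pairs
#'
#' The comparator statistics: \code{n_shortest_paths} counts only the
#' minimum-length paths of the pair; \code{n_valid_paths} counts paths with
#' z > 0 in informative patterns; \code{raw_sum}, \code{raw_max} and
#' \code{raw_mean} aggregate the raw scores of all paths. Pairs with no path
#' score 0 under every method.
#'
#' @param model A [slap_fit()] model.
#' @param pairs Data frame with columns \code{source}, \code{target}.
#' @param method One of \code{"n_shortest_paths"}, \code{"n_valid_paths"},
#'   \code{"raw_sum"}, \code{"raw_max"}, \code{"raw_mean"}.
#' @param exclude_direct As in [score_pairs()] (default TRUE).
#' @param graph Graph override, as in [score_pairs()].
#' @return Data frame with columns \code{source}, \code{target},
#'   \code{score}, \code{status}.
#' @export
baseline_scores <- function(model, pairs,
                            method = c("n_shortest_paths", "n_valid_paths",
                                       "raw_sum", "raw_max", "raw_mean"),
                            exclude_direct = TRUE, graph = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "slap_model"))
  g <- if (is.null(graph)) model$graph else graph
  if (is.null(g)) stop("model carries no graph; pass one via 'graph'",
                       call. = FALSE)
  n <- nrow(pairs)
  score <- numeric(n); status <- character(n)
  for (i in seq_len(n)) {
    a <- association_score(g, pairs$source[i], pairs$target[i],
                           model$pattern_stats, model$informative,
                           exclude_direct = exclude_direct,
                           max_length = model$config$max_length)
    status[i] <- a$status
    pd <- a$paths
    if (!nrow(pd)) { score[i] <- 0; next }
    score[i] <- switch(method,
      n_shortest_paths = sum(pd$length == min(pd$length)),
      n_valid_paths = sum(pd$valid),
      raw_sum = sum(pd$raw),
      raw_max = max(pd$raw),
      raw_mean = mean(pd$raw))
  }
  data.frame(source = pairs$source, target = pairs$target, score = score,
             status = status, stringsAsFactors = FALSE)
}

#' Decoy-ratio robustness experiment
#'
#' Evaluates the model on benchmarks whose decoy set is 1, 4, 8 and 12 times
#' (configurable) the size of the positive set. Decoys are drawn without
#' replacement from the model's source and target pools, excluding the
#' positives, and the decoy sets are nested across ratios (the 1:8 set
#' contains the 1:4 set), which couples the runs: the recall-threshold is
#' identical across ratios, so precision at fixed recall responds to the
#' class imbalance alone.
#'
#' @param model A [slap_fit()] model.
#' @param positives Data frame with columns \code{source}, \code{target}.
#' @param multipliers Integer decoy-to-positive ratios (default
#'   \code{c(1, 4, 8, 12)}).
#' @param seed Integer seed for decoy sampling.
#' @param exclude_direct As in [score_pairs()] (default TRUE).
#' @return Named list of \code{slap_evaluation} runs, one per multiplier.
#' @export
ratio_experiment <- function(model, positives, multipliers = c(1, 4, 8, 12),
                             seed = 1, exclude_direct = TRUE) {
  stopifnot(inherits(model, "slap_model"), nrow(positives) >= 1)
  n_pos <- nrow(positives)
  n_max <- max(multipliers) * n_pos
  decoys <- .sample_pairs(model$source_pool, model$target_pool, n_max, seed,
                          exclude_pairs = positives)
  pos_scores <- score_pairs(model, positives,
                            exclude_direct = exclude_direct)$score
  dec_scores <- score_pairs(model, decoys,
                            exclude_direct = exclude_direct)$score
  out <- lapply(multipliers, function(k) {
    nd <- k * n_pos
    roc_pr(c(pos_scores, dec_scores[seq_len(nd)]),
           c(rep(1L, n_pos), rep(0L, nd)),
           method = sprintf("slap 1:%d", k))
  })
  names(out) <- paste0("ratio_", multipliers)
  out
}
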