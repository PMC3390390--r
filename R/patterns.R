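# Pattern informativeness: standalone ability of each meta-path to separate
# known positive pairs from decoys.

#' Raw-score sum of a pair's paths within one pattern
#'
#' Sums the raw scores of all paths between the pair that carry the given
#' signature. Used to evaluate a pattern as a standalone predictor. A pair
#' with no matching path scores 0, with attribute \code{n_paths = 0}; a pair
#' with an unmapped node scores 0 with attribute \code{not_mapped = TRUE}.
#'
#' @param graph A [semantic_graph].
#' @param source,target Node ids.
#' @param signature Pattern signature string (see [pattern_signature()]).
#' @param max_length Maximum path length (default 3).
#' @return A single number with attributes \code{n_paths} and
#'   \code{not_mapped}.
#' @export
pattern_pair_score <- function(graph, source, target, signature,
                               max_length = 3) {
  paths <- enumerate_paths(graph, source, target, max_length = max_length)
  if (identical(attr(paths, "status"), "not_mapped")) {
    return(structure(0, n_paths = 0L, not_mapped = TRUE))
  }
  if (length(paths)) {
    sig <- vapply(paths, function(p) pattern_signature(p, graph), character(1))
    paths <- paths[sig == signature]
  }
  if (!length(paths)) return(structure(0, n_paths = 0L, not_mapped = FALSE))
  raw <- vapply(paths, function(p) raw_path_score(p, graph), numeric(1))
  structure(sum(raw), n_paths = length(raw), not_mapped = FALSE)
}

#' Standalone AUROC of one pattern on a positive/decoy benchmark
#'
#' Scores every pair with [pattern_pair_score()] and computes the AUROC of
#' ranking positives above decoys. The pattern score is a sum of path
#' log-probabilities, so its magnitude grows with the amount of matching-path
#' evidence between the pair; ranking therefore uses the magnitude of the
#' score, with 0 (no matching path, hence no evidence) the weakest possible
#' value. Ties (including ties among the path-less pairs) contribute 1/2,
#' the Mann-Whitney convention.
#'
#' @param graph A [semantic_graph].
#' @param signature Pattern signature.
#' @param positives,decoys Data frames with columns \code{source},
#'   \code{target}; both non-empty.
#' @param max_length Maximum path length (default 3).
#' @return AUROC in [0, 1].
#' @export
pattern_auroc <- function(graph, signature, positives, decoys,
                          max_length = 3) {
  if (!nrow(positives) || !nrow(decoys)) {
    stop("both positives and decoys must be non-empty", call. = FALSE)
  }
  pairs <- rbind(positives[c("source", "target")],
                 decoys[c("source", "target")])
  labels <- c(rep(1L, nrow(positives)), rep(0L, nrow(decoys)))
  strength <- .pattern_strengths(graph, pairs, signature,
                                 max_length = max_length)[, 1L]
  auroc(strength, labels)
}

# Batched pattern-evidence strengths: one path enumeration per pair, then
# per-signature |sum of raw scores|. Returns a |pairs| x |signatures| matrix.
.pattern_strengths <- function(graph, pairs, signatures, max_length = 3) {
  out <- matrix(0, nrow = nrow(pairs), ncol = length(signatures),
                dimnames = list(NULL, signatures))
  for (i in seq_len(nrow(pairs))) {
    paths <- enumerate_paths(graph, pairs$source[i], pairs$target[i],
                             max_length = max_length)
    if (!length(paths)) next
    sc <- .score_paths(graph, paths)
    keep <- sc$signature %in% signatures
    if (!any(keep)) next
    sums <- tapply(sc$raw[keep], sc$signature[keep], sum)
    out[i, names(sums)] <- abs(sums)
  }
  out
}

#' Evaluate every pattern's standalone AUROC on one or more benchmarks
#'
#' @param graph A [semantic_graph].
#' @param signatures Character vector of pattern signatures (typically the
#'   usable patterns of a \code{slap_pattern_stats} fit).
#' @param benchmarks A list of benchmarks, each a list with elements
#'   \code{positives} and \code{decoys} (data frames with \code{source},
#'   \code{target}). One or two benchmarks are typical.
#' @param max_length Maximum path length (default 3).
#' @param threshold Informativeness threshold on AUROC (default 0.55): a
#'   pattern is flagged uninformative only when its AUROC is at or below the
#'   threshold on every supplied benchmark.
#' @return An object of class \code{slap_pattern_report}: a data frame with
#'   \code{signature}, one \code{auroc_<k>} column per benchmark and an
#'   \code{informative} flag.
#' @export
pattern_reports <- function(graph, signatures, benchmarks, max_length = 3,
                            threshold = 0.55) {
  stopifnot(is.list(benchmarks), length(benchmarks) >= 1)
  auc <- matrix(NA_real_, nrow = length(signatures),
                ncol = length(benchmarks))
  for (k in seq_along(benchmarks)) {
    b <- benchmarks[[k]]
    if (!nrow(b$positives) || !nrow(b$decoys)) {
      stop("benchmark ", k, " has an empty class", call. = FALSE)
    }
    pairs <- rbind(b$positives[c("source", "target")],
                   b$decoys[c("source", "target")])
    labels <- c(rep(1L, nrow(b$positives)), rep(0L, nrow(b$decoys)))
    strengths <- .pattern_strengths(graph, pairs, signatures,
                                    max_length = max_length)
    auc[, k] <- apply(strengths, 2L, auroc, labels = labels)
  }
  out <- data.frame(signature = signatures, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(auc))) out[[paste0("auroc_", k)]] <- auc[, k]
  out$informative <- apply(auc > threshold, 1L, any)
  attr(out, "threshold") <- threshold
  class(out) <- c("slap_pattern_report", "data.frame")
  out
}

#' Informative pattern signatures from a pattern report
#'
#' A pattern is removed only when its AUROC is at or below the threshold on
#' every supplied benchmark (removal requires agreement across benchmarks);
#' all others are retained. Monotone in the threshold: raising it never adds
#' a pattern.
#'
#' @param reports A \code{slap_pattern_report} from [pattern_reports()].
#' @param threshold AUROC threshold; defaults to the one stored in the
#'   report.
#' @return Character vector of retained (informative) signatures.
#' @export
select_informative <- function(reports, threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(reports, "threshold")
  auc_cols <- grep("^auroc_", names(reports), value = TRUE)
  if (!length(auc_cols)) stop("report has no AUROC columns", call. = FALSE)
  auc <- as.matrix(reports[auc_cols])
  keep <- apply(auc > threshold, 1L, any)
  reports$signature[keep]
}
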