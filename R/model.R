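#' Fit a semantic link association model
#'
#' The model has three fitted components, estimated in sequence from the
#' graph:
#' \enumerate{
#'   \item \emph{Pattern statistics}: \code{n_pairs} random source-target
#'     pairs are sampled (excluding known positives), every path of length at
#'     most \code{max_length} between them is scored with
#'     [raw_path_score()], and each path pattern's raw scores are fitted to a
#'     normal distribution ([fit_pattern_stats()]).
#'   \item \emph{Informative patterns}: when a positive pair list is
#'     supplied, each usable pattern is evaluated as a standalone predictor
#'     against one or more positive/decoy benchmarks and patterns whose
#'     AUROC stays at or below \code{pattern_threshold} on every benchmark
#'     are removed ([pattern_reports()], [select_informative()]).
#'   \item \emph{Null model}: \code{n_null} fresh random pairs are scored
#'     with [association_score()] and the natural logs of the positive
#'     scores are fitted to a normal distribution ([fit_null_model()]),
#'     giving p-values for any future score.
#' }
#'
#' @param graph A [semantic_graph].
#' @param source_pool,target_pool Candidate node ids for random sampling;
#'   default to all nodes of class \code{"Compound"} and \code{"Target"}.
#' @param positives Optional data frame of known positive pairs
#'   (\code{source}, \code{target}); used both to exclude them from random
#'   sampling and to build the default pattern benchmark.
#' @param benchmarks Optional list of pattern benchmarks, each a list with
#'   \code{positives} and \code{decoys} data frames. When \code{NULL} and
#'   \code{positives} is given, one benchmark is built from the positives and
#'   an equal number of seeded decoys. When no benchmark is available every
#'   usable pattern is kept.
#' @param n_pairs Random pairs for the pattern-statistics fit (default 1000).
#' @param n_null Random pairs for the null fit (default 500).
#' @param seed Integer seed controlling all sampling; the fit is
#'   deterministic given it.
#' @param max_length Maximum path length (default 3).
#' @param pattern_threshold AUROC threshold for pattern informativeness
#'   (default 0.55).
#' @param min_pattern_n Minimum sampled paths for a usable pattern
#'   (default 30).
#' @param null_exclude_direct Whether null-pair scoring removes direct edges
#'   (default FALSE; random pairs essentially never have one).
#' @return An object of class \code{slap_model}: list with
#'   \code{pattern_stats}, \code{pattern_report} (or NULL),
#'   \code{informative} (character), \code{null} (a \code{slap_null}),
#'   \code{null_scores} / \code{null_pairs} (the random pairs and
#'   association scores behind the null fit), \code{source_pool},
#'   \code{target_pool}, \code{graph} and \code{config}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{plot}.
#' @examples
#' \donttest{
#' bundle <- synth_generate(synth_config(seed = 1))
#' bench <- benchmark_from(bundle, decoy_multiplier = 1, seed = 2)
#' fit <- slap_fit(bundle$graph, positives = bundle$positives,
#'                 n_pairs = 300, n_null = 200, seed = 3)
#' predict(fit, utils::head(bundle$positives))
#' }
#' @export
slap_fit <- function(graph, source_pool = NULL, target_pool = NULL,
                     positives = NULL, benchmarks = NULL,
                     n_pairs = 1000, n_null = 500, seed = 1,
                     max_length = 3, pattern_threshold = 0.55,
                     min_pattern_n = 30, null_exclude_direct = FALSE) {
  stopifnot(inherits(graph, "semantic_graph"))
  if (is.null(source_pool)) {
    source_pool <- names(graph$nodes)[graph$nodes == "Compound"]
  }
  if (is.null(target_pool)) {
    target_pool <- names(graph$nodes)[graph$nodes == "Target"]
  }
  if (!length(source_pool) || !length(target_pool)) {
    stop("empty source or target pool; pass source_pool/target_pool",
         call. = FALSE)
  }
  seed <- as.integer(seed)

  stats <- fit_pattern_stats(graph, source_pool, target_pool, n_pairs,
                             seed = seed, max_length = max_length,
                             exclude_pairs = positives,
                             min_n = min_pattern_n)
  usable_sigs <- stats$signature[stats$usable]

  report <- NULL
  if (is.null(benchmarks) && !is.null(positives) && nrow(positives) > 0) {
    dec <- .sample_pairs(source_pool, target_pool, nrow(positives),
                         seed + 1L, exclude_pairs = positives)
    benchmarks <- list(list(positives = positives, decoys = dec))
  }
  if (!is.null(benchmarks) && length(usable_sigs)) {
    report <- pattern_reports(graph, usable_sigs, benchmarks,
                              max_length = max_length,
                              threshold = pattern_threshold)
    informative <- select_informative(report)
  } else {
    informative <- usable_sigs
  }

  null_pairs <- .sample_pairs(source_pool, target_pool, n_null, seed + 2L,
                              exclude_pairs = positives)
  null_scores <- vapply(seq_len(nrow(null_pairs)), function(i) {
    association_score(graph, null_pairs$source[i], null_pairs$target[i],
                      stats, informative,
                      exclude_direct = null_exclude_direct,
                      max_length = max_length)$score
  }, numeric(1))
  null <- fit_null_model(null_scores)

  structure(list(pattern_stats = stats,
                 pattern_report = report,
                 informative = informative,
                 null = null,
                 null_scores = null_scores,
                 null_pairs = null_pairs,
                 source_pool = sort(source_pool),
                 target_pool = sort(target_pool),
                 graph = graph,
                 config = list(n_pairs = n_pairs, n_null = n_null,
                               seed = seed, max_length = max_length,
                               pattern_threshold = pattern_threshold,
                               min_pattern_n = min_pattern_n,
                               null_exclude_direct = null_exclude_direct)),
            class = "slap_model")
}

#' @export
print.slap_model <- function(x, ...) {
  st <- x$pattern_stats
  cat("Semantic link association model\n")
  cat(sprintf("  patterns: %d fitted, %d usable, %d informative\n",
              nrow(st), sum(st$usable), length(x$informative)))
  cat(sprintf("  null: log-normal mu = %.3f, sigma = %.3f (n = %d)\n",
              x$null$mu_log, x$null$sigma_log, x$null$n))
  cat(sprintf("  sampling: %d pattern pairs, %d null pairs, seed %d, max path length %d\n",
              x$config$n_pairs, x$config$n_null, x$config$seed,
              x$config$max_length))
  invisible(x)
}

#' @export
summary.slap_model <- function(object, ...) {
  out <- list(pattern_stats = object$pattern_stats,
              pattern_report = object$pattern_report,
              informative = object$informative,
              null = object$null,
              threshold_05 = significance_threshold(object$null, 0.05),
              config = object$config)
  class(out) <- "summary.slap_model"
  out
}

#' @export
print.summary.slap_model <- function(x, ...) {
  cat("Pattern raw-score fits:\n")
  print.data.frame(x$pattern_stats)
  if (!is.null(x$pattern_report)) {
    cat("\nPattern standalone AUROC (threshold ",
        attr(x$pattern_report, "threshold"), "):\n", sep = "")
    print.data.frame(x$pattern_report)
  }
  cat("\n"); print(x$null)
  cat(sprintf("score threshold at p = 0.05: %.3f\n", x$threshold_05))
  invisible(x)
}

#' Pattern-level coefficients of a fitted model
#'
#' @param object A \code{slap_model}.
#' @param ... Unused.
#' @return Data frame of per-pattern fitted mean, standard deviation, sample
#'   size, usability and informativeness.
#' @export
coef.slap_model <- function(object, ...) {
  st <- as.data.frame(object$pattern_stats)
  st$informative <- st$signature %in% object$informative
  st
}

#' Score drug-target pairs with a fitted model
#'
#' @param object A \code{slap_model}.
#' @param pairs Data frame with columns \code{source}, \code{target}.
#' @param exclude_direct Remove direct edges before scoring (default TRUE).
#' @param graph Graph override (needed when the model was deserialized
#'   without its graph).
#' @param ... Unused.
#' @return Data frame with \code{source}, \code{target}, \code{score},
#'   \code{p_value}, \code{n_valid}, \code{status}.
#' @export
predict.slap_model <- function(object, pairs, exclude_direct = TRUE,
                               graph = NULL, ...) {
  score_pairs(object, pairs, exclude_direct = exclude_direct, graph = graph)
}

#' Plot the fitted random-pair null
#'
#' Histogram of the log association scores of the random pairs behind the
#' null fit, with the fitted normal density overlaid.
#'
#' @param x A \code{slap_model}.
#' @param ... Passed to \code{hist}.
#' @export
plot.slap_model <- function(x, ...) {
  lg <- log(x$null_scores[x$null_scores > 0])
  graphics::hist(lg, freq = FALSE, xlab = "log association score",
                 main = "Random-pair null", ...)
  xs <- seq(min(lg), max(lg), length.out = 200)
  graphics::lines(xs, stats::dnorm(xs, x$null$mu_log, x$null$sigma_log),
                  col = "red3", lwd = 2)
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes every fitted component (pattern statistics, pattern report,
#' informative set, null fit, pools, configuration) to a versioned JSON
#' file. The graph itself is not serialized; re-supply it to
#' [predict.slap_model()] via the \code{graph} argument after reading the
#' model back.
#'
#' @param model A \code{slap_model}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_slap_model <- function(model, path) {
  stopifnot(inherits(model, "slap_model"))
  payload <- list(
    format = "slapr-model",
    version = 1L,
    pattern_stats = as.data.frame(model$pattern_stats),
    pattern_stats_meta = attributes(model$pattern_stats)[
      c("n_pairs", "n_pairs_with_paths", "n_paths", "seed", "max_length",
        "min_n", "sigma_tol")],
    pattern_report = if (is.null(model$pattern_report)) NULL else
      as.data.frame(model$pattern_report),
    pattern_report_threshold = if (is.null(model$pattern_report)) NULL else
      attr(model$pattern_report, "threshold"),
    informative = model$informative,
    null = unclass(model$null),
    null_scores = model$null_scores,
    null_pairs = model$null_pairs,
    source_pool = model$source_pool,
    target_pool = model$target_pool,
    config = model$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path Path written by [write_slap_model()].
#' @return A \code{slap_model} with \code{graph = NULL}; pass a graph to
#'   [predict.slap_model()] when scoring.
#' @export
read_slap_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
    stop("cannot read model file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!identical(payload$format, "slapr-model")) {
    stop("not a slapr model file: ", path, call. = FALSE)
  }
  if (!identical(as.integer(payload$version), 1L)) {
    stop("unsupported model format version: ", payload$version,
         call. = FALSE)
  }
  st <- payload$pattern_stats
  meta <- payload$pattern_stats_meta
  stats <- structure(st, class = c("slap_pattern_stats", "data.frame"),
                     n_pairs = meta$n_pairs,
                     n_pairs_with_paths = meta$n_pairs_with_paths,
                     n_paths = meta$n_paths, seed = meta$seed,
                     max_length = meta$max_length, min_n = meta$min_n,
                     sigma_tol = meta$sigma_tol)
  report <- NULL
  if (!is.null(payload$pattern_report)) {
    report <- payload$pattern_report
    attr(report, "threshold") <- payload$pattern_report_threshold
    class(report) <- c("slap_pattern_report", "data.frame")
  }
  null <- structure(payload$null, class = "slap_null")
  structure(list(pattern_stats = stats,
                 pattern_report = report,
                 informative = as.character(payload$informative),
                 null = null,
                 null_scores = as.numeric(payload$null_scores),
                 null_pairs = payload$null_pairs,
                 source_pool = as.character(payload$source_pool),
                 target_pool = as.character(payload$target_pool),
                 graph = NULL,
                 config = payload$config),
            class = "slap_model")
}
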