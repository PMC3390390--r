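test_that("raw path scores match hand-computed log-probabilities", {
  # single edge, both endpoints bind-degree 1: probability 1 both ways
  g1 <- tiny_graph(edge_df("D1", "bind", "T1"))
  p1 <- enumerate_paths(g1, "D1", "T1")[[1]]
  expect_equal(raw_path_score(p1, g1), 0, tolerance = 1e-12)

  # D1-T1-D2 via bind where T1 has 3 bind neighbors: both directions
  # traverse (1/1)(1/3), so the average log-probability is log(1/3)
  g2 <- tiny_graph(edge_df("D1", "bind", "T1", "D2", "bind", "T1",
                           "D3", "bind", "T1"))
  p2 <- enumerate_paths(g2, "D1", "D2", max_length = 2)[[1]]
  expect_equal(raw_path_score(p2, g2), log(1 / 3), tolerance = 1e-12)

  # 3-step chain with every traversal degree 2: (1/2)^3 both ways
  g3 <- tiny_graph(edge_df("D1", "bind", "T1", "D1", "bind", "T9",
                           "T1", "bind", "D2",
                           "D2", "bind", "T2",
                           "T2", "bind", "D8"))
  p3 <- enumerate_paths(g3, "D1", "T2", max_length = 3)
  chain <- Filter(function(p) identical(p$nodes, c("D1", "T1", "D2", "T2")),
                  p3)
  expect_length(chain, 1)
  expect_equal(raw_path_score(chain[[1]], g3), -log(8), tolerance = 1e-12)
})

test_that("raw scores are non-positive and direction-symmetric", {
  for (seed in c(2, 14)) {
    g <- random_typed_graph(seed, n_nodes = 30, n_edges = 80)
    cs <- names(g$nodes)[g$nodes == "Compound"]
    ts <- names(g$nodes)[g$nodes == "Target"]
    paths <- enumerate_paths(g, cs[1], ts[1])
    for (p in paths) {
      r <- raw_path_score(p, g)
      expect_lte(r, 0)
      expect_equal(raw_path_score(reverse_path(p), g), r,
                   tolerance = 1e-12)
    }
  }
})

test_that("pattern statistics are seeded, deterministic and oracle-consistent", {
  g <- random_typed_graph(21, n_nodes = 40, n_edges = 150)
  cs <- names(g$nodes)[g$nodes == "Compound"]
  ts <- names(g$nodes)[g$nodes == "Target"]
  st1 <- fit_pattern_stats(g, cs, ts, n_pairs = 80, seed = 5, min_n = 5)
  st2 <- fit_pattern_stats(g, cs, ts, n_pairs = 80, seed = 5, min_n = 5)
  expect_identical(as.data.frame(st1), as.data.frame(st2))

  # independent recomputation of per-pattern mean/sd from the same pairs
  pairs <- slapr:::.sample_pairs(cs, ts, 80, 5)
  sig_all <- character(0); raw_all <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    paths <- enumerate_paths(g, pairs$source[i], pairs$target[i])
    for (p in paths) {
      sig_all <- c(sig_all, pattern_signature(p, g))
      raw_all <- c(raw_all, raw_path_score(p, g))
    }
  }
  for (k in seq_len(nrow(st1))) {
    sel <- sig_all == st1$signature[k]
    expect_equal(sum(sel), st1$n[k])
    expect_equal(mean(raw_all[sel]), st1$mu[k], tolerance = 1e-12)
    if (sum(sel) > 1) {
      expect_equal(sd(raw_all[sel]), st1$sigma[k], tolerance = 1e-12)
    }
  }

  # a pattern whose scores are constant is unusable (sigma 0)
  expect_true(all(!st1$usable[st1$sigma < 1e-9]))
  # requesting more pairs than the pool holds errors
  expect_error(fit_pattern_stats(g, cs[1:2], ts[1:2], n_pairs = 100,
                                 seed = 1), "pool too small")
})

test_that("z scores standardize raw scores within their pattern", {
  st <- data.frame(signature = c("A", "B"), mu = c(-5, -2),
                   sigma = c(2, 0), n = c(50L, 40L),
                   usable = c(TRUE, FALSE))
  class(st) <- c("slap_pattern_stats", "data.frame")
  expect_equal(path_z_score(-5, st, "A"), 0)
  expect_equal(path_z_score(-3, st, "A"), 1)
  expect_equal(path_z_score(-9, st, "A"), -2)
  expect_error(path_z_score(-2, st, "B"), "not usable")
  expect_error(path_z_score(-2, st, "C"), "unknown pattern")
})

test_that("association scores sum positive z of informative patterns only", {
  # three parallel length-2 routes, each a distinct pattern
  g <- tiny_graph(edge_df("D1", "bind", "T9", "T9", "PPI", "T1",
                          "D1", "express", "T8", "T8", "PPI", "T1",
                          "D1", "bind", "T7", "T7", "bind", "D9",
                          "D9", "bind", "T1", "D9", "express", "T1"))
  paths <- enumerate_paths(g, "D1", "T1")
  sigs <- vapply(paths, function(p) pattern_signature(p, g), character(1))
  raws <- vapply(paths, function(p) raw_path_score(p, g), numeric(1))
  usigs <- unique(sigs)
  # craft stats so the first path of each pattern has z = 2, -1, 0.5, ...
  zwant <- c(2, -1, 0.5, -3, -3)[seq_along(usigs)]
  st <- data.frame(signature = usigs,
                   mu = raws[match(usigs, sigs)] - zwant,
                   sigma = 1, n = 50L, usable = TRUE,
                   stringsAsFactors = FALSE)
  class(st) <- c("slap_pattern_stats", "data.frame")

  res <- association_score(g, "D1", "T1", st, informative = usigs,
                           exclude_direct = FALSE)
  zs <- res$paths$z[res$paths$valid]
  expect_true(all(zs > 0))
  expect_equal(res$score, sum(res$paths$z[res$paths$z > 0]))
  expect_equal(res$status, "scored")

  # dropping the z = 2 pattern from the informative set removes its paths
  drop_sig <- usigs[zwant == 2]
  res2 <- association_score(g, "D1", "T1", st,
                            informative = setdiff(usigs, drop_sig),
                            exclude_direct = FALSE)
  expect_equal(res2$score, res$score - sum(
    res$paths$z[res$paths$valid & res$paths$signature == drop_sig]))

  # pairs without paths or not in the graph are flagged, not errors
  g_np <- tiny_graph(edge_df("D1", "bind", "T1", "D2", "bind", "T2"))
  expect_equal(association_score(g_np, "D1", "T2", st, usigs)$status,
               "no_paths")
  # a pair connected only by its direct edge scores 0 when it is excluded
  direct <- association_score(g_np, "D1", "T1", st, usigs,
                              exclude_direct = TRUE)
  expect_equal(direct$score, 0)
  expect_equal(direct$status, "no_paths")
  nm <- association_score(g, "D1", "T99", st, usigs)
  expect_equal(nm$status, "not_mapped")
  expect_equal(nm$score, 0)
})

test_that("z scores are invariant to the logarithm base", {
  g <- random_typed_graph(31, n_nodes = 40, n_edges = 150)
  cs <- names(g$nodes)[g$nodes == "Compound"]
  ts <- names(g$nodes)[g$nodes == "Target"]
  st <- fit_pattern_stats(g, cs, ts, n_pairs = 60, seed = 9, min_n = 5)
  k <- 1 / log(10)      # natural log -> log10 rescales every raw score
  pairs <- slapr:::.sample_pairs(cs, ts, 10, 77)
  for (i in seq_len(nrow(pairs))) {
    paths <- enumerate_paths(g, pairs$source[i], pairs$target[i])
    for (p in paths) {
      sig <- pattern_signature(p, g)
      j <- match(sig, st$signature)
      if (is.na(j) || !st$usable[j]) next
      z_nat <- path_z_score(raw_path_score(p, g), st, sig)
      z_b10 <- (k * raw_path_score(p, g) - k * st$mu[j]) / (k * st$sigma[j])
      expect_equal(z_b10, z_nat, tolerance = 1e-9)
    }
  }
})

test_that("the null model fits logs of positive scores and excludes zeros", {
  set.seed(4)
  draws <- exp(rnorm(10000, mean = 3, sd = 0.5))
  null <- fit_null_model(draws)
  expect_equal(null$mu_log, 3, tolerance = 0.02)
  expect_equal(null$sigma_log, 0.5, tolerance = 0.02)

  with_zeros <- c(draws[1:100], rep(0, 25))
  null2 <- fit_null_model(with_zeros)
  expect_equal(null2$n, 100)
  expect_equal(null2$n_zero, 25)

  expect_error(fit_null_model(rep(0, 50)), "all scores are zero")
  expect_error(fit_null_model(rep(exp(1), 100)), "zero spread")
  expect_error(fit_null_model(draws[1:10]), "at least")
})

test_that("p-values invert the score scale exactly and monotonically", {
  null <- structure(list(mu_log = 1.2, sigma_log = 0.6, n = 500L,
                         n_zero = 10L), class = "slap_null")
  expect_equal(p_value(exp(null$mu_log), null), 0.5, tolerance = 1e-12)
  expect_equal(p_value(exp(null$mu_log + qnorm(0.95) * null$sigma_log),
                       null), 0.05, tolerance = 1e-9)
  expect_equal(p_value(0, null), 1)
  expect_equal(p_value(-3, null), 1)

  s <- sort(exp(rnorm(50, 1.2, 2)))
  expect_true(all(diff(p_value(s, null)) < 0))

  for (a in c(0.01, 0.05, 0.1)) {
    expect_equal(p_value(significance_threshold(null, a), null), a,
                 tolerance = 1e-9)
  }
  thr <- vapply(c(0.01, 0.05, 0.1, 0.5, 0.9), significance_threshold,
                numeric(1), null = null)
  expect_true(all(diff(thr) < 0))
  expect_equal(significance_threshold(null, 0.5), exp(null$mu_log))
})
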