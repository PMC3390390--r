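# Fitted model on a group-structured bundle, shared across profile tests.
profile_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pb <- synth_profile_groups(seed = 3, drugs_per_group = 4,
                                 targets_per_group = 5)
      fit <- slap_fit(pb$graph, positives = pb$positives, n_pairs = 200,
                      n_null = 150, seed = 30)
      cache <<- list(pb = pb, fit = fit)
    }
    cache
  }
})

test_that("score matrices are complete, consistent and flag unmapped drugs", {
  fx <- profile_fixture()
  drugs <- c(names(fx$pb$groups)[1:2], "UNKNOWN")
  targets <- fx$pb$targets[1:3]
  m <- build_score_matrix(fx$fit, drugs, targets)
  expect_equal(dim(m$score), c(3, 3))
  expect_true(all(m$score >= 0))
  expect_true(all(m$score[3, ] == 0))
  expect_true(all(m$status[3, ] == "not_mapped"))

  # cells equal single-pair association_score calls
  for (d in drugs[1:2]) for (t in targets) {
    a <- association_score(fx$pb$graph, d, t, fx$fit$pattern_stats,
                           fx$fit$informative, exclude_direct = FALSE)
    expect_equal(m$score[d, t], a$score, tolerance = 1e-12)
  }
  expect_error(build_score_matrix(fx$fit, character(0), targets),
               "non-empty")
})

test_that("significance filtering drops weak rows/columns and is idempotent", {
  null <- structure(list(mu_log = 0, sigma_log = 1, n = 100L, n_zero = 0L),
                    class = "slap_null")
  thr <- significance_threshold(null, 0.05)
  sc <- rbind(c(thr + 1, 0.1, 0.2),
              c(0.3, thr + 2, 0.1),
              c(0.1, 0.2, 0.3))    # row 3 and column 3 always weak
  m <- structure(list(score = matrix(sc, 3, 3,
                                     dimnames = list(paste0("d", 1:3),
                                                     paste0("t", 1:3))),
                      status = matrix("scored", 3, 3)),
                 class = "slap_score_matrix")
  f1 <- filter_matrix(m, null, alpha = 0.05, mode = "both")
  expect_equal(rownames(f1$score), c("d1", "d2"))
  expect_equal(colnames(f1$score), c("t1", "t2"))
  f2 <- filter_matrix(f1, null, alpha = 0.05, mode = "both")
  expect_identical(f1$score, f2$score)

  frow <- filter_matrix(m, null, alpha = 0.05, mode = "rows")
  expect_equal(ncol(frow$score), 3)
  expect_equal(nrow(frow$score), 2)

  strict <- structure(list(score = matrix(0.01, 2, 2,
                                          dimnames = list(c("a", "b"),
                                                          c("x", "y"))),
                           status = matrix("scored", 2, 2)),
                      class = "slap_score_matrix")
  expect_error(filter_matrix(strict, null, alpha = 0.05), "removed every")
})

test_that("profile similarity is Pearson correlation with NA propagation", {
  sc <- rbind(a = c(1, 2, 3, 4),
              b = c(2, 4, 6, 8),     # identical shape to a -> r = 1
              c = c(4, 3, 2, 1),     # exact negation of the trend -> r = -1
              d = c(5, 5, 5, 5))     # zero variance -> undefined
  m <- structure(list(score = sc, status = matrix("scored", 4, 4)),
                 class = "slap_score_matrix")
  sim <- profile_similarity(m)
  expect_equal(sim["a", "b"], 1, tolerance = 1e-12)
  expect_equal(sim["a", "c"], -1, tolerance = 1e-12)
  expect_true(all(is.na(sim["d", c("a", "b", "c")])))
  expect_equal(diag(sim), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(sim, t(sim))

  # matches a textbook two-pass covariance computation
  set.seed(8)
  rsc <- matrix(rnorm(60), nrow = 6,
                dimnames = list(paste0("d", 1:6), paste0("t", 1:10)))
  rm <- structure(list(score = rsc, status = matrix("scored", 6, 10)),
                  class = "slap_score_matrix")
  rsim <- profile_similarity(rm)
  for (i in 1:5) for (j in (i + 1):6) {
    x <- rsc[i, ]; y <- rsc[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(rsim[i, j], r, tolerance = 1e-12)
  }
})

test_that("similarity networks threshold edges and keep isolated drugs", {
  sim <- rbind(c(1, 0.9, 0.1), c(0.9, 1, 0.2), c(0.1, 0.2, 1))
  dimnames(sim) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- build_similarity_network(sim, threshold = 0.75,
                                  annotations = c(a = "x", b = "y",
                                                  c = "z"))
  expect_equal(igraph::vcount(net), 3)       # isolated node retained
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::E(net)$weight, 0.9)
  expect_equal(igraph::V(net)$annotation, c("x", "y", "z"))

  empty <- build_similarity_network(sim, threshold = 0.95)
  expect_equal(igraph::ecount(empty), 0)
  complete <- build_similarity_network(sim, threshold = -1)
  expect_equal(igraph::ecount(complete), 3)
})

test_that("similar-drug queries rank by correlation and ignore row order", {
  sc <- rbind(q = c(1, 5, 2, 7), dup = c(2, 10, 4, 14),
              other = c(7, 2, 5, 1), flat = c(1, 1, 1, 1))
  m <- structure(list(score = sc, status = matrix("scored", 4, 4)),
                 class = "slap_score_matrix")
  res <- query_similar(m, "q", top_k = 10)
  expect_equal(res$drug[1], "dup")
  expect_equal(res$similarity[1], 1, tolerance = 1e-12)
  expect_false("flat" %in% res$drug)         # undefined similarity omitted
  expect_equal(nrow(res), 2)                 # top_k larger than library

  perm <- structure(list(score = sc[c(3, 1, 4, 2), ],
                         status = matrix("scored", 4, 4)),
                    class = "slap_score_matrix")
  expect_equal(query_similar(perm, "q", top_k = 10), res)
  expect_error(query_similar(m, "nope"), "unknown drug")
})

test_that("matrix and network exports round-trip through files", {
  fx <- profile_fixture()
  drugs <- names(fx$pb$groups)[1:4]
  m <- build_score_matrix(fx$fit, drugs, fx$pb$targets[1:6])
  wide <- withr::local_tempfile(fileext = ".tsv")
  long <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(m, wide, long, null = fx$fit$null)
  w <- utils::read.delim(wide, check.names = FALSE)
  expect_equal(dim(w), c(4, 7))
  l <- utils::read.delim(long)
  expect_equal(nrow(l), 24)
  expect_true(all(c("drug", "target", "score", "p_value", "status") %in%
                    names(l)))
  i <- which(l$drug == drugs[2] & l$target == fx$pb$targets[3])
  expect_equal(l$score[i], m$score[drugs[2], fx$pb$targets[3]],
               tolerance = 1e-6)

  sim <- profile_similarity(m)
  net <- build_similarity_network(sim, threshold = -1)
  ef <- withr::local_tempfile(fileext = ".tsv")
  gf <- withr::local_tempfile(fileext = ".graphml")
  write_similarity_network(net, ef, gf)
  back <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::vcount(back), 4)       # node count = drug count
  el <- utils::read.delim(ef)
  expect_equal(nrow(el), igraph::ecount(net))
})

test_that("the adjusted Rand index agrees with the mclust implementation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  skip_if_not_installed("mclust")
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("profile similarity separates shared-profile from shared-structure drugs", {
  # two drugs with identical substructures but different wired targets:
  # structural columns coincide while profile similarity stays low
  fx <- profile_fixture()
  pb <- fx$pb
  g1 <- names(pb$groups)[pb$groups == "group1"][1]
  g2 <- names(pb$groups)[pb$groups == "group2"][1]
  m <- build_score_matrix(fx$fit, c(g1, g2), pb$targets)
  r <- suppressWarnings(stats::cor(m$score[1, ], m$score[2, ]))
  within <- names(pb$groups)[pb$groups == "group1"][2]
  mw <- build_score_matrix(fx$fit, c(g1, within), pb$targets)
  rw <- suppressWarnings(stats::cor(mw$score[1, ], mw$score[2, ]))
  expect_lt(r, rw)   # same-group profiles more similar than cross-group
})
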