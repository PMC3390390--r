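test_that("schema construction validates classes, types and duplicates", {
  sc <- slap_schema(c("Compound", "Target"),
                    list(bind = c("Compound", "Target")))
  expect_s3_class(sc, "slap_schema")
  expect_length(sc$node_classes, 2)
  expect_length(sc$edge_types, 1)

  expect_error(slap_schema(c("A", "A"), list(x = c("A", "A"))), "duplicate")
  expect_error(slap_schema("A", list(x = c("A", "B"))), "undeclared")
  expect_error(slap_schema("A", list(x = "A")), "exactly two")
})

test_that("schema files round-trip through YAML and reject malformed input", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("node_classes: [Compound, Target, GOTerm]",
               "edge_types:",
               "  bind: [Compound, Target]",
               "  hasGO: [Target, GOTerm]"), f)
  sc <- read_schema(f)
  expect_setequal(sc$node_classes, c("Compound", "Target", "GOTerm"))

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("node_classes: [Compound, Target]",
               "edge_types:",
               "  hasGO: [Target, GOTerm]"), bad)
  expect_error(read_schema(bad), "hasGO")
  writeLines("node_classes: [A", bad)
  expect_error(read_schema(bad), "parse")
})

test_that("bundled default schema declares 10 node classes and 12 edge types", {
  sc <- default_schema()
  expect_length(sc$node_classes, 10)
  expect_length(sc$edge_types, 12)
  for (ty in names(sc$edge_types)) {
    expect_true(all(sc$edge_types[[ty]] %in% sc$node_classes))
  }
})

test_that("graph loading validates, collapses duplicates and drops self-loops", {
  nodes <- data.frame(id = c("D1", "T1", "G1"),
                      class = c("Compound", "Target", "GOTerm"))
  edges <- edge_df("D1", "bind", "T1",
                   "T1", "hasGO", "G1")
  g <- tiny_graph(edges, nodes)
  expect_equal(length(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)

  # same edge twice (in either direction) stores once
  g2 <- tiny_graph(rbind(edges, edge_df("T1", "bind", "D1")), nodes)
  expect_equal(nrow(g2$edges), 2)

  # class mismatch for the declared type
  expect_error(tiny_graph(edge_df("D1", "bind", "G1"), nodes), "declares")
  # edge referencing a missing node names the id
  expect_error(tiny_graph(edge_df("D1", "bind", "T9"), nodes), "T9")
  # self loops dropped with a warning
  expect_warning(g3 <- tiny_graph(rbind(edges, edge_df("T1", "PPI", "T1")),
                                  nodes), "self-loop")
  expect_equal(nrow(g3$edges), 2)
})

test_that("type_degree counts distinct neighbors per edge type", {
  g <- tiny_graph(edge_df("D1", "bind", "T1",
                          "D1", "bind", "T2",
                          "D1", "hasSubstructure", "S1"))
  expect_equal(type_degree(g, "D1", "bind"), 2)
  expect_equal(type_degree(g, "D1", "hasSubstructure"), 1)
  expect_equal(type_degree(g, "D1", "hasGO"), 0)
  expect_error(type_degree(g, "D9", "bind"), "unknown node")

  # sum over types equals distinct (type, neighbor) incidences
  for (n in names(g$nodes)) {
    per_type <- vapply(c("bind", "express", "hasGO", "hasSubstructure",
                         "PPI"),
                       function(ty) type_degree(g, n, ty), numeric(1))
    inc <- g$edges[g$edges$source == n | g$edges$target == n, ]
    expect_equal(sum(per_type), nrow(unique(inc[c("type", "source",
                                                  "target")])))
  }
})

test_that("graph tables round-trip regardless of row order", {
  g <- random_typed_graph(7)
  nf <- withr::local_tempfile(fileext = ".tsv")
  ef <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tables(g, nf, ef)

  # shuffle rows and flip some edge directions before re-reading
  ed <- utils::read.delim(ef, stringsAsFactors = FALSE)
  set.seed(1)
  ed <- ed[sample(nrow(ed)), ]
  flip <- seq(1, nrow(ed), by = 2)
  ed[flip, c("source", "target")] <- ed[flip, c("target", "source")]
  utils::write.table(ed, ef, sep = "\t", quote = FALSE, row.names = FALSE)

  g2 <- read_graph(nf, ef, tiny_schema())
  expect_identical(g$edges, g2$edges)
  expect_identical(g$nodes, g2$nodes)
  expect_true(validate_graph(g2))
})

test_that("validation rejects tampered graphs", {
  g <- random_typed_graph(8)
  bad <- g
  # class constraint violation injected directly into the edge table
  goterm <- names(bad$nodes)[bad$nodes == "GOTerm"][1]
  comp <- names(bad$nodes)[bad$nodes == "Compound"][1]
  bad$edges <- rbind(bad$edges,
                     data.frame(source = comp, type = "bind",
                                target = goterm, stringsAsFactors = FALSE))
  expect_error(validate_graph(bad), "declares")

  # adjacency index out of sync with the edge table
  bad2 <- g
  bad2$edges <- bad2$edges[-1, ]
  expect_error(validate_graph(bad2))
})

test_that("per-type weight cutoffs filter edges at load", {
  nodes <- data.frame(id = c("D1", "T1", "T2"),
                      class = c("Compound", "Target", "Target"))
  edges <- edge_df("D1", "bind", "T1", "D1", "bind", "T2")
  edges$weight <- c(5, 50)
  g <- semantic_graph(nodes, edges, tiny_schema(),
                      max_weight = c(bind = 30))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$target, "T1")
  # default: no filtering
  g2 <- semantic_graph(nodes, edges, tiny_schema())
  expect_equal(nrow(g2$edges), 2)
})

test_that("pair lists round-trip and validate labels", {
  pairs <- data.frame(source = c("D1", "D2"), target = c("T1", "T2"),
                      label = c(1L, 0L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pairs, f)
  back <- read_pairs(f)
  expect_identical(back, pairs)
  writeLines("source\ttarget\tlabel\nD1\tT1\t2", f)
  expect_error(read_pairs(f), "0 or 1")
})
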