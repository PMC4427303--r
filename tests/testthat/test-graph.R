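# Interaction-graph representation, serialization, compression, dummies.

test_that("edge lists round-trip through CSV and SIF", {
  g <- interaction_graph(
    edges = data.frame(source = c("A", "B", "A"), target = c("B", "C", "C"),
                       sign = c(1, -1, 1),
                       mechanism = c(NA, "M1", NA)))
  csv <- withr::local_tempfile(fileext = ".csv")
  save_graph(g, csv)
  g2 <- load_graph(csv)
  expect_equal(g2$edges[order(g2$edges$source, g2$edges$target), ],
               g$edges[order(g$edges$source, g$edges$target), ],
               ignore_attr = TRUE)
  # serialization is bit-identical under canonical ordering
  csv2 <- withr::local_tempfile(fileext = ".csv")
  save_graph(g2, csv2)
  expect_identical(readLines(csv), readLines(csv2))

  sif <- withr::local_tempfile(fileext = ".sif")
  save_graph(g, sif, format = "sif")
  g3 <- load_graph(sif, format = "sif")
  expect_setequal(paste(g3$edges$source, g3$edges$target, g3$edges$sign),
                  paste(g$edges$source, g$edges$target, g$edges$sign))
  expect_true(all(is.na(g3$edges$mechanism)))  # SIF loses mechanism grouping
})

test_that("an empty edge file loads to an empty graph", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("source,sign,target,mechanism", f)
  g <- load_graph(f)
  expect_equal(nrow(g$edges), 0)
  expect_equal(nrow(g$species), 0)
})

test_that("malformed rows are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,sign,target,mechanism", "A,+1,B,", "A,?,C,"), f)
  expect_error(load_graph(f), "line 3")
})

test_that("structures are defined by their blocks and share graph edges", {
  m <- tiny_master()
  s1 <- model_structure(m, c("M1", "M2"))
  s2 <- model_structure(m, c("M2", "M1"))
  expect_identical(s1$block, s2$block)
  expect_error(model_structure(m, "M9"), "unknown mechanism")
  e <- structure_edges(model_structure(m, "M2"))
  expect_setequal(e$mechanism[!is.na(e$mechanism)], "M2")
})

test_that("edges shared between mechanisms are deduplicated per structure", {
  edges <- data.frame(source = c("S", "A", "A", "B"),
                      target = c("A", "B", "B", "C"),
                      sign = 1L, mechanism = c(NA, "M1", "M2", "M2"))
  g <- interaction_graph(edges = edges)
  e12 <- structure_edges(model_structure(g, c("M1", "M2")))
  expect_equal(nrow(e12), 3)  # the shared A->B edge appears once
})

test_that("chain compression multiplies signs and is idempotent", {
  # A -(+)-> B -(-)-> C with B unprotected collapses to A -(-)-> C
  g <- interaction_graph(
    data.frame(id = c("A", "B", "C"), role = "protein"),
    data.frame(source = c("A", "B"), target = c("B", "C"),
               sign = c(1L, -1L), mechanism = NA),
    measured = c("A", "C"))
  cs <- compress_structure(model_structure(g, character(0)))
  e <- cs$graph$edges
  expect_equal(nrow(e), 1)
  expect_equal(unname(unlist(e[1, c("source", "target")])), c("A", "C"))
  expect_equal(e$sign, -1L)
  cs2 <- compress_structure(cs)
  expect_identical(cs2$graph$edges, cs$graph$edges)
})

test_that("compression preserves dependency classes between protected nodes", {
  for (seed in 1:6) {
    g <- random_signed_graph(9, 18, seed = 100 + seed)
    protected <- g$species$id[1:4]
    g$measured <- protected
    s <- model_structure(g, character(0))
    cs <- compress_structure(s)
    dep_before <- dependency_matrix(g)
    dep_after <- dependency_matrix(cs$graph)
    for (a in protected) for (b in setdiff(protected, a)) {
      expect_equal(dep_after[a, b], dep_before[a, b],
                   label = sprintf("seed %d, %s->%s", seed, a, b))
    }
  }
})

test_that("kinase-activity dummies reroute outgoing edges", {
  fx <- hgf_fixture()
  r <- insert_dummy_nodes(fx$master, "Mek_inh")
  expect_equal(r$target, "pMEK_act")
  out <- r$graph$edges[r$graph$edges$source == "pMEK_act", ]
  expect_equal(out$target, "pERK")  # MEK's only downstream node is ERK
  expect_equal(r$graph$edges$target[r$graph$edges$source == "pMEK"], "pMEK_act")
  # node-kind inhibitors leave the graph unchanged
  r2 <- insert_dummy_nodes(fx$master, "Met_inh")
  expect_identical(r2$graph, fx$master)
  expect_equal(r2$target, "pMet")
})

test_that("dummy insertion preserves pre-existing dependency classes", {
  for (seed in 1:4) {
    g <- random_signed_graph(8, 16, seed = 200 + seed)
    src <- g$species$id[which.max(tabulate(match(g$edges$source,
                                                 g$species$id)))]
    g$inhibitors <- list(kin = list(kind = "kinase_activity", species = src))
    if (!any(g$edges$source == src)) next
    g2 <- insert_dummy_nodes(g, "kin")$graph
    dep1 <- dependency_matrix(g)
    dep2 <- dependency_matrix(g2)
    ids <- g$species$id
    expect_equal(dep2[ids, ids], dep1, label = paste("seed", seed))
  }
})

test_that("a kinase-activity inhibitor on a sink node is an error", {
  g <- interaction_graph(
    edges = data.frame(source = "A", target = "B", sign = 1L),
    inhibitors = list(x = list(kind = "kinase_activity", species = "B")))
  expect_error(insert_dummy_nodes(g, "x"), "no outgoing")
})

test_that("structure descriptors round-trip through JSON", {
  m <- tiny_master()
  f <- withr::local_tempfile(fileext = ".json")
  save_structure(model_structure(m, c("M1", "M3")), f)
  s <- read_structure(f, m)
  expect_identical(s$block, c("M1", "M3"))
})
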