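# Dependency-matrix classification and qualitative response prediction.

test_that("sign reachability matches single- and two-path examples", {
  g <- interaction_graph(edges = data.frame(
    source = c("A"), target = c("B"), sign = 1L))
  r <- sign_reachability(g, "A", "B")
  expect_true(r$has_positive_path)
  expect_false(r$has_negative_path)

  g2 <- interaction_graph(edges = data.frame(
    source = c("A", "A", "C"), target = c("B", "C", "B"),
    sign = c(1L, 1L, -1L)))
  r2 <- sign_reachability(g2, "A", "B")
  expect_true(r2$has_positive_path)
  expect_true(r2$has_negative_path)
})

test_that("sign reachability agrees with exhaustive path enumeration", {
  for (seed in 1:8) {
    g <- random_signed_graph(sample(4:12, 1), sample(8:24, 1), seed = seed)
    ids <- g$species$id
    for (trial in 1:6) {
      ab <- sample(ids, 2)
      signs <- oracle_path_signs(g, ab[1], ab[2])
      r <- sign_reachability(g, ab[1], ab[2])
      expect_equal(r$has_positive_path, any(signs > 0),
                   label = sprintf("seed %d %s->%s pos", seed, ab[1], ab[2]))
      expect_equal(r$has_negative_path, any(signs < 0),
                   label = sprintf("seed %d %s->%s neg", seed, ab[1], ab[2]))
    }
  }
})

test_that("negative feedback nodes match the cycle-enumeration oracle", {
  expect_equal(negative_feedback_nodes(interaction_graph(edges = data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = 1L))), character(0))
  expect_setequal(negative_feedback_nodes(interaction_graph(edges = data.frame(
    source = c("A", "B"), target = c("B", "A"), sign = c(1L, -1L)))),
    c("A", "B"))
  for (seed in 1:8) {
    g <- random_signed_graph(sample(4:10, 1), sample(6:20, 1), seed = 50 + seed)
    expect_equal(sort(negative_feedback_nodes(g)), oracle_neg_feedback(g),
                 label = paste("seed", 50 + seed))
  }
})

test_that("dependency matrix agrees with the brute-force oracle", {
  g <- interaction_graph(edges = data.frame(
    source = "A", target = "B", sign = 1L))
  m <- dependency_matrix(g)
  expect_equal(m["A", "B"], "strong_activator")
  expect_equal(m["B", "A"], "neutral")

  g2 <- interaction_graph(edges = data.frame(
    source = c("A", "B"), target = c("B", "A"), sign = c(1L, -1L)))
  expect_equal(dependency_matrix(g2)["A", "B"], "weak_activator")

  for (seed in 1:6) {
    g <- random_signed_graph(sample(4:12, 1), sample(6:22, 1), seed = 70 + seed)
    m <- dependency_matrix(g)
    ids <- g$species$id
    for (trial in 1:8) {
      ab <- sample(ids, 2)
      expect_equal(m[ab[1], ab[2]], oracle_dependency(g, ab[1], ab[2]),
                   label = sprintf("seed %d %s->%s", seed, ab[1], ab[2]))
    }
  }
})

test_that("ERK is ambivalent for MEK in the HGF master model", {
  fx <- hgf_fixture()
  r <- sign_reachability(fx$master, "pERK", "pMEK")
  expect_true(r$has_positive_path)   # e.g. the ERK -> Raf1 feedback route
  expect_true(r$has_negative_path)   # e.g. ERK/RSK_d -| SOS1
  expect_equal(dependency_matrix(fx$master)["pERK", "pMEK"], "ambivalent")
})

test_that("response predictions follow the dependency-class rules", {
  # single strong activator: decrease at every time point
  g <- interaction_graph(edges = data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = 1L))
  p <- predict_response(g, "A", "C")
  expect_equal(p$early_allowed, "decrease")
  expect_equal(p$late_allowed, "decrease")
  # weak activator: the feedback may overturn the late response
  g2 <- interaction_graph(edges = data.frame(
    source = c("A", "B"), target = c("B", "A"), sign = c(1L, -1L)))
  p2 <- predict_response(g2, "A", "B")
  expect_equal(p2$early_allowed, "decrease")
  expect_setequal(p2$late_allowed, c("increase", "decrease", "no_change"))
  # neutral: no change at all times
  g3 <- interaction_graph(edges = data.frame(
    source = "A", target = "B", sign = 1L),
    species = data.frame(id = c("A", "B", "C")))
  p3 <- predict_response(g3, "C", "B")
  expect_equal(p3$early_allowed, "no_change")
  expect_equal(p3$late_allowed, "no_change")
  expect_error(predict_response(g3, "B", "B"), "not a meaningful")
})

test_that("adding an edge never turns a non-neutral pair neutral", {
  for (seed in 1:5) {
    g <- random_signed_graph(7, 10, seed = 300 + seed)
    m1 <- dependency_matrix(g)
    ids <- g$species$id
    repeat {
      extra <- sample(ids, 2)
      if (!any(g$edges$source == extra[1] & g$edges$target == extra[2]))
        break
    }
    g2 <- interaction_graph(g$species, rbind(
      g$edges, data.frame(source = extra[1], target = extra[2],
                          sign = sample(c(-1L, 1L), 1), mechanism = NA)))
    m2 <- dependency_matrix(g2)
    was_nonneutral <- !is.na(m1) & m1 != "neutral"
    expect_true(all(m2[was_nonneutral] != "neutral"),
                label = paste("seed", 300 + seed))
  }
})

test_that("consistency checking applies the membership rule", {
  m <- tiny_master()
  expect_true(check_consistency(model_structure(m, character(0)),
                                data.frame())$consistent)
  obs <- data.frame(inhibitors = "inh_A", species = "B",
                    early = "decrease", late = "increase")
  # core: A is a strong activator of B -> late increase impossible
  expect_false(check_consistency(model_structure(m, character(0)),
                                 obs)$consistent)
  # M1 closes a negative loop (B -> C -| A): A becomes weak -> consistent
  expect_true(check_consistency(model_structure(m, "M1"), obs)$consistent)
  # not_conclusive entries are skipped
  obs2 <- data.frame(inhibitors = "inh_A", species = "B",
                     early = "decrease", late = "not_conclusive")
  expect_true(check_consistency(model_structure(m, character(0)),
                                obs2)$consistent)
  expect_error(check_consistency(
    model_structure(m, character(0)),
    data.frame(inhibitors = "nope", species = "B",
               early = "decrease", late = "decrease")), "unknown inhibitor")
})
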