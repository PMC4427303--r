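# Interaction-graph to mass-action ODE translation.

simple_structure <- function(extra = NULL) {
  edges <- data.frame(source = c("S", "A", "B"),
                      target = c("A", "B", "C"),
                      sign = 1L, mechanism = NA)
  if (!is.null(extra)) edges <- rbind(edges, extra)
  g <- interaction_graph(
    data.frame(id = c("S", "A", "B", "C"),
               role = c("signal", "protein", "protein", "protein")),
    edges, measured = c("A", "B", "C"))
  model_structure(g, graph_mechanisms(g))
}

test_that("core edges become activation plus one shared deactivation", {
  s <- simple_structure()
  m <- translate_structure(s, options = translate_options(signal = "S"))
  # 3 activations + 3 deactivations
  expect_equal(n_reactions(m), 6)
  subs <- vapply(m$reactions, `[[`, "", "substrate")
  expect_equal(sum(subs == "A_i"), 1)
  act <- Filter(function(r) identical(r$product, "B"), m$reactions)
  expect_length(act, 1)
  expect_equal(act[[1]]$modifiers, "A")   # catalyst, not consumed
})

test_that("negative edges translate to catalyzed deactivations", {
  extra <- data.frame(source = "C", target = "A", sign = -1L,
                      mechanism = "M1")
  m <- translate_structure(simple_structure(extra),
                           options = translate_options(signal = "S"))
  deact <- Filter(function(r) identical(r$substrate, "A") &&
                    "C" %in% r$modifiers, m$reactions)
  expect_length(deact, 1)
  expect_equal(deact[[1]]$product, "A_i")
})

test_that("modulating and independent candidates add one reaction each", {
  extra <- data.frame(source = c("C", "C"), target = c("B", "A"),
                      sign = 1L, mechanism = c("M1", "M2"))
  s <- simple_structure(extra)
  ann <- data.frame(source = c("C", "C"), target = c("B", "A"),
                    type = c("modulating", "independent"),
                    modulates = c("A", NA))
  m <- translate_structure(s, annotations = ann,
                           options = translate_options(signal = "S"))
  expect_equal(n_reactions(m), 8)
  mod <- Filter(function(r) identical(r$product, "B") &&
                  length(r$modifiers) == 2, m$reactions)
  expect_length(mod, 1)
  expect_setequal(mod[[1]]$modifiers, c("A", "C"))
  # a positive candidate without annotation is an error
  expect_error(translate_structure(s, annotations = ann[1, ],
                                   options = translate_options(signal = "S")),
               "annotation")
})

test_that("the Jacobian sign pattern reproduces the graph edges", {
  for (seed in c(2, 5, 9)) {
    st <- generate_study(seed = seed, n_core_nodes = 4, n_mechanisms = 3,
                         block_size = 2, noise_cv = 0, n_replicates = 1,
                         gel_scale_range = 0, n_double = 0)
    m <- st$model
    e <- structure_edges(st$truth)
    params <- stats::setNames(m$parameters$value, m$parameters$id)
    params[names(st$true_params)] <- 10^st$true_params
    params["S"] <- 1
    # numeric Jacobian of the active-form subsystem at a generic state
    active <- m$species$id[m$species$form == "active"]
    rt_y <- stats::setNames(stats::runif(nrow(m$species), 0.2, 0.6),
                            m$species$id)
    # evaluate the RHS via a tiny forward integration step
    rhs_at <- function(y) {
      h <- 1e-6
      cond <- new_condition("j", inputs = c(S = 1))
      m2 <- m
      m2$species$initial <- unname(y[m$species$id])
      tr <- simulate_condition(m2, cond, params, times = h,
                               rtol = 1e-10, atol = 1e-12)
      (tr[1, m$species$id] - y[m$species$id]) / h
    }
    base <- rhs_at(rt_y)
    for (i in seq_len(nrow(e))) {
      a <- e$source[i]; b <- e$target[i]
      if (!a %in% active) next   # signal/constant sources are parameters
      y2 <- rt_y; y2[a] <- y2[a] + 1e-4
      d <- (rhs_at(y2)[b] - base[b]) / 1e-4
      expect_gt(d * e$sign[i], 0)
    }
  }
})

test_that("inhibitor strengths scale the targeted rate constants", {
  fx <- hgf_fixture()
  m <- hgf_translate(fx, fx$reference_block)
  params <- stats::setNames(10^fx$params[m$parameters$id],
                            m$parameters$id)
  expect_identical(apply_inhibitors(m, c(), params), params)
  p0 <- apply_inhibitors(m, c(Met_inh = 0), params)
  expect_equal(p0, params)
  p50 <- apply_inhibitors(m, c(Met_inh = 0.5), params)
  hit <- vapply(m$reactions[m$inhibitors$Met_inh$reactions], `[[`, "",
                "param")
  expect_true(length(hit) >= 1)
  expect_equal(unname(p50[hit]), unname(params[hit]) / 2)
  expect_equal(p50[setdiff(names(params), hit)],
               params[setdiff(names(params), hit)])
  expect_error(apply_inhibitors(m, c(Met_inh = 1.5), params), "0, 1")
  expect_error(apply_inhibitors(m, c(nope = 0.5), params), "undeclared")
  # full Met inhibition: pMet never rises from 0
  p1 <- apply_inhibitors(m, c(Met_inh = 1), params)
  tr <- simulate_condition(m, new_condition("x", inputs = c(HGF = 1)), p1)
  expect_equal(max(abs(tr[, "pMet"])), 0)
})

test_that("moieties are conserved and trajectories stay non-negative", {
  st <- generate_study(seed = 4, n_core_nodes = 4, n_mechanisms = 3,
                       block_size = 1, noise_cv = 0, n_replicates = 1,
                       gel_scale_range = 0, n_double = 0)
  m <- st$model
  params <- stats::setNames(m$parameters$value, m$parameters$id)
  params[names(st$true_params)] <- 10^st$true_params
  for (cond in st$conditions[1:3]) {
    tr <- simulate_condition(m, cond, params,
                             times = seq(0, 120, length.out = 25))
    expect_true(all(tr[, -1] > -1e-8))
    tot <- moiety_totals(m, tr)
    drift <- apply(tot, 2, function(x) max(abs(x - x[1])))
    expect_lt(max(drift), 1e-8)
  }
})
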