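# Frozen synthetic scenarios shared by selection and prediction-band tests.

# A ground-truth study whose planted mechanisms all have kinetic rates
# above 10^-0.5 (detectable) and whose core model cannot explain the
# discretized data: the first seed satisfying these preconditions (judged
# before any fitting).
selection_scenario <- function() {
  for (seed in 1:50) {
    st <- generate_study(seed = seed, n_core_nodes = 4, n_mechanisms = 3,
                         block_size = 2, noise_cv = 0.02, n_replicates = 2,
                         gel_scale_range = 0, n_double = 2)
    cand_par <- unique(vapply(Filter(function(r) r$origin != "core",
                                     st$model$reactions),
                              `[[`, "", "param"))
    strong <- all(st$true_params[cand_par] > -0.5)
    core_ok <- check_consistency(model_structure(st$master, character(0)),
                                 st$observations)$consistent
    if (strong && !core_ok) return(st)
  }
  stop("no informative study found")
}

# stateful fitter: once the complete (null) model has been fitted, nested
# structures are additionally warm-started from its optimum (their
# parameters are a subset of the null model's)
scenario_fitter <- function(st, dataset = st$dataset, n_starts = 12,
                            max_iter = 40, seed = 7) {
  warm <- NULL
  function(id, s) {
    m <- translate_structure(compress_structure(s),
                             annotations = annotate_independent(s),
                             options = st$options)
    fit <- multistart_fit(m, dataset, n_starts = n_starts, seed = seed,
                          max_iter = max_iter, extra_starts = warm)
    if (identical(id, "complete")) warm <<- fit$par
    fit
  }
}

# A cascade S -> P1 -> P2 -> P3 -> P4 (the truth) and a candidate bypass
# P1 -> P3 around the unmeasured node P2: fitted to core-generated data,
# the bypass-carrying model leaves P2 poorly determined, so its prediction
# band for P2 must be wider than the true structure's.
bypass_scenario <- function(seed = 1) {
  set.seed(seed)
  edges <- rbind(
    data.frame(source = c("S", "P1", "P2", "P3"),
               target = c("P1", "P2", "P3", "P4"),
               sign = 1L, mechanism = NA),
    data.frame(source = "P1", target = "P3", sign = 1L, mechanism = "M1"))
  master <- interaction_graph(
    data.frame(id = c("S", "P1", "P2", "P3", "P4"),
               role = c("signal", rep("protein", 4))),
    edges, measured = c("P1", "P3", "P4"),
    inhibitors = list(inh_P1 = list(kind = "node", species = "P1")))
  opts <- translate_options(signal = "S")
  truth <- model_structure(master, character(0))
  m_true <- translate_structure(truth, options = opts)
  p <- stats::setNames(rep(1, nrow(m_true$parameters)),
                       m_true$parameters$id)
  p[grep("deact", names(p))] <- 0.3
  p["S"] <- 1
  conds <- list(
    ctrl = new_condition("ctrl", inputs = c(S = 1)),
    inh = new_condition("inh", inputs = c(S = 1),
                        inhibitors = c(inh_P1 = 0.7)))
  times <- c(5, 10, 30, 60, 120)
  recs <- list()
  for (cid in names(conds)) {
    tr <- simulate_condition(m_true, conds[[cid]], p, times = times)
    for (obs in c("P1", "P3", "P4")) for (rep_ in 1:2) {
      recs[[length(recs) + 1L]] <- data.frame(
        condition = cid, gel = 1, observable = obs, time = times,
        value = pmax(tr[, obs] * exp(stats::rnorm(length(times), 0, 0.05)),
                     1e-12))
    }
  }
  ds <- make_dataset(do.call(rbind, recs),
                     data.frame(observable = c("P1", "P3", "P4"),
                                species = c("P1", "P3", "P4"),
                                scaled = FALSE), conds)
  list(master = master, options = opts, truth = truth,
       bypass = model_structure(master, "M1"), dataset = ds,
       conditions = conds)
}
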