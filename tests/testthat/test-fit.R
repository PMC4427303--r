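# Condition simulation, likelihood objective, multistart estimation.

small_study <- function(seed = 5) {
  generate_study(seed = seed, n_core_nodes = 3, n_mechanisms = 2,
                 block_size = 1, noise_cv = 0.05, n_replicates = 2,
                 gel_scale_range = 0, n_double = 0)
}

true_params_of <- function(st) {
  p <- stats::setNames(st$model$parameters$value, st$model$parameters$id)
  p[names(st$true_params)] <- 10^st$true_params
  p
}

test_that("no stimulus means no activation", {
  st <- small_study()
  m <- st$model
  tr <- simulate_condition(m, new_condition("off", inputs = c(S = 0)),
                           true_params_of(st))
  active <- m$species$id[m$species$form == "active"]
  expect_equal(max(abs(tr[, active])), 0)
})

test_that("trajectories are converged with respect to solver tolerances", {
  st <- small_study()
  p <- true_params_of(st)
  cond <- st$conditions[[2]]
  t1 <- simulate_condition(st$model, cond, p, rtol = 1e-8, atol = 1e-10)
  t2 <- simulate_condition(st$model, cond, p, rtol = 5e-9, atol = 5e-11)
  rel <- max(abs(t1 - t2) / pmax(abs(t1), 1e-6))
  expect_lt(rel, 1e-6)
})

test_that("the objective matches hand-computed values", {
  st <- small_study()
  m <- st$model
  p <- true_params_of(st)
  # a perfect fit leaves only the normalization terms
  cond <- st$conditions$control
  tr <- simulate_condition(m, cond, p, times = c(10, 30, 60))
  rec <- data.frame(condition = "control", gel = 1, observable = "P1",
                    time = c(10, 30, 60), value = tr[, "P1"])
  ds <- make_dataset(rec, data.frame(observable = "P1", species = "P1",
                                     scaled = FALSE),
                     list(control = cond))
  sig <- c(P1 = 0.1)
  v <- objective_neg2loglik(m, ds, p, sigmas = sig)
  expect_equal(as.numeric(v), 3 * log(2 * pi * 0.01), tolerance = 1e-6)
  # doubling sigma on a perfectly fit observable adds 2 n log 2
  v2 <- objective_neg2loglik(m, ds, p, sigmas = c(P1 = 0.2))
  expect_equal(as.numeric(v2) - as.numeric(v), 2 * 3 * log(2), tolerance = 1e-6)
  # three records against a constant prediction, computed by hand
  rec3 <- rec
  rec3$value <- rec$value * c(10, 1, 0.1)
  ds3 <- make_dataset(rec3, ds$observables, ds$conditions)
  v3 <- objective_neg2loglik(m, ds3, p, sigmas = sig)
  expect_equal(as.numeric(v3), 100 + 0 + 100 + 3 * log(2 * pi * 0.01),
               tolerance = 1e-6)
  expect_error(make_dataset(transform(rec, value = 0), ds$observables,
                            ds$conditions), "positive")
})

test_that("profiled noise parameters maximize the likelihood", {
  st <- small_study()
  p <- true_params_of(st)
  v <- objective_neg2loglik(st$model, st$dataset, p)
  sig <- attr(v, "sigmas")
  for (mult in c(0.8, 1.25)) {
    expect_gt(as.numeric(objective_neg2loglik(st$model, st$dataset, p,
                                              sigmas = sig * mult)),
              as.numeric(v))
  }
})

test_that("multistart fitting recovers identifiable planted parameters", {
  st <- small_study(seed = 5)
  fit <- multistart_fit(st$model, st$dataset, n_starts = 8, seed = 2)
  # the optimum cannot be worse than the truth, within optimizer slack
  p <- true_params_of(st)
  v_true <- as.numeric(objective_neg2loglik(st$model, st$dataset, p))
  expect_lte(fit$objective, v_true + 1e-3)
  # identifiable = the profile likelihood (re-optimizing all other
  # parameters) rises above the chi-square threshold when the parameter is
  # displaced; single-axis curvature would misclassify ridge pairs such as
  # a fast-equilibrating activation/deactivation couple
  eval_at <- function(free) {
    u <- hybridnet:::.unpack_free(st$model, st$dataset, free)
    tryCatch(as.numeric(objective_neg2loglik(st$model, st$dataset,
                                             u$params, u$scalings,
                                             rtol = 1e-6, atol = 1e-8)),
             error = function(e) Inf)
  }
  profile_at <- function(nm, delta) {
    fixed <- fit$par[nm] + delta
    others <- setdiff(names(fit$par), nm)
    obj <- function(x) {
      free <- fit$par
      free[others] <- x
      free[nm] <- fixed
      eval_at(free)
    }
    stats::optim(fit$par[others], obj, method = "Nelder-Mead",
                 control = list(maxit = 300))$value
  }
  thr <- stats::qchisq(0.95, 1)
  idf <- names(st$true_params)[vapply(names(st$true_params), function(nm) {
    min(profile_at(nm, 0.25), profile_at(nm, -0.25)) - fit$objective > thr
  }, TRUE)]
  expect_gt(length(idf), 0)
  rmse <- sqrt(mean((fit$par[idf] - st$true_params[idf])^2))
  expect_lt(rmse, 0.2)
})

test_that("fits are reproducible and improve with more starts", {
  st <- small_study(seed = 8)
  f1 <- multistart_fit(st$model, st$dataset, n_starts = 4, seed = 3)
  f2 <- multistart_fit(st$model, st$dataset, n_starts = 4, seed = 3)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$waterfall, f2$waterfall)
  f3 <- multistart_fit(st$model, st$dataset, n_starts = 8, seed = 3)
  expect_lte(f3$objective, f1$objective + 1e-9)
  expect_equal(f1$waterfall, sort(f1$waterfall))
})

test_that("repeated starts reach a common optimum plateau", {
  st <- generate_study(seed = 12, n_core_nodes = 2, n_mechanisms = 1,
                       block_size = 1, noise_cv = 0.05, n_replicates = 2,
                       gel_scale_range = 0, n_double = 0)
  fit <- multistart_fit(st$model, st$dataset, n_starts = 15, seed = 4)
  near <- sum(fit$waterfall <= fit$objective + 0.1)
  expect_gte(near / length(fit$waterfall), 0.2)
})

test_that("a model with no free parameters reports the fixed objective", {
  st <- small_study()
  m <- st$model
  m$parameters$value <- unname(true_params_of(st)[m$parameters$id])
  m$parameters$kind[m$parameters$kind == "kinetic"] <- "fixed"
  fit <- multistart_fit(m, st$dataset, n_starts = 3, seed = 1)
  v <- objective_neg2loglik(m, st$dataset,
                            stats::setNames(m$parameters$value,
                                            m$parameters$id))
  expect_equal(fit$objective, as.numeric(v), tolerance = 1e-6)
  expect_equal(fit$df, length(unique(st$dataset$records$observable)))
})
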