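# AUC screens, synergy, prediction profiles, crosstalk flux.

test_that("trapezoidal AUC is exact for linear trajectories", {
  t <- seq(0, 120, by = 10)
  expect_equal(auc_trapezoid(t, rep(2, length(t))), 240)
  expect_equal(auc_trapezoid(t, t / 60), 120)
  # linear in the readout: sum readout = sum of AUCs
  a <- stats::runif(length(t)); b <- stats::runif(length(t))
  expect_equal(auc_trapezoid(t, a + b),
               auc_trapezoid(t, a) + auc_trapezoid(t, b))
})

test_that("the inhibitor screen normalizes to the control", {
  fx <- hgf_fixture()
  m <- hgf_translate(fx, fx$reference_block)
  params <- stats::setNames(10^fx$params[m$parameters$id], m$parameters$id)
  cond <- new_condition("ctrl", inputs = c(HGF = 1))
  sc <- inhibitor_screen(m, params, cond, readouts = c("pAkt", "pERK"),
                         targets = c("pMet", "pPI3K", "pMEK"),
                         strength = 0.5, grid_points = 61)
  for (r in c("pAkt", "pERK", "sum")) {
    A <- sc$auc_percent[[r]]
    expect_true(all(is.finite(A)))
    # pairwise part is symmetric under inhibitor exchange
    P <- A[, sc$targets]
    expect_equal(P, t(P))
  }
  # zero strength leaves every readout at 100% of control
  sc0 <- inhibitor_screen(m, params, cond, readouts = c("pAkt", "pERK"),
                          targets = c("pMet", "pMEK"), strength = 0,
                          grid_points = 31)
  expect_equal(max(abs(sc0$auc_percent$sum - 100)), 0, tolerance = 1e-6)
  # Met inhibition cuts receptor-driven signaling below control
  expect_lt(sc$auc_percent$sum["pMet", "none"], 100)
})

test_that("synergy is the excess effect over additivity", {
  mk <- function(vals) {
    # vals: named list with singles s1, s2 and the pair p (AUC percent)
    targets <- c("I1", "I2")
    A <- matrix(NA_real_, 2, 3, dimnames = list(targets,
                                                c("none", targets)))
    A["I1", "none"] <- vals$s1; A["I2", "none"] <- vals$s2
    A["I1", "I2"] <- A["I2", "I1"] <- vals$p
    A["I1", "I1"] <- vals$s1; A["I2", "I2"] <- vals$s2
    structure(list(auc_percent = list(sum = A), targets = targets,
                   readouts = "sum"), class = "screen_result")
  }
  # effects 10 + 20 with combined 30: additive, synergy 0
  S <- synergy_matrix(mk(list(s1 = 90, s2 = 80, p = 70)))
  expect_equal(S["I1", "I2"], 0)
  # singles 18% each, combination 50%: +14 percentage points
  S2 <- synergy_matrix(mk(list(s1 = 82, s2 = 82, p = 50)))
  expect_equal(S2["I1", "I2"], 14)
  # combination weaker than one single alone: negative synergy
  S3 <- synergy_matrix(mk(list(s1 = 70, s2 = 90, p = 75)))
  expect_lt(S3["I1", "I2"], 0)
  expect_equal(S3, t(S3))
})

test_that("prediction bands collapse without free parameters and widen with alpha", {
  st <- generate_study(seed = 12, n_core_nodes = 2, n_mechanisms = 1,
                       block_size = 1, noise_cv = 0.05, n_replicates = 2,
                       gel_scale_range = 0, n_double = 0)
  m <- st$model
  p <- stats::setNames(m$parameters$value, m$parameters$id)
  p[names(st$true_params)] <- 10^st$true_params
  m0 <- m
  m0$parameters$value <- unname(p[m0$parameters$id])
  m0$parameters$kind[m0$parameters$kind == "kinetic"] <- "fixed"
  fit0 <- multistart_fit(m0, st$dataset, n_starts = 1, seed = 1)
  band0 <- prediction_profile(m0, fit0, st$dataset, "P2",
                              st$conditions$control, times = c(30, 60))
  expect_equal(band0$lower, band0$fit)
  expect_equal(band0$upper, band0$fit)

  fit <- multistart_fit(m, st$dataset, n_starts = 4, seed = 1)
  times <- c(30, 60)
  b95 <- prediction_profile(m, fit, st$dataset, "P2",
                            st$conditions$control, times, alpha = 0.95,
                            n_steps = 6)
  b80 <- prediction_profile(m, fit, st$dataset, "P2",
                            st$conditions$control, times, alpha = 0.80,
                            n_steps = 6)
  expect_true(all(b95$lower <= b95$fit + 1e-9))
  expect_true(all(b95$upper >= b95$fit - 1e-9))
  expect_true(all(b95$lower <= b80$lower + 1e-9))
  expect_true(all(b95$upper >= b80$upper - 1e-9))
  # accepted band endpoints respect the likelihood threshold
  thr <- fit$objective + stats::qchisq(0.95, 1)
  expect_true(all(b95$lower_obj <= thr + 1e-3))
  expect_true(all(b95$upper_obj <= thr + 1e-3))
})

test_that("crosstalk flux reduction is zero without inhibition and grows with fold", {
  fx <- hgf_fixture()
  m <- hgf_translate(fx, fx$reference_block)
  params <- stats::setNames(10^fx$params[m$parameters$id], m$parameters$id)
  cond <- new_condition("ctrl", inputs = c(HGF = 1))
  rx <- "pRaf1_deact_by_pAkt"
  expect_equal(flux_reduction(m, params, cond, rx, "pAkt", fold = 1,
                              grid_points = 61), 0, tolerance = 1e-8)
  r3 <- flux_reduction(m, params, cond, rx, "pAkt", fold = 3,
                       grid_points = 61)
  r6 <- flux_reduction(m, params, cond, rx, "pAkt", fold = 6,
                       grid_points = 61)
  expect_gt(r3, 0)
  expect_gt(r6, r3)
  expect_lt(r6, 100)
})
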