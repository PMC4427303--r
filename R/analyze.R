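# Post-fit analysis: prediction-profile confidence bands, in-silico
# inhibitor screens with AUC readouts, synergy scoring and crosstalk flux
# analysis.

#' Trapezoidal area under a trajectory
#' @param time,value numeric vectors
#' @export
auc_trapezoid <- function(time, value) {
  sum(diff(time) * (utils::head(value, -1) + utils::tail(value, -1)) / 2)
}

# reactions counted as "outgoing" for a protein's active form: the protein
# acts as a catalyst (modifier) or as the substrate of a forward conversion
# to another active species; its own basal deactivation is excluded
.outgoing_reactions <- function(m, species) {
  active <- m$species$id[m$species$form == "active"]
  idx <- integer(0)
  for (r in m$reactions) {
    if (species %in% r$modifiers) { idx <- c(idx, r$id); next }
    if (identical(r$substrate, species) && !is.na(r$product) &&
        r$product %in% active)
      idx <- c(idx, r$id)
  }
  idx
}

#' In-silico single and pairwise inhibitor screen
#'
#' For each protein (and each unordered protein pair), all outgoing
#' reactions of the protein are down-regulated by scaling their rate
#' constants by `(1 - strength)`; the perturbed model is simulated and the
#' trapezoidal area under the curve of each readout over `[0, horizon]` is
#' reported as a percentage of the unperturbed control.
#'
#' @param m ode_model
#' @param params named parameter values (linear scale)
#' @param condition baseline condition (stimulus on, no inhibitors)
#' @param readouts character vector of readout species; their sum is
#'   reported as an additional readout `sum`
#' @param targets proteins to inhibit (default: all active species with at
#'   least one outgoing reaction, excluding the readout-only leaves)
#' @param strength inhibition strength in [0,1]
#' @param horizon simulation horizon (minutes)
#' @param grid_points number of points of the uniform AUC grid
#' @return object of class `screen_result`: list of AUC% matrices (rows =
#'   inhibitor I, columns = inhibitor II with a `none` column for single
#'   inhibitions), one per readout
#' @export
inhibitor_screen <- function(m, params, condition, readouts,
                             targets = NULL, strength = 0.5, horizon = 120,
                             grid_points = 241) {
  stopifnot(strength >= 0, strength <= 1)
  times <- seq(0, horizon, length.out = grid_points)
  if (is.null(targets)) {
    active <- m$species$id[m$species$form == "active"]
    cst <- m$parameters$id[m$parameters$kind == "constant"]
    targets <- c(active, cst)
    targets <- targets[vapply(targets,
                              function(s) length(.outgoing_reactions(m, s)) > 0,
                              TRUE)]
  }
  rx_of <- lapply(stats::setNames(targets, targets),
                  function(s) .outgoing_reactions(m, s))
  scale_params <- function(p, targ) {
    for (s in targ) for (r in rx_of[[s]]) {
      pid <- m$reactions[[r]]$param
      p[pid] <- p[pid] * (1 - strength)
    }
    p
  }
  run_auc <- function(p) {
    traj <- simulate_condition(m, condition, p, times = times)
    a <- vapply(readouts, function(sp) auc_trapezoid(times, traj[, sp]),
                numeric(1))
    c(a, sum = sum(a))
  }
  ctrl <- run_auc(params)
  nt <- length(targets)
  rn <- c("none", targets)
  mats <- lapply(c(readouts, "sum"), function(r)
    matrix(NA_real_, nt, nt + 1, dimnames = list(targets, rn)))
  names(mats) <- c(readouts, "sum")
  cell <- function(targ) {
    a <- tryCatch(run_auc(scale_params(params, targ)),
                  error = function(e) rep(NA_real_, length(ctrl)))
    100 * a / ctrl
  }
  for (i in seq_len(nt)) {
    v <- cell(targets[i])
    for (r in names(mats)) mats[[r]][i, "none"] <- v[[r]]
  }
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (j < i) {
      for (r in names(mats)) mats[[r]][i, targets[j]] <- mats[[r]][j, targets[i]]
      next
    }
    v <- if (i == j) {
      vv <- numeric(length(ctrl)); names(vv) <- names(ctrl)
      for (r in names(mats)) vv[[r]] <- mats[[r]][i, "none"]
      vv
    } else cell(c(targets[i], targets[j]))
    for (r in names(mats)) mats[[r]][i, targets[j]] <- v[[r]]
  }
  structure(list(auc_percent = mats, strength = strength,
                 horizon = horizon, readouts = readouts,
                 targets = targets),
            class = "screen_result")
}

#' Synergy matrix of an inhibitor screen
#'
#' On the percent-reduction scale (`effect = 100 - AUC%`), synergy of a
#' pair is `effect(I) + effect(II) - effect(I, II)` negated, i.e.
#' `synergy = effect(I, II) - [effect(I) + effect(II)]`: positive values
#' mean the double inhibition is stronger than the sum of the single
#' inhibitions, 0 means additive, negative values antagonism. A
#' Bliss-independence variant (`bliss = TRUE`) compares the combined AUC%
#' against the product of the single AUC fractions.
#'
#' @param screen screen_result
#' @param readout which readout matrix to use
#' @param bliss use Bliss independence instead of linear additivity
#' @return symmetric matrix of synergy scores (percentage points)
#' @export
synergy_matrix <- function(screen, readout = "sum", bliss = FALSE) {
  A <- screen$auc_percent[[readout]]
  targets <- screen$targets
  singles <- A[, "none"]
  if (anyNA(singles)) stop("missing single-inhibition entries")
  n <- length(targets)
  S <- matrix(NA_real_, n, n, dimnames = list(targets, targets))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { S[i, j] <- 0; next }
    comb <- A[i, targets[j]]
    if (bliss) {
      S[i, j] <- (singles[i] / 100) * (singles[j] / 100) * 100 - comb
    } else {
      ei <- 100 - singles[i]; ej <- 100 - singles[j]
      S[i, j] <- (100 - comb) - (ei + ej)
    }
  }
  S
}

#' Prediction-profile confidence band for an unobserved species
#'
#' At each requested time the band is the range of the species' predicted
#' value over parameter sets whose `-2 log(L)` exceeds the optimum by at
#' most the chi-square quantile with one degree of freedom at `alpha`. The
#' band is found by constrained re-optimization: the prediction is stepped
#' away from its fitted value under a quadratic penalty pulling it to the
#' target while the likelihood is re-optimized over all parameters, and
#' the extreme accepted prediction is recorded.
#'
#' @param m ode_model
#' @param fit fit_result
#' @param dataset experiment_dataset used for the fit
#' @param species species id to profile
#' @param condition condition under which to profile
#' @param times time points of the band
#' @param alpha confidence level
#' @param n_steps profile steps per direction
#' @param step_factor multiplicative step on the prediction per move
#' @return data.frame with columns `time`, `fit`, `lower`, `upper`,
#'   `lower_obj`, `upper_obj` (the constrained objectives at the band
#'   endpoints)
#' @export
prediction_profile <- function(m, fit, dataset, species, condition, times,
                               alpha = 0.95, n_steps = 12,
                               step_factor = 1.35) {
  thr <- fit$objective + stats::qchisq(alpha, df = 1)
  free0 <- fit$par
  predict_at <- function(free, t) {
    u <- .unpack_free(m, dataset, free)
    traj <- simulate_condition(m, condition, u$params, times = t)
    traj[1, species]
  }
  objective_of <- function(free) {
    u <- .unpack_free(m, dataset, free)
    tryCatch(as.numeric(objective_neg2loglik(m, dataset, u$params,
                                             u$scalings)),
             error = function(e) Inf)
  }
  if (!length(free0)) {
    # no free parameters: the band collapses onto the trajectory
    v <- vapply(times, function(t) predict_at(free0, t), numeric(1))
    return(data.frame(time = times, fit = v, lower = v, upper = v,
                      lower_obj = fit$objective, upper_obj = fit$objective))
  }
  lower <- upper <- fitv <- lo_obj <- up_obj <- numeric(length(times))
  for (ti in seq_along(times)) {
    t <- times[ti]
    v0 <- predict_at(free0, t)
    fitv[ti] <- v0
    for (dir in c(-1, 1)) {
      free <- free0
      extreme <- v0
      extreme_obj <- fit$objective
      target <- max(v0, 1e-9)
      for (step in seq_len(n_steps)) {
        target <- target * step_factor^dir
        pen_fn <- function(x) {
          g <- tryCatch(predict_at(x, t), error = function(e) NA_real_)
          if (!is.finite(g)) return(1e8)
          objective_of(x) + 1e4 * (log10(max(g, 1e-12)) -
                                     log10(max(target, 1e-12)))^2
        }
        opt <- try(stats::optim(free, pen_fn, method = "Nelder-Mead",
                                control = list(maxit = 200)), silent = TRUE)
        if (inherits(opt, "try-error")) break
        free <- opt$par
        g <- predict_at(free, t)
        ob <- objective_of(free)
        if (ob > thr) break
        extreme <- g
        extreme_obj <- ob
      }
      if (dir < 0) { lower[ti] <- min(extreme, v0); lo_obj[ti] <- extreme_obj }
      else { upper[ti] <- max(extreme, v0); up_obj[ti] <- extreme_obj }
    }
  }
  data.frame(time = times, fit = fitv, lower = lower, upper = upper,
             lower_obj = lo_obj, upper_obj = up_obj)
}

#' Reduction of a crosstalk flux under graded inhibition
#'
#' Quantifies how strongly an inhibitory crosstalk reaction (e.g. the
#' deactivation of active Raf1 catalyzed by active Akt) is weakened when
#' the catalyzing protein is inhibited n-fold. The n-fold inhibition is
#' implemented by dividing the rate constants of the protein's activation
#' reactions by `fold`; the readout is the percent reduction of the
#' time-integrated flux of the crosstalk reaction relative to control.
#'
#' @param m ode_model
#' @param params named parameter values (linear scale)
#' @param condition baseline condition
#' @param reaction_name name of the crosstalk reaction (see
#'   `m$reactions[[i]]$name`)
#' @param inhibit_species active species whose activation is reduced
#' @param fold fold inhibition (>= 1)
#' @param horizon,grid_points integration grid
#' @return percent reduction of the integrated flux (0-100)
#' @export
flux_reduction <- function(m, params, condition, reaction_name,
                           inhibit_species, fold, horizon = 120,
                           grid_points = 241) {
  stopifnot(fold >= 1)
  times <- seq(0, horizon, length.out = grid_points)
  rid <- which(vapply(m$reactions, `[[`, "", "name") == reaction_name)
  if (length(rid) != 1) stop("no unique reaction named '", reaction_name, "'")
  r <- m$reactions[[rid]]
  act_rx <- which(vapply(m$reactions, function(x)
    identical(x$product, inhibit_species) && !is.na(x$substrate), TRUE))
  if (!length(act_rx)) stop("species '", inhibit_species,
                            "' has no activation reactions")
  flux_integral <- function(p) {
    traj <- simulate_condition(m, condition, p, times = times)
    k <- p[[r$param]]
    for (pm in r$modifiers[!r$modifiers %in% m$species$id])
      k <- k * p[[pm]]
    rate <- rep(k, length(times))
    for (mod in r$modifiers[r$modifiers %in% m$species$id])
      rate <- rate * traj[, mod]
    if (!is.na(r$substrate)) rate <- rate * traj[, r$substrate]
    auc_trapezoid(times, rate)
  }
  p_inh <- params
  for (ri in act_rx) {
    pid <- m$reactions[[ri]]$param
    p_inh[pid] <- p_inh[pid] / fold
  }
  f0 <- flux_integral(params)
  f1 <- flux_integral(p_inh)
  100 * (1 - f1 / f0)
}
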