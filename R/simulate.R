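# Simulation of ODE models per experimental condition and multistart
# maximum-likelihood parameter estimation.

#' Define an experimental condition
#'
#' @param id condition label
#' @param inputs named numeric vector of input-parameter values (e.g. the
#'   stimulus dose in ng/ml)
#' @param inhibitors named numeric vector of inhibitor strengths in [0,1];
#'   the per-condition binary switch is on exactly for the inhibitors named
#'   here
#' @param times default time grid (minutes)
#' @export
new_condition <- function(id, inputs = numeric(), inhibitors = numeric(),
                          times = c(0, 5, 10, 30, 60, 120)) {
  stopifnot(all(inhibitors >= 0 & inhibitors <= 1))
  list(id = id, inputs = inputs, inhibitors = inhibitors, times = times)
}

# precomputed indices for fast right-hand-side evaluation: every reaction
# rate is eff_k * product of up to `kmax` state factors (modifiers plus
# substrate); factor indices are 1-based into c(1, y) with 1 as padding,
# so the rate vector and the stoichiometry product are fully vectorized
.model_runtime <- function(m) {
  states <- m$species$id
  nr <- length(m$reactions)
  ns <- length(states)
  mod_param <- vector("list", nr)
  factor_list <- vector("list", nr)
  S <- matrix(0, ns, nr)
  par_of <- character(nr)
  for (i in seq_len(nr)) {
    r <- m$reactions[[i]]
    par_of[i] <- r$param
    mods <- r$modifiers
    mod_param[[i]] <- mods[!mods %in% states]
    f <- match(mods[mods %in% states], states)
    if (!is.na(r$substrate)) {
      si <- match(r$substrate, states)
      f <- c(f, si)
      S[si, i] <- S[si, i] - 1
    }
    if (!is.na(r$product)) {
      pi <- match(r$product, states)
      S[pi, i] <- S[pi, i] + 1
    }
    factor_list[[i]] <- f
  }
  kmax <- max(1L, max(lengths(factor_list)))
  Fidx <- matrix(1L, nr, kmax)   # index 1 = the padding constant
  for (i in seq_len(nr)) {
    f <- factor_list[[i]]
    if (length(f)) Fidx[i, seq_along(f)] <- f + 1L
  }
  nz <- which(S != 0, arr.ind = TRUE)
  trip <- as.vector(rbind(nz[, 1], nz[, 2], S[nz]))
  # fixed-size parameter block consumed by the compiled right-hand side
  head <- c(nr, ns, kmax, nrow(nz))
  pvec <- numeric(8192)
  body <- c(head, rep(0, nr), as.vector(Fidx), trip)
  pvec[seq_along(body)] <- body
  list(states = states, par_of = par_of, mod_param = mod_param,
       Fidx = Fidx, S = S, pvec = pvec, effk_at = 4 + seq_len(nr))
}

#' Simulate an ODE model under one condition
#'
#' Deterministic trajectories of all species at the requested times.
#' Integration failures surface as errors (never silent NaN).
#'
#' @param m ode_model
#' @param condition a [new_condition()]
#' @param params named vector of parameter values (linear scale) covering
#'   all kinetic/constant parameters; input parameters are overridden by
#'   the condition's `inputs`
#' @param times time points (minutes); defaults to the condition's grid
#' @param rtol,atol solver tolerances
#' @param runtime precomputed internal index structure (used by the fitter
#'   to avoid rebuilding it for every simulated condition)
#' @return matrix with a `time` column and one column per species
#' @export
simulate_condition <- function(m, condition, params = NULL,
                               times = condition$times,
                               rtol = 1e-8, atol = 1e-10,
                               runtime = NULL) {
  if (is.null(params))
    params <- stats::setNames(m$parameters$value, m$parameters$id)
  if (anyNA(params[m$parameters$id[m$parameters$kind %in%
                                   c("kinetic", "constant")]]))
    stop("missing parameter values")
  for (nm in names(condition$inputs)) params[nm] <- condition$inputs[[nm]]
  if (!is.na(m$signal) && !(m$signal %in% names(condition$inputs)) &&
      !(m$signal %in% names(params)))
    params[m$signal] <- 1
  params <- apply_inhibitors(m, condition$inhibitors, params)

  rt <- if (is.null(runtime)) .model_runtime(m) else runtime
  nr <- length(rt$par_of)
  effk <- unname(params[rt$par_of])
  for (i in seq_len(nr)) {
    for (pm in rt$mod_param[[i]]) effk[i] <- effk[i] * params[[pm]]
  }
  y0 <- stats::setNames(m$species$initial, m$species$id)
  pvec <- rt$pvec
  pvec[rt$effk_at] <- effk
  tt <- sort(unique(c(0, times)))
  out <- try(deSolve::ode(y = y0, times = tt, func = "hn_derivs",
                          parms = pvec, dllname = "hybridnet",
                          initfunc = "hn_initmod",
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error") || anyNA(out) ||
      nrow(out) < length(tt))
    stop("integration failure in condition '", condition$id, "'")
  out[match(times, out[, "time"]), , drop = FALSE]
}

#' Moiety totals along a trajectory
#'
#' For every conserved pool (all proteins except those with explicit
#' synthesis/degradation) returns the total of active + inactive amounts at
#' each time point; these must be constant along any trajectory.
#' @param m ode_model
#' @param traj trajectory matrix from [simulate_condition()]
#' @return matrix time x pool
#' @export
moiety_totals <- function(m, traj) {
  synth <- m$options$synth_deg
  pools <- unique(m$species$pool)
  keep <- vapply(pools, function(p) {
    members <- m$species$id[m$species$pool == p & m$species$form == "active"]
    !any(members %in% synth)
  }, TRUE)
  pools <- pools[keep]
  out <- vapply(pools, function(p) {
    members <- m$species$id[m$species$pool == p]
    rowSums(traj[, members, drop = FALSE])
  }, numeric(nrow(traj)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(traj),
                                       dimnames = list(NULL, pools))
  out
}

#' Assemble a fitting dataset
#'
#' @param records data.frame with columns `condition`, `gel`, `observable`,
#'   `time`, `value` (arbitrary units, > 0)
#' @param observables data.frame with columns `observable`, `species` (the
#'   model species the observable reports) and `scaled` (logical: fit one
#'   multiplicative scaling factor per gel x observable; absolute
#'   observables such as mass-spectrometric degrees of phosphorylation get
#'   `FALSE` and scaling fixed to 1)
#' @param conditions named list of [new_condition()] objects covering every
#'   condition id in `records`
#' @return object of class `experiment_dataset`
#' @export
make_dataset <- function(records, observables, conditions) {
  records <- as.data.frame(records)
  stopifnot(all(c("condition", "gel", "observable", "time", "value") %in%
                  names(records)))
  if (any(records$value <= 0)) stop("observed values must be positive")
  if (!all(records$observable %in% observables$observable))
    stop("unmapped observable(s) in records")
  if (!all(records$condition %in% names(conditions)))
    stop("unknown condition id(s) in records")
  structure(list(records = records, observables = observables,
                 conditions = conditions),
            class = "experiment_dataset")
}

# names of the free scaling parameters of a dataset
.scaling_names <- function(dataset) {
  r <- dataset$records
  sc <- dataset$observables$observable[dataset$observables$scaled]
  u <- unique(r[r$observable %in% sc, c("observable", "gel")])
  if (!nrow(u)) return(character(0))
  u <- u[order(u$observable, u$gel), ]
  paste0("s_", u$observable, "_g", u$gel)
}

# simulate all conditions needed by the dataset and return the model
# prediction for every record (same order as dataset$records)
.predict_records <- function(m, dataset, params, rtol = 1e-8, atol = 1e-10) {
  r <- dataset$records
  pred <- numeric(nrow(r))
  sp_of <- stats::setNames(dataset$observables$species,
                           dataset$observables$observable)
  runtime <- .model_runtime(m)
  for (cid in unique(r$condition)) {
    idx <- which(r$condition == cid)
    times <- sort(unique(r$time[idx]))
    traj <- simulate_condition(m, dataset$conditions[[cid]], params,
                               times = times, rtol = rtol, atol = atol,
                               runtime = runtime)
    for (i in idx) {
      pred[i] <- traj[match(r$time[i], times), sp_of[[r$observable[i]]]]
    }
  }
  pred
}

#' -2 log-likelihood of a parameter set
#'
#' Independent Gaussian errors on log10-transformed observations: each
#' record contributes `((log10 y - log10(s * x)) / sigma)^2 +
#' log(2 * pi * sigma^2)` where `s` is the gel x observable scaling factor
#' and `sigma` the observable's noise parameter. When `sigmas` is `NULL`
#' the noise parameters are profiled analytically (their conditional
#' maximum-likelihood values are used).
#'
#' @param m ode_model
#' @param dataset experiment_dataset
#' @param params named kinetic/constant parameter values (linear scale)
#' @param scalings named vector of scaling factors (linear scale); missing
#'   entries default to 1
#' @param sigmas named per-observable noise SDs (log10 scale) or `NULL`
#' @param floor predictions are floored at this value before the log
#' @return scalar -2 log(L) with attributes `sigmas` and `residuals`
#' @export
objective_neg2loglik <- function(m, dataset, params, scalings = NULL,
                                 sigmas = NULL, floor = 1e-12,
                                 rtol = 1e-8, atol = 1e-10) {
  r <- dataset$records
  pred <- .predict_records(m, dataset, params, rtol = rtol, atol = atol)
  s <- rep(1, nrow(r))
  sc_names <- paste0("s_", r$observable, "_g", r$gel)
  if (!is.null(scalings)) {
    hit <- sc_names %in% names(scalings)
    s[hit] <- scalings[sc_names[hit]]
  }
  raw <- log10(r$value) - log10(pmax(s * pred, floor))
  obs <- r$observable
  if (is.null(sigmas)) {
    sigmas <- vapply(split(raw, obs), function(z) sqrt(mean(z^2)),
                     numeric(1))
    sigmas <- pmax(sigmas, 1e-6)
  }
  sig <- sigmas[obs]
  val <- sum((raw / sig)^2 + log(2 * pi * sig^2))
  attr(val, "sigmas") <- sigmas
  attr(val, "residuals") <- raw
  val
}

# split a free-parameter vector (log10) into model params / scalings
.unpack_free <- function(m, dataset, free) {
  kin <- m$parameters$id[m$parameters$kind %in% c("kinetic", "constant")]
  sc <- .scaling_names(dataset)
  params <- stats::setNames(m$parameters$value, m$parameters$id)
  params[kin] <- 10^free[kin]
  scalings <- 10^free[sc]
  names(scalings) <- sc
  list(params = params, scalings = scalings)
}

#' Multistart maximum-likelihood fit
#'
#' Starting points are drawn by Latin hypercube sampling over the log10
#' parameter bounds; each start is optimized by Levenberg-Marquardt
#' (trust-region) least squares on the log10 parameters, iterating between
#' the weighted least-squares step and the analytic update of the noise
#' parameters. Parameters estimated close to a bound are temporarily fixed
#' for a short period of optimization cycles and then released
#' (boundary-fixing heuristic). Returns the best fit and the sorted
#' waterfall of final objectives across starts.
#'
#' @param m ode_model
#' @param dataset experiment_dataset
#' @param n_starts number of Latin hypercube starts
#' @param seed integer seed (reproducible)
#' @param max_iter Levenberg-Marquardt iterations per cycle
#' @param log_bounds log10 bounds for kinetic/constant parameters
#' @param scaling_bounds log10 bounds for scaling factors
#' @param extra_starts optional matrix (or single named vector) of
#'   additional starting points on the log10 scale, e.g. the optimum of an
#'   enclosing model when fitting a nested structure (warm start); columns
#'   must be named by free parameter, missing entries are filled from the
#'   first Latin hypercube row
#' @param boundary_tol distance (log10 units) from a bound below which a
#'   parameter is considered boundary-close
#' @param fix_iters iterations for which boundary-close parameters stay
#'   fixed
#' @param rtol,atol solver tolerances
#' @return object of class `fit_result`: list with `par` (best parameters,
#'   log10 scale), `objective` (-2 log L), `df` (free kinetic + scaling +
#'   noise parameters), `sigmas`, `waterfall` (sorted per-start
#'   objectives), `seed`, `n_starts`
#' @export
multistart_fit <- function(m, dataset, n_starts = 20, seed = 1,
                           max_iter = 30, log_bounds = c(-5, 3),
                           scaling_bounds = c(-3, 3), extra_starts = NULL,
                           boundary_tol = 0.05, fix_iters = 20,
                           rtol = 1e-6, atol = 1e-8) {
  kin <- m$parameters$id[m$parameters$kind %in% c("kinetic", "constant")]
  sc <- .scaling_names(dataset)
  free_names <- c(kin, sc)
  lower <- c(rep(log_bounds[1], length(kin)), rep(scaling_bounds[1], length(sc)))
  upper <- c(rep(log_bounds[2], length(kin)), rep(scaling_bounds[2], length(sc)))
  names(lower) <- names(upper) <- free_names
  n_obs_sigma <- length(unique(dataset$records$observable))
  df <- length(free_names) + n_obs_sigma

  eval_obj <- function(free) {
    u <- .unpack_free(m, dataset, free)
    tryCatch(objective_neg2loglik(m, dataset, u$params, u$scalings,
                                  rtol = rtol, atol = atol),
             error = function(e) structure(Inf, sigmas = NULL))
  }

  if (!length(free_names)) {
    val <- eval_obj(stats::setNames(numeric(0), character(0)))
    return(structure(list(par = stats::setNames(numeric(0), character(0)),
                          objective = as.numeric(val),
                          sigmas = attr(val, "sigmas"), df = n_obs_sigma,
                          waterfall = as.numeric(val), seed = seed,
                          n_starts = 0L),
                     class = "fit_result"))
  }

  set.seed(as.integer(seed))
  # incrementally augmented Latin hypercube: the first k rows are identical
  # for every n_starts >= k (same seed), so adding starts can only improve
  # the best objective
  H <- lhs::randomLHS(1, length(free_names))
  while (nrow(H) < n_starts) H <- lhs::augmentLHS(H, 1)
  starts <- t(t(H) * (upper - lower))
  starts <- sweep(starts, 2, lower, `+`)
  colnames(starts) <- free_names
  if (!is.null(extra_starts)) {
    if (is.null(dim(extra_starts))) extra_starts <- t(as.matrix(extra_starts))
    for (r in seq_len(nrow(extra_starts))) {
      row <- starts[1, ]
      hit <- intersect(free_names, colnames(extra_starts))
      row[hit] <- pmin(pmax(extra_starts[r, hit], lower[hit]), upper[hit])
      starts <- rbind(starts, row)
    }
    n_starts <- nrow(starts)
  }

  run_lm <- function(free, fixed_mask, sigmas, iters) {
    act <- !fixed_mask
    if (!any(act)) return(free)
    resid_fn <- function(x) {
      fr <- free
      fr[act] <- x
      u <- .unpack_free(m, dataset, fr)
      out <- tryCatch({
        v <- objective_neg2loglik(m, dataset, u$params, u$scalings,
                                  sigmas = sigmas, rtol = rtol, atol = atol)
        attr(v, "residuals") / sigmas[dataset$records$observable]
      }, error = function(e) NULL)
      if (is.null(out)) rep(1e6, nrow(dataset$records)) else out
    }
    # iteration caps are deliberate; nls.lm warns when it hits them
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = free[act], lower = lower[act], upper = upper[act],
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = iters))), silent = TRUE)
    if (!inherits(fit, "try-error")) free[act] <- fit$par
    free
  }

  fit_one <- function(free) {
    v0 <- eval_obj(free)
    if (!is.finite(v0)) return(list(par = free, objective = Inf))
    sigmas <- attr(v0, "sigmas")
    fixed <- rep(FALSE, length(free))
    for (cycle in 1:2) {
      free <- run_lm(free, fixed, sigmas, max_iter)
      v <- eval_obj(free)
      if (!is.finite(v)) return(list(par = free, objective = Inf))
      sigmas <- attr(v, "sigmas")
      at_bound <- (free - lower) < boundary_tol | (upper - free) < boundary_tol
      if (cycle == 1 && any(at_bound) && !all(at_bound)) {
        # boundary-fixing heuristic: freeze boundary-close parameters for a
        # limited period, then release them
        free <- run_lm(free, at_bound, sigmas, fix_iters)
        v <- eval_obj(free)
        if (is.finite(v)) sigmas <- attr(v, "sigmas")
      }
    }
    v <- eval_obj(free)
    list(par = free, objective = as.numeric(v),
         sigmas = attr(v, "sigmas"))
  }

  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) fits[[i]] <- fit_one(starts[i, ])
  objs <- vapply(fits, `[[`, numeric(1), "objective")
  if (all(!is.finite(objs)))
    stop("all ", n_starts, " starts failed; objectives: ",
         paste(utils::head(objs), collapse = ", "))
  best <- fits[[which.min(objs)]]
  structure(list(par = best$par, objective = best$objective,
                 sigmas = best$sigmas, df = df,
                 waterfall = sort(objs), seed = seed, n_starts = n_starts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: -2logL =", format(x$objective, digits = 6),
      " df =", x$df, " (", x$n_starts, "starts )\n")
  invisible(x)
}
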