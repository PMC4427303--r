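# Ranking of fitted model structures by AIC and likelihood-ratio criteria.

#' Akaike Information Criterion of a fit
#'
#' `AIC = 2 k - 2 log(L)` where `k` is the number of free parameters; the
#' fit's objective already stores `-2 log(L)`.
#' @param fit fit_result
#' @return scalar AIC
#' @export
score_aic <- function(fit) 2 * fit$df + fit$objective

#' Likelihood-ratio comparison of a nested fit against the null model
#'
#' The null model is the complete model (the union of all selected building
#' blocks); every candidate structure is nested within it. The penalized
#' score used for ranking is `-2 log(L_nested) - icdf_chisq(alpha, ddf)`
#' with `ddf = df_null - df_nested`; the pass flag tests whether the nested
#' model is a valid simplification of the null model, i.e. whether
#' `-2 log(L_nested) + 2 log(L_null) <= icdf_chisq(alpha, ddf)`.
#'
#' @param fit fit_result of the nested model
#' @param null_fit fit_result of the null (complete) model
#' @param alpha confidence level of the chi-square quantile
#' @return list(penalized =, pass =, ddf =, threshold =)
#' @export
score_lrt <- function(fit, null_fit, alpha = 0.95) {
  ddf <- null_fit$df - fit$df
  if (ddf < 0) stop("model is not nested: df exceeds the null model's df")
  thr <- if (ddf == 0) 0 else stats::qchisq(alpha, df = ddf)
  list(penalized = fit$objective - thr,
       pass = (fit$objective - null_fit$objective) <= thr,
       ddf = ddf, threshold = thr)
}

#' Fit and rank a set of model structures
#'
#' Modes: `forward` ranks the supplied minimal structures together with the
#' core and complete structures; `backward` ranks the complete model and
#' every structure obtained by removing one designated building block from
#' it; `combination` enumerates all unions of two or more designated
#' blocks; `random_control` ranks externally supplied structures (e.g. the
#' random models). Every structure is fitted with the identical fit
#' configuration, scored against the complete (null) model by the
#' LRT-penalized objective, and reported with AIC alongside. Ties are
#' broken by smaller df, then by structure id.
#'
#' @param mode selection mode
#' @param structures named list of model_structure objects (forward /
#'   random_control) or of building blocks; see Details per mode
#' @param master interaction_graph (used to build derived structures)
#' @param complete_block mechanisms of the complete (null) model
#' @param blocks named list of designated building blocks (backward /
#'   combination modes): each element a character vector of mechanism ids
#' @param fitter function(structure_id, model_structure) -> fit_result;
#'   injected so that translation annotations and dataset stay under the
#'   caller's control
#' @param alpha LRT confidence level
#' @return data.frame ranking with columns `id`, `df`, `neg2loglik`,
#'   `aic`, `lrt_penalized`, `lrt_pass`, sorted ascending by the penalized
#'   objective
#' @export
run_selection <- function(mode = c("forward", "backward", "combination",
                                   "random_control"),
                          master, complete_block, fitter,
                          structures = NULL, blocks = NULL, alpha = 0.95) {
  mode <- match.arg(mode)
  todo <- list()
  if (mode == "forward") {
    stopifnot(!is.null(structures))
    todo <- structures
    todo[["core"]] <- model_structure(master, character(0))
    todo[["complete"]] <- model_structure(master, complete_block)
  } else if (mode == "backward") {
    stopifnot(!is.null(blocks))
    todo[["complete"]] <- model_structure(master, complete_block)
    for (nm in names(blocks)) {
      todo[[paste0("minus_", nm)]] <-
        model_structure(master, setdiff(complete_block, blocks[[nm]]))
    }
  } else if (mode == "combination") {
    stopifnot(!is.null(blocks))
    nm <- names(blocks)
    for (k in 2:length(blocks)) {
      for (cmb in utils::combn(nm, k, simplify = FALSE)) {
        todo[[paste(cmb, collapse = "_")]] <-
          model_structure(master, sort(unique(unlist(blocks[cmb]))))
      }
    }
    todo[["complete"]] <- model_structure(master, complete_block)
  } else {
    stopifnot(!is.null(structures))
    todo <- structures
    todo[["complete"]] <- model_structure(master, complete_block)
  }

  fits <- list()
  for (nm in sort(names(todo))) {
    fits[[nm]] <- tryCatch(fitter(nm, todo[[nm]]),
                           error = function(e) e)
  }
  null_fit <- fits[["complete"]]
  if (inherits(null_fit, "error"))
    stop("fit of the complete (null) model failed: ",
         conditionMessage(null_fit))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "error"))
      return(data.frame(id = nm, df = NA, neg2loglik = NA, aic = NA,
                        lrt_penalized = NA, lrt_pass = NA,
                        failed = TRUE))
    l <- score_lrt(f, null_fit, alpha)
    data.frame(id = nm, df = f$df, neg2loglik = f$objective,
               aic = score_aic(f), lrt_penalized = l$penalized,
               lrt_pass = l$pass, failed = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lrt_penalized, out$df, out$id, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Number of structures fitted in combination mode over n blocks
#'
#' All unions of two or more designated blocks: `2^n - n - 1`, e.g. 11 for
#' four blocks (the complete model is fitted in addition as the null).
#' @param n number of designated blocks
#' @export
n_combination_structures <- function(n) 2^n - n - 1
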