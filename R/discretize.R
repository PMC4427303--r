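# Discretization of replicated fold-change time courses into qualitative
# early/late observations.

#' Fold changes between two experimental conditions
#'
#' Computes the per-time-point ratio of a measured quantity in a treatment
#' condition (C2) over its control (C1), optionally dividing each lane by a
#' normalizer channel first (e.g. actin). Replicates are matched by
#' replicate id; time grids are inner-joined on shared times. Fold changes
#' are stored on the natural-log scale.
#'
#' @param d1,d2 data.frames with columns `time`, `value`, optional
#'   `replicate` (default a single replicate) and optional `normalizer`
#' @param pair length-2 character vector naming (C1, C2)
#' @param species measured species id
#' @return object of class `fold_change_series`: data.frame with columns
#'   `time`, `replicate`, `log_fc`, plus attributes `pair` and `species`
#' @export
compute_fold_changes <- function(d1, d2, pair = c("C1", "C2"), species = "x") {
  prep <- function(d) {
    d <- as.data.frame(d)
    if (is.null(d$replicate)) d$replicate <- 1L
    if (any(!is.finite(d$value)) || any(d$value <= 0))
      stop("raw values must be positive and finite")
    if (!is.null(d$normalizer)) {
      if (any(d$normalizer <= 0)) stop("normalizer values must be positive")
      d$value <- d$value / d$normalizer
    }
    d[c("time", "replicate", "value")]
  }
  a <- prep(d1); b <- prep(d2)
  m <- merge(a, b, by = c("time", "replicate"), suffixes = c("_c1", "_c2"))
  if (!nrow(m)) stop("no shared (time, replicate) points between conditions")
  m <- m[order(m$replicate, m$time), ]
  out <- data.frame(time = m$time, replicate = m$replicate,
                    log_fc = log(m$value_c2) - log(m$value_c1))
  attr(out, "pair") <- pair
  attr(out, "species") <- species
  class(out) <- c("fold_change_series", "data.frame")
  out
}

#' Discretize a fold-change series into an early/late observation
#'
#' Per time point, the call is `increase` if all replicates exceed the fold
#' threshold `theta`, `decrease` if all fall below `1/theta`, `no_change`
#' if all lie within `[1/theta, theta]`, and `not_conclusive` if the
#' replicates disagree. The early response is the first conclusive call at
#' a time within `early_window`; the late response is the first subsequent
#' conclusive call that differs from the early one, or, if the response
#' never changes direction, the persisting early call. With
#' `early_rule = "all"` every conclusive point inside the early window must
#' agree, otherwise the early call is `not_conclusive`.
#'
#' @param fc a `fold_change_series` (log-scale fold changes)
#' @param theta fold threshold on the ratio scale, > 1
#' @param early_window end of the early window in minutes
#' @param early_rule `"first"` (default) or `"all"`
#' @return data.frame row with columns `pair`, `species`, `early`, `late`
#' @export
discretize_responses <- function(fc, theta = 1.5, early_window = 30,
                                 early_rule = c("first", "all")) {
  stopifnot(theta > 1)
  early_rule <- match.arg(early_rule)
  lt <- log(theta)
  times <- sort(unique(fc$time))
  call_at <- vapply(times, function(t) {
    v <- fc$log_fc[fc$time == t]
    if (all(v > lt)) "increase"
    else if (all(v < -lt)) "decrease"
    else if (all(abs(v) <= lt)) "no_change"
    else "not_conclusive"
  }, character(1))
  conclusive <- call_at != "not_conclusive"
  in_early <- times <= early_window
  early <- "not_conclusive"
  early_t <- NA_real_
  if (any(conclusive & in_early)) {
    idx <- which(conclusive & in_early)
    if (early_rule == "first") {
      early <- call_at[idx[1]]; early_t <- times[idx[1]]
    } else if (length(unique(call_at[idx])) == 1L) {
      early <- call_at[idx[1]]; early_t <- times[idx[length(idx)]]
    }
  }
  late <- "not_conclusive"
  if (early != "not_conclusive") {
    # the late response is the first *effect* opposite to the early one;
    # a below-threshold (no_change) call is not an opposite effect
    after <- which(conclusive & times > early_t)
    flip <- after[call_at[after] != early &
                    call_at[after] %in% c("increase", "decrease")]
    late <- if (length(flip)) call_at[flip[1]] else early
  }
  data.frame(pair = paste(attr(fc, "pair"), collapse = " vs "),
             species = attr(fc, "species"),
             early = early, late = late, stringsAsFactors = FALSE)
}

#' Discretize a quantitative dataset into qualitative observations
#'
#' Convenience wrapper: for each requested condition pair and observable,
#' extracts the two conditions from a long-format dataset, computes fold
#' changes replicate-wise and discretizes them.
#'
#' @param dataset data.frame with columns `condition`, `replicate`, `time`,
#'   `observable`, `value`
#' @param pairs data.frame with columns `c1`, `c2`, `inhibitors` (the
#'   additional inhibitors of c2 relative to c1, `+`-separated)
#' @param observables character vector of observable ids (must equal the
#'   measured species ids they report on)
#' @inheritParams discretize_responses
#' @return data.frame of observations with columns `pair`, `inhibitors`,
#'   `species`, `early`, `late`
#' @export
discretize_dataset <- function(dataset, pairs, observables, theta = 1.5,
                               early_window = 30,
                               early_rule = c("first", "all")) {
  early_rule <- match.arg(early_rule)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (obs in observables) {
      d1 <- dataset[dataset$condition == pairs$c1[i] &
                      dataset$observable == obs & dataset$time > 0, ]
      d2 <- dataset[dataset$condition == pairs$c2[i] &
                      dataset$observable == obs & dataset$time > 0, ]
      if (!nrow(d1) || !nrow(d2)) next
      fc <- compute_fold_changes(d1[c("time", "replicate", "value")],
                                 d2[c("time", "replicate", "value")],
                                 pair = c(pairs$c1[i], pairs$c2[i]),
                                 species = obs)
      r <- discretize_responses(fc, theta = theta,
                                early_window = early_window,
                                early_rule = early_rule)
      r$inhibitors <- pairs$inhibitors[i]
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(pair = character(),
                                      inhibitors = character(),
                                      species = character(),
                                      early = character(),
                                      late = character()))
  out[c("pair", "inhibitors", "species", "early", "late")]
}
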