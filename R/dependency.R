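# Qualitative prediction via the dependency matrix.
#
# Path semantics: "paths" are simple directed paths; signs are products of
# edge signs along the path. Computed exactly by depth-first enumeration
# (the graphs handled here have <= ~35 nodes and are sparse). Walk
# semantics would differ in sign through negative cycles, hence the exact
# simple-path treatment.

#' Signed reachability between two species
#'
#' Tests whether a simple directed path with positive (resp. negative) sign
#' product exists from `a` to `b`.
#' @param g interaction_graph
#' @param a,b species ids, `a != b`
#' @return list(has_positive_path =, has_negative_path =)
#' @export
sign_reachability <- function(g, a, b) {
  stopifnot(a != b, a %in% g$species$id, b %in% g$species$id)
  dep <- path_profile(g, a, nfb = character(0))
  i <- match(b, g$species$id)
  list(has_positive_path = dep$pos[i], has_negative_path = dep$neg[i])
}

#' Species on negative feedback loops
#'
#' Returns every species lying on at least one directed simple cycle whose
#' edge-sign product is negative.
#' @param g interaction_graph
#' @return character vector of species ids
#' @export
negative_feedback_nodes <- function(g) {
  ids <- g$species$id
  if (!length(ids) || !nrow(g$edges)) return(character(0))
  on_neg <- .neg_cycle_nodes_cpp(length(ids),
                                 match(g$edges$source, ids),
                                 match(g$edges$target, ids),
                                 g$edges$sign)
  ids[on_neg]
}

# For one source node: for every target, whether a positive / negative
# simple path exists, and whether any simple path touches a node of the
# negative-feedback set (endpoints count as touched).
path_profile <- function(g, from, nfb = NULL) {
  ids <- g$species$id
  if (is.null(nfb)) nfb <- negative_feedback_nodes(g)
  if (!nrow(g$edges)) {
    z <- logical(length(ids))
    return(list(pos = z, neg = z, via_nfb = z))
  }
  m <- .path_profile_cpp(length(ids),
                         match(g$edges$source, ids),
                         match(g$edges$target, ids),
                         g$edges$sign, match(from, ids), ids %in% nfb)
  list(pos = m[1, ], neg = m[2, ], via_nfb = m[3, ])
}

#' Dependency matrix of an interaction graph
#'
#' Classifies the qualitative influence of every ordered species pair
#' (a, b), a != b, from the signs of all simple directed paths a -> b:
#' activator if all paths are positive, inhibitor if all are negative,
#' ambivalent if both signs occur, neutral if no path exists. Activators
#' and inhibitors are *weak* if at least one path from a to b traverses a
#' node involved in a negative feedback loop (endpoints included), and
#' *strong* otherwise. A weak factor cannot pin down the late response: the
#' feedback may overturn the initial effect.
#'
#' @param g interaction_graph
#' @return character matrix (rows = perturbed species a, columns =
#'   measured species b) with entries in `strong_activator`,
#'   `weak_activator`, `strong_inhibitor`, `weak_inhibitor`, `ambivalent`,
#'   `neutral`; the diagonal is `NA`.
#' @export
dependency_matrix <- function(g) {
  ids <- g$species$id
  n <- length(ids)
  m <- matrix(NA_character_, n, n, dimnames = list(ids, ids))
  nfb <- negative_feedback_nodes(g)
  for (i in seq_len(n)) {
    prof <- path_profile(g, ids[i], nfb = nfb)
    for (j in seq_len(n)) {
      if (i == j) next
      m[i, j] <- classify_dependency(prof$pos[j], prof$neg[j], prof$via_nfb[j])
    }
  }
  m
}

classify_dependency <- function(pos, neg, via_nfb) {
  if (pos && neg) return("ambivalent")
  if (!pos && !neg) return("neutral")
  kind <- if (pos) "activator" else "inhibitor"
  paste0(if (via_nfb) "weak_" else "strong_", kind)
}

#' Export a dependency matrix as CSV
#' @param m matrix from [dependency_matrix()]
#' @param path output file
#' @export
write_dependency_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Predicted qualitative response to inhibition
#'
#' Given the species additionally inhibited in a treatment condition
#' (relative to its control) and a measured species, derives the set of
#' qualitatively allowed early and late differential responses from the
#' dependency matrix. Early: if all inhibited species are activators
#' (strong or weak) of the measured species the model predicts a decrease;
#' if all are inhibitors, an increase; if all are neutral, no change;
#' otherwise (an ambivalent factor, or a mix of classes) any response is
#' allowed. Late: as early but only *strong* factors restrict the
#' response; any weak factor leaves the late response unrestricted.
#'
#' @param g interaction_graph (dummy nodes already inserted)
#' @param inhibited non-empty character vector of inhibited species ids
#' @param measured measured species id (must not be inhibited)
#' @param dep optional precomputed dependency matrix of `g`
#' @return list(early_allowed =, late_allowed =), subsets of
#'   `c("increase","decrease","no_change")`
#' @export
predict_response <- function(g, inhibited, measured, dep = NULL) {
  if (!length(inhibited)) stop("'inhibited' must be non-empty")
  if (measured %in% inhibited)
    stop("measured species '", measured, "' is itself inhibited: ",
         "not a meaningful comparison")
  if (is.null(dep)) dep <- dependency_matrix(g)
  cls <- dep[inhibited, measured]
  .allowed_from_classes(cls)
}

# combination rule over the dependency classes of all inhibited species
.allowed_from_classes <- function(cls) {
  all3 <- c("increase", "decrease", "no_change")
  early <-
    if (all(cls %in% c("strong_activator", "weak_activator"))) "decrease"
    else if (all(cls %in% c("strong_inhibitor", "weak_inhibitor"))) "increase"
    else if (all(cls == "neutral")) "no_change"
    else all3
  late <-
    if (all(cls == "strong_activator")) "decrease"
    else if (all(cls == "strong_inhibitor")) "increase"
    else if (all(cls == "neutral")) "no_change"
    else all3
  list(early_allowed = early, late_allowed = late)
}

# dependency classes from the given source species to every species of g;
# cheaper than the full matrix when only a few perturbed rows are needed
.dep_rows <- function(g, sources) {
  ids <- g$species$id
  nfb <- negative_feedback_nodes(g)
  m <- matrix(NA_character_, length(sources), length(ids),
              dimnames = list(sources, ids))
  for (src in sources) {
    prof <- path_profile(g, src, nfb = nfb)
    for (j in seq_along(ids)) {
      if (ids[j] == src) next
      m[src, j] <- classify_dependency(prof$pos[j], prof$neg[j],
                                       prof$via_nfb[j])
    }
  }
  m
}

#' Check a model structure against discretized observations
#'
#' An observation is a condition pair (control vs the same condition with
#' one or two additional inhibitors), a measured species, and discretized
#' early/late responses in `increase`, `decrease`, `no_change`,
#' `not_conclusive`. A structure is consistent iff every conclusive
#' observed response is a member of the corresponding allowed set;
#' `not_conclusive` entries are skipped.
#'
#' @param s model_structure
#' @param data data.frame with columns `inhibitors` (inhibitor names of the
#'   additional treatment, several separated by `+`), `species`, `early`,
#'   `late`; an optional `pair` column labels the condition pair.
#' @param stop_first stop at the first violated observation (used by the
#'   enumeration for speed)
#' @param cache optional environment memoizing dependency matrices across
#'   calls, keyed by condition + edge set
#' @return list(consistent = flag, report = data.frame of per-observation
#'   pass/fail with the allowed sets)
#' @export
check_consistency <- function(s, data, stop_first = FALSE, cache = NULL) {
  if (!nrow(data)) return(list(consistent = TRUE, report = data.frame()))
  g0 <- structure_graph(s)
  bad <- setdiff(data$species, g0$species$id)
  if (length(bad)) stop("observation references unknown species: ",
                        paste(unique(bad), collapse = ", "))
  inh_sets <- strsplit(as.character(data$inhibitors), "+", fixed = TRUE)
  bad <- setdiff(unlist(inh_sets), names(g0$inhibitors))
  if (length(bad)) stop("observation references unknown inhibitor: ",
                        paste(unique(bad), collapse = ", "))
  ekey <- paste(with(g0$edges, paste(source, target, sign, sep = ",")),
                collapse = ";")
  rep_rows <- vector("list", nrow(data))
  consistent <- TRUE
  dep_local <- list()
  for (i in seq_len(nrow(data))) {
    inhs <- inh_sets[[i]]
    ckey <- paste(sort(inhs), collapse = "+")
    dep <- NULL; gi <- NULL; targets <- NULL
    full_key <- paste(ckey, ekey, sep = "|")
    if (!is.null(cache) && !is.null(cache[[full_key]])) {
      ent <- cache[[full_key]]
      dep <- ent$dep; targets <- ent$targets
    } else if (!is.null(dep_local[[ckey]])) {
      ent <- dep_local[[ckey]]
      dep <- ent$dep; targets <- ent$targets
    } else {
      r <- resolve_inhibitors(g0, inhs)
      targets <- r$targets
      dep <- .dep_rows(r$graph, unique(unname(targets)))
      ent <- list(dep = dep, targets = targets)
      dep_local[[ckey]] <- ent
      if (!is.null(cache)) cache[[full_key]] <- ent
    }
    pr <- predict_response(NULL, unname(targets), data$species[i], dep = dep)
    early_ok <- data$early[i] == "not_conclusive" ||
      data$early[i] %in% pr$early_allowed
    late_ok <- data$late[i] == "not_conclusive" ||
      data$late[i] %in% pr$late_allowed
    ok <- early_ok && late_ok
    consistent <- consistent && ok
    rep_rows[[i]] <- data.frame(
      inhibitors = data$inhibitors[i], species = data$species[i],
      early = data$early[i], late = data$late[i],
      early_allowed = paste(pr$early_allowed, collapse = "/"),
      late_allowed = paste(pr$late_allowed, collapse = "/"),
      pass = ok, stringsAsFactors = FALSE)
    if (stop_first && !ok) break
  }
  list(consistent = consistent,
       report = do.call(rbind, rep_rows[!vapply(rep_rows, is.null, TRUE)]))
}
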