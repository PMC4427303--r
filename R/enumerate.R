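# Exact enumeration of minimal consistent model structures.

# Build a fast per-block consistency tester for one (master, data) pair.
# Dummy nodes for every kinase-activity inhibitor are inserted once up
# front (dummy insertion preserves the dependency class of every
# pre-existing species pair), all species are mapped to integer indices,
# and each block is tested with the compiled signed-path search, avoiding
# any per-block graph construction.
.fast_consistency_tester <- function(master, data) {
  gD <- master
  targets_of <- character(0)
  for (nm in names(master$inhibitors)) {
    r <- insert_dummy_nodes(gD, nm)
    gD <- r$graph
    targets_of[nm] <- r$target
  }
  ids <- gD$species$id
  n <- length(ids)
  e <- gD$edges
  from <- match(e$source, ids)
  to <- match(e$target, ids)
  sgn <- e$sign
  mech <- e$mechanism
  # deduplication groups for edges shared between mechanisms
  grp <- match(paste(from, to, sgn), unique(paste(from, to, sgn)))
  is_core <- is.na(mech)

  inh_sets <- strsplit(as.character(data$inhibitors), "+", fixed = TRUE)
  cond_key <- vapply(inh_sets, function(x) paste(sort(x), collapse = "+"), "")
  conds <- lapply(split(seq_len(nrow(data)), cond_key), function(idx) {
    tg <- match(unique(targets_of[inh_sets[[idx[1]]]]), ids)
    list(targets = tg,
         measured = match(data$species[idx], ids),
         early = data$early[idx], late = data$late[idx])
  })

  keep_rows <- function(block) {
    sel <- which(is_core | mech %in% block)
    sel[!duplicated(grp[sel])]               # dedup edges shared by mechanisms
  }
  key_fn <- function(block) paste(keep_rows(block), collapse = ",")
  test_fn <- function(block) {
    keep <- keep_rows(block)
    f <- from[keep]; t <- to[keep]; s <- sgn[keep]
    nfb <- .neg_cycle_nodes_cpp(n, f, t, s)
    for (cd in conds) {
      cls <- matrix(NA_character_, length(cd$targets), n)
      for (i in seq_along(cd$targets)) {
        prof <- .path_profile_cpp(n, f, t, s, cd$targets[i], nfb)
        for (j in unique(cd$measured)) {
          cls[i, j] <- classify_dependency(prof[1, j], prof[2, j],
                                           prof[3, j])
        }
      }
      for (k in seq_along(cd$measured)) {
        al <- .allowed_from_classes(cls[, cd$measured[k]])
        if (cd$early[k] != "not_conclusive" &&
            !cd$early[k] %in% al$early_allowed) return(FALSE)
        if (cd$late[k] != "not_conclusive" &&
            !cd$late[k] %in% al$late_allowed) return(FALSE)
      }
    }
    TRUE
  }
  list(test = test_fn, key = key_fn)
}

#' Enumerate all minimal model structures consistent with qualitative data
#'
#' Searches the space of building blocks (subsets of candidate mechanisms)
#' breadth-first over block cardinality. Because no `no_change` response is
#' ever restricted away by adding edges, consistency is monotone: every
#' superset of a consistent block is consistent (when the data contain no
#' conclusive `no_change` observation). The search therefore prunes every
#' superset of an already-selected block, which simultaneously guarantees
#' minimality (no submodel of a selected structure explains the data) and
#' completeness (every minimal structure is found). Consistency verdicts
#' are memoized by the structure's induced edge set: different blocks that
#' induce the same edge set (mechanisms may share edges) are evaluated
#' once.
#'
#' @param master interaction_graph with candidate mechanisms
#' @param data discretized observations (see [check_consistency()])
#' @param max_block optional cap on block cardinality (default: all)
#' @param progress print per-level progress
#' @return list with elements `minimal_structures` (list of
#'   [model_structure()]), `n_tested` (number of consistency evaluations,
#'   memoized duplicates not re-counted), `complete_block` (union of all
#'   selected blocks) and, when nothing is consistent, `diagnostic` (the
#'   failure report of the full master model).
#' @export
enumerate_minimal_models <- function(master, data, max_block = Inf,
                                     progress = FALSE) {
  mechs <- graph_mechanisms(master)
  verdicts <- new.env(parent = emptyenv())
  n_tested <- 0L
  tester <- .fast_consistency_tester(master, data)
  test_block <- function(block) {
    k <- tester$key(block)
    if (!is.null(verdicts[[k]])) return(verdicts[[k]])
    n_tested <<- n_tested + 1L
    v <- tester$test(block)
    verdicts[[k]] <- v
    v
  }

  selected <- list()
  kmax <- min(length(mechs), max_block)
  # level-wise (Apriori) search: a size-k block is a candidate only if
  # every size-(k-1) sub-block failed; this both prunes supersets of
  # selected blocks (minimality) and mirrors the procedure of combining a
  # failing structure with further candidate mechanisms (completeness,
  # given monotone consistency)
  failed_prev <- new.env(parent = emptyenv())
  bkey <- function(b) if (length(b)) paste(b, collapse = ",") else "(empty)"
  if (test_block(character(0))) {
    selected[[1L]] <- model_structure(master, character(0))
  } else {
    failed_prev[[bkey(character(0))]] <- TRUE
    for (k in seq_len(kmax)) {
      prev <- ls(failed_prev)
      if (!length(prev)) break
      cand <- list()
      for (pk in prev) {
        b <- if (pk != "(empty)") strsplit(pk, ",", fixed = TRUE)[[1]]
             else character(0)
        ext <- if (length(b)) mechs[mechs > b[length(b)]] else mechs
        for (m in ext) cand[[length(cand) + 1L]] <- c(b, m)
      }
      if (k > 1L) {
        cand <- Filter(function(b) {
          all(vapply(seq_along(b), function(i)
            !is.null(failed_prev[[bkey(b[-i])]]), TRUE))
        }, cand)
      }
      if (!length(cand)) break
      failed_now <- new.env(parent = emptyenv())
      found <- 0L
      for (b in cand) {
        if (test_block(b)) {
          selected[[length(selected) + 1L]] <- model_structure(master, b)
          found <- found + 1L
        } else {
          failed_now[[bkey(b)]] <- TRUE
        }
      }
      if (progress)
        message("block size ", k, ": tested ", length(cand),
                ", selected ", found)
      failed_prev <- failed_now
    }
  }

  out <- list(minimal_structures = selected,
              n_tested = n_tested,
              complete_block = sort(unique(unlist(lapply(selected,
                                                         `[[`, "block")))))
  if (!length(selected)) {
    full <- check_consistency(model_structure(master, mechs), data)
    out$diagnostic <- full$report[!full$report$pass, , drop = FALSE]
  }
  out
}

#' Complete model structure from an enumeration result
#'
#' The complete model contains exactly those candidate mechanisms included
#' in at least one selected minimal model structure.
#' @param master interaction_graph
#' @param enum result of [enumerate_minimal_models()]
#' @return model_structure
#' @export
complete_structure <- function(master, enum) {
  model_structure(master, enum$complete_block)
}

#' Membership matrix of selected structures
#'
#' One row per structure, one column per candidate mechanism of the
#' complete model; 1 indicates that the mechanism is present in the
#' structure's block, 0 that it is not.
#' @param enum result of [enumerate_minimal_models()]
#' @return integer matrix
#' @export
membership_matrix <- function(enum) {
  mechs <- enum$complete_block
  m <- t(vapply(enum$minimal_structures,
                function(s) as.integer(mechs %in% s$block),
                integer(length(mechs))))
  colnames(m) <- mechs
  rownames(m) <- seq_len(nrow(m))
  m
}

#' Random control model structures
#'
#' Draws random subsets of `edge_count` candidate edges from the candidate
#' edges of the complete model. Draws that are identical to or comprise the
#' edge set of any selected minimal model structure are rejected and
#' redrawn. Used as a negative control for the selection procedure: random
#' structures should mostly rank worse than selected ones.
#'
#' @param master interaction_graph
#' @param minimal list of minimal [model_structure()]s
#' @param edge_count candidate edges per random model
#' @param n number of random models
#' @param seed integer seed (draws are reproducible)
#' @param max_draws bound on total draws before giving up
#' @return list of `n` random structures; each is a list with elements
#'   `edges` (data.frame of the chosen candidate edges) and `label`.
#' @export
generate_random_models <- function(master, minimal, edge_count = 5, n = 50,
                                   seed = 1, max_draws = 10000 * n) {
  complete_block <- sort(unique(unlist(lapply(minimal, `[[`, "block"))))
  ce <- master$edges[!is.na(master$edges$mechanism) &
                       master$edges$mechanism %in% complete_block, ,
                     drop = FALSE]
  ce <- ce[!duplicated(paste(ce$source, ce$target, ce$sign, sep = "\r")), ,
           drop = FALSE]
  if (nrow(ce) < edge_count)
    stop("complete model has fewer than ", edge_count, " candidate edges")
  ekey <- function(e) sort(paste(e$source, e$target, e$sign, sep = ","))
  min_keys <- lapply(minimal, function(s) {
    e <- structure_edges(s)
    ekey(e[!is.na(e$mechanism), , drop = FALSE])
  })
  set.seed(as.integer(seed))
  out <- list()
  draws <- 0L
  while (length(out) < n) {
    draws <- draws + 1L
    if (draws > max_draws)
      stop("rejection rate too high: could not draw ", n,
           " admissible random models in ", max_draws, " attempts")
    idx <- sort(sample.int(nrow(ce), edge_count))
    e <- ce[idx, , drop = FALSE]
    k <- ekey(e)
    if (any(vapply(min_keys, function(mk) all(mk %in% k), TRUE))) next
    out[[length(out) + 1L]] <- list(edges = e,
                                    label = paste0("rand", length(out) + 1L))
  }
  out
}
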