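#' Signed interaction graphs with a core / candidate-mechanism partition
#'
#' An `interaction_graph` represents a signaling network as a directed graph
#' whose nodes are species (usually the active forms of signaling proteins)
#' and whose edges carry a sign: `+1` for activation, `-1` for inhibition.
#' Edges are partitioned into an always-present *core model* and named
#' *candidate mechanisms* (crosstalk/feedback edges reported in the
#' literature that may or may not be active in a given cell context).
#'
#' @param species data.frame with columns `id`, `name`, `role`
#'   (`"signal"`, `"protein"`, `"constant"` or `"dummy"`). Missing columns
#'   are filled with defaults (`name = id`, `role = "protein"`).
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (+1/-1) and `mechanism` (candidate mechanism id, `NA` for core edges).
#' @param measured character vector of measured species ids.
#' @param inhibitors named list; each element is
#'   `list(kind = "node"|"kinase_activity", species = <id>)` describing how
#'   the named perturbation acts on the network.
#' @param mechanism_labels optional named character vector of free-text
#'   labels for mechanism ids.
#' @return An object of class `interaction_graph`.
#' @export
interaction_graph <- function(species = NULL, edges = NULL,
                              measured = character(), inhibitors = list(),
                              mechanism_labels = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), mechanism = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (col in c("source", "target")) edges[[col]] <- as.character(edges[[col]])
  if (is.null(edges$mechanism)) edges$mechanism <- rep(NA_character_, nrow(edges))
  edges$mechanism <- as.character(edges$mechanism)
  edges$mechanism[!is.na(edges$mechanism) & edges$mechanism == ""] <- NA_character_
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L)))
    stop("edge signs must be +1 or -1")
  if (nrow(edges) && any(edges$source == edges$target))
    stop("self-loops are not allowed in input graphs")

  ids <- unique(c(if (!is.null(species)) as.character(species$id),
                  edges$source, edges$target))
  if (is.null(species)) {
    species <- data.frame(id = ids, stringsAsFactors = FALSE)
  } else {
    species <- as.data.frame(species, stringsAsFactors = FALSE)
    species$id <- as.character(species$id)
    extra <- setdiff(ids, species$id)
    if (length(extra)) {
      pad <- data.frame(id = extra, stringsAsFactors = FALSE)
      for (col in setdiff(names(species), "id")) pad[[col]] <- NA
      species <- rbind(species, pad[names(species)])
    }
  }
  if (anyDuplicated(species$id)) stop("species ids must be unique")
  if (is.null(species$name)) species$name <- species$id
  species$name[is.na(species$name)] <- species$id[is.na(species$name)]
  if (is.null(species$role)) species$role <- rep("protein", nrow(species))
  species$role[is.na(species$role)] <- "protein"
  ok_roles <- c("signal", "protein", "constant", "dummy")
  if (!all(species$role %in% ok_roles))
    stop("species roles must be one of: ", paste(ok_roles, collapse = ", "))

  measured <- as.character(measured)
  if (!all(measured %in% species$id))
    stop("measured species not in graph: ",
         paste(setdiff(measured, species$id), collapse = ", "))
  for (nm in names(inhibitors)) {
    spec <- inhibitors[[nm]]
    if (!is.list(spec) || !spec$kind %in% c("node", "kinase_activity"))
      stop("inhibitor '", nm, "' must have kind 'node' or 'kinase_activity'")
    if (!spec$species %in% species$id)
      stop("inhibitor '", nm, "' targets unknown species '", spec$species, "'")
  }

  # duplicate identical (source,target,sign,mechanism) rows collapse silently;
  # contradictory duplicates (same pair, both signs) are allowed but noted
  key <- with(edges, paste(source, target, sign, mechanism, sep = "\r"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  pair <- with(edges, paste(source, target, mechanism, sep = "\r"))
  contra <- pair[duplicated(pair)]
  if (length(contra))
    message("note: ", length(contra), " contradictory signed edge pair(s) kept (multigraph)")
  rownames(edges) <- NULL
  rownames(species) <- NULL

  structure(list(species = species,
                 edges = edges[c("source", "target", "sign", "mechanism")],
                 measured = measured,
                 inhibitors = inhibitors,
                 mechanism_labels = mechanism_labels),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", nrow(x$species), "species,",
      sum(is.na(x$edges$mechanism)), "core edges,",
      length(graph_mechanisms(x)), "candidate mechanisms\n")
  if (length(x$measured))
    cat("  measured:", paste(x$measured, collapse = ", "), "\n")
  if (length(x$inhibitors))
    cat("  inhibitors:", paste(names(x$inhibitors), collapse = ", "), "\n")
  invisible(x)
}

#' Candidate mechanism ids of a graph (sorted)
#' @param g interaction_graph
#' @return character vector of mechanism ids
#' @export
graph_mechanisms <- function(g) {
  sort(unique(g$edges$mechanism[!is.na(g$edges$mechanism)]))
}

#' Construct a model structure (core + building block)
#'
#' A model structure is a subgraph of a master interaction graph consisting
#' of the full core model plus a subset of candidate mechanisms, the
#' "building block". Two structures are equal iff their blocks are equal.
#'
#' @param graph an `interaction_graph` (the master model)
#' @param block character vector of mechanism ids
#' @return object of class `model_structure`
#' @export
model_structure <- function(graph, block = character()) {
  stopifnot(inherits(graph, "interaction_graph"))
  block <- sort(unique(as.character(block)))
  bad <- setdiff(block, graph_mechanisms(graph))
  if (length(bad)) stop("unknown mechanism id(s): ", paste(bad, collapse = ", "))
  structure(list(graph = graph, block = block), class = "model_structure")
}

#' @export
print.model_structure <- function(x, ...) {
  cat("model_structure: block {",
      if (length(x$block)) paste(x$block, collapse = ", ") else "core only",
      "}\n")
  invisible(x)
}

#' Edge set induced by a model structure
#'
#' Core edges plus the edges of every mechanism in the block. An edge shared
#' by several mechanisms of the block is deduplicated at the graph level, so
#' a structure's edge set is core union-of-block edges.
#'
#' @param s model_structure
#' @return data.frame of edges (`source`, `target`, `sign`, `mechanism`)
#' @export
structure_edges <- function(s) {
  e <- s$graph$edges
  e <- e[is.na(e$mechanism) | e$mechanism %in% s$block, , drop = FALSE]
  key <- with(e, paste(source, target, sign, sep = "\r"))
  # prefer the core copy of a duplicated signed edge
  e <- e[order(!is.na(e$mechanism), e$mechanism, method = "radix"), , drop = FALSE]
  key <- with(e, paste(source, target, sign, sep = "\r"))
  e <- e[!duplicated(key), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Interaction graph induced by a model structure
#'
#' Species with no incident edge in the structure are dropped unless they
#' are measured, inhibited, constants or the signal.
#' @param s model_structure
#' @param drop_isolated drop species not touched by any retained edge
#' @return interaction_graph
#' @export
structure_graph <- function(s, drop_isolated = FALSE) {
  e <- structure_edges(s)
  g <- s$graph
  sp <- g$species
  if (drop_isolated) {
    keep <- sp$id %in% c(e$source, e$target, g$measured,
                         vapply(g$inhibitors, `[[`, "", "species")) |
      sp$role %in% c("signal", "constant")
    sp <- sp[keep, , drop = FALSE]
    e <- e[e$source %in% sp$id & e$target %in% sp$id, , drop = FALSE]
  }
  interaction_graph(sp, e, measured = intersect(g$measured, sp$id),
                    inhibitors = g$inhibitors[vapply(g$inhibitors, `[[`, "",
                                                     "species") %in% sp$id],
                    mechanism_labels = g$mechanism_labels)
}

#' Read a signed interaction graph from an edge-list file
#'
#' The CSV dialect has header `source,sign,target,mechanism` with sign in
#' \{+1, -1\} (also accepted: `+`, `-`, `1`, `-1`) and an empty mechanism
#' field for core edges. The SIF dialect is tab-separated
#' `source relation target` with relation `activates`/`inhibits`; SIF has no
#' mechanism column, so all SIF edges load as core.
#'
#' @param path file path
#' @param format `"csv"` or `"sif"`
#' @param ... passed on to [interaction_graph()] (e.g. `measured`,
#'   `inhibitors`, `species`)
#' @return interaction_graph
#' @export
load_graph <- function(path, format = c("csv", "sif"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  parse_sign <- function(x, line) {
    s <- ifelse(x %in% c("+", "+1", "1", "activates"), 1L,
                ifelse(x %in% c("-", "-1", "inhibits"), -1L, NA_integer_))
    if (anyNA(s))
      stop("parse error at line ", line[which(is.na(s))[1]],
           ": bad sign/relation '", x[which(is.na(s))[1]], "'")
    s
  }
  if (format == "csv") {
    d <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
    need <- c("source", "sign", "target")
    if (!all(need %in% names(d)))
      stop("parse error: CSV must have columns source,sign,target[,mechanism]")
    if (is.null(d$mechanism)) d$mechanism <- ""
    bad <- which(d$source == "" | d$target == "")
    if (length(bad)) stop("parse error at line ", bad[1] + 1L, ": empty species id")
    edges <- data.frame(source = d$source, target = d$target,
                        sign = parse_sign(d$sign, seq_len(nrow(d)) + 1L),
                        mechanism = ifelse(d$mechanism == "", NA, d$mechanism),
                        stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    if (length(parts) && !all(lengths(parts) == 3L))
      stop("parse error at line ", which(lengths(parts) != 3L)[1],
           ": SIF rows must be 'source<TAB>relation<TAB>target'")
    edges <- data.frame(
      source = vapply(parts, `[[`, "", 1L),
      target = vapply(parts, `[[`, "", 3L),
      sign = parse_sign(vapply(parts, `[[`, "", 2L), seq_along(parts)),
      mechanism = NA_character_, stringsAsFactors = FALSE)
  }
  interaction_graph(edges = edges, ...)
}

#' Write a graph as a CSV edge list or SIF file
#'
#' CSV round-trips with [load_graph()] bit-identically under the canonical
#' edge ordering (mechanism, source, target, sign). SIF export loses the
#' mechanism grouping.
#' @param g interaction_graph
#' @param path output file
#' @param format `"csv"` or `"sif"`
#' @export
save_graph <- function(g, path, format = c("csv", "sif")) {
  format <- match.arg(format)
  e <- g$edges
  o <- order(!is.na(e$mechanism), e$mechanism, e$source, e$target, e$sign,
             method = "radix")
  e <- e[o, , drop = FALSE]
  if (format == "csv") {
    out <- data.frame(source = e$source,
                      sign = ifelse(e$sign > 0, "+1", "-1"),
                      target = e$target,
                      mechanism = ifelse(is.na(e$mechanism), "", e$mechanism))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    rel <- ifelse(e$sign > 0, "activates", "inhibits")
    writeLines(paste(e$source, rel, e$target, sep = "\t"), path)
  }
  invisible(path)
}

#' Compress a model structure for ODE translation
#'
#' Reduces a structure's graph by (i) merging parallel edges of equal sign
#' between the same ordered species pair and (ii) collapsing maximal linear
#' chains through unprotected nodes with in-degree 1 and out-degree 1 into a
#' single edge whose sign is the product of the chain signs. Protected
#' species (measured, inhibitor targets, signal and constant species, plus
#' anything in `protect`) are never removed. After compression each
#' candidate mechanism is represented by a single edge. Compression is
#' idempotent; chain traversal is deterministic (lexicographic species
#' order).
#'
#' @param s model_structure
#' @param protect additional species ids to protect
#' @return model_structure whose graph is the compressed structure graph;
#'   its `block` is unchanged.
#' @export
compress_structure <- function(s, protect = character()) {
  stopifnot(inherits(s, "model_structure"))
  g <- s$graph
  protected <- unique(c(g$measured,
                        vapply(g$inhibitors, `[[`, "", "species"),
                        g$species$id[g$species$role %in% c("signal", "constant")],
                        protect))
  e <- structure_edges(s)
  repeat {
    # merge parallel equal-sign edges (keep core attribution if present)
    e <- e[order(!is.na(e$mechanism), e$mechanism, method = "radix"), , drop = FALSE]
    e <- e[!duplicated(paste(e$source, e$target, e$sign, sep = "\r")), , drop = FALSE]
    indeg <- table(factor(e$target, levels = s$graph$species$id))
    outdeg <- table(factor(e$source, levels = s$graph$species$id))
    cand <- sort(s$graph$species$id[indeg == 1L & outdeg == 1L])
    cand <- setdiff(cand, protected)
    done <- TRUE
    for (v in cand) {
      i_in <- which(e$target == v)
      i_out <- which(e$source == v)
      if (length(i_in) != 1L || length(i_out) != 1L) next
      u <- e$source[i_in]; w <- e$target[i_out]
      if (u == w || u == v || w == v) next   # would create a self-loop
      new_sign <- e$sign[i_in] * e$sign[i_out]
      mech <- e$mechanism[i_in]
      if (is.na(mech)) mech <- e$mechanism[i_out]
      e <- e[-c(i_in, i_out), , drop = FALSE]
      e <- rbind(e, data.frame(source = u, target = w, sign = new_sign,
                               mechanism = mech, stringsAsFactors = FALSE))
      done <- FALSE
      break
    }
    if (done) break
  }
  keep <- g$species$id %in% c(e$source, e$target) | g$species$id %in% protected
  sp <- g$species[keep, , drop = FALSE]
  cg <- interaction_graph(sp, e,
                          measured = intersect(g$measured, sp$id),
                          inhibitors = g$inhibitors,
                          mechanism_labels = g$mechanism_labels)
  out <- model_structure(cg, intersect(s$block, graph_mechanisms(cg)))
  out$block <- s$block   # block identity is preserved even if a mechanism
                         # merged into a core edge during compression
  out
}

#' Insert a dummy node mimicking kinase-activity inhibition
#'
#' Some inhibitors block the catalytic activity of a kinase rather than its
#' own activation: the kinase is still phosphorylated, but its outgoing
#' influence is lost. For such inhibitors a dummy node D is inserted: the
#' kinase X activates D, and every former outgoing edge of X is rerouted to
#' start from D. The inhibition target becomes D, so inhibiting D removes
#' the downstream influence while X's own measured phosphorylation can still
#' respond (e.g. through feedback onto X). For `kind = "node"` inhibitors
#' the graph is returned unchanged and the target is X itself.
#'
#' @param g interaction_graph
#' @param inhibitor name of an inhibitor declared in `g$inhibitors`
#' @return list with elements `graph` (possibly modified) and `target`
#'   (species id that the inhibitor acts on)
#' @export
insert_dummy_nodes <- function(g, inhibitor) {
  spec <- g$inhibitors[[inhibitor]]
  if (is.null(spec)) stop("unknown inhibitor: ", inhibitor)
  x <- spec$species
  if (spec$kind == "node") return(list(graph = g, target = x))
  out_idx <- which(g$edges$source == x)
  if (!length(out_idx))
    stop("kinase-activity inhibitor '", inhibitor, "': species '", x,
         "' has no outgoing edges (nothing to inhibit)")
  d <- paste0(x, "_act")
  if (d %in% g$species$id) return(list(graph = g, target = d))  # already inserted
  sp <- g$species
  pad <- sp[1, , drop = FALSE]
  pad$id <- d; pad$name <- paste(x, "kinase activity"); pad$role <- "dummy"
  sp <- rbind(sp, pad)
  e <- g$edges
  moved <- e[out_idx, , drop = FALSE]
  moved$source <- d
  e <- rbind(e[-out_idx, , drop = FALSE],
             data.frame(source = x, target = d, sign = 1L,
                        mechanism = NA_character_, stringsAsFactors = FALSE),
             moved)
  g2 <- interaction_graph(sp, e, measured = g$measured,
                          inhibitors = g$inhibitors,
                          mechanism_labels = g$mechanism_labels)
  list(graph = g2, target = d)
}

#' Resolve a set of inhibitors on a graph
#'
#' Applies [insert_dummy_nodes()] for every named inhibitor and returns the
#' resulting graph together with the species each inhibitor acts on.
#' @param g interaction_graph
#' @param inhibitors character vector of inhibitor names
#' @return list(graph =, targets = named character vector)
#' @export
resolve_inhibitors <- function(g, inhibitors) {
  targets <- character(0)
  for (nm in inhibitors) {
    r <- insert_dummy_nodes(g, nm)
    g <- r$graph
    targets[nm] <- r$target
  }
  list(graph = g, targets = targets)
}

#' Write / read a structure descriptor as JSON
#' @param s model_structure
#' @param path file path
#' @export
save_structure <- function(s, path) {
  jsonlite::write_json(list(block = s$block), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_structure
#' @param graph master interaction_graph the descriptor refers to
#' @export
read_structure <- function(path, graph) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_structure(graph, as.character(d$block))
}
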