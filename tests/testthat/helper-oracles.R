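# Brute-force oracles, independent of the package's compiled path search.

# all simple directed paths a -> b via igraph; returns sign products
oracle_path_signs <- function(g, a, b) {
  ig <- igraph::graph_from_data_frame(
    g$edges[c("source", "target")], directed = TRUE,
    vertices = g$species$id)
  paths <- igraph::all_simple_paths(ig, from = a, to = b, mode = "out")
  esign <- function(u, v) {
    g$edges$sign[g$edges$source == u & g$edges$target == v][1]
  }
  vapply(paths, function(p) {
    nm <- names(p)
    prod(mapply(esign, nm[-length(nm)], nm[-1]))
  }, numeric(1))
}

# nodes of all simple path node-sets a -> b (for via-nfb checks)
oracle_path_nodes <- function(g, a, b) {
  ig <- igraph::graph_from_data_frame(
    g$edges[c("source", "target")], directed = TRUE,
    vertices = g$species$id)
  lapply(igraph::all_simple_paths(ig, a, b, mode = "out"), names)
}

# all species on a negative simple cycle, by enumerating simple paths
# v -> u over every edge u -> v that closes a cycle
oracle_neg_feedback <- function(g) {
  out <- character(0)
  for (i in seq_len(nrow(g$edges))) {
    u <- g$edges$source[i]; v <- g$edges$target[i]; s <- g$edges$sign[i]
    nodes <- oracle_path_nodes(g, v, u)
    signs <- oracle_path_signs(g, v, u)
    neg <- which(signs * s < 0)
    out <- union(out, unlist(nodes[neg]))
  }
  sort(out)
}

oracle_dependency <- function(g, a, b) {
  signs <- oracle_path_signs(g, a, b)
  if (!length(signs)) return("neutral")
  pos <- any(signs > 0); neg <- any(signs < 0)
  if (pos && neg) return("ambivalent")
  nfb <- oracle_neg_feedback(g)
  nodes <- oracle_path_nodes(g, a, b)
  via <- any(vapply(nodes, function(nd) any(nd %in% nfb), TRUE))
  paste0(if (via) "weak_" else "strong_",
         if (pos) "activator" else "inhibitor")
}

# random signed directed graph without self-loops
random_signed_graph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  ids <- paste0("N", seq_len(n_nodes))
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  idx <- sample.int(nrow(pairs), min(n_edges, nrow(pairs)))
  e <- pairs[idx, ]
  e$sign <- sample(c(-1L, 1L), nrow(e), replace = TRUE)
  interaction_graph(data.frame(id = ids), e)
}

# small ground-truth master + observations where only planted mechanisms
# explain the data (used by enumeration tests)
tiny_master <- function() {
  edges <- data.frame(
    source = c("S", "A", "B", "C", "C", "D", "B"),
    target = c("A", "B", "C", "A", "D", "B", "D"),
    sign = c(1L, 1L, 1L, -1L, 1L, 1L, 1L),
    mechanism = c(NA, NA, NA, "M1", "M2", "M3", NA))
  interaction_graph(
    data.frame(id = c("S", "A", "B", "C", "D"),
               role = c("signal", rep("protein", 4))),
    edges, measured = c("A", "B", "C", "D"),
    inhibitors = list(inh_A = list(kind = "node", species = "A"),
                      inh_C = list(kind = "node", species = "C")))
}
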