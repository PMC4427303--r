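# Deterministic translation of compressed model structures into mass-action
# ODE models.
#
# Every graph node is the active form of a protein; the translator adds the
# matching inactive form. A positive edge pA -> pB becomes the activation
# reaction B -> pB with rate k * pA * B (pA catalyzes, is not consumed);
# each active species gets exactly one basal deactivation pB -> B with rate
# k * pB, shared by all its activating edges. A negative edge pA -| pB
# becomes a catalyzed deactivation pB -> B with rate k * pA * pB. Positive
# candidate edges are either "independent" (a parallel activation with the
# candidate source as sole modifier) or "modulating" (a parallel activation
# carrying both the core activator and the candidate source as modifiers);
# each candidate edge contributes exactly one additional reaction with its
# own rate constant.

#' Default translation options
#'
#' @param signal id of the stimulus species (becomes a per-condition input
#'   parameter), or NA for none
#' @param constants ids of constitutively active species included as
#'   constant (but estimated) parameters
#' @param synth_deg ids of active species whose moiety is not conserved: a
#'   zeroth-order synthesis of the inactive form and a first-order
#'   degradation of the active form are added (receptor turnover)
#' @param chains list of character vectors of sequentially activated forms
#'   sharing one inactive pool (e.g. the two phospho-forms of p90RSK); all
#'   active forms of a chain deactivate to the shared pool
#' @param bounds kinetic parameter bounds (linear scale)
#' @export
translate_options <- function(signal = NA_character_,
                              constants = character(),
                              synth_deg = character(),
                              chains = list(),
                              bounds = c(1e-5, 1e3)) {
  list(signal = signal, constants = constants, synth_deg = synth_deg,
       chains = chains, bounds = bounds)
}

#' Annotate all positive candidate edges as independent activations
#'
#' Convenience for synthetic studies where no modulating mechanisms exist.
#' @param s model_structure
#' @return annotation data.frame (`source`, `target`, `type`, `modulates`)
#' @export
annotate_independent <- function(s) {
  e <- structure_edges(s)
  e <- e[!is.na(e$mechanism) & e$sign > 0, , drop = FALSE]
  data.frame(source = e$source, target = e$target,
             type = rep("independent", nrow(e)),
             modulates = rep(NA_character_, nrow(e)),
             stringsAsFactors = FALSE)
}

#' Translate a compressed model structure into a mass-action ODE model
#'
#' @param s compressed model_structure (see [compress_structure()])
#' @param annotations data.frame with columns `source`, `target`, `type`
#'   (`independent`, `modulating` or `deactivating`) and `modulates` (for
#'   modulating edges, the core activator whose activation reaction the
#'   candidate joins). Required for every *positive* candidate edge;
#'   negative edges default to `deactivating`.
#' @param options [translate_options()]
#' @return object of class `ode_model`
#' @export
translate_structure <- function(s, annotations = NULL,
                                options = translate_options()) {
  g <- structure_graph(s)
  if (any(g$species$role == "dummy"))
    stop("translate_structure expects a structure without dummy nodes")
  e <- structure_edges(s)
  opt <- options
  ids <- g$species$id
  chain_members <- unlist(opt$chains)
  chain_pool <- character(0)
  for (ch in opt$chains) {
    pool <- paste0(sub("_[sd]$", "", ch[1]), "_pool")
    chain_pool[ch] <- pool
  }
  is_signal <- !is.na(opt$signal) & ids == opt$signal
  is_const <- ids %in% opt$constants
  dynamic <- ids[!is_signal & !is_const]

  inactive_of <- function(x) {
    if (x %in% chain_members) unname(chain_pool[x]) else paste0(x, "_i")
  }

  ann_key <- function(src, tgt) paste(src, tgt, sep = "->")
  ann <- list()
  if (!is.null(annotations) && nrow(annotations)) {
    for (i in seq_len(nrow(annotations)))
      ann[[ann_key(annotations$source[i], annotations$target[i])]] <-
        annotations[i, , drop = FALSE]
  }

  reactions <- list()
  params <- list()
  add_param <- function(id, kind = "kinetic", value = NA_real_) {
    params[[id]] <<- list(id = id, value = value, kind = kind)
    id
  }
  add_reaction <- function(name, substrate, product, modifiers, param,
                           origin) {
    reactions[[length(reactions) + 1L]] <<-
      list(id = length(reactions) + 1L, name = name,
           substrate = substrate, product = product,
           modifiers = modifiers, param = param, origin = origin)
  }

  mod_id <- function(x) x  # active-form ids are used directly as modifiers
  core <- e[is.na(e$mechanism), , drop = FALSE]
  cand <- e[!is.na(e$mechanism), , drop = FALSE]
  ord <- function(d) d[order(d$target, d$source, method = "radix"), , drop = FALSE]
  core <- ord(core); cand <- ord(cand)

  in_chain_step <- function(src, tgt) {
    for (ch in opt$chains) {
      i <- match(src, ch); j <- match(tgt, ch)
      if (!is.na(i) && !is.na(j) && j == i + 1L) return(TRUE)
    }
    FALSE
  }

  emit_edge <- function(row, candidate) {
    src <- row$source; tgt <- row$target
    if (tgt %in% ids[is_signal | is_const])
      stop("edge into signal/constant species '", tgt, "' cannot be translated")
    if (row$sign < 0) {
      p <- add_param(paste0("k_deact_", tgt, "_by_", src))
      add_reaction(paste0(tgt, "_deact_by_", src), substrate = tgt,
                   product = inactive_of(tgt), modifiers = src, param = p,
                   origin = if (candidate) row$mechanism else "core")
      return(invisible())
    }
    if (in_chain_step(src, tgt)) {
      # sequential activation: the upstream active form is consumed
      p <- add_param(paste0("k_act_", tgt, "_from_", src))
      add_reaction(paste0(tgt, "_from_", src), substrate = src,
                   product = tgt, modifiers = character(0), param = p,
                   origin = if (candidate) row$mechanism else "core")
      return(invisible())
    }
    mods <- src
    type <- "core"
    if (candidate) {
      a <- ann[[ann_key(src, tgt)]]
      if (is.null(a))
        stop("positive candidate edge ", src, " -> ", tgt,
             " has no translation annotation (independent/modulating)")
      type <- a$type
      if (type == "deactivating") {
        p <- add_param(paste0("k_deact_", tgt, "_by_", src))
        add_reaction(paste0(tgt, "_deact_by_", src), substrate = tgt,
                     product = inactive_of(tgt), modifiers = src, param = p,
                     origin = row$mechanism)
        return(invisible())
      }
      if (type == "modulating") {
        if (is.na(a$modulates))
          stop("modulating edge ", src, " -> ", tgt,
               " must name the core activator it modulates")
        mods <- c(a$modulates, src)
      }
    }
    p <- add_param(paste0("k_act_", tgt, "_by_", paste(mods, collapse = "_")))
    add_reaction(paste0(tgt, "_act_by_", paste(mods, collapse = "_")),
                 substrate = inactive_of(tgt), product = tgt,
                 modifiers = mods, param = p,
                 origin = if (candidate) row$mechanism else "core")
  }

  # --- core reactions: activations in canonical order, with the species'
  #     basal deactivation and turnover reactions grouped by target
  targets <- unique(core$target)
  seen_deact <- character(0)
  for (tgt in targets) {
    rows <- core[core$target == tgt, , drop = FALSE]
    for (i in seq_len(nrow(rows))) emit_edge(rows[i, ], candidate = FALSE)
    if (!(tgt %in% seen_deact)) {
      p <- add_param(paste0("k_deact_", tgt))
      add_reaction(paste0(tgt, "_deact"), substrate = tgt,
                   product = inactive_of(tgt), modifiers = character(0),
                   param = p, origin = "core")
      seen_deact <- c(seen_deact, tgt)
    }
    if (tgt %in% opt$synth_deg) {
      # receptor turnover: synthesis of the inactive form, constitutive
      # degradation of the inactive form, degradation of the active form
      p1 <- add_param(paste0("k_synth_", tgt))
      add_reaction(paste0(tgt, "_synth"), substrate = NA_character_,
                   product = inactive_of(tgt), modifiers = character(0),
                   param = p1, origin = "core")
      p2 <- add_param(paste0("k_deg_", inactive_of(tgt)))
      add_reaction(paste0(inactive_of(tgt), "_deg"),
                   substrate = inactive_of(tgt), product = NA_character_,
                   modifiers = character(0), param = p2, origin = "core")
      p3 <- add_param(paste0("k_deg_", tgt))
      add_reaction(paste0(tgt, "_deg"), substrate = tgt,
                   product = NA_character_, modifiers = character(0),
                   param = p3, origin = "core")
    }
  }
  n_core <- length(reactions)
  # --- candidate reactions (exactly one per candidate edge)
  for (i in seq_len(nrow(cand))) emit_edge(cand[i, ], candidate = TRUE)
  # basal deactivation for species activated only by candidate mechanisms
  for (tgt in setdiff(unique(cand$target[cand$sign > 0]), seen_deact)) {
    p <- add_param(paste0("k_deact_", tgt))
    add_reaction(paste0(tgt, "_deact"), substrate = tgt,
                 product = inactive_of(tgt), modifiers = character(0),
                 param = p, origin = "support")
    seen_deact <- c(seen_deact, tgt)
  }

  # --- species table; `pool` names the moiety group (shared inactive form)
  # species untouched by any reaction (possible after compression with a
  # wide protected set) are dropped from the ODE
  referenced <- unique(unlist(lapply(reactions, function(r)
    c(r$substrate, r$product, r$modifiers))))
  active <- dynamic[dynamic %in% referenced]
  pools <- unique(vapply(active, inactive_of, ""))
  species <- rbind(
    data.frame(id = active, form = "active",
               pool = vapply(active, inactive_of, ""),
               initial = 0, stringsAsFactors = FALSE),
    data.frame(id = pools, form = "inactive", pool = pools,
               initial = 1, stringsAsFactors = FALSE))
  rownames(species) <- NULL

  # --- parameters
  ptab <- do.call(rbind, lapply(params, function(p)
    data.frame(id = p$id, value = p$value, lower = opt$bounds[1],
               upper = opt$bounds[2], kind = p$kind,
               stringsAsFactors = FALSE)))
  if (!is.na(opt$signal))
    ptab <- rbind(ptab, data.frame(id = opt$signal, value = 1,
                                   lower = 0, upper = Inf, kind = "input"))
  for (cst in opt$constants)
    ptab <- rbind(ptab, data.frame(id = cst, value = NA_real_,
                                   lower = opt$bounds[1],
                                   upper = opt$bounds[2], kind = "constant"))
  rownames(ptab) <- NULL

  # --- inhibitor coupling: inhibitor parameter in [0,1] gated by a binary
  #     per-condition switch; targeted reactions get rate k * (1 - inh)
  inhibitors <- list()
  for (nm in names(g$inhibitors)) {
    spec <- g$inhibitors[[nm]]
    x <- spec$species
    target_rx <- integer(0)
    for (r in reactions) {
      hit <- if (x %in% opt$constants || spec$kind == "kinase_activity")
        x %in% r$modifiers
      else
        identical(r$product, x) && !is.na(r$substrate) # activations of x
      if (hit) target_rx <- c(target_rx, r$id)
    }
    inhibitors[[nm]] <- list(param = paste0(nm, "_strength"),
                             reactions = target_rx)
  }

  structure(list(species = species, reactions = reactions,
                 parameters = ptab, inhibitors = inhibitors,
                 n_core_reactions = n_core,
                 signal = opt$signal, constants = opt$constants,
                 options = opt),
            class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat("ode_model:", nrow(x$species), "species,", length(x$reactions),
      "reactions (", x$n_core_reactions, "core ),",
      sum(x$parameters$kind == "kinetic"), "kinetic parameters\n")
  invisible(x)
}

#' Number of reactions of an ODE model
#' @param m ode_model
#' @export
n_reactions <- function(m) length(m$reactions)

#' Apply inhibitor strengths to an ODE model
#'
#' Multiplies the rate constant of every reaction targeted by each named
#' inhibitor by `(1 - strength)`. Strengths must be in [0, 1]; the binary
#' per-condition switch is represented by including (switch on) or omitting
#' (switch off) the inhibitor in `settings`.
#'
#' @param m ode_model
#' @param settings named numeric vector of strengths in [0,1]
#' @param params named vector of parameter values (default: stored values)
#' @return named parameter vector with inhibited rates scaled
#' @export
apply_inhibitors <- function(m, settings, params = NULL) {
  if (is.null(params)) {
    params <- stats::setNames(m$parameters$value, m$parameters$id)
  }
  if (!length(settings)) return(params)
  if (any(settings < 0 | settings > 1))
    stop("inhibitor strengths must lie in [0, 1]")
  bad <- setdiff(names(settings), names(m$inhibitors))
  if (length(bad)) stop("undeclared inhibitor(s): ", paste(bad, collapse = ", "))
  for (nm in names(settings)) {
    rx <- m$inhibitors[[nm]]$reactions
    for (r in rx) {
      p <- m$reactions[[r]]$param
      params[p] <- params[p] * (1 - settings[[nm]])
    }
  }
  params
}
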