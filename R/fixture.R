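# Bundled example network: a reconstruction of HGF-stimulated MAPK/PI3K
# signaling in primary hepatocytes. The species list, core activation
# routes, candidate crosstalk/feedback mechanisms, discretized perturbation
# observations and reference parameter values are synthetic resources
# shipped with the package (inst/extdata/synthetic_hgf_*); see the files'
# README for their provenance.

#' Load the bundled HGF signaling example
#'
#' Returns the HGF master interaction graph (core model plus 17 candidate
#' crosstalk/feedback mechanisms), the discretized early/late perturbation
#' observations, the ODE translation annotations, a synthetic reference
#' parameter table, the reference combined building block, and the
#' translation options (HGF as stimulus input, PDK1 as constitutively
#' active constant, Met receptor turnover, p90RSK two-step activation).
#'
#' @return list with elements `master`, `observations`, `annotations`,
#'   `params` (named log10 values), `reference_block`, `options`,
#'   `mechanism_labels`
#' @export
hgf_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "hybridnet",
                                  mustWork = TRUE)
  species <- utils::read.csv(path("synthetic_hgf_species.csv"),
                             colClasses = "character")
  edges <- utils::read.csv(path("synthetic_hgf_edges.csv"),
                           colClasses = "character")
  edges$sign <- as.integer(edges$sign)
  mechs <- utils::read.csv(path("synthetic_hgf_mechanisms.csv"),
                           colClasses = "character")
  obs <- utils::read.csv(path("synthetic_hgf_observations.csv"),
                         colClasses = "character")
  ann <- utils::read.csv(path("synthetic_hgf_annotations.csv"),
                         colClasses = "character")
  ann$modulates[ann$modulates == ""] <- NA_character_
  par_tab <- utils::read.csv(path("synthetic_hgf_params.csv"))
  params <- stats::setNames(par_tab$log10_value, par_tab$parameter)

  inhibitors <- list(
    Met_inh = list(kind = "node", species = "pMet"),
    Mek_inh = list(kind = "kinase_activity", species = "pMEK"),
    Pdk_inh = list(kind = "node", species = "PDK1"),
    ERK_siRNA = list(kind = "node", species = "pERK"))
  measured <- c("pMet", "pAkt", "pMEK", "pERK", "RSK_s", "RSK_d", "pSOS")
  master <- interaction_graph(
    species, edges, measured = measured, inhibitors = inhibitors,
    mechanism_labels = stats::setNames(mechs$label, mechs$id))

  list(master = master,
       observations = obs,
       annotations = ann,
       params = params,
       reference_block = c("M02", "M03", "M04", "M05", "M06", "M08",
                           "M09", "M10"),
       options = translate_options(
         signal = "HGF", constants = "PDK1", synth_deg = "pMet",
         chains = list(RSK = c("RSK_s", "RSK_d"))),
       mechanism_labels = stats::setNames(mechs$label, mechs$id))
}

#' Translate a structure of the HGF example
#'
#' Convenience wrapper: compresses the structure and translates it with the
#' bundled annotations and options. All endpoints of master-model candidate
#' edges are protected during compression, so every translated structure
#' shares one species set and the reaction table stays comparable across
#' structures.
#' @param fixture result of [hgf_fixture()]
#' @param block character vector of mechanism ids
#' @return ode_model
#' @export
hgf_translate <- function(fixture, block) {
  s <- model_structure(fixture$master, block)
  ce <- fixture$master$edges[!is.na(fixture$master$edges$mechanism), ]
  cs <- compress_structure(s, protect = unique(c(ce$source, ce$target)))
  translate_structure(cs, annotations = fixture$annotations,
                      options = fixture$options)
}
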