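# Bundled four-cell Drosophila segment polarity network (SPN).
#
# The reference rules follow the Albert-Othmer Boolean formulation,
# re-encoded in dominant-inhibition form. Rules that do not fit the
# dominant-inhibition pattern are carried as frozen clauses (SMO's
# activation-by-absence of PTC, PTC's self-persistence with HH-mediated
# removal, ci's constitutive transcription), with companion prespecified
# interactions recorded for the structural bookkeeping. Cells form a ring of
# four (parasegments repeat); interactions are identical in every cell and
# inter-cell membrane contacts are symmetric.

#' Per-cell species of the segment polarity network
#'
#' @return data.frame with `name` and `kind` for the 15 per-cell species
#' @export
spn_species_template <- function() {
  data.frame(
    name = c("wg", "en", "hh", "ptc", "ci",
             "SLP", "EN", "CI", "CIR", "CIA",
             "WG", "PTC", "SMO", "PH", "HH"),
    kind = c(rep("gene", 5L),
             rep("internal_protein", 5L),
             rep("membrane_protein", 5L)),
    stringsAsFactors = FALSE)
}

spn_file <- function(name) {
  f <- system.file("extdata", "spn", name, package = "boolsynth")
  if (!nzchar(f)) stop("SPN fixture file missing: ", name)
  f
}

#' Load the segment polarity network fixture
#'
#' @return list with the reference `model` (60 species over 4 cells), the
#'   search `constraints`, and the four experimental `conditions` (wild type
#'   and wg / hh / en knockouts)
#' @export
load_spn <- function() {
  model <- read_boolean_model(spn_file("model.txt"))
  constraints <- read_constraints(spn_file("constraints.yaml"))
  conditions <- read_conditions(spn_file("conditions.yaml"), model)
  list(model = model, constraints = constraints, conditions = conditions)
}

#' Collapse a concrete SPN interaction to its per-cell template
#'
#' Same-cell source members lose their cell index; members from a different
#' (neighboring) cell become `name@adj`.
#'
#' @param edge a [new_interaction()] with concrete cell indices, or its id
#' @return template interaction id string
#' @export
spn_template_id <- function(edge) {
  if (is.character(edge)) edge <- parse_interaction_id(edge)
  tgt <- parse_species_key(edge$target)
  members <- vapply(edge$source, function(k) {
    p <- parse_species_key(k)
    if (p$cell == tgt$cell) p$name else paste0(p$name, "@adj")
  }, "")
  paste(paste(sort(members), collapse = "&"), "->", tgt$name,
        if (edge$sign == "activate") "+" else "-")
}

#' Template-level interaction sets of an SPN-shaped model
#'
#' The per-cell rules of the SPN are identical, so the model's concrete
#' interactions collapse onto per-cell templates; the published interaction
#' counts (26 total, 11 prespecified) refer to this template level.
#'
#' @param model a 4-cell [boolean_model()]
#' @param include_prespecified include prior-knowledge edges?
#' @return sorted character vector of template interaction ids
#' @export
spn_template_interactions <- function(model, include_prespecified = FALSE) {
  edges <- interactions_of(model, include_prespecified)
  sort(unique(vapply(edges, spn_template_id, "")))
}

# Remove concrete rule terms matching the given template ids, leaving frozen
# clauses and the prespecified list untouched. Used to build the search base
# model (the prior-knowledge scaffold).
strip_template_terms <- function(model, template_ids) {
  for (tgt in names(model$rules)) {
    r <- model$rules[[tgt]]
    keep_a <- !vapply(r$activators, function(t)
      spn_template_id(new_interaction(t, tgt, "activate")) %in% template_ids, TRUE)
    keep_i <- !vapply(r$inhibitors, function(t)
      spn_template_id(new_interaction(t, tgt, "inhibit")) %in% template_ids, TRUE)
    r$activators <- r$activators[keep_a]
    r$inhibitors <- r$inhibitors[keep_i]
    model$rules[[tgt]] <- r
  }
  model
}

#' Build the SPN search problem
#'
#' The base model contains exactly the prespecified interactions (and the
#' frozen non-dominant-inhibition logic); the action list is the constrained
#' enumeration over the four-cell ring; scoring averages the four
#' conditions, whose gene knockouts are applied before simulation.
#'
#' @param spn a [load_spn()] bundle (loaded afresh when omitted)
#' @return a [search_problem()]
#' @export
spn_problem <- function(spn = load_spn()) {
  searchable <- spn_template_interactions(spn$model, include_prespecified = FALSE)
  base <- strip_template_terms(spn$model, searchable)
  actions <- enumerate_actions(spn_species_template(), spn$constraints,
                               n_cells = 4L,
                               adjacency = cell_adjacency(4L, periodic = TRUE))
  search_problem(base, actions, spn$conditions)
}

#' The bundled three-species toy model
#'
#' `A <- B and C; B <- C; C <- A or B`: the worked simulation example whose
#' four-step trajectory from `(1, 0, 1)` ends in the all-ones fixed point.
#'
#' @return a [boolean_model()]
#' @export
toy_model <- function() {
  read_boolean_model(system.file("extdata", "toy_model.txt",
                                 package = "boolsynth"))
}
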