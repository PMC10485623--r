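# Action space: the candidate interactions the search may add, under
# biological constraints, with multicellular tiling.

#' Constraint specification for action enumeration
#'
#' @param allowed data.frame with columns `source_kind`, `target_kind`,
#'   `locality` (`"same_cell"` or `"adjacent_cell"`): the permitted
#'   regulator/target kind pairs
#' @param self_edges may a species regulate itself?
#' @param and_pairs propose two-species AND-composite sources?
#' @param prespecified template interaction ids treated as prior knowledge
#'   (never proposed; already in the base model)
#' @param forbidden template interaction ids never proposed
#' @param whitelist optional template ids; when given, only these are proposed
#' @return object of class `constraint_spec`
#' @export
constraint_spec <- function(allowed, self_edges = FALSE, and_pairs = FALSE,
                            prespecified = character(0),
                            forbidden = character(0), whitelist = NULL) {
  stopifnot(is.data.frame(allowed),
            all(c("source_kind", "target_kind", "locality") %in% names(allowed)))
  if (!all(allowed$locality %in% c("same_cell", "adjacent_cell")))
    stop("locality must be same_cell or adjacent_cell")
  if (length(intersect(prespecified, forbidden)))
    stop("prespecified and forbidden edge sets overlap")
  structure(list(allowed = allowed, self_edges = self_edges,
                 and_pairs = and_pairs, prespecified = prespecified,
                 forbidden = forbidden, whitelist = whitelist),
            class = "constraint_spec")
}

#' Read / write a constraint specification as YAML
#' @param file YAML path
#' @return a [constraint_spec()]
#' @export
read_constraints <- function(file) {
  doc <- yaml::read_yaml(file)
  allowed <- do.call(rbind, lapply(doc$allowed, function(a)
    data.frame(source_kind = a[[1]], target_kind = a[[2]], locality = a[[3]],
               stringsAsFactors = FALSE)))
  constraint_spec(allowed,
                  self_edges = isTRUE(doc$self_edges),
                  and_pairs = isTRUE(doc$and_pairs),
                  prespecified = unlist(doc$prespecified) %||% character(0),
                  forbidden = unlist(doc$forbidden) %||% character(0),
                  whitelist = unlist(doc$whitelist))
}

#' @rdname read_constraints
#' @param constraints a [constraint_spec()]
#' @export
write_constraints <- function(constraints, file) {
  doc <- list(allowed = lapply(seq_len(nrow(constraints$allowed)), function(i)
    as.list(unname(constraints$allowed[i, ]))),
    self_edges = constraints$self_edges,
    and_pairs = constraints$and_pairs,
    prespecified = as.list(constraints$prespecified),
    forbidden = as.list(constraints$forbidden))
  if (!is.null(constraints$whitelist)) doc$whitelist <- as.list(constraints$whitelist)
  yaml::write_yaml(doc, file)
  invisible(file)
}

#' Cell adjacency for a row of cells
#'
#' @param n_cells number of cells
#' @param periodic wrap the ends into a ring?
#' @return two-column matrix of 0-based unordered neighbor pairs
#' @export
cell_adjacency <- function(n_cells, periodic = TRUE) {
  if (n_cells < 2L) return(matrix(integer(0), ncol = 2L))
  pairs <- cbind(0:(n_cells - 2L), 1:(n_cells - 1L))
  if (periodic && n_cells > 2L) pairs <- rbind(pairs, c(0L, n_cells - 1L))
  pairs
}

# template member syntax: "name" (same cell as target) or "name@adj"
template_is_adjacent <- function(template) {
  any(grepl("@adj$", template$source))
}

#' Instantiate a per-cell interaction template across cells
#'
#' Intra-cell templates yield one instance per cell. Templates with
#' `@adj`-tagged source members (inter-cell membrane contacts) instantiate
#' for every adjacent ordered cell pair, in both directions when
#' `symmetric_membrane` is set. All instances of a template are added to a
#' model atomically.
#'
#' @param template a [new_interaction()] whose source members use the
#'   template syntax `name` / `name@adj` and whose target is a plain name
#' @param n_cells number of cells
#' @param adjacency neighbor pair matrix, see [cell_adjacency()]
#' @param symmetric_membrane instantiate adjacent templates in both directions
#' @return object of class `tiled_action` with `template`, `instances`, `id`
#' @export
tile_multicell <- function(template, n_cells, adjacency = cell_adjacency(n_cells),
                           symmetric_membrane = TRUE) {
  adj <- template_is_adjacent(template)
  mk <- function(tcell, scell) {
    members <- vapply(template$source, function(mname) {
      if (grepl("@adj$", mname)) species_key(sub("@adj$", "", mname), scell)
      else species_key(mname, tcell)
    }, "")
    new_interaction(members, species_key(template$target, tcell), template$sign)
  }
  if (!adj) {
    instances <- lapply(0:(n_cells - 1L), function(c) mk(c, c))
  } else {
    if (n_cells < 2L || !nrow(adjacency))
      stop("adjacent-cell template requires an adjacency over >= 2 cells: ",
           interaction_id(template))
    pairs <- adjacency
    if (symmetric_membrane) pairs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
    pairs <- unique(pairs)
    instances <- lapply(seq_len(nrow(pairs)), function(i)
      mk(pairs[i, 2L], pairs[i, 1L])) # source cell -> target cell
  }
  structure(list(template = template, instances = instances,
                 id = interaction_id(template)),
            class = "tiled_action")
}

#' @export
print.tiled_action <- function(x, ...) {
  cat(sprintf("%s  [%d instance(s)]\n", x$id, length(x$instances)))
  invisible(x)
}

#' Enumerate all candidate interactions under constraints
#'
#' Generates every single-source and (when enabled) same-cell AND-pair
#' interaction template permitted by the constraint kind/locality table,
#' both signs, excluding prespecified, forbidden and (by default) self
#' edges, in a deterministic order, and tiles each across cells.
#'
#' @param species per-cell template species: data.frame with `name`, `kind`
#' @param constraints a [constraint_spec()]
#' @param n_cells number of cells (1 = single-cell model)
#' @param adjacency neighbor pairs for inter-cell templates
#' @return list of [tile_multicell()] actions
#' @export
enumerate_actions <- function(species, constraints, n_cells = 1L,
                              adjacency = cell_adjacency(n_cells)) {
  stopifnot(is.data.frame(species), all(c("name", "kind") %in% names(species)))
  al <- constraints$allowed
  allowed_loc <- function(sk, tk)
    al$locality[al$source_kind == sk & al$target_kind == tk]
  templates <- list()
  addt <- function(members, target, sign)
    templates[[length(templates) + 1L]] <<- new_interaction(members, target, sign)
  for (ti in seq_len(nrow(species))) {
    tname <- species$name[ti]; tkind <- species$kind[ti]
    for (si in seq_len(nrow(species))) {
      sname <- species$name[si]; skind <- species$kind[si]
      for (loc in allowed_loc(skind, tkind)) {
        if (loc == "same_cell" && sname == tname && !constraints$self_edges) next
        member <- if (loc == "adjacent_cell") paste0(sname, "@adj") else sname
        for (sg in c("activate", "inhibit")) addt(member, tname, sg)
      }
    }
    if (isTRUE(constraints$and_pairs)) {
      ok_same <- species$name[vapply(species$kind, function(k)
        "same_cell" %in% allowed_loc(k, tkind), TRUE)]
      ok_same <- setdiff(ok_same, if (constraints$self_edges) character(0) else tname)
      if (length(ok_same) >= 2L) {
        prs <- utils::combn(sort(ok_same), 2L)
        for (j in seq_len(ncol(prs)))
          for (sg in c("activate", "inhibit")) addt(prs[, j], tname, sg)
      }
    }
  }
  ids <- vapply(templates, interaction_id, "")
  keep <- !(ids %in% c(constraints$prespecified, constraints$forbidden))
  if (!is.null(constraints$whitelist)) keep <- keep & ids %in% constraints$whitelist
  templates <- templates[keep]
  ids <- ids[keep]
  key <- vapply(templates, function(t)
    sprintf("%s|%s|%s", t$target, term_id(t$source), t$sign), "")
  templates <- templates[order(key)]
  dup <- duplicated(vapply(templates, interaction_id, ""))
  templates <- templates[!dup]
  lapply(templates, tile_multicell, n_cells = n_cells, adjacency = adjacency)
}

#' Prune incorrect actions to simulate prior knowledge
#'
#' Keeps every action whose template is in the reference interaction set and
#' removes a seeded-random fraction of the remaining ("incorrect") actions.
#' With a common RNG state, removal sets across increasing fractions are
#' nested.
#'
#' @param actions list of tiled actions
#' @param reference reference interactions (list of [new_interaction()] or id
#'   strings)
#' @param remove_fraction fraction of incorrect actions to drop, in `[0, 1]`
#' @return pruned action list (original order preserved)
#' @export
prune_actions <- function(actions, reference, remove_fraction) {
  stopifnot(remove_fraction >= 0, remove_fraction <= 1)
  ref_ids <- vapply(reference, function(e)
    if (is.character(e)) e else interaction_id(e), "")
  ids <- vapply(actions, function(a) a$id, "")
  incorrect <- which(!(ids %in% ref_ids))
  n_remove <- floor(remove_fraction * length(incorrect))
  if (n_remove == 0L) return(actions)
  perm <- incorrect[sample.int(length(incorrect))]
  drop <- perm[seq_len(n_remove)]
  actions[setdiff(seq_along(actions), drop)]
}

#' Actions still addable to a model
#'
#' Excludes actions already present in the model (any instance), actions
#' whose opposite-sign duplicate is present, and (optionally) actions whose
#' target rule already holds `max_terms` terms.
#'
#' @param model a [boolean_model()]
#' @param actions list of tiled actions
#' @param max_terms optional cap on terms per rule
#' @return filtered action list
#' @export
valid_actions <- function(model, actions, max_terms = Inf) {
  present <- names(interactions_of(model, include_prespecified = TRUE))
  term_count <- vapply(model$rules, function(r)
    length(r$activators) + length(r$inhibitors), 0L)
  flip <- flip_sign_id
  keep <- vapply(actions, function(a) {
    inst_ids <- vapply(a$instances, interaction_id, "")
    if (any(inst_ids %in% present)) return(FALSE)
    if (any(flip(inst_ids) %in% present)) return(FALSE)
    if (is.finite(max_terms)) {
      tgts <- vapply(a$instances, function(e) e$target, "")
      tc <- term_count[tgts]
      tc[is.na(tc)] <- 0L
      if (any(tc >= max_terms)) return(FALSE)
    }
    TRUE
  }, TRUE)
  actions[keep]
}

#' Apply a tiled action to a model
#'
#' Adds every concrete instance of the action atomically.
#'
#' @param model a [boolean_model()]
#' @param action a [tile_multicell()] action
#' @return modified copy of `model`
#' @export
apply_action <- function(model, action) {
  for (e in action$instances) model <- add_interaction(model, e)
  model
}
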