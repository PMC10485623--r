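#' @useDynLib boolsynth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median setNames runif cmdscale sd
#' @importFrom utils head modifyList
NULL

SPECIES_KINDS <- c("gene", "internal_protein", "membrane_protein", "external_input")

#' Species identifier key
#'
#' Species are addressed by a key `name` (cell 0) or `name@cell`
#' (multicellular models). Names may not contain `@`.
#'
#' @param name species name
#' @param cell non-negative integer cell index
#' @return character key
#' @export
species_key <- function(name, cell = 0L) {
  ifelse(cell == 0L, name, paste0(name, "@", cell))
}

parse_species_key <- function(key) {
  parts <- strsplit(key, "@", fixed = TRUE)
  name <- vapply(parts, `[[`, "", 1L)
  cell <- vapply(parts, function(p) if (length(p) > 1L) as.integer(p[[2L]]) else 0L, 0L)
  list(name = name, cell = cell)
}

empty_rule <- function() {
  list(activators = list(), inhibitors = list(), frozen = NULL)
}

#' Construct a dominant-inhibition Boolean model
#'
#' A model holds an ordered species table and one update rule per regulated
#' species. Rules have the dominant-inhibition form
#' `x(t+1) = (OR of activator terms) AND NOT (OR of inhibitor terms)`,
#' where a term is a single species or an AND-composite of several species.
#' Species without a rule are external inputs and hold their initial value.
#' A rule may additionally carry a `frozen` clause: an opaque Boolean
#' expression (disjunctive normal form over species literals, or `TRUE`)
#' OR-ed into the activator side, used for pre-specified logic that does not
#' fit the dominant-inhibition pattern.
#'
#' @param species data.frame with columns `name`, `kind`
#'   (one of gene, internal_protein, membrane_protein, external_input)
#'   and optionally `cell` (default 0)
#' @param rules named list of rules keyed by target species key; each rule is
#'   a list with `activators` / `inhibitors` (lists of character vectors of
#'   member keys) and optional `frozen` (`TRUE` or list of character vectors
#'   of literals, `!` prefix for negation)
#' @param prespecified list of [new_interaction()] objects marked as prior
#'   knowledge
#' @return object of class `boolean_model`
#' @export
boolean_model <- function(species, rules = list(), prespecified = list()) {
  stopifnot(is.data.frame(species), all(c("name", "kind") %in% names(species)))
  if (is.null(species$cell)) species$cell <- 0L
  species <- data.frame(name = as.character(species$name),
                        kind = as.character(species$kind),
                        cell = as.integer(species$cell),
                        stringsAsFactors = FALSE)
  if (!all(species$kind %in% SPECIES_KINDS))
    stop("unknown species kind(s): ",
         paste(setdiff(species$kind, SPECIES_KINDS), collapse = ", "))
  if (any(grepl("@", species$name, fixed = TRUE)))
    stop("species names may not contain '@'")
  keys <- species_key(species$name, species$cell)
  if (anyDuplicated(keys))
    stop("duplicate (name, cell) pairs: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  m <- structure(list(species = species, rules = list(), prespecified = list()),
                 class = "boolean_model")
  for (tgt in names(rules)) {
    r <- rules[[tgt]]
    m <- set_rule(m, tgt, r$activators %||% list(), r$inhibitors %||% list(),
                  r$frozen)
  }
  for (e in prespecified) m <- mark_prespecified(m, e)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

model_keys <- function(model) species_key(model$species$name, model$species$cell)

check_species <- function(model, keys, what = "rule") {
  known <- model_keys(model)
  bad <- setdiff(keys, known)
  if (length(bad))
    stop("unknown species in ", what, ": ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

norm_term <- function(members) sort(unique(as.character(members)))

term_id <- function(members) paste(norm_term(members), collapse = "&")

validate_rule <- function(model, target, activators, inhibitors, frozen) {
  check_species(model, target, "rule target")
  for (t in c(activators, inhibitors)) check_species(model, t, "rule term")
  a_ids <- vapply(activators, term_id, "")
  i_ids <- vapply(inhibitors, term_id, "")
  if (anyDuplicated(a_ids) || anyDuplicated(i_ids))
    stop("duplicate terms in rule for ", target)
  both <- intersect(a_ids, i_ids)
  if (length(both))
    stop("term(s) present as both activator and inhibitor of ", target, ": ",
         paste(both, collapse = ", "))
  if (!is.null(frozen) && !isTRUE(frozen)) {
    lits <- gsub("^!", "", unlist(frozen))
    if (length(lits)) check_species(model, lits, "frozen clause")
  }
  invisible(TRUE)
}

set_rule <- function(model, target, activators = list(), inhibitors = list(),
                     frozen = NULL) {
  activators <- lapply(activators, norm_term)
  inhibitors <- lapply(inhibitors, norm_term)
  validate_rule(model, target, activators, inhibitors, frozen)
  model$rules[[target]] <- list(activators = activators,
                                inhibitors = inhibitors, frozen = frozen)
  model
}

#' Signed regulatory interaction
#'
#' The atomic action of model construction: a source term (one species, or an
#' AND-composite of several) regulating a target with a sign.
#'
#' @param source character vector of source species keys (length >= 1)
#' @param target target species key
#' @param sign `"activate"` or `"inhibit"`
#' @return object of class `bs_interaction`
#' @export
new_interaction <- function(source, target, sign = c("activate", "inhibit")) {
  sign <- match.arg(sign)
  source <- norm_term(source)
  if (!length(source)) stop("source term must be non-empty")
  structure(list(source = source, target = target, sign = sign),
            class = "bs_interaction")
}

#' Canonical identifier of an interaction
#' @param edge a [new_interaction()] object
#' @return character scalar, e.g. `"EN -> ci -"` or `"CI&SMO -> CIA +"`
#' @export
interaction_id <- function(edge) {
  paste(term_id(edge$source), "->", edge$target,
        if (edge$sign == "activate") "+" else "-")
}

#' @export
print.bs_interaction <- function(x, ...) {
  cat(interaction_id(x), "\n")
  invisible(x)
}

parse_interaction_id <- function(id) {
  mm <- regmatches(id, regexec("^(.+) -> (\\S+) ([+-])$", id))[[1]]
  if (length(mm) != 4L) stop("malformed interaction id: ", id)
  new_interaction(strsplit(mm[2], "&", fixed = TRUE)[[1]], mm[3],
                  if (mm[4] == "+") "activate" else "inhibit")
}

#' Evaluate one update rule on a state
#'
#' Implements dominant inhibition: the target is on at the next step iff at
#' least one activator term (or the frozen clause) is true and no inhibitor
#' term is true. An AND-composite term is true iff all its members are on.
#' A rule with no activators and no frozen clause is constant false.
#'
#' @param rule a rule list (`activators`, `inhibitors`, optional `frozen`)
#' @param state named numeric/logical vector of species states
#' @return logical scalar
#' @export
evaluate_rule <- function(rule, state) {
  need <- unique(c(unlist(rule$activators), unlist(rule$inhibitors),
                   if (!isTRUE(rule$frozen)) gsub("^!", "", unlist(rule$frozen))))
  missing <- setdiff(need, names(state))
  if (length(missing))
    stop("state does not assign species: ", paste(missing, collapse = ", "))
  term_true <- function(t) all(state[t] > 0)
  act <- any(vapply(rule$activators, term_true, TRUE))
  if (!act && !is.null(rule$frozen)) {
    if (isTRUE(rule$frozen)) act <- TRUE
    else act <- any(vapply(rule$frozen, function(cl) {
      all(vapply(cl, function(lit) {
        if (startsWith(lit, "!")) state[substring(lit, 2)] == 0
        else state[lit] > 0
      }, TRUE))
    }, TRUE))
  }
  if (!act) return(FALSE)
  !any(vapply(rule$inhibitors, term_true, TRUE))
}

rule_term_ids <- function(rule) {
  list(act = vapply(rule$activators, term_id, character(1)),
       inh = vapply(rule$inhibitors, term_id, character(1)))
}

#' Add an interaction to a model
#'
#' Returns a new model whose target rule gains the source term on the
#' activator or inhibitor side; the input model is unchanged. Adding a term
#' already present, or the opposite-sign duplicate of a present term, is an
#' error.
#'
#' @param model a [boolean_model()]
#' @param edge a [new_interaction()]
#' @return modified copy of `model`
#' @export
add_interaction <- function(model, edge) {
  check_species(model, c(edge$source, edge$target), "interaction")
  r <- model$rules[[edge$target]] %||% empty_rule()
  ids <- rule_term_ids(r)
  tid <- term_id(edge$source)
  if (tid %in% c(ids$act, ids$inh)) {
    if ((edge$sign == "activate" && tid %in% ids$act) ||
        (edge$sign == "inhibit" && tid %in% ids$inh))
      stop("duplicate interaction: ", interaction_id(edge))
    stop("term already present with opposite sign: ", interaction_id(edge))
  }
  if (edge$sign == "activate") r$activators <- c(r$activators, list(edge$source))
  else r$inhibitors <- c(r$inhibitors, list(edge$source))
  model$rules[[edge$target]] <- r
  model
}

mark_prespecified <- function(model, edge) {
  model$prespecified[[interaction_id(edge)]] <- edge
  model
}

#' Extract the interaction set of a model
#'
#' One interaction per (source term, target, sign) triple across all rules.
#' Frozen clauses are opaque and contribute no interactions; prespecified
#' edges are listed only when `include_prespecified = TRUE` (this covers both
#' prespecified rule terms and prespecified edges that exist solely as
#' companions of frozen clauses).
#'
#' @param model a [boolean_model()]
#' @param include_prespecified include prior-knowledge edges?
#' @return named list of interactions, keyed and ordered by [interaction_id()]
#' @export
interactions_of <- function(model, include_prespecified = FALSE) {
  out <- list()
  for (tgt in names(model$rules)) {
    r <- model$rules[[tgt]]
    for (t in r$activators) {
      e <- new_interaction(t, tgt, "activate")
      out[[interaction_id(e)]] <- e
    }
    for (t in r$inhibitors) {
      e <- new_interaction(t, tgt, "inhibit")
      out[[interaction_id(e)]] <- e
    }
  }
  if (include_prespecified) {
    for (id in names(model$prespecified)) out[[id]] <- model$prespecified[[id]]
  } else {
    out <- out[setdiff(names(out), names(model$prespecified))]
  }
  if (!length(out)) return(setNames(list(), character(0)))
  out[order(names(out))]
}

#' Remove specific interactions from a model
#'
#' Deletes the given edges from their rules. A rule that loses its last
#' remaining interaction (no activator and no inhibitor terms left) is
#' silenced entirely: any frozen clause is dropped with it and the rule
#' becomes constant false. Each edge must be present as a rule term.
#'
#' @param model a [boolean_model()]
#' @param edges list of [new_interaction()] objects (or interaction id strings)
#' @return modified copy of `model`
#' @export
knockout_interactions <- function(model, edges) {
  for (e in edges) {
    if (is.character(e)) e <- parse_interaction_id(e)
    r <- model$rules[[e$target]]
    tid <- term_id(e$source)
    found <- FALSE
    if (!is.null(r)) {
      ids <- rule_term_ids(r)
      if (e$sign == "activate" && tid %in% ids$act) {
        r$activators <- r$activators[ids$act != tid]
        found <- TRUE
      } else if (e$sign == "inhibit" && tid %in% ids$inh) {
        r$inhibitors <- r$inhibitors[ids$inh != tid]
        found <- TRUE
      }
    }
    if (!found)
      stop("interaction not present in model: ", interaction_id(e))
    if (!length(r$activators) && !length(r$inhibitors)) r$frozen <- NULL
    model$rules[[e$target]] <- r
    model$prespecified[[interaction_id(e)]] <- NULL
  }
  model
}

#' Knock out a gene across all cells
#'
#' Removes every interaction targeting the gene and every interaction whose
#' source term contains the gene (any cell), including gene-to-protein
#' activations. Rules emptied by the removal become constant false. Frozen
#' clauses of other species are left untouched.
#'
#' @param model a [boolean_model()]
#' @param gene gene name (without cell suffix)
#' @return modified copy of `model`
#' @export
knockout_gene <- function(model, gene) {
  hits <- model$species$name == gene
  if (!any(hits)) stop("unknown gene: ", gene)
  gkeys <- species_key(model$species$name[hits], model$species$cell[hits])
  for (gk in gkeys) {
    if (!is.null(model$rules[[gk]]))
      model$rules[[gk]] <- empty_rule()
  }
  for (tgt in names(model$rules)) {
    r <- model$rules[[tgt]]
    keep_a <- !vapply(r$activators, function(t) any(t %in% gkeys), TRUE)
    keep_i <- !vapply(r$inhibitors, function(t) any(t %in% gkeys), TRUE)
    r$activators <- r$activators[keep_a]
    r$inhibitors <- r$inhibitors[keep_i]
    model$rules[[tgt]] <- r
  }
  if (length(model$prespecified)) {
    touch <- vapply(model$prespecified, function(e)
      any(c(e$source, e$target) %in% gkeys), TRUE)
    model$prespecified <- model$prespecified[!touch]
  }
  model
}

frozen_canonical <- function(frozen) {
  if (is.null(frozen)) return("")
  if (isTRUE(frozen)) return("TRUE")
  cls <- vapply(frozen, function(cl) paste(sort(cl), collapse = "&"), "")
  paste(sort(cls), collapse = "|")
}

#' Canonical serialization key of a model
#'
#' Deterministic string: species sorted by (name, cell); per-rule terms sorted
#' by member names; frozen clauses canonicalized; prespecified edge ids
#' appended. Equal models (as interaction sets with identical frozen logic)
#' yield equal keys regardless of species order or edge insertion order.
#'
#' @param model a [boolean_model()]
#' @return character scalar
#' @export
canonical_key <- function(model) {
  ord <- order(model$species$name, model$species$cell)
  sp <- model$species[ord, , drop = FALSE]
  keys <- species_key(sp$name, sp$cell)
  parts <- vapply(seq_along(keys), function(i) {
    k <- keys[i]
    r <- model$rules[[k]]
    if (is.null(r)) return(sprintf("%s:%s", k, sp$kind[i]))
    ids <- rule_term_ids(r)
    sprintf("%s:%s<-A(%s)I(%s)F(%s)", k, sp$kind[i],
            paste(sort(ids$act), collapse = ";"),
            paste(sort(ids$inh), collapse = ";"),
            frozen_canonical(r$frozen))
  }, "")
  pre <- paste(sort(names(model$prespecified)), collapse = ";")
  paste0(paste(parts, collapse = "|"), "||P(", pre, ")")
}

#' @export
print.boolean_model <- function(x, ...) {
  n_int <- length(interactions_of(x, include_prespecified = TRUE))
  cat(sprintf("Dominant-inhibition Boolean model: %d species (%d cells), %d rules, %d interactions (%d prespecified)\n",
              nrow(x$species), length(unique(x$species$cell)),
              length(x$rules), n_int, length(x$prespecified)))
  invisible(x)
}

#' @export
summary.boolean_model <- function(object, ...) {
  print(object)
  cat("Species kinds:\n")
  print(table(object$species$kind))
  inputs <- setdiff(model_keys(object), names(object$rules))
  if (length(inputs))
    cat("External inputs:", paste(inputs, collapse = ", "), "\n")
  invisible(object)
}

# flip the trailing sign of an interaction id ("... +" <-> "... -")
flip_sign_id <- function(id) {
  paste0(substr(id, 1L, nchar(id) - 1L), ifelse(endsWith(id, "+"), "-", "+"))
}
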