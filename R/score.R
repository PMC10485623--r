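# Greedy attractor edit distance and condition scoring.

#' Manhattan distance between two states
#'
#' Sum of absolute per-species differences; fractional (cycle-averaged)
#' values are allowed.
#'
#' @param a,b numeric state vectors of equal length
#' @return non-negative real
#' @export
state_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("state length mismatch: ", length(a), " vs ", length(b))
  sum(abs(as.numeric(a) - as.numeric(b)))
}

#' Greedy attractor edit distance between two censuses
#'
#' Transforms the simulated census into the reference census by repeatedly
#' picking the (simulated state, reference state) pair with the smallest
#' Manhattan distance among pairs with remaining supply and demand, and
#' transferring `min(supply, demand)` occurrences at a cost of
#' `distance x transferred`. Ties break to the lexicographically smallest
#' (simulated state, reference state) pair, making the procedure fully
#' deterministic. The total cost is normalized by the maximum possible cost
#' `n_species * N_c` to give `d_edit` in `[0, 1]`.
#'
#' @param sim simulated [attractor_census()]
#' @param ref reference [attractor_census()]
#' @param n_species number of species (defaults to the census state length)
#' @return object of class `edit_result` with a `steps` data.frame
#'   (per-transfer distance, transferred count, cost), `total_cost`,
#'   `d_edit`, and `n_c`
#' @export
edit_distance <- function(sim, ref, n_species = NULL) {
  stopifnot(inherits(sim, "attractor_census"), inherits(ref, "attractor_census"))
  if (is.null(n_species)) n_species <- ncol(sim$states)
  if (ncol(sim$states) != ncol(ref$states))
    stop("censuses have different state lengths")
  res <- cpp_edit_distance(sim$states, sim$counts, ref$states, ref$counts,
                           as.integer(n_species))
  steps <- data.frame(sim_idx = res$sim_idx, ref_idx = res$ref_idx,
                      per_state_distance = res$per_state_distance,
                      transferred = res$transferred, cost = res$cost)
  structure(list(steps = steps, total_cost = res$total_cost,
                 d_edit = res$d_edit, n_c = res$n_c,
                 sim_states = res$sim_states, ref_states = res$ref_states),
            class = "edit_result")
}

#' @export
print.edit_result <- function(x, ...) {
  cat(sprintf("Edit distance: %d transfer(s), total cost %g, normalized D = %.4f\n",
              nrow(x$steps), x$total_cost, x$d_edit))
  invisible(x)
}

#' Define an experimental condition
#'
#' A condition bundles the gene knockouts to apply before simulation, the
#' initial states to simulate from, and the reference attractor census the
#' simulation is compared to. The census total must equal the number of
#' initial states.
#'
#' @param name condition label
#' @param knockouts character vector of gene names knocked out in this
#'   condition (applied via [knockout_gene()])
#' @param initials binary initial states (matrix or list of vectors)
#' @param reference reference [attractor_census()] (see [as_census()])
#' @return object of class `bs_condition`
#' @export
condition <- function(name, knockouts = character(0), initials, reference) {
  if (is.list(initials)) initials <- do.call(rbind, initials)
  if (is.null(dim(initials))) initials <- matrix(initials, nrow = 1L)
  stopifnot(inherits(reference, "attractor_census"))
  if (nrow(initials) != reference$total)
    stop("reference census total (", reference$total,
         ") must equal the number of initial states (", nrow(initials), ")")
  structure(list(name = name, knockouts = as.character(knockouts),
                 initials = initials, reference = reference),
            class = "bs_condition")
}

condition_model <- function(model, cond) {
  for (g in cond$knockouts) model <- knockout_gene(model, g)
  model
}

#' Behavioral similarity of a model to one condition
#'
#' Applies the condition's gene knockouts, simulates an attractor census from
#' the condition's initial states, and returns `1 - d_edit` against the
#' condition's reference census.
#'
#' @param model a [boolean_model()]
#' @param cond a [condition()]
#' @param max_steps simulation step cap
#' @return similarity in `[0, 1]`
#' @export
similarity <- function(model, cond, max_steps = 10000L) {
  m <- condition_model(model, cond)
  cen <- attractor_census(m, cond$initials, max_steps = max_steps)
  1 - edit_distance(cen, cond$reference)$d_edit
}

#' Mean similarity across conditions
#'
#' Unweighted arithmetic mean of per-condition [similarity()] scores.
#'
#' @param model a [boolean_model()]
#' @param conditions non-empty list of [condition()] objects
#' @param max_steps simulation step cap
#' @return mean similarity in `[0, 1]`
#' @export
multi_condition_score <- function(model, conditions, max_steps = 10000L) {
  if (!length(conditions)) stop("at least one condition is required")
  mean(vapply(conditions, function(cn) similarity(model, cn, max_steps), 0))
}

# ---- condition file I/O ----------------------------------------------------

state_to_yaml <- function(s) {
  if (all(s %in% c(0, 1))) paste(as.integer(s), collapse = "")
  else as.numeric(s)
}

yaml_to_state <- function(x, n) {
  if (is.character(x)) {
    v <- as.numeric(strsplit(x, "")[[1]])
  } else v <- as.numeric(unlist(x))
  if (length(v) != n) stop("state of length ", length(v), ", expected ", n)
  v
}

#' Write conditions to a YAML file
#'
#' @param conditions list of [condition()] objects
#' @param species character vector of species keys giving the state order
#' @param file output path
#' @export
write_conditions <- function(conditions, species, file) {
  doc <- list(species = as.list(species),
              conditions = lapply(conditions, function(cn) {
                list(name = cn$name,
                     knockouts = as.list(cn$knockouts),
                     initial_states = lapply(seq_len(nrow(cn$initials)),
                                             function(i) state_to_yaml(cn$initials[i, ])),
                     reference = lapply(seq_len(nrow(cn$reference$states)), function(i)
                       list(state = state_to_yaml(cn$reference$states[i, ]),
                            count = cn$reference$counts[i])))
              }))
  yaml::write_yaml(doc, file)
  invisible(file)
}

#' Read conditions from a YAML file
#'
#' The file lists the species order its states use; when `model` is given,
#' states are reordered to the model's species order and validated against
#' it.
#'
#' @param file YAML path
#' @param model optional [boolean_model()] to validate/align against
#' @return list of [condition()] objects
#' @export
read_conditions <- function(file, model = NULL) {
  doc <- yaml::read_yaml(file)
  if (is.null(doc$species) || is.null(doc$conditions))
    stop("malformed conditions file (need 'species' and 'conditions'): ", file)
  sp <- unlist(doc$species)
  perm <- seq_along(sp)
  if (!is.null(model)) {
    keys <- model_keys(model)
    if (!setequal(keys, sp))
      stop("conditions file species do not match the model")
    perm <- match(keys, sp)
  }
  lapply(doc$conditions, function(cd) {
    ini <- do.call(rbind, lapply(cd$initial_states, yaml_to_state, n = length(sp)))
    refs <- do.call(rbind, lapply(cd$reference, function(r)
      yaml_to_state(r$state, length(sp))))
    cnt <- vapply(cd$reference, function(r) as.integer(r$count), 1L)
    ini <- ini[, perm, drop = FALSE]
    refs <- refs[, perm, drop = FALSE]
    if (!is.null(model)) colnames(ini) <- colnames(refs) <- model_keys(model)
    condition(cd$name, unlist(cd$knockouts) %||% character(0),
              ini, as_census(refs, cnt))
  })
}
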