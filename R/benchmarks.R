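# Random-model generation and recovery benchmarks.

#' Generate a random dominant-inhibition model
#'
#' Samples `n_interactions` distinct single-source interactions (both signs,
#' no self edges) uniformly without replacement from the unconstrained action
#' list over `n_species` species, skipping opposite-sign duplicates, and
#' assembles them into rules. Species are named `g01, g02, ...`; species that
#' receive no rule remain external inputs.
#'
#' @param n_species number of species
#' @param n_interactions number of interactions; the default density of one
#'   interaction per species keeps attractors away from the all-off/all-on
#'   extremes, with roughly one-third of species active on average
#' @return a [boolean_model()]
#' @export
random_model <- function(n_species, n_interactions = n_species) {
  species <- data.frame(name = sprintf("g%02d", seq_len(n_species)),
                        kind = "gene", stringsAsFactors = FALSE)
  acts <- enumerate_actions(species, unconstrained_spec())
  if (n_interactions > length(acts) / 2L)
    stop("cannot place ", n_interactions,
         " contradiction-free interactions among ", length(acts), " candidates")
  m <- boolean_model(species)
  if (n_interactions == 0L) return(m)
  perm <- sample.int(length(acts))
  taken <- character(0)
  for (i in perm) {
    id <- acts[[i]]$id
    if (flip_sign_id(id) %in% taken) next
    m <- apply_action(m, acts[[i]])
    taken <- c(taken, id)
    if (length(taken) == n_interactions) break
  }
  m
}

#' Unconstrained action space
#'
#' One kind, single-source edges of both signs, no self edges: the action
#' list used for random-model recovery.
#' @return a [constraint_spec()]
#' @export
unconstrained_spec <- function() {
  constraint_spec(data.frame(source_kind = "gene", target_kind = "gene",
                             locality = "same_cell", stringsAsFactors = FALSE))
}

#' Build a recovery problem from a reference model
#'
#' Samples distinct random binary initial states, simulates the reference
#' model to obtain the reference attractor census, and returns a search
#' problem whose base model is empty (all species are inputs) and whose
#' action list is the full unconstrained list.
#'
#' @param reference a [boolean_model()]
#' @param n_initials number of random initial states
#' @return a [search_problem()] with one condition
#' @export
make_problem <- function(reference, n_initials = 64L) {
  n <- nrow(reference$species)
  if (n <= 30L && n_initials > 2^n)
    stop("cannot draw ", n_initials, " distinct states over ", n, " species")
  if (n <= 30L) {
    picks <- sample.int(2^n, n_initials) - 1L
    ini <- t(vapply(picks, function(p) as.integer(intToBits(p))[seq_len(n)],
                    integer(n)))
  } else {
    ini <- matrix(sample(0:1, n_initials * n, replace = TRUE), nrow = n_initials)
    ini <- unique(ini)
    while (nrow(ini) < n_initials) {
      extra <- matrix(sample(0:1, n, replace = TRUE), nrow = 1L)
      ini <- unique(rbind(ini, extra))
    }
  }
  colnames(ini) <- model_keys(reference)
  cen <- attractor_census(reference, ini)
  base <- boolean_model(reference$species)
  cond <- condition("recovery", character(0), ini, cen)
  search_problem(base, enumerate_actions(reference$species, unconstrained_spec()),
                 list(cond))
}

#' Jaccard structural similarity between two models
#'
#' `|I_a intersect I_b| / |I_a union I_b|` over the models' interaction sets;
#' `1` when both sets are empty.
#'
#' @param a,b [boolean_model()] objects
#' @param include_prespecified include prior-knowledge edges?
#' @return similarity in `[0, 1]`
#' @export
jaccard <- function(a, b, include_prespecified = FALSE) {
  ia <- names(interactions_of(a, include_prespecified))
  ib <- names(interactions_of(b, include_prespecified))
  jaccard_sets(ia, ib)
}

jaccard_sets <- function(ia, ib) {
  u <- length(union(ia, ib))
  if (u == 0L) return(1)
  length(intersect(ia, ib)) / u
}

#' Mean fraction of active species across attractors
#'
#' Simulates the model from random initial states and averages the active
#' fraction over the census's attractor representatives, weighted by
#' occurrence count.
#'
#' @param model a [boolean_model()]
#' @param n_initials number of random initial states
#' @return value in `[0, 1]`
#' @export
attractor_activity <- function(model, n_initials = 64L) {
  n <- nrow(model$species)
  ini <- matrix(sample(0:1, n_initials * n, replace = TRUE), nrow = n_initials)
  colnames(ini) <- model_keys(model)
  cen <- attractor_census(model, ini)
  sum(rowMeans(cen$states) * cen$counts) / cen$total
}

#' Prior-knowledge sweep
#'
#' For each removal fraction, prunes the problem's action list (keeping all
#' reference interactions), runs a full search, and reports the best score
#' and the best model's Jaccard similarity to the reference.
#'
#' @param reference a [boolean_model()]
#' @param fractions removal fractions in `[0, 1]`
#' @param config a [search_config()]
#' @param n_initials initial states for the recovery problem
#' @return data.frame with one row per fraction: `fraction`, `n_actions`,
#'   `best_score`, `best_jaccard`
#' @export
prior_knowledge_sweep <- function(reference, fractions,
                                  config = search_config(), n_initials = 64L) {
  if (!length(fractions))
    return(data.frame(fraction = numeric(0), n_actions = integer(0),
                      best_score = numeric(0), best_jaccard = numeric(0)))
  set.seed(config$seed)
  problem <- make_problem(reference, n_initials)
  ref_ids <- names(interactions_of(reference))
  out <- lapply(fractions, function(f) {
    set.seed(config$seed) # common permutation: removal sets nest across fractions
    acts <- prune_actions(problem$actions, ref_ids, f)
    pr <- search_problem(problem$base_model, acts, problem$conditions)
    res <- run_search(pr, config)
    best_edges <- vapply(pr$actions[res$best_action_idx],
                         function(a) a$id, "")
    data.frame(fraction = f, n_actions = length(acts),
               best_score = res$best_score,
               best_jaccard = jaccard_sets(best_edges, ref_ids))
  })
  do.call(rbind, out)
}
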