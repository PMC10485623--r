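# Monte Carlo tree search over interaction-addition sequences.
#
# The tree lives in R (environments); model building, simulation and scoring
# of rollout endpoints happen in compiled code against a pre-compiled search
# problem. All randomness flows through the R RNG stream, so a single
# set.seed() makes a whole search reproducible.

#' Bundle a search problem
#'
#' @param base_model starting [boolean_model()] (usually only prespecified
#'   interactions; may be an empty model)
#' @param actions candidate actions from [enumerate_actions()]
#' @param conditions list of [condition()] objects defining the reference data
#' @return object of class `search_problem`
#' @export
search_problem <- function(base_model, actions, conditions) {
  stopifnot(inherits(base_model, "boolean_model"), length(conditions) >= 1L)
  for (cn in conditions)
    if (ncol(cn$initials) != nrow(base_model$species))
      stop("condition '", cn$name, "' states do not match the model species")
  structure(list(base_model = base_model, actions = actions,
                 conditions = conditions),
            class = "search_problem")
}

#' @export
print.search_problem <- function(x, ...) {
  cat(sprintf("Search problem: %d species, %d candidate actions, %d condition(s)\n",
              nrow(x$base_model$species), length(x$actions), length(x$conditions)))
  invisible(x)
}

#' Search configuration
#'
#' @param iterations_per_step rollouts simulated before committing one action
#' @param min_steps minimum number of committed interactions before stopping
#' @param max_steps maximum committed interactions; also the rollout depth
#'   target (rollouts extend the model to this many added interactions)
#' @param c_uct UCT exploration constant
#' @param rave_k RAVE equivalence parameter; the RAVE weight is
#'   `beta = sqrt(rave_k / (3 n + rave_k))`. `0` disables RAVE.
#' @param nested commit the first action of the best rollout of the step
#'   (nested search) instead of the most-visited root child
#' @param retention carry the committed child's subtree statistics into the
#'   next step (branch retention)
#' @param seed master RNG seed
#' @param max_steps_sim simulation step cap per trajectory
#' @return object of class `search_config`
#' @export
search_config <- function(iterations_per_step = 10000L, min_steps = 8L,
                          max_steps = 30L, c_uct = sqrt(2), rave_k = 1000,
                          nested = TRUE, retention = TRUE, seed = 1L,
                          max_steps_sim = 10000L) {
  stopifnot(iterations_per_step >= 1L, min_steps <= max_steps)
  structure(list(iterations_per_step = as.integer(iterations_per_step),
                 min_steps = as.integer(min_steps),
                 max_steps = as.integer(max_steps),
                 c_uct = c_uct, rave_k = rave_k,
                 nested = isTRUE(nested), retention = isTRUE(retention),
                 seed = as.integer(seed),
                 max_steps_sim = as.integer(max_steps_sim)),
            class = "search_config")
}

compile_problem <- function(problem, max_steps_sim = 10000L) {
  base <- compile_model(problem$base_model)
  keys <- base$keys
  idx <- setNames(seq_along(keys) - 1L, keys)
  acts <- lapply(problem$actions, function(a)
    lapply(a$instances, function(e)
      list(target = unname(idx[[e$target]]),
           sign = if (e$sign == "activate") 0L else 1L,
           members = as.integer(unname(idx[e$source])))))
  ids <- vapply(problem$actions, function(a) a$id, "")
  opp <- match(flip_sign_id(ids), ids) - 1L
  opp[is.na(opp)] <- -1L
  conds <- lapply(problem$conditions, function(cn) {
    genes <- cn$knockouts
    mask <- which(problem$base_model$species$name %in% genes) - 1L
    list(initials = cn$initials,
         mask = as.integer(mask),
         ref_states = cn$reference$states,
         ref_counts = as.integer(cn$reference$counts))
  })
  list(ptr = cpp_compile_problem(base, acts, as.integer(opp), conds,
                                 as.integer(max_steps_sim)),
       ids = ids, nact = length(ids))
}

#' Score the model formed by a set of actions
#'
#' Compiled fast path: builds base model + actions and returns the mean
#' condition similarity.
#'
#' @param problem a [search_problem()]
#' @param action_idx integer indices into `problem$actions`
#' @param max_steps_sim simulation step cap
#' @return similarity in `[0, 1]`
#' @export
score_actions <- function(problem, action_idx, max_steps_sim = 10000L) {
  cp <- compile_problem(problem, max_steps_sim)
  cpp_score_ids(cp$ptr, as.integer(action_idx) - 1L)
}

#' Reconstruct the model encoded by archive actions
#'
#' @param problem a [search_problem()]
#' @param action_idx integer indices into `problem$actions`
#' @return a [boolean_model()]
#' @export
archive_model <- function(problem, action_idx) {
  m <- problem$base_model
  for (i in action_idx) m <- apply_action(m, problem$actions[[i]])
  m
}

#' Upper confidence bound of a search branch
#'
#' RAVE-blended mean plus the UCT exploration bonus:
#' `(1 - beta) Q + beta Q_rave + c_uct sqrt(log(parent_n) / n)` with
#' `beta = sqrt(rave_k / (3 n + rave_k))`. An unvisited branch has value
#' `Inf`, forcing exploration before any visited sibling.
#'
#' @param child list with `n`, `W` and optionally `rave_n`, `rave_W`
#' @param parent_n visit count of the parent node
#' @param config a [search_config()]
#' @return numeric upper bound
#' @export
uct_value <- function(child, parent_n, config) {
  n <- child$n %||% 0
  if (n == 0) return(Inf)
  q <- child$W / n
  rn <- child$rave_n %||% 0
  beta <- if (config$rave_k > 0 && rn > 0) sqrt(config$rave_k / (3 * n + config$rave_k)) else 0
  qr <- if (rn > 0) child$rave_W / rn else 0
  (1 - beta) * q + beta * qr + config$c_uct * sqrt(log(parent_n) / n)
}

new_node <- function(st, ids) {
  valid <- cpp_valid_ids(st$cp$ptr, as.integer(ids))
  node <- new.env(parent = emptyenv())
  node$n <- 0
  node$W <- 0
  node$children <- list()
  node$untried <- if (length(valid)) valid[sample.int(length(valid))] else integer(0)
  node$rave_n <- NULL
  node$rave_W <- NULL
  node
}

new_search_state <- function(problem, config) {
  st <- new.env(parent = emptyenv())
  st$problem <- problem
  st$config <- config
  st$cp <- compile_problem(problem, config$max_steps_sim)
  st$nact <- st$cp$nact
  st$committed <- integer(0)       # 0-based action ids
  st$archive <- new.env(parent = emptyenv())
  st$best_score <- -Inf
  st$best_ids <- integer(0)
  st$step_index <- 0L
  st$step_best_score <- -Inf
  st$step_best_first <- NULL
  st$n_iterations <- 0L
  st$scores <- numeric(0)        # per-iteration rollout scores, in order
  st$root <- new_node(st, st$committed)
  st
}

select_action <- function(node, config) {
  keys <- names(node$children)
  best <- -Inf
  pick <- keys[1L]
  for (k in keys) {
    ch <- node$children[[k]]
    a1 <- as.integer(k) + 1L
    v <- uct_value(list(n = ch$n, W = ch$W,
                        rave_n = if (!is.null(node$rave_n)) node$rave_n[a1] else 0,
                        rave_W = if (!is.null(node$rave_W)) node$rave_W[a1] else 0),
                   node$n, config)
    if (v > best) { best <- v; pick <- k }
  }
  as.integer(pick)
}

#' One MCTS iteration
#'
#' Selects by upper confidence bound to a leaf, expands one child, completes
#' the model with a uniform random rollout up to the depth target, scores the
#' terminal model across all conditions, backpropagates visit counts and
#' scores along the path, updates the RAVE (all-moves-as-first) statistics of
#' every path node with every action played below it, and archives the
#' terminal model.
#'
#' @param st a search state created by [run_search()] internals
#' @return list with the action sequence below the root and the rollout score
#' @keywords internal
mcts_iteration <- function(st) {
  cfg <- st$config
  path_nodes <- list(st$root)
  path_actions <- integer(0)
  ids <- st$committed
  node <- st$root
  repeat {
    if (length(ids) >= cfg$max_steps) break
    if (length(node$untried)) {
      a <- node$untried[1L]
      node$untried <- node$untried[-1L]
      child <- new_node(st, c(ids, a))
      node$children[[as.character(a)]] <- child
      ids <- c(ids, a)
      path_actions <- c(path_actions, a)
      path_nodes[[length(path_nodes) + 1L]] <- child
      node <- child
      break
    } else if (length(node$children)) {
      a <- select_action(node, cfg)
      node <- node$children[[as.character(a)]]
      ids <- c(ids, a)
      path_actions <- c(path_actions, a)
      path_nodes[[length(path_nodes) + 1L]] <- node
    } else break
  }
  res <- cpp_rollout_score(st$cp$ptr, as.integer(ids), cfg$max_steps)
  score <- res$score
  below <- c(path_actions, res$added)
  all_ids <- sort(c(st$committed, below))
  key <- paste(all_ids, collapse = ",")
  if (is.null(st$archive[[key]]))
    st$archive[[key]] <- list(ids = all_ids, score = score, step = st$step_index)
  if (length(below) && score > st$step_best_score) {
    st$step_best_score <- score
    st$step_best_first <- below[1L]
  }
  if (score > st$best_score) {
    st$best_score <- score
    st$best_ids <- all_ids
  }
  acc <- res$added
  for (j in length(path_nodes):1L) {
    nd <- path_nodes[[j]]
    nd$n <- nd$n + 1
    nd$W <- nd$W + score
    if (length(acc)) {
      if (is.null(nd$rave_n)) {
        nd$rave_n <- numeric(st$nact)
        nd$rave_W <- numeric(st$nact)
      }
      nd$rave_n[acc + 1L] <- nd$rave_n[acc + 1L] + 1
      nd$rave_W[acc + 1L] <- nd$rave_W[acc + 1L] + score
    }
    if (j > 1L) acc <- c(path_actions[j - 1L], acc)
  }
  st$n_iterations <- st$n_iterations + 1L
  st$scores[st$n_iterations] <- score
  invisible(list(actions = below, score = score))
}

#' One search step: explore, then commit one interaction
#'
#' Runs `iterations_per_step` MCTS iterations, then commits the first action
#' of the best rollout seen this step (nested search) or the most-visited
#' root child. With branch retention, the committed child's subtree becomes
#' the next root, keeping its statistics.
#'
#' @param st search state
#' @return the committed 0-based action id, or `NULL` when the search is
#'   exhausted (no addable action remains)
#' @keywords internal
search_step <- function(st) {
  cfg <- st$config
  st$step_index <- st$step_index + 1L
  st$step_best_score <- -Inf
  st$step_best_first <- NULL
  if (!length(st$root$untried) && !length(st$root$children)) return(NULL)
  for (i in seq_len(cfg$iterations_per_step)) mcts_iteration(st)
  if (!length(st$root$children)) return(NULL)
  a <- if (cfg$nested && !is.null(st$step_best_first)) st$step_best_first
  else {
    ks <- names(st$root$children)
    visits <- vapply(ks, function(k) st$root$children[[k]]$n, 0)
    kmax <- ks[visits == max(visits)]
    min(as.integer(kmax))
  }
  st$committed <- c(st$committed, a)
  # simulate and archive the committed working model itself; a perfect
  # committed model also satisfies the stopping rule
  cscore <- cpp_score_ids(st$cp$ptr, as.integer(st$committed))
  ckey <- paste(sort(st$committed), collapse = ",")
  if (is.null(st$archive[[ckey]]))
    st$archive[[ckey]] <- list(ids = sort(st$committed), score = cscore,
                               step = st$step_index)
  if (cscore > st$best_score) {
    st$best_score <- cscore
    st$best_ids <- sort(st$committed)
  }
  child <- st$root$children[[as.character(a)]]
  st$root <- if (cfg$retention && !is.null(child)) child
  else new_node(st, st$committed)
  a
}

finalize_archive <- function(st, search_id = 1L) {
  keys <- ls(st$archive)
  recs <- lapply(keys, function(k) st$archive[[k]])
  df <- data.frame(
    stringsAsFactors = FALSE,
    key = keys,
    score = vapply(recs, function(r) r$score, 0),
    step = vapply(recs, function(r) r$step, 0L),
    n_edges = vapply(recs, function(r) length(r$ids), 0L),
    search_id = rep(as.integer(search_id), length(keys)),
    seed = rep(st$config$seed, length(keys)))
  df$action_idx <- lapply(recs, function(r) r$ids + 1L)
  df$edges <- lapply(recs, function(r) st$cp$ids[r$ids + 1L])
  df <- df[order(-df$score, df$key), ]
  rownames(df) <- NULL
  class(df) <- c("search_archive", "data.frame")
  df
}

#' @export
print.search_archive <- function(x, ...) {
  cat(sprintf("Model archive: %d unique model(s), best score %.4f, %d perfect\n",
              nrow(x), if (nrow(x)) max(x$score) else NA_real_,
              sum(x$score >= 1 - 1e-9)))
  invisible(x)
}

#' Run one MCTS model search
#'
#' Grows the working model one committed interaction per step. Terminates at
#' `max_steps` committed interactions, or as soon as a perfect-scoring model
#' has been found and at least `min_steps` steps are complete, or when no
#' addable action remains. Every distinct simulated model is archived with
#' its score and provenance.
#'
#' @param problem a [search_problem()]
#' @param config a [search_config()]
#' @param search_id provenance label stored in the archive
#' @return object of class `mcts_search`: the `archive`
#'   (data.frame), `best_score`, `best_action_idx`,
#'   `committed_idx`, and the `config`
#' @export
run_search <- function(problem, config = search_config(), search_id = 1L) {
  set.seed(config$seed)
  st <- new_search_state(problem, config)
  for (step in seq_len(config$max_steps)) {
    a <- search_step(st)
    if (is.null(a)) break
    if (st$best_score >= 1 - 1e-9 && step >= config$min_steps) break
  }
  structure(list(archive = finalize_archive(st, search_id),
                 best_score = st$best_score,
                 best_action_idx = st$best_ids + 1L,
                 committed_idx = st$committed + 1L,
                 n_iterations = st$n_iterations,
                 iteration_scores = st$scores,
                 config = config, search_id = search_id),
            class = "mcts_search")
}

#' @export
print.mcts_search <- function(x, ...) {
  cat(sprintf("MCTS search %s: best score %.4f after %d iterations, %d committed interaction(s), archive of %d models\n",
              x$search_id, x$best_score, x$n_iterations,
              length(x$committed_idx), nrow(x$archive)))
  invisible(x)
}

derive_seed <- function(master, i) {
  as.integer((as.double(master %% 100003L) * 20011 + i * 7919) %% 2147483647)
}

#' Run a batch of independent searches
#'
#' Searches are independently seeded (derived deterministically from the
#' master seed and the search index), optionally executed on forked worker
#' processes, and their archives merged with per-search provenance. The
#' merged result is independent of the worker count.
#'
#' @param problem a [search_problem()]
#' @param n_searches number of independent searches
#' @param config base [search_config()]; each search gets a derived seed
#' @param n_workers parallel processes (1 = sequential)
#' @return list of class `mcts_batch` with the merged `archive`, per-search
#'   `best_scores`, and the `searches` themselves
#' @export
run_batch <- function(problem, n_searches, config = search_config(),
                      n_workers = 1L) {
  if (n_searches == 0L)
    return(structure(list(archive = finalize_archive(
      new_search_state(problem, config)), best_scores = numeric(0),
      searches = list()), class = "mcts_batch"))
  one <- function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    run_search(problem, cfg, search_id = i)
  }
  searches <- if (n_workers > 1L)
    parallel::mclapply(seq_len(n_searches), one, mc.cores = n_workers)
  else lapply(seq_len(n_searches), one)
  failed <- vapply(searches, function(s) inherits(s, "try-error") ||
                     !inherits(s, "mcts_search"), TRUE)
  if (any(failed))
    warning(sum(failed), " search(es) failed and were dropped from the archive")
  searches <- searches[!failed]
  merged <- do.call(rbind, lapply(searches, function(s) s$archive))
  merged <- merged[!duplicated(paste(merged$search_id, merged$key)), ]
  rownames(merged) <- NULL
  class(merged) <- c("search_archive", "data.frame")
  structure(list(archive = merged,
                 best_scores = vapply(searches, function(s) s$best_score, 0),
                 searches = searches),
            class = "mcts_batch")
}

#' Write / read an archive as JSON lines
#'
#' One JSON object per line: canonical key, edge ids, score, provenance.
#'
#' @param archive a `search_archive` data.frame
#' @param file path
#' @export
write_archive <- function(archive, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(archive))) {
    rec <- list(key = archive$key[i], edges = archive$edges[[i]],
                score = archive$score[i], search_id = archive$search_id[i],
                step = archive$step[i], seed = archive$seed[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(file)
}

#' @rdname write_archive
#' @export
read_archive <- function(file) {
  lines <- readLines(file)
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- data.frame(
    key = vapply(recs, function(r) r$key, ""),
    score = vapply(recs, function(r) as.numeric(r$score), 0),
    step = vapply(recs, function(r) as.integer(r$step), 0L),
    n_edges = vapply(recs, function(r) length(r$edges), 0L),
    search_id = vapply(recs, function(r) as.integer(r$search_id), 0L),
    seed = vapply(recs, function(r) as.integer(r$seed), 0L),
    stringsAsFactors = FALSE)
  df$edges <- lapply(recs, function(r) as.character(r$edges))
  class(df) <- c("search_archive", "data.frame")
  df
}
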