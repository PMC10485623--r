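# Synchronous simulation. The heavy lifting (stepping, attractor detection,
# censuses) happens in compiled code; these wrappers convert the R-level
# model into its compiled form.

compile_model <- function(model) {
  keys <- model_keys(model)
  idx <- setNames(seq_along(keys) - 1L, keys) # 0-based
  n <- length(keys)
  has_rule <- keys %in% names(model$rules)
  acts <- vector("list", n)
  inhs <- vector("list", n)
  frozen <- vector("list", n)
  frozen_true <- logical(n)
  for (i in seq_len(n)) {
    acts[[i]] <- list(); inhs[[i]] <- list(); frozen[[i]] <- list()
    if (!has_rule[i]) next
    r <- model$rules[[keys[i]]]
    acts[[i]] <- lapply(r$activators, function(t) unname(idx[t]))
    inhs[[i]] <- lapply(r$inhibitors, function(t) unname(idx[t]))
    if (isTRUE(r$frozen)) frozen_true[i] <- TRUE
    else if (!is.null(r$frozen))
      frozen[[i]] <- lapply(r$frozen, function(cl) {
        neg <- startsWith(cl, "!")
        ids <- unname(idx[gsub("^!", "", cl)]) + 1L
        as.integer(ifelse(neg, -ids, ids))
      })
  }
  list(n = n, has_rule = has_rule, acts = acts, inhs = inhs,
       frozen = frozen, frozen_true = frozen_true, keys = keys)
}

as_state_vector <- function(model, state) {
  keys <- model_keys(model)
  if (!is.null(names(state))) {
    check_species(model, names(state), "state")
    missing <- setdiff(keys, names(state))
    if (length(missing))
      stop("state does not assign species: ", paste(missing, collapse = ", "))
    state <- state[keys]
  }
  if (length(state) != length(keys))
    stop("state length ", length(state), " != number of species ", length(keys))
  v <- as.numeric(state)
  if (!all(v %in% c(0, 1))) stop("simulation states must be binary")
  setNames(as.integer(v), keys)
}

as_initials_matrix <- function(model, initials) {
  if (is.list(initials))
    initials <- do.call(rbind, lapply(initials, function(s) as_state_vector(model, s)))
  if (is.null(dim(initials))) initials <- matrix(initials, nrow = 1L)
  storage.mode(initials) <- "integer"
  if (ncol(initials) != nrow(model$species))
    stop("initial states have wrong length")
  colnames(initials) <- model_keys(model)
  initials
}

#' One synchronous update step
#'
#' Every regulated species takes the value of its rule evaluated on the
#' previous state; external inputs hold their value.
#'
#' @param model a [boolean_model()]
#' @param state binary state vector (named, or in model species order)
#' @return named binary state vector at the next time step
#' @export
step_state <- function(model, state) {
  s <- as_state_vector(model, state)
  setNames(cpp_step(compile_model(model), s), names(s))
}

#' Simulate to an attractor
#'
#' Iterates synchronous updates, recording the full state history, and halts
#' at the first state equal to a previously visited one. Deterministic
#' synchronous dynamics guarantee a fixed point (period 1) or a cyclic
#' attractor.
#'
#' @param model a [boolean_model()]
#' @param initial binary initial state
#' @param max_steps safety cap on simulated steps
#' @return object of class `boolean_trajectory`: a state matrix (one row per
#'   time point, `t0 ...`), the 1-based `attractor_start` row, and the cycle
#'   `period` (1 = fixed point)
#' @export
run_to_attractor <- function(model, initial, max_steps = 10000L) {
  stopifnot(max_steps >= 1L)
  s <- as_state_vector(model, initial)
  res <- cpp_run_to_attractor(compile_model(model), s, as.integer(max_steps))
  colnames(res$states) <- names(s)
  rownames(res$states) <- paste0("t", seq_len(nrow(res$states)) - 1L)
  structure(list(states = res$states, attractor_start = res$attractor_start,
                 period = res$period), class = "boolean_trajectory")
}

#' @export
print.boolean_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points, attractor starts at t%d, period %d%s\n",
              nrow(x$states), x$attractor_start - 1L, x$period,
              if (x$period == 1L) " (fixed point)" else " (cyclic)"))
  print(t(x$states))
  invisible(x)
}

#' Representative state of an attractor
#'
#' A fixed point represents itself; a cyclic attractor is averaged
#' elementwise over its cycle states, giving a fractional state in `[0, 1]`.
#'
#' @param traj a [run_to_attractor()] trajectory
#' @return named numeric state vector
#' @export
attractor_representative <- function(traj) {
  rows <- traj$attractor_start:(traj$attractor_start + traj$period - 1L)
  colMeans(traj$states[rows, , drop = FALSE])
}

#' Attractor census over many initial states
#'
#' Simulates the model once from each initial state and counts how many
#' initial states converge to each attractor representative. Cyclic
#' attractors whose averaged representatives coincide share a census entry.
#'
#' @param model a [boolean_model()]
#' @param initials list of state vectors or a matrix (one row per state)
#' @param max_steps simulation step cap
#' @return object of class `attractor_census`: `states` matrix (one row per
#'   distinct representative, lexicographically ordered), integer `counts`,
#'   and `total` = number of initial states
#' @export
attractor_census <- function(model, initials, max_steps = 10000L) {
  ini <- as_initials_matrix(model, initials)
  if (!nrow(ini)) stop("at least one initial state is required")
  res <- cpp_census(compile_model(model), ini, integer(0), as.integer(max_steps))
  colnames(res$states) <- model_keys(model)
  as_census(res$states, res$counts)
}

#' Build a census from explicit states and counts
#'
#' Used for reference (data) censuses. Duplicate states are aggregated;
#' entries are stored in lexicographic state order.
#'
#' @param states numeric matrix, one attractor state per row (values in
#'   `[0, 1]`; fractional values represent averaged cycles)
#' @param counts positive integer occurrence counts, one per row
#' @return object of class `attractor_census`
#' @export
as_census <- function(states, counts) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  counts <- as.integer(counts)
  stopifnot(nrow(states) == length(counts), all(counts > 0))
  key <- apply(states, 1L, paste, collapse = ",")
  agg <- tapply(counts, key, sum)
  first <- !duplicated(key)
  states <- states[first, , drop = FALSE]
  key <- key[first]
  counts <- as.integer(agg[key])
  ord <- do.call(order, as.data.frame(states))
  structure(list(states = states[ord, , drop = FALSE],
                 counts = counts[ord], total = sum(counts)),
            class = "attractor_census")
}

#' @export
print.attractor_census <- function(x, ...) {
  cat(sprintf("Attractor census: %d distinct state(s), %d observation(s)\n",
              nrow(x$states), x$total))
  df <- as.data.frame(x$states)
  df$count <- x$counts
  print(df)
  invisible(x)
}
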