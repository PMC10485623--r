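# Independent oracles used across the suite. These deliberately avoid the
# compiled simulation/scoring path: stepping goes through evaluate_rule()
# in plain R, and optimization problems are solved by brute force.

# plain-R synchronous step (independent of the compiled simulator)
r_step <- function(model, state) {
  keys <- names(state)
  out <- state
  for (k in keys) {
    r <- model$rules[[k]]
    if (is.null(r)) next
    out[k] <- as.integer(evaluate_rule(r, state))
  }
  out
}

r_run_to_attractor <- function(model, state, max_steps = 5000) {
  seen <- character(0)
  states <- list()
  for (i in seq_len(max_steps)) {
    key <- paste(state, collapse = "")
    hit <- match(key, seen)
    if (!is.na(hit)) {
      return(list(states = states, attractor_start = hit,
                  period = length(states) - hit + 1))
    }
    seen <- c(seen, key)
    states[[length(states) + 1]] <- state
    state <- r_step(model, state)
  }
  stop("oracle did not halt")
}

# exhaustive min-cost transport between two tiny censuses
brute_transport_cost <- function(sim_states, sim_counts, ref_states, ref_counts) {
  best <- Inf
  recurse <- function(sc, rc, acc) {
    if (acc >= best) return()
    if (all(rc == 0)) { best <<- min(best, acc); return() }
    j <- which(rc > 0)[1]
    for (i in which(sc > 0)) {
      k <- min(sc[i], rc[j])
      d <- sum(abs(sim_states[i, ] - ref_states[j, ]))
      sc2 <- sc; rc2 <- rc
      sc2[i] <- sc2[i] - k; rc2[j] <- rc2[j] - k
      recurse(sc2, rc2, acc + d * k)
    }
  }
  recurse(sim_counts, ref_counts, 0)
  best
}

# brute-force distinguishing-set enumeration (no pruning, no minimality)
brute_distinguishing <- function(target_sets, other_clusters, max_size,
                                 in_freq, out_freq) {
  items <- sort(unique(unlist(target_sets)))
  support <- function(sets, s) mean(vapply(sets, function(x) all(s %in% x), TRUE))
  found <- list()
  for (k in seq_len(min(max_size, length(items)))) {
    cmb <- utils::combn(items, k, simplify = FALSE)
    for (s in cmb) {
      ins <- support(target_sets, s)
      outs <- if (length(other_clusters))
        max(vapply(other_clusters, support, 0, s = s)) else 0
      if (ins >= in_freq - 1e-12 && outs <= out_freq + 1e-12)
        found[[length(found) + 1]] <- list(set = s, in_freq = ins,
                                           max_out_freq = outs)
    }
  }
  found
}

mean_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# small fixed models
two_species_model <- function() {
  boolean_model(data.frame(name = c("a", "b"), kind = "gene"))
}

negation_oscillator <- function() {
  boolean_model(data.frame(name = "a", kind = "gene"),
                rules = list(a = list(activators = list(), inhibitors = list("a"),
                                      frozen = TRUE)))
}

random_state <- function(keys) setNames(sample(0:1, length(keys), TRUE), keys)
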