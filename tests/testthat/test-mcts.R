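tiny_problem <- function(seed = 1, n = 3, k = 3, ini = 8) {
  set.seed(seed)
  ref <- random_model(n, k)
  make_problem(ref, ini)
}

test_that("uct_value balances exploitation and exploration", {
  cfg <- search_config(c_uct = 1, rave_k = 0)
  expect_identical(uct_value(list(n = 0, W = 0), 10, cfg), Inf)
  # worked arithmetic: Q = 0.8, n = 4, parent 100, c = 1, no RAVE
  expect_equal(uct_value(list(n = 4, W = 3.2), 100, cfg),
               0.8 + sqrt(log(100) / 4))
  # equal means: the less-visited child has the higher bound
  lo <- uct_value(list(n = 10, W = 5), 200, cfg)
  hi <- uct_value(list(n = 100, W = 50), 200, cfg)
  expect_gt(lo, hi)
  # RAVE blending pulls toward the all-moves-as-first mean
  cfgr <- search_config(c_uct = 0, rave_k = 1000)
  v <- uct_value(list(n = 4, W = 0, rave_n = 8, rave_W = 8), 100, cfgr)
  beta <- sqrt(1000 / (3 * 4 + 1000))
  expect_equal(v, beta * 1)
})

test_that("one iteration updates root statistics and archives its model", {
  prob <- tiny_problem()
  cfg <- search_config(iterations_per_step = 1, min_steps = 1, max_steps = 3, seed = 5)
  set.seed(cfg$seed)
  st <- boolsynth:::new_search_state(prob, cfg)
  out <- boolsynth:::mcts_iteration(st)
  expect_equal(st$root$n, 1)
  expect_equal(st$root$W, out$score)
  expect_length(ls(st$archive), 1)
  rec <- st$archive[[ls(st$archive)[1]]]
  expect_equal(rec$score, out$score)
  # RAVE stats of the root cover the whole action sequence
  expect_equal(sum(st$root$rave_n), length(out$actions))
})

test_that("searches are deterministic under a fixed seed", {
  prob <- tiny_problem()
  cfg <- search_config(iterations_per_step = 50, min_steps = 2, max_steps = 4,
                       seed = 11)
  r1 <- run_search(prob, cfg)
  r2 <- run_search(prob, cfg)
  expect_identical(r1$archive$key, r2$archive$key)
  expect_identical(r1$archive$score, r2$archive$score)
  expect_identical(r1$committed_idx, r2$committed_idx)
})

test_that("archives are deduplicated on the canonical action set", {
  prob <- tiny_problem()
  res <- run_search(prob, search_config(iterations_per_step = 100,
                                        min_steps = 2, max_steps = 4, seed = 3))
  expect_false(any(duplicated(res$archive$key)))
  expect_true(all(res$archive$score >= 0 & res$archive$score <= 1))
  # perfect-scoring models carry their score
  if (any(res$archive$score >= 1 - 1e-9))
    expect_gte(res$best_score, 1 - 1e-9)
})

test_that("a single decisive action is committed on a toy problem", {
  # reference with ONE activating interaction, probed with asymmetric
  # initial states (a symmetric census cannot tell a->b from b->a); brute
  # force confirms exactly which single-action models reach score 1 before
  # the search is run
  sp <- data.frame(name = sprintf("g%02d", 1:3), kind = "gene")
  ref <- add_interaction(boolean_model(sp), new_interaction("g01", "g02"))
  ini <- matrix(c(0, 0, 0,
                  1, 0, 0,
                  1, 1, 0,
                  1, 0, 1), 4, 3, byrow = TRUE,
                dimnames = list(NULL, sp$name))
  cen <- attractor_census(ref, ini)
  cond <- condition("recovery", character(0), ini, cen)
  prob <- search_problem(boolean_model(sp),
                         enumerate_actions(sp, unconstrained_spec()),
                         list(cond))
  singles <- vapply(seq_along(prob$actions), function(i)
    score_actions(prob, i), 0)
  best_single <- which(singles >= 1 - 1e-9)
  expect_length(best_single, 1) # unique decisive action for this seed
  cfg <- search_config(iterations_per_step = 150, min_steps = 1, max_steps = 2,
                       seed = 23)
  res <- run_search(prob, cfg)
  expect_equal(res$committed_idx[1], best_single)
  expect_equal(res$best_score, 1)
})

test_that("greedy limit: no exploration and no RAVE commits the best-known action", {
  set.seed(18)
  ref <- add_interaction(boolean_model(data.frame(name = sprintf("g%02d", 1:3),
                                                  kind = "gene")),
                         new_interaction("g02", "g03"))
  prob <- make_problem(ref, 8)
  cfg <- search_config(iterations_per_step = length(prob$actions) * 3,
                       min_steps = 1, max_steps = 1, c_uct = 1e-9, rave_k = 0,
                       nested = FALSE, seed = 29)
  res <- run_search(prob, cfg)
  singles <- vapply(seq_along(prob$actions), function(i) score_actions(prob, i), 0)
  expect_equal(singles[res$committed_idx[1]], max(singles))
})

test_that("branch retention carries statistics across steps", {
  prob <- tiny_problem()
  for (keep in c(TRUE, FALSE)) {
    cfg <- search_config(iterations_per_step = 40, min_steps = 2, max_steps = 2,
                         retention = keep, nested = FALSE, seed = 31)
    set.seed(cfg$seed)
    st <- boolsynth:::new_search_state(prob, cfg)
    boolsynth:::search_step(st)
    if (keep) expect_gt(st$root$n, 0) else expect_equal(st$root$n, 0)
  }
})

test_that("min_steps forces continued growth past a perfect model", {
  set.seed(19)
  ref <- add_interaction(boolean_model(data.frame(name = sprintf("g%02d", 1:3),
                                                  kind = "gene")),
                         new_interaction("g01", "g03"))
  prob <- make_problem(ref, 8)
  cfg <- search_config(iterations_per_step = 100, min_steps = 3, max_steps = 5,
                       seed = 37)
  res <- run_search(prob, cfg)
  expect_gte(length(res$committed_idx), 3)
  expect_equal(res$best_score, 1)
})

test_that("tree visit counts reconcile along the root after many iterations", {
  prob <- tiny_problem()
  cfg <- search_config(iterations_per_step = 120, min_steps = 1, max_steps = 3,
                       seed = 41)
  set.seed(cfg$seed)
  st <- boolsynth:::new_search_state(prob, cfg)
  for (i in 1:120) boolsynth:::mcts_iteration(st)
  kids <- st$root$children
  expect_equal(st$root$n, 120)
  expect_lte(sum(vapply(kids, function(k) k$n, 0)), st$root$n)
  for (k in kids) {
    expect_lte(k$W, k$n + 1e-9)
    if (k$n > 0) expect_lte(k$W / k$n, 1 + 1e-9)
  }
})

test_that("batches merge deterministically and independently of workers", {
  prob <- tiny_problem()
  cfg <- search_config(iterations_per_step = 40, min_steps = 2, max_steps = 3,
                       seed = 43)
  b1 <- run_batch(prob, 3, cfg, n_workers = 1)
  b2 <- run_batch(prob, 3, cfg, n_workers = 2)
  expect_identical(b1$archive$key, b2$archive$key)
  expect_identical(b1$archive$search_id, b2$archive$search_id)
  expect_identical(b1$best_scores, b2$best_scores)
  expect_setequal(unique(b1$archive$search_id), 1:3)
  b0 <- run_batch(prob, 0, cfg)
  expect_equal(nrow(b0$archive), 0)
})

test_that("archives round-trip through JSONL", {
  prob <- tiny_problem()
  res <- run_search(prob, search_config(iterations_per_step = 30, min_steps = 1,
                                        max_steps = 3, seed = 47))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_archive(res$archive, f)
  back <- read_archive(f)
  expect_equal(back$key, res$archive$key)
  expect_equal(back$score, res$archive$score)
  expect_identical(back$edges, res$archive$edges)
})
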