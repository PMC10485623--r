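# synthetic archive helpers: records with planted structural clusters
fake_archive <- function(groups) {
  # groups: named list of lists of edge-id vectors
  rows <- do.call(rbind, lapply(seq_along(groups), function(g)
    data.frame(key = paste0(names(groups)[g], "_", seq_along(groups[[g]])),
               score = 1, step = 1L, n_edges = lengths(groups[[g]]),
               search_id = g, seed = 1L, stringsAsFactors = FALSE)))
  rows$edges <- unlist(groups, recursive = FALSE, use.names = FALSE)
  class(rows) <- c("search_archive", "data.frame")
  rows
}

edge_ids <- function(...) paste(c(...), "-> t +")

test_that("archive sampling is uniform, seeded, and order-stable", {
  arch <- fake_archive(list(a = lapply(1:20, function(i) edge_ids(letters[1:3]))))
  expect_identical(sample_archive(arch, nrow(arch))$key, arch$key)
  set.seed(61)
  s1 <- sample_archive(arch, 5)
  set.seed(61)
  s2 <- sample_archive(arch, 5)
  expect_identical(s1$key, s2$key)
  expect_error(sample_archive(arch, 99), "cannot sample")
})

test_that("jaccard distance matrices are valid semimetrics", {
  sets <- list(c("e1", "e2", "e3"), c("e1", "e2", "e3"), c("x1", "x2"))
  d <- jaccard_distance_matrix(sets)
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d[1, 2], 0)      # duplicates at distance zero
  expect_equal(d[1, 3], 1)      # disjoint sets at distance one
  # consistency with pairwise calls on models
  set.seed(62)
  ms <- lapply(1:3, function(i) random_model(5, 6))
  dm <- jaccard_distance_matrix(ms)
  expect_equal(dm[1, 2], 1 - jaccard(ms[[1]], ms[[2]]))
  expect_equal(dm[2, 3], 1 - jaccard(ms[[2]], ms[[3]]))
})

test_that("embedding is shaped, deterministic, and separates planted clusters", {
  # two planted groups: tight within, far between
  g1 <- lapply(1:6, function(i) c("a1", "a2", "a3", "a4", paste0("n", i)))
  g2 <- lapply(1:6, function(i) c("b1", "b2", "b3", "b4", paste0("m", i)))
  arch <- fake_archive(list(A = g1, B = g2))
  d <- jaccard_distance_matrix(arch)
  xy <- embed_2d(d)
  expect_equal(dim(xy), c(12, 2))
  expect_identical(xy, embed_2d(d))
  labels <- arch$search_id
  expect_gt(mean_silhouette(d, labels), 0)
  # degenerate two-point case
  expect_equal(dim(embed_2d(jaccard_distance_matrix(list(c("a"), c("b"))))),
               c(2, 2))
})

test_that("common interactions respect the frequency threshold", {
  sets <- c(lapply(1:9, function(i) c("keep", "also")), list(c("keep")))
  cm <- common_interactions(sets, threshold = 0.9)
  expect_true("keep" %in% names(cm$common))
  expect_true("also" %in% names(cm$common)) # 9/10 = 0.9 boundary included
  cm2 <- common_interactions(sets, threshold = 1)
  expect_identical(names(cm2$common), "keep")
  # prespecified edges are reported separately
  cm3 <- common_interactions(sets, 0.9, prespecified = "keep")
  expect_false("keep" %in% names(cm3$common))
  expect_identical(cm3$prespecified, "keep")
})

test_that("intersection statistics mirror the reference-overlap table", {
  ref <- paste("r", 1:15, "-> t +")
  cl <- list(ref, ref[1:10], ref[1:5])
  st <- intersection_stats(cl, ref)
  expect_equal(st$mean, mean(c(15, 10, 5)))
  expect_equal(st$median, 10)
  expect_equal(st$max, 15)
  expect_equal(st$cluster_size, 3)
  # excluded prespecified edges cap the attainable intersection
  st2 <- intersection_stats(cl, ref, exclude_prespecified = ref[1:5])
  expect_equal(st2$max, 10)
  expect_equal(intersection_stats(list(character(0)), ref)$mean, 0)
})

test_that("distinguishing sets match brute-force enumeration on small alphabets", {
  set.seed(63)
  for (rep in 1:10) {
    alphabet <- paste0("e", 1:sample(6:12, 1))
    mk_cluster <- function(m) lapply(1:m, function(i)
      sample(alphabet, sample(2:length(alphabet), 1)))
    clusters <- list(A = mk_cluster(8), B = mk_cluster(8))
    in_freq <- 0.6
    out_freq <- 0.4
    mined <- distinguishing_sets(clusters, max_size = 3,
                                 in_freq = in_freq, out_freq = out_freq)
    for (ci in names(clusters)) {
      brute <- brute_distinguishing(clusters[[ci]], clusters[setdiff(names(clusters), ci)],
                                    3, in_freq, out_freq)
      # the miner reports the minimal sets; every brute-force set must
      # contain a mined set with identical support signature, and every
      # mined set must be in the brute-force list
      mined_keys <- vapply(mined[[ci]]$set, paste, "", collapse = ";")
      brute_keys <- vapply(brute, function(b) paste(b$set, collapse = ";"), "")
      expect_true(all(mined_keys %in% brute_keys))
      for (b in brute) {
        covered <- any(vapply(seq_along(mined[[ci]]$set), function(j)
          all(mined[[ci]]$set[[j]] %in% b$set) &&
            abs(mined[[ci]]$in_freq[j] - b$in_freq) < 1e-9 ||
            identical(sort(mined[[ci]]$set[[j]]), sort(b$set)), TRUE))
        expect_true(covered)
      }
    }
  }
})

test_that("planted distinguishing signals are recovered and null cases are empty", {
  base <- c("c1", "c2")
  clA <- lapply(1:10, function(i) c(base, "only_a"))
  clB <- lapply(1:10, function(i) c(base, "only_b"))
  ds <- distinguishing_sets(list(A = clA, B = clB), in_freq = 0.9, out_freq = 0.1)
  expect_true(list("only_a") %in% ds$A$set)
  expect_false(any(vapply(ds$A$set, function(s) "c1" %in% s && length(s) == 1, TRUE)))
  # identical distributions: nothing distinguishes
  ds0 <- distinguishing_sets(list(A = clA, B = clA), in_freq = 0.9, out_freq = 0.1)
  expect_equal(nrow(ds0$A), 0)
  expect_error(distinguishing_sets(list(A = clA, B = clB), in_freq = 0.1,
                                   out_freq = 0.5))
  # a planted 3-edge motif is reported via its minimal distinguishing subsets
  clC <- lapply(1:20, function(i)
    if (i <= 19) c(base, "m1", "m2", "m3") else base)
  clD <- lapply(1:20, function(i) base)
  ds3 <- distinguishing_sets(list(C = clC, D = clD), max_size = 3,
                             in_freq = 0.9, out_freq = 0.05)
  keys <- vapply(ds3$C$set, paste, "", collapse = ";")
  expect_true(all(c("m1", "m2", "m3") %in% unlist(ds3$C$set)))
  # supersets with the same signature are pruned: singletons suffice
  expect_false("m1;m2" %in% keys)
})

test_that("disruption ranking recovers a planted essential interaction", {
  # models built on the toy circuit: knocking out the C->B activation
  # breaks convergence to the all-ones attractor
  m <- toy_model()
  cond <- condition("toy", character(0), matrix(c(1, 0, 1), 1),
                    as_census(matrix(c(1, 1, 1), 1), 1L))
  models <- list(m, m, m)
  singles <- lapply(names(interactions_of(m)), identity)
  set.seed(64)
  rank <- disruption_rank(singles, models, list(cond), n_sample = 3)
  # oracle: exhaustive knockout of every single edge
  oracle <- vapply(singles, function(s) {
    km <- knockout_interactions(m, list(s[[1]]))
    similarity(m, cond) - similarity(km, cond)
  }, 0)
  expect_equal(rank$set[[1]],
               singles[[which.max(oracle)]])
  expect_equal(max(rank$mean_reduction), max(oracle))
  # absent edges are skipped and counted; the empty set is a strict no-op
  rank2 <- disruption_rank(list("zz -> q +", character(0)), models, list(cond))
  skip_row <- which(vapply(rank2$set, identical, TRUE, "zz -> q +"))
  expect_equal(rank2$n_skipped[skip_row], 3L)
  empty_row <- which(lengths(rank2$set) == 0)
  expect_equal(rank2$mean_reduction[empty_row], 0)
})

test_that("provenance clustering partitions the archive", {
  arch <- fake_archive(list(A = lapply(1:3, function(i) edge_ids("a")),
                            B = lapply(1:2, function(i) edge_ids("b"))))
  cv <- cluster_archive(arch)
  expect_length(cv, 2)
  expect_equal(sum(vapply(cv, nrow, 0L)), nrow(arch))
})
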