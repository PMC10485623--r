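test_that("rule evaluation follows dominant inhibition", {
  rule <- list(activators = list("a"), inhibitors = list("b"), frozen = NULL)
  expect_false(evaluate_rule(rule, c(a = 1, b = 1))) # inhibition dominates
  expect_true(evaluate_rule(rule, c(a = 1, b = 0)))
  expect_false(evaluate_rule(rule, c(a = 0, b = 0)))
  empty <- list(activators = list(), inhibitors = list("b"), frozen = NULL)
  expect_false(evaluate_rule(empty, c(a = 1, b = 0))) # no activator: constant false
  expect_false(evaluate_rule(empty, c(a = 1, b = 1)))
  comp <- list(activators = list(c("a", "c")), inhibitors = list(), frozen = NULL)
  expect_false(evaluate_rule(comp, c(a = 1, c = 0))) # composite needs all members
  expect_true(evaluate_rule(comp, c(a = 1, c = 1)))
  frz <- list(activators = list(), inhibitors = list("b"), frozen = TRUE)
  expect_true(evaluate_rule(frz, c(b = 0)))
  expect_false(evaluate_rule(frz, c(b = 1)))
  dnf <- list(activators = list(), inhibitors = list(),
              frozen = list(c("a", "!b"), "c"))
  expect_true(evaluate_rule(dnf, c(a = 1, b = 0, c = 0)))
  expect_false(evaluate_rule(dnf, c(a = 1, b = 1, c = 0)))
  expect_true(evaluate_rule(dnf, c(a = 0, b = 1, c = 1)))
  expect_error(evaluate_rule(rule, c(a = 1)), "b")
})

test_that("rule evaluation is monotone in activators and inhibitor-dominant", {
  set.seed(11)
  sp <- letters[1:5]
  for (i in 1:80) {
    acts <- unique(replicate(sample(0:3, 1), sample(sp, sample(1:2, 1)),
                             simplify = FALSE))
    inhs <- unique(replicate(sample(0:2, 1), sample(sp, 1), simplify = FALSE))
    acts <- acts[!vapply(acts, term_id <- function(t) paste(sort(t), collapse = "&"), "") %in%
                   vapply(inhs, function(t) paste(sort(t), collapse = "&"), "")]
    rule <- list(activators = acts, inhibitors = inhs, frozen = NULL)
    st <- random_state(sp)
    v0 <- evaluate_rule(rule, st)
    # adding an activator never flips true -> false
    rule2 <- rule
    rule2$activators <- c(rule$activators, list(sample(sp, 1)))
    if (v0) expect_true(evaluate_rule(rule2, st))
    # any true inhibitor forces false
    if (length(inhs) && any(vapply(inhs, function(t) all(st[t] > 0), TRUE)))
      expect_false(v0)
  }
})

test_that("add_interaction grows rules immutably and rejects duplicates", {
  m <- two_species_model()
  m1 <- add_interaction(m, new_interaction("a", "b"))
  expect_identical(m$rules, list()) # input unchanged
  expect_equal(names(interactions_of(m1)), "a -> b +")
  m2 <- add_interaction(m1, new_interaction("a", "b", "inhibit")) |> try(silent = TRUE)
  expect_s3_class(m2, "try-error") # contradictory sign
  expect_error(add_interaction(m1, new_interaction("a", "b")), "duplicate")
  expect_error(add_interaction(m1, new_interaction("zz", "b")), "zz")
})

test_that("interactions_of is the union property under add_interaction", {
  set.seed(21)
  for (rep in 1:20) {
    m <- random_model(5, 6)
    e <- new_interaction("g01", "g04", sample(c("activate", "inhibit"), 1))
    if (interaction_id(e) %in% names(interactions_of(m)) ||
        flip_sign_id(interaction_id(e)) %in% names(interactions_of(m))) next
    m2 <- add_interaction(m, e)
    expect_setequal(names(interactions_of(m2)),
                    union(names(interactions_of(m)), interaction_id(e)))
  }
  expect_length(interactions_of(two_species_model()), 0)
})

test_that("knockout_interactions removes edges and silences emptied rules", {
  m <- add_interaction(two_species_model(), new_interaction("a", "b"))
  km <- knockout_interactions(m, list(new_interaction("a", "b")))
  expect_length(interactions_of(km), 0)
  # b now has an empty rule: constant false even from b = 1
  tr <- run_to_attractor(km, c(a = 1, b = 1))
  expect_equal(unname(attractor_representative(tr)), c(1, 0))
  expect_error(knockout_interactions(km, list(new_interaction("a", "b"))),
               "not present")
  # empty knockout is the identity
  expect_identical(canonical_key(knockout_interactions(m, list())),
                   canonical_key(m))
  # removed edges never reappear
  set.seed(5)
  for (rep in 1:10) {
    rm <- random_model(5, 8)
    edges <- interactions_of(rm)
    drop <- edges[sample(length(edges), 3)]
    kk <- knockout_interactions(rm, drop)
    expect_length(intersect(names(interactions_of(kk)), names(drop)), 0)
  }
})

test_that("a rule stripped of its last interaction loses its frozen clause", {
  m <- boolean_model(data.frame(name = c("a", "x"), kind = "gene"),
                     rules = list(x = list(activators = list(),
                                           inhibitors = list("a"), frozen = TRUE)))
  # constitutive-unless-inhibited behaves as NOT a
  expect_equal(unname(step_state(m, c(a = 0, x = 0))), c(0, 1))
  km <- knockout_interactions(m, list(new_interaction("a", "x", "inhibit")))
  expect_equal(unname(step_state(km, c(a = 0, x = 1))), c(0, 0))
})

test_that("knockout_gene removes the gene from targets and sources", {
  spn <- load_spn()
  km <- knockout_gene(spn$model, "en")
  ids <- names(interactions_of(km, include_prespecified = TRUE))
  expect_false(any(grepl("(^|&)en(@[0-9])?( |&)", ids)))
  expect_false(any(grepl("-> en(@[0-9])? [+-]$", ids)))
  # en is off at every simulated step, from any condition initial state
  ini <- spn$conditions[[1]]$initials[1, ]
  ini[grep("^en(@|$)", names(ini))] <- 0
  tr <- run_to_attractor(km, ini)
  expect_true(all(tr$states[, grep("^en(@|$)", colnames(tr$states))] == 0))
  # hh knockout: HH is never activated again (its only activator was hh)
  kh <- knockout_gene(spn$model, "hh")
  inih <- spn$conditions[[1]]$initials[1, ]
  inih[grep("^(hh|HH)(@|$)", names(inih))] <- 0
  trh <- run_to_attractor(kh, inih)
  expect_true(all(trh$states[, grep("^HH(@|$)", colnames(trh$states))] == 0))
  expect_error(knockout_gene(spn$model, "nosuch"), "unknown gene")
  # knockout of an interaction-free gene is the identity
  m <- two_species_model()
  expect_identical(canonical_key(knockout_gene(m, "a")), canonical_key(m))
})

test_that("canonical_key is invariant to construction order", {
  set.seed(31)
  base_edges <- list(new_interaction("a", "b"),
                     new_interaction("c", "b", "inhibit"),
                     new_interaction(c("a", "c"), "d"),
                     new_interaction("b", "a"))
  sp <- data.frame(name = letters[1:4], kind = "gene")
  for (rep in 1:10) {
    m1 <- Reduce(add_interaction, base_edges, boolean_model(sp))
    m2 <- Reduce(add_interaction, sample(base_edges), boolean_model(sp[sample(4), ]))
    expect_identical(canonical_key(m1), canonical_key(m2))
  }
  # sign change changes the key
  m1 <- add_interaction(boolean_model(sp), new_interaction("a", "b"))
  m2 <- add_interaction(boolean_model(sp), new_interaction("a", "b", "inhibit"))
  expect_false(canonical_key(m1) == canonical_key(m2))
})

test_that("text format round-trips bit-exactly", {
  spn <- load_spn()
  for (m in list(toy_model(), spn$model, random_model(6, 10))) {
    lines <- write_boolean_model(m)
    m2 <- read_boolean_model(text = lines)
    expect_identical(canonical_key(m2), canonical_key(m))
    expect_identical(write_boolean_model(m2), lines)
  }
  expect_error(read_boolean_model(text = c("SPECIES a gene", "GIBBERISH")),
               ":2:")
})

test_that("BoolNet export expands dominant inhibition", {
  m <- boolean_model(data.frame(name = c("a", "b", "x"), kind = "gene"),
                     rules = list(x = list(activators = list("a"),
                                           inhibitors = list("b"), frozen = NULL)))
  f <- withr::local_tempfile(fileext = ".bn")
  lines <- write_boolnet(m, f)
  expect_equal(lines[1], "targets, factors")
  expect_true("a, a" %in% lines)     # inputs map to themselves
  expect_true(any(grepl("^x, \\(a\\) & !\\(b\\)$", lines)))
})
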