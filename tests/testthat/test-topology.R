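test_that("scope expansion layers a linear chain and respects AND-semantics", {
  m <- chain_model(c("A", "B", "C"))
  sc <- compute_scope(m, "A")
  expect_setequal(sc$producible, c("A", "B", "C"))
  expect_equal(sc$layer[c("A", "B", "C")], c(A = 0L, B = 1L, C = 2L))
  expect_setequal(sc$fired, c("r1", "r2"))

  # a reaction with an unavailable co-reactant must not fire
  m2 <- add_rxn(gsm_model("and"), "r1", c("A", "X"), "B")
  sc2 <- compute_scope(m2, "A")
  expect_equal(sc2$producible, "A")
  expect_length(sc2$fired, 0L)
})

test_that("reversible reactions expand both ways; self-loops don't bootstrap", {
  m <- chain_model(c("A", "B"), reversible = TRUE)
  expect_setequal(compute_scope(m, "B")$producible, c("A", "B"))

  loop <- add_rxn(gsm_model("loop"), "r1", c("S", "X"), c("X", "P"))
  expect_equal(compute_scope(loop, "S")$producible, "S")
  expect_setequal(compute_scope(loop, c("S", "X"))$producible,
                  c("P", "S", "X"))
})

test_that("unknown seeds warn and are excluded rather than crashing", {
  m <- chain_model(c("A", "B"))
  expect_warning(sc <- compute_scope(m, c("A", "GHOST")), "GHOST")
  expect_equal(sc$unknown_seeds, "GHOST")
  expect_setequal(sc$producible, c("A", "B"))
})

test_that("scope agrees with the naive oracle and is monotone and idempotent", {
  for (s in 1:20) {
    net <- random_network(n_compounds = 8 + (s %% 20),
                          n_reactions = 10 + (s %% 15),
                          reversible_fraction = 0.3, leak_prob = 0.3, seed = s)
    sc <- compute_scope(net$model, net$seeds)
    expect_identical(sc$producible, oracle_scope(net$model, net$seeds))
    # seed monotonicity
    extra <- setdiff(entity_ids(net$model, "compound"), net$seeds)[1]
    sc_more <- compute_scope(net$model, c(net$seeds, extra))
    expect_true(all(sc$producible %in% sc_more$producible))
    # fixpoint: feeding the scope back as seeds adds nothing
    sc_fix <- compute_scope(net$model, sc$producible)
    expect_setequal(sc_fix$producible, sc$producible)
    # every fired reaction had all reactants producible
    dirs <- gsmtrace:::directed_reactions(net$model)
    for (d in dirs) {
      key <- paste(d$rid, d$dir)
      fired_keys <- paste(sc$fired_detail$rid, sc$fired_detail$dir)
      if (key %in% fired_keys)
        expect_true(all(d$reactants %in% sc$producible))
    }
  }
})

test_that("unproducible target detection matches scope and flags absent ids", {
  m <- chain_model(c("A", "B", "C"))
  expect_length(unproducible_targets(m, "A", "C"), 0L)
  bad <- unproducible_targets(m, "A", "D")
  expect_equal(as.character(bad), "D")
  expect_equal(unname(attr(bad, "reason")["D"]), "absent")
  for (s in 1:5) {
    net <- random_network(n_compounds = 15, n_reactions = 12,
                          leak_prob = 0.4, seed = s)
    bad <- unproducible_targets(net$model, net$seeds, net$targets)
    oracle_bad <- sort(setdiff(net$targets,
                               oracle_scope(net$model, net$seeds)))
    expect_identical(as.character(bad), oracle_bad)
  }
})

test_that("unblocking compounds enumerates subset-minimal sets in order", {
  m <- gsm_model("u")
  m <- add_entity(m, gsm_entity("A", "compound"))
  m <- add_rxn(m, "r1", "B", "C")
  sets <- unblocking_compounds(m, "A", "C")
  expect_equal(sets, list("B", "C"), ignore_attr = TRUE)

  # all targets already producible
  m2 <- chain_model(c("A", "B"))
  empty <- unblocking_compounds(m2, "A", "B")
  expect_length(empty, 0L)
  expect_true(attr(empty, "already_producible"))

  # AND-blocked target needs both missing reactants within the bound
  m3 <- gsm_model("u3")
  m3 <- add_entity(m3, gsm_entity("A", "compound"))
  m3 <- add_rxn(m3, "r1", c("B", "D"), "C")
  at1 <- unblocking_compounds(m3, "A", "C", max_size = 1)
  expect_equal(at1, list("C"), ignore_attr = TRUE)
  at2 <- unblocking_compounds(m3, "A", "C", max_size = 2)
  expect_equal(at2, list("C", c("B", "D")), ignore_attr = TRUE)
})

test_that("unblocking agrees with exhaustive enumeration on random networks", {
  for (s in 1:6) {
    net <- random_network(n_compounds = 9, n_reactions = 8,
                          leak_prob = 0.5, n_targets = 2, seed = s)
    got <- unblocking_compounds(net$model, net$seeds, net$targets, max_size = 2)
    want <- brute_unblocking(net$model, net$seeds, net$targets, max_k = 2)
    key <- function(sets) sort(vapply(sets, paste, character(1), collapse = "+"))
    expect_identical(key(got), key(want))
  }
})

test_that("production paths replay validly and fail with a typed error", {
  m <- chain_model(c("A", "B", "C"))
  expect_equal(production_path(m, "A", "C"), c("r1", "r2"))
  expect_equal(production_path(m, "A", "A"), character(0))
  err <- tryCatch(production_path(m, "B", "A"), error = function(e) e)
  expect_s3_class(err, "gsm_not_producible")
  expect_match(conditionMessage(err), "missing precursor")

  # replay oracle: walking the returned sequence never lacks a reactant
  replay_ok <- function(model, seeds, target, path) {
    have <- seeds
    for (rid in path) {
      s <- gsmtrace:::reaction_sides(model, rid)
      lhs <- vapply(s$reactants, `[[`, character(1), "id")
      rhs <- vapply(s$products, `[[`, character(1), "id")
      fired <- FALSE
      for (d in list(list(lhs, rhs),
                     if (reaction_direction(model, rid) == "REVERSIBLE")
                       list(rhs, lhs))) {
        if (is.null(d)) next
        if (all(d[[1]] %in% have)) { have <- union(have, d[[2]]); fired <- TRUE; break }
      }
      if (!fired) return(FALSE)
    }
    target %in% have
  }
  for (s in 1:8) {
    net <- random_network(n_compounds = 12, n_reactions = 12,
                          reversible_fraction = 0.3, leak_prob = 0.2, seed = s)
    sc <- compute_scope(net$model, net$seeds)
    for (tgt in intersect(net$targets, sc$producible)) {
      p <- production_path(net$model, net$seeds, tgt)
      expect_true(replay_ok(net$model, net$seeds, tgt, p))
    }
  }
})

test_that("class reactions instantiate over direct instances with a cap", {
  m <- gsm_model("inst")
  m <- add_entity(m, gsm_entity("K", "class"))
  for (k in c("k1", "k2")) {
    m <- add_entity(m, gsm_entity(k, "compound"))
    m <- add_relation(m, k, "is_a", "K")
  }
  m <- add_rxn(m, "RXN", "K", "P")
  out <- instantiate_class_reactions(m)
  expect_setequal(attr(out, "variants"), c("RXN/k1", "RXN/k2"))
  expect_true(has_entity(out, "RXN"))  # original retained
  expect_equal(get_entity(out, "RXN/k1")$attributes[["instance-of"]], "RXN")
  expect_equal(out$tags$category[out$tags$entity == "RXN/k1"], "gap-filling")

  # no class participants: unchanged
  plain <- add_rxn(gsm_model("p"), "r", "A", "B")
  expect_length(attr(instantiate_class_reactions(plain), "variants"), 0L)

  # two class slots with 2 and 3 instances -> 6 variants
  m2 <- gsm_model("inst2")
  for (cl in c("K1", "K2")) m2 <- add_entity(m2, gsm_entity(cl, "class"))
  for (k in c("a1", "a2")) {
    m2 <- add_entity(m2, gsm_entity(k, "compound"))
    m2 <- add_relation(m2, k, "is_a", "K1")
  }
  for (k in c("b1", "b2", "b3")) {
    m2 <- add_entity(m2, gsm_entity(k, "compound"))
    m2 <- add_relation(m2, k, "is_a", "K2")
  }
  m2 <- add_rxn(m2, "RXN2", "K1", "K2")
  expect_length(attr(instantiate_class_reactions(m2), "variants"), 6L)
  # the cap skips and reports instead of exploding
  capped <- instantiate_class_reactions(m2, max_variants = 5)
  expect_equal(attr(capped, "skipped"), "RXN2")
  expect_length(attr(capped, "variants"), 0L)
})

test_that("cyclic ontologies are rejected", {
  m <- gsm_model("cyc")
  m <- add_entity(m, gsm_entity("X", "class"))
  m <- add_entity(m, gsm_entity("Y", "class"))
  m <- add_relation(m, "X", "is_a", "Y")
  m <- add_relation(m, "Y", "is_a", "X")
  expect_error(instantiate_class_reactions(m), class = "gsm_cyclic_ontology")
})

test_that("gap-filling handles trivial, infeasible and bounded cases", {
  fx <- make_folate_fixture()
  # already-producible targets give the empty completion
  done <- gapfill(fx$draft, fx$database, fx$seeds, "DIHYDROFOLATE")
  expect_equal(done$solutions, list(character(0)))

  # unreachable targets raise a typed error naming them
  err <- tryCatch(gapfill(fx$draft, fx$database, "WATER", "THF-GLU-N"),
                  error = function(e) e)
  expect_s3_class(err, "gsm_infeasible")
  expect_match(conditionMessage(err), "THF-GLU-N")
})

test_that("gap-filling agrees with exhaustive enumeration on random instances", {
  n_checked <- 0L
  for (s in 1:10) {
    net <- random_network(n_compounds = 12, n_reactions = 12,
                          leak_prob = 0, n_targets = 2, seed = s)
    full <- net$model
    # carve a draft by deleting a third of the reactions
    rids <- entity_ids(full, "reaction")
    drop <- rids[seq(1, length(rids), by = 3)]
    draft <- full
    for (rid in drop)
      draft <- apply_form(draft, curation_form(
        "delete_entity", list(id = rid), "test carve", "fixture"))
    want <- brute_min_completions(draft, full, net$seeds, net$targets, max_k = 3)
    got <- tryCatch(
      gapfill(draft, full, net$seeds, net$targets, max_size = 3,
              enumerate = TRUE),
      gsm_error = function(e) e)
    if (length(want) == 0) {
      expect_s3_class(got, "gsm_error")
      next
    }
    key <- function(sets) sort(vapply(sets, paste, character(1), collapse = "+"))
    expect_identical(key(got$solutions), key(want))
    # post-hoc: every solution produces the targets and is single-removal minimal
    for (sol in got$solutions) {
      m <- apply_completion(draft, full, sol)
      expect_true(all(net$targets %in% compute_scope(m, net$seeds)$producible))
      for (r in sol) {
        m_less <- apply_completion(draft, full, setdiff(sol, r))
        expect_false(all(net$targets %in%
                           compute_scope(m_less, net$seeds)$producible))
      }
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 3L)
})

test_that("adding reactions never shrinks the scope", {
  for (s in 1:5) {
    net <- random_network(n_compounds = 12, n_reactions = 10,
                          leak_prob = 0.2, seed = s)
    full_scope <- compute_scope(net$model, net$seeds)$producible
    rid <- entity_ids(net$model, "reaction")[1]
    less <- apply_form(net$model, curation_form(
      "delete_entity", list(id = rid), "monotonicity probe", "fixture"))
    less_scope <- compute_scope(less, net$seeds)$producible
    expect_true(all(less_scope %in% full_scope))
  }
})
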