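test_that("curation forms validate their audit trail and payload", {
  expect_error(curation_form("add_reaction",
                             list(id = "R", reactants = "A:1", products = "B:1"),
                             justification = "", source = "PMID:1"),
               class = "gsm_validation_error")
  expect_error(curation_form("add_reaction",
                             list(id = "R", reactants = "A:1", products = "B:1"),
                             justification = "why", source = ""),
               class = "gsm_validation_error")
  expect_error(curation_form("add_reaction", list(id = "R", products = "B:1"),
                             justification = "why", source = "PMID:1"),
               class = "gsm_validation_error")
  expect_error(curation_form("frobnicate", list(id = "R"), "why", "PMID:1"),
               class = "gsm_validation_error")
})

test_that("applying forms edits the model and stamps manual provenance", {
  m <- gsm_model("cur")
  f <- curation_form("add_reaction",
                     list(id = "NEW-RXN", reactants = "A:1,B:2",
                          products = "C:1", direction = "LEFT-TO-RIGHT",
                          genes = "g1"),
                     justification = "expert knowledge", source = "PMID:42")
  m <- apply_form(m, f)
  expect_true(has_entity(m, "NEW-RXN"))
  expect_true(has_entity(m, "g1"))
  tags <- m$tags[m$tags$entity == "NEW-RXN", ]
  expect_equal(tags$category, "manual")
  expect_equal(tags$tool, "curation-form")
  expect_equal(tags$source, "PMID:42")
  expect_equal(tags$comment, "expert knowledge")
  idx <- gsmtrace:::relation_index(m, "NEW-RXN", "consumes", "B")
  expect_equal(m$relations[[idx]]$attributes$coefficient, "2")
  expect_length(m$log, 1L)

  # deleting the two flagged-useless reactions shrinks the count by two
  m2 <- add_rxn(m, "USELESS-1", "A", "C")
  m2 <- add_rxn(m2, "USELESS-2", "B", "C")
  n_before <- length(entity_ids(m2, "reaction"))
  for (rid in c("USELESS-1", "USELESS-2"))
    m2 <- apply_form(m2, curation_form("delete_entity", list(id = rid),
                                       "useless in this organism", "review"))
  expect_equal(length(entity_ids(m2, "reaction")), n_before - 2L)
  expect_false(any(vapply(m2$relations, function(r)
    r$subject %in% c("USELESS-1", "USELESS-2"), logical(1))))
})

test_that("add then delete restores the original entity set", {
  base <- chain_model(c("A", "B"))
  add <- curation_form("add_compound", list(id = "Z"), "probe", "fixture")
  del <- curation_form("delete_entity", list(id = "Z"), "probe", "fixture")
  m <- apply_form(apply_form(base, add), del)
  expect_setequal(names(m$entities), names(base$entities))
  expect_length(m$log, 2L)  # history survives in the log
})

test_that("modify and delete on unknown targets raise not-found errors", {
  m <- chain_model(c("A", "B"))
  expect_error(apply_form(m, curation_form("modify_entity",
                                           list(id = "GHOST", charge = "1"),
                                           "j", "s")),
               class = "gsm_not_found")
  expect_error(apply_form(m, curation_form("delete_entity", list(id = "GHOST"),
                                           "j", "s")),
               class = "gsm_not_found")
})

test_that("replay reproduces the curated model and skips drifted targets", {
  base <- chain_model(c("A", "B", "C"))
  m <- apply_form(base, curation_form("add_reaction",
                                      list(id = "RX", reactants = "C:1",
                                           products = "D:1"),
                                      "extension", "PMID:7"))
  m <- apply_form(m, curation_form("modify_entity",
                                   list(id = "A", charge = "-1"), "fix", "PMID:8"))
  replayed <- replay_log(base, m$log)
  expect_equal(nrow(replayed$skipped), 0L)
  expect_model_equal(replayed$model, m)

  # a base that lost one target: the form is skipped with a report, not fatal
  drifted <- apply_form(base, curation_form("delete_entity", list(id = "A"),
                                            "regenerated upstream", "assembly-2"))
  drifted$log <- list()
  rep2 <- replay_log(drifted, m$log)
  expect_equal(nrow(rep2$skipped), 1L)
  expect_equal(rep2$skipped$id, "A")
  expect_true(has_entity(rep2$model, "RX"))

  # empty log is the identity
  rep3 <- replay_log(base, list())
  expect_model_equal(rep3$model, base)
})

test_that("forms parse from the flat block dialect", {
  f <- withr::local_tempfile()
  writeLines(c("# curated additions",
               "op: add_reaction",
               "id\tRX1",
               "reactants\tA:1",
               "products\tB:1",
               "justification\tseen in vivo",
               "source\tPMID:99",
               "",
               "op: delete_entity",
               "id\tRX0",
               "justification\tspurious",
               "source\treview"), f)
  forms <- read_forms(f)
  expect_length(forms, 2L)
  expect_equal(forms[[1]]$op, "add_reaction")
  expect_equal(forms[[2]]$payload$id, "RX0")
})

test_that("model diff partitions ids and is antisymmetric", {
  fx <- make_folate_fixture()
  self <- diff_models(fx$draft, fx$draft)
  expect_true(all(self$summary[, c("added", "removed", "changed")] == 0))

  plus <- add_rxn(fx$draft, "EXTRA-RXN", "GTP", "WATER")
  d <- diff_models(fx$draft, plus)
  expect_equal(d$reactions$added, "EXTRA-RXN")
  expect_equal(d$summary$added[d$summary$category == "reactions"], 1L)

  for (s in 1:4) {
    a <- random_network(n_compounds = 10, n_reactions = 7, seed = s)$model
    b <- random_network(n_compounds = 10, n_reactions = 7, seed = s + 50)$model
    ab <- diff_models(a, b); ba <- diff_models(b, a)
    for (cat in c("reactions", "compounds", "genes", "pathways")) {
      expect_identical(ab[[cat]]$added, ba[[cat]]$removed)
      expect_identical(ab[[cat]]$removed, ba[[cat]]$added)
      # counts always equal list lengths
      srow <- ab$summary[ab$summary$category == cat, ]
      expect_equal(srow$added, length(ab[[cat]]$added))
      expect_equal(srow$changed, length(ab[[cat]]$changed))
    }
  }
})

test_that("diff reports attribute- and relation-level changes", {
  a <- chain_model(c("A", "B"))
  b <- apply_form(a, curation_form("modify_entity",
                                   list(id = "A", formula = "C1"),
                                   "annotate", "db"))
  b <- add_rxn(b, "r1b", "B", "A")  # new reaction; r1 itself unchanged
  b2 <- b
  idx <- gsmtrace:::relation_index(b2, "r1", "consumes", "A")
  b2$relations[[idx]]$attributes$coefficient <- "3"
  d <- diff_models(a, b2)
  expect_true("A" %in% names(d$compounds$changed))
  expect_match(d$compounds$changed$A[1], "formula")
  expect_true("r1" %in% names(d$reactions$changed))
  expect_match(paste(d$reactions$changed$r1, collapse = " "), "x3")
})
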