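test_that("stoichiometric matrix export signs and counts are right", {
  m <- add_rxn(gsm_model("m"), "r1", "A", "B")
  f <- withr::local_tempfile()
  mat <- export_matrix(m, f)
  expect_equal(mat["A", "r1"], -1)
  expect_equal(mat["B", "r1"], 1)

  m2 <- add_rxn(gsm_model("m2"), "r1", "A:2", "B")
  mat2 <- export_matrix(m2, f)
  expect_equal(mat2["A", "r1"], -2)

  # column count equals reaction count on generated fixtures
  for (s in 1:3) {
    net <- random_network(n_compounds = 12, n_reactions = 9, seed = s)
    mat <- export_matrix(net$model, f)
    expect_equal(ncol(mat), length(entity_ids(net$model, "reaction")))
    # file round-trip agrees with the returned matrix
    back <- as.matrix(read.delim(f, row.names = 1, check.names = FALSE))
    expect_equal(unname(back), unname(mat))
  }
})

test_that("identifier mapping rewrites entities, relations and tags", {
  m <- gsm_model("m", ref_db = "bigg")
  m <- add_rxn(m, "RXN1", "bigg:atp", "bigg:adp")
  m <- add_tag(m, gsm_tag("bigg:atp", "annotation", "tool", "src", 0L))
  tab <- gsm_mapping(data.frame(
    foreign_id = c("bigg:atp", "bigg:adp"),
    reference_id = c("ATP", "ADP"), scope = "compound"))
  res <- map_identifiers(m, tab)
  expect_equal(res$report$mapped[["compound"]], 2L)
  expect_true(has_entity(res$model, "ATP"))
  expect_false(has_entity(res$model, "bigg:atp"))
  expect_equal(get_entity(res$model, "ATP")$attributes$xrefs, "bigg:atp")
  expect_equal(res$model$tags$entity, "ATP")
  edge <- gsmtrace:::relation_index(res$model, "RXN1", "consumes", "ATP")
  expect_false(is.na(edge))

  # empty table: identity, everything reported unmapped
  res0 <- map_identifiers(m, gsm_mapping(data.frame(
    foreign_id = character(0), reference_id = character(0),
    scope = character(0))))
  expect_model_equal(res0$model, m)
  expect_setequal(res0$report$unmapped$compound, c("bigg:atp", "bigg:adp"))
  # mapped + unmapped = every id encountered (2 compounds + 1 reaction)
  expect_equal(sum(res0$report$mapped) + sum(lengths(res0$report$unmapped)),
               length(m$entities))
})

test_that("mapping collisions merge compatible entities and refuse clashes", {
  m <- gsm_model("m")
  m <- add_rxn(m, "rA", "x", "y")
  m <- add_rxn(m, "rB", "x", "y")
  m <- add_tag(m, gsm_tag("rA", "annotation", "t1", "s1", 0L))
  m <- add_tag(m, gsm_tag("rB", "orthology", "t2", "s2", 1L))
  tab <- gsm_mapping(data.frame(foreign_id = c("rA", "rB"),
                                reference_id = "RXN", scope = "reaction"))
  res <- map_identifiers(m, tab)
  expect_equal(entity_ids(res$model, "reaction"), "RXN")
  expect_setequal(res$model$tags$category[res$model$tags$entity == "RXN"],
                  c("annotation", "orthology"))
  expect_equal(res$report$collisions, "RXN")

  m2 <- add_entity(m, gsm_entity("METAB", "compound"))
  tab2 <- gsm_mapping(data.frame(
    foreign_id = c("rA", "METAB"), reference_id = "CLASH",
    scope = c("reaction", "compound")))
  expect_error(map_identifiers(m2, tab2), class = "gsm_mapping_collision")
})

test_that("mapping tables reject ambiguity and transitive chains", {
  expect_error(gsm_mapping(data.frame(
    foreign_id = c("a", "a"), reference_id = c("x", "y"), scope = "compound")),
    class = "gsm_invalid_mapping")
  expect_error(gsm_mapping(data.frame(
    foreign_id = c("a", "x"), reference_id = c("x", "z"), scope = "compound")),
    class = "gsm_invalid_mapping")
})

test_that("map_identifiers is idempotent", {
  for (s in 1:3) {
    m <- random_network(n_compounds = 10, n_reactions = 6, seed = s)$model
    tab <- gsm_mapping(data.frame(
      foreign_id = c("C001", "C002", "R001"),
      reference_id = c("ATP", "ADP", "ATPASE-RXN"),
      scope = c("compound", "compound", "reaction")))
    once <- map_identifiers(m, tab)$model
    twice <- map_identifiers(once, tab)$model
    expect_model_equal(once, twice)
  }
})

test_that("RDF export matches the closed-form triple count", {
  # one reaction A -> B, no attributes, one tag: 2 + 0 + 5 = 7 triples
  m <- gsm_model("rdf")
  m <- add_entity(m, gsm_entity("A", "compound"))
  m <- add_entity(m, gsm_entity("B", "compound"))
  m <- add_entity(m, gsm_entity("r1", "reaction"))
  m <- add_relation(m, "r1", "consumes", "A")
  m <- add_relation(m, "r1", "produces", "B")
  m$relations <- lapply(m$relations, function(r) { r$attributes <- list(); r })
  m <- add_tag(m, gsm_tag("r1", "annotation", "tool", "src", 0L))
  f <- withr::local_tempfile(fileext = ".ttl")
  expect_equal(export_rdf(m, f), 7L)
  triples <- grep("^@prefix|^\\s*$", readLines(f), invert = TRUE, value = TRUE)
  expect_length(triples, 7L)

  expect_equal(export_rdf(gsm_model("empty"), f), 0L)

  for (s in 1:3) {
    net <- random_network(n_compounds = 10, n_reactions = 8, seed = s)
    n <- export_rdf(net$model, f)
    expected <- length(net$model$relations) + n_attr_values(net$model) +
      5L * nrow(net$model$tags)
    expect_equal(n, expected)
    expect_length(grep("^@prefix|^\\s*$", readLines(f), invert = TRUE,
                       value = TRUE), expected)
  }
})
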