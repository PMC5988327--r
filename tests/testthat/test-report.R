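test_that("pathway completeness computes direct ratios and sorts by rate", {
  defs <- gsm_model("defs")
  defs <- add_entity(defs, gsm_entity("PWY-A", "pathway"))
  defs <- add_entity(defs, gsm_entity("PWY-EMPTY", "pathway"))
  model <- gsm_model("m")
  for (i in 1:8) {
    rid <- sprintf("r%d", i)
    defs <- add_rxn(defs, rid, sprintf("c%d", i), sprintf("c%d", i + 1))
    defs <- add_relation(defs, rid, "is_in_pathway", "PWY-A")
    if (i <= 6) model <- add_rxn(model, rid, sprintf("c%d", i),
                                 sprintf("c%d", i + 1))
  }
  rep <- pathway_completeness(model, defs)
  row <- rep$table[rep$table$pathway == "PWY-A", ]
  expect_equal(row$total, 8L)
  expect_equal(row$present, 6L)
  expect_equal(row$ratio, 0.75)
  expect_setequal(rep$missing[["PWY-A"]], c("r7", "r8"))
  expect_equal(rep$excluded, "PWY-EMPTY")

  # none present -> 0; all ratios within [0, 1]
  rep0 <- pathway_completeness(gsm_model("empty"), defs)
  expect_equal(rep0$table$ratio, 0)
})

test_that("completeness is invariant under consistent reaction renaming", {
  fx <- make_folate_fixture()
  before <- pathway_completeness(fx$draft, fx$pathway_defs)
  tab <- gsm_mapping(data.frame(
    foreign_id = c("PABASYN-RXN", "H2PTEROATESYNTH-RXN"),
    reference_id = c("RENAMED-1", "RENAMED-2"), scope = "reaction"))
  model2 <- map_identifiers(fx$draft, tab)$model
  defs2 <- map_identifiers(fx$pathway_defs, tab)$model
  after <- pathway_completeness(model2, defs2)
  expect_equal(before$table$ratio, after$table$ratio)
})

test_that("provenance breakdown does exact set algebra with overlaps", {
  m <- gsm_model("b")
  for (i in 1:6) m <- add_entity(m, gsm_entity(sprintf("E%d", i), "protein"))
  for (i in 1:4) m <- add_tag(m, gsm_tag(sprintf("E%d", i), "annotation",
                                         "pathway-tools", "genome", 0L))
  for (i in 3:6) m <- add_tag(m, gsm_tag(sprintf("E%d", i), "orthology",
                                         "pantograph", "template", 1L))
  b <- provenance_breakdown(m, "category")
  expect_equal(b$counts[["annotation"]], 4L)
  expect_equal(b$counts[["orthology"]], 4L)
  expect_equal(b$overlap["annotation", "orthology"], 2L)
  expect_equal(b$exclusive[["annotation"]], 2L)
  expect_equal(b$union, 6L)
  expect_true(isSymmetric(b$overlap))

  # single category: zero off-diagonal overlap
  m1 <- gsm_model("one")
  m1 <- add_entity(m1, gsm_entity("X", "reaction", list(boundary = "true")),
                   gsm_tag("X", "manual", "curation-form", "s", 0L))
  b1 <- provenance_breakdown(m1, "category")
  expect_equal(dim(b1$overlap), c(1L, 1L))
})

test_that("breakdown counts match a brute-force recount on random tags", {
  for (s in 1:4) {
    net <- random_network(n_compounds = 10, n_reactions = 15,
                          tag_categories = c("annotation", "orthology",
                                             "gap-filling"), seed = s)
    m <- net$model
    # sprinkle second tags to create overlaps
    rids <- entity_ids(m, "reaction")
    for (rid in rids[seq(1, length(rids), by = 3)])
      m <- add_tag(m, gsm_tag(rid, "manual", "curation-form", "probe", 99L))
    b <- provenance_breakdown(m, "category", etype = "reaction")
    for (g1 in names(b$counts)) {
      set1 <- unique(m$tags$entity[m$tags$category == g1])
      expect_equal(b$counts[[g1]], length(set1))
      for (g2 in names(b$counts)) {
        set2 <- unique(m$tags$entity[m$tags$category == g2])
        expect_equal(b$overlap[g1, g2], length(intersect(set1, set2)))
        # inclusion-exclusion on every pair
        expect_equal(length(union(set1, set2)),
                     b$counts[[g1]] + b$counts[[g2]] - b$overlap[g1, g2])
      }
    }
  }
})

test_that("formula parsing accepts Hill notation and refuses R-groups", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("H2O")[["H"]], 2)
  expect_null(parse_formula("C10H16N5O13P3R"))   # R-group
  expect_null(parse_formula("(C5H8)n"))          # polymer
  expect_null(parse_formula(NA_character_))
})

test_that("quality report balances mass and charge stoichiometrically", {
  m <- gsm_model("q")
  m <- add_entity(m, gsm_entity("GLC", "compound", list(formula = "C6H12O6",
                                                        charge = "0")))
  m <- add_entity(m, gsm_entity("LAC", "compound", list(formula = "C3H6O3",
                                                        charge = "0")))
  m <- add_entity(m, gsm_entity("r_split", "reaction"))
  m <- add_relation(m, "r_split", "consumes", "GLC")
  m <- add_relation(m, "r_split", "produces", "LAC", list(coefficient = "2"))
  q <- quality_report(m)
  expect_false("r_split" %in% names(q$mass_unbalanced))
  expect_false("r_split" %in% names(q$charge_unbalanced))
  expect_false("r_split" %in% names(q$undetermined))

  m <- add_entity(m, gsm_entity("A", "compound", list(formula = "C1H4",
                                                      charge = "0")))
  m <- add_entity(m, gsm_entity("B", "compound", list(formula = "C1H3",
                                                      charge = "-1")))
  m <- add_rxn(m, "r_bad", "A", "B")
  q2 <- quality_report(m)
  expect_equal(q2$mass_unbalanced$r_bad[["H"]], -1)
  expect_equal(unname(q2$charge_unbalanced["r_bad"]), -1)

  # missing formula: undetermined, never silently balanced
  m <- add_entity(m, gsm_entity("X", "compound"))
  m <- add_rxn(m, "r_unk", "X", "B")
  q3 <- quality_report(m)
  expect_true("r_unk" %in% names(q3$undetermined))
  expect_false("r_unk" %in% names(q3$mass_unbalanced))
})

test_that("gene-association ratio is a percentage over non-exchange reactions", {
  m <- gsm_model("g")
  for (i in 1:7) m <- add_rxn(m, sprintf("r%d", i), sprintf("a%d", i),
                              sprintf("b%d", i))
  for (i in 1:5) {
    g <- sprintf("gene%d", i)
    m <- add_entity(m, gsm_entity(g, "gene"))
    m <- add_relation(m, g, "is_linked_to", sprintf("r%d", i))
  }
  q <- quality_report(m)
  expect_equal(q$gene_ratio, 71.4)  # 5/7 to one decimal
  expect_equal(q$n_considered, 7L)

  # an exchange reaction drops out of the denominator
  m <- add_entity(m, gsm_entity("r_ex", "reaction", list(boundary = "true")))
  q2 <- quality_report(m)
  expect_equal(q2$n_considered, 7L)
  expect_equal(quality_report(m, exclude_exchange = FALSE)$n_considered, 8L)
})

test_that("the report suite writes its TSV exports", {
  fx <- make_folate_fixture()
  out <- withr::local_tempdir()
  files <- write_reports(fx$draft, out, fx$pathway_defs)
  expect_true(all(file.exists(files)))
  comp <- read.delim(file.path(out, "completeness.tsv"))
  expect_setequal(comp$pathway, c("PWY-6147", "PWY-6614"))
})
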