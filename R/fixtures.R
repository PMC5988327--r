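# Built-in fixtures: the tetrahydrofolate class/instance example and a
# deterministic random-network generator, so every operation is testable
# without downloading a reference database.

#' The tetrahydrofolate biosynthesis fixture
#'
#' A self-contained encoding of the classic class/instance gap in folate
#' biosynthesis: the 6-hydroxymethyl-dihydropterin diphosphate pathway
#' (PWY-6147, 4 reactions) followed by tetrahydrofolate biosynthesis
#' (PWY-6614, 4 reactions) — eight reactions in total leading from seed GTP
#' to the target THF-GLU-N. The draft holds 7 of the 8 reactions: 3 found by
#' annotation and 4 by orthology (one by both), plus one recovered by an
#' earlier gap-filling step. The missing step is the dihydrofolate
#' reductase: the database writes it against the compound *class*
#' DIHYDROFOLATE-GLU-N, while the upstream synthase produces the *instance*
#' DIHYDROFOLATE (declared `is_a` the class), so the generic reaction can
#' never fire and the target stays unproducible. The database also carries
#' the instantiated variant
#' `DIHYDROFOLATEREDUCT-RXN-THF/NADP//DIHYDROFOLATE/NADPH/PROTON.37.` that
#' consumes the instance — the unique single-reaction completion restoring
#' producibility and bringing both pathways to completion rate 1.
#'
#' Stoichiometries are schematic (one unit per participant, five neutral
#' cofactor seeds), not MetaCyc's: producibility hinges only on the
#' class/instance mismatch.
#'
#' @return list with `draft`, `database`, `seeds`, `targets`,
#'   `pathway_defs` (a `gsm_model` defining the two reference pathways).
#' @export
make_folate_fixture <- function() {
  cofactors <- c("ATP", "GLT", "NADPH", "CHORISMATE", "WATER")
  seeds <- c("GTP", cofactors)
  target <- "THF-GLU-N"
  compounds <- c(seeds, "DIHYDRONEOPTERIN-P3", "DIHYDRONEOPTERIN-P",
                 "6-HYDROXYMETHYL-DIHYDROPTERIN", "DIHYDROPTERIN-CH2OH-PP",
                 "P-AMINO-BENZOATE", "H2PTEROATE", "DIHYDROFOLATE", target)

  rxn <- function(id, reactants, products, pathway) {
    list(id = id, reactants = reactants, products = products, pathway = pathway)
  }
  reactions <- list(
    rxn("GTP-CYCLOHYDRO-I-RXN", c("GTP", "WATER"),
        "DIHYDRONEOPTERIN-P3", "PWY-6147"),
    rxn("H2NEOPTERINP3PYROPHOSPHOHYDRO-RXN", c("DIHYDRONEOPTERIN-P3", "WATER"),
        "DIHYDRONEOPTERIN-P", "PWY-6147"),
    rxn("H2NEOPTERINALDOL-RXN", "DIHYDRONEOPTERIN-P",
        "6-HYDROXYMETHYL-DIHYDROPTERIN", "PWY-6147"),
    rxn("H2PTERIDINEPYROPHOSPHOKIN-RXN",
        c("6-HYDROXYMETHYL-DIHYDROPTERIN", "ATP"),
        "DIHYDROPTERIN-CH2OH-PP", "PWY-6147"),
    rxn("PABASYN-RXN", "CHORISMATE", "P-AMINO-BENZOATE", "PWY-6614"),
    rxn("H2PTEROATESYNTH-RXN", c("DIHYDROPTERIN-CH2OH-PP", "P-AMINO-BENZOATE"),
        "H2PTEROATE", "PWY-6614"),
    rxn("DIHYDROFOLATESYNTH-RXN", c("H2PTEROATE", "GLT", "ATP"),
        "DIHYDROFOLATE", "PWY-6614"),
    rxn("DIHYDROFOLATEREDUCT-RXN", c("DIHYDROFOLATE-GLU-N", "NADPH"),
        target, "PWY-6614"))

  build <- function(model_id, which, with_ontology = FALSE) {
    m <- gsm_model(model_id, ref_db = "metacyc")
    for (cid in compounds) m <- add_entity(m, gsm_entity(cid, "compound"))
    if (with_ontology || "DIHYDROFOLATEREDUCT-RXN" %in% which) {
      m <- add_entity(m, gsm_entity("DIHYDROFOLATE-GLU-N", "class"))
      m <- add_relation(m, "DIHYDROFOLATE", "is_a", "DIHYDROFOLATE-GLU-N")
    }
    for (pwy in c("PWY-6147", "PWY-6614"))
      m <- add_entity(m, gsm_entity(pwy, "pathway"))
    for (r in reactions) {
      if (!r$id %in% which) next
      m <- add_entity(m, gsm_entity(r$id, "reaction",
                                    list(direction = "LEFT-TO-RIGHT")))
      for (c_ in r$reactants)
        m <- add_relation(m, r$id, "consumes", c_, list(coefficient = "1"))
      for (c_ in r$products)
        m <- add_relation(m, r$id, "produces", c_, list(coefficient = "1"))
      m <- add_relation(m, r$id, "is_in_pathway", r$pathway)
    }
    m
  }

  rids <- vapply(reactions, `[[`, character(1), "id")
  draft <- build("folate-draft", setdiff(rids, "DIHYDROFOLATEREDUCT-RXN"))
  annotation <- c("GTP-CYCLOHYDRO-I-RXN", "H2NEOPTERINALDOL-RXN",
                  "DIHYDROFOLATESYNTH-RXN")
  orthology <- c("H2NEOPTERINP3PYROPHOSPHOHYDRO-RXN", "H2NEOPTERINALDOL-RXN",
                 "PABASYN-RXN", "H2PTEROATESYNTH-RXN")
  for (rid in annotation)
    draft <- add_tag(draft, gsm_tag(rid, "annotation", "pathway-tools",
                                    "genome", 0L))
  for (rid in orthology)
    draft <- add_tag(draft, gsm_tag(rid, "orthology", "pantograph",
                                    "template-models", 1L))
  draft <- add_tag(draft, gsm_tag("H2PTERIDINEPYROPHOSPHOKIN-RXN",
                                  "gap-filling", "meneco", "metacyc", 2L,
                                  "biomass gap-filling"))
  genes <- c("GTP-CYCLOHYDRO-I-RXN" = "folE", "H2NEOPTERINALDOL-RXN" = "folB",
             "DIHYDROFOLATESYNTH-RXN" = "folC")
  for (rid in names(genes)) {
    draft <- add_entity(draft, gsm_entity(genes[[rid]], "gene"),
                        gsm_tag(genes[[rid]], "annotation", "pathway-tools",
                                "genome", 0L))
    draft <- add_relation(draft, genes[[rid]], "is_linked_to", rid)
  }

  database <- build("folate-database", rids, with_ontology = TRUE)
  variant <- "DIHYDROFOLATEREDUCT-RXN-THF/NADP//DIHYDROFOLATE/NADPH/PROTON.37."
  database <- add_entity(database, gsm_entity(variant, "reaction", list(
    direction = "LEFT-TO-RIGHT", `instance-of` = "DIHYDROFOLATEREDUCT-RXN")))
  for (c_ in c("DIHYDROFOLATE", "NADPH"))
    database <- add_relation(database, variant, "consumes", c_,
                             list(coefficient = "1"))
  database <- add_relation(database, variant, "produces", target,
                           list(coefficient = "1"))
  database <- add_relation(database, variant, "is_in_pathway", "PWY-6614")

  pathway_defs <- build("folate-pathways", rids)

  list(draft = draft, database = database, seeds = seeds, targets = target,
       pathway_defs = pathway_defs)
}

#' Deterministic random metabolic network generator
#'
#' Builds a connected-by-construction network: compounds `C001...`, the
#' first `n_seeds` of them forming the growth medium; each reaction draws
#' its reactants from the already-reachable pool (seeds plus products of
#' earlier reactions), except that with probability `leak_prob` a reactant
#' is drawn from the unreachable pool instead, creating genuinely blocked
#' branches for gap-filling and unblocking suites to find. With
#' `leak_prob = 0` every generated target is producible. A fraction of
#' reactions is reversible; optionally a fraction of non-seed compounds is
#' promoted to ontology classes with fresh instance compounds. Identical
#' seeds yield identical networks.
#'
#' @param n_compounds,n_reactions,n_seeds network size (positive).
#' @param max_reactants,max_products participants per reaction (default 2/2).
#' @param reversible_fraction fraction of reversible reactions in `[0, 1]`.
#' @param leak_prob per-reactant probability of drawing from the unreachable
#'   pool.
#' @param class_fraction fraction of non-seed compounds promoted to classes,
#'   each given `instances_per_class` instance compounds.
#' @param instances_per_class instances per promoted class.
#' @param tag_categories categories sampled uniformly for reaction tags.
#' @param n_targets number of target compounds drawn (without replacement)
#'   from the products of the later reactions.
#' @param seed RNG seed.
#' @return list with `model`, `seeds`, `targets`.
#' @export
random_network <- function(n_compounds = 30, n_reactions = 25, n_seeds = 3,
                           max_reactants = 2, max_products = 2,
                           reversible_fraction = 0.2, leak_prob = 0.2,
                           class_fraction = 0, instances_per_class = 2,
                           tag_categories = c("annotation", "orthology"),
                           n_targets = 3, seed = 1) {
  stopifnot(n_compounds > 0, n_reactions > 0, n_seeds > 0,
            n_seeds <= n_compounds,
            reversible_fraction >= 0, reversible_fraction <= 1,
            leak_prob >= 0, leak_prob <= 1,
            class_fraction >= 0, class_fraction <= 1)
  if (max_reactants + max_products > n_compounds)
    gsm_abort("reactions need more compounds than the network holds",
              "gsm_invalid_spec")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)

  compounds <- sprintf("C%03d", seq_len(n_compounds))
  seeds <- compounds[seq_len(n_seeds)]
  model <- gsm_model(sprintf("random-%d", seed), ref_db = "synthetic")
  for (cid in compounds) model <- add_entity(model, gsm_entity(cid, "compound"))

  reachable <- seeds
  product_history <- character(0)
  for (i in seq_len(n_reactions)) {
    rid <- sprintf("R%03d", i)
    n_r <- sample.int(max_reactants, 1)
    n_p <- sample.int(max_products, 1)
    unreachable <- setdiff(compounds, reachable)
    reactants <- character(0)
    for (j in seq_len(n_r)) {
      pool <- if (length(unreachable) && stats::runif(1) < leak_prob)
        unreachable else reachable
      reactants <- unique(c(reactants, sample(pool, 1)))
    }
    products <- sample(setdiff(compounds, reactants), n_p)
    direction <- if (stats::runif(1) < reversible_fraction)
      "REVERSIBLE" else "LEFT-TO-RIGHT"
    model <- add_entity(model, gsm_entity(rid, "reaction",
                                          list(direction = direction)),
                        gsm_tag(rid, sample(tag_categories, 1),
                                "generator", "synthetic", i))
    for (c_ in reactants)
      model <- add_relation(model, rid, "consumes", c_, list(coefficient = "1"))
    for (c_ in products)
      model <- add_relation(model, rid, "produces", c_, list(coefficient = "1"))
    if (all(reactants %in% reachable))
      reachable <- unique(c(reachable, products))
    product_history <- c(product_history, products)
  }

  if (class_fraction > 0) {
    promotable <- setdiff(compounds, seeds)
    n_classes <- floor(class_fraction * length(promotable))
    if (n_classes > 0) {
      for (cid in sample(promotable, n_classes)) {
        klass <- paste0(cid, "-CLASS")
        model <- add_entity(model, gsm_entity(klass, "class"))
        model <- add_relation(model, cid, "is_a", klass)
        for (k in seq_len(instances_per_class - 1L)) {
          inst <- sprintf("%s-INST%d", cid, k)
          model <- add_entity(model, gsm_entity(inst, "compound"))
          model <- add_relation(model, inst, "is_a", klass)
        }
      }
    }
  }

  late <- unique(rev(product_history))
  targets <- late[seq_len(min(n_targets, length(late)))]
  list(model = model, seeds = seeds, targets = targets)
}
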