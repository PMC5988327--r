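# Independent oracles and tiny model builders shared across the suite.

# Naive network-expansion oracle: scan every reaction every pass until the
# producible set stops growing. Deliberately different from the layered
# kernel in the package (no frontier bookkeeping, arbitrary scan order).
oracle_scope <- function(model, seeds) {
  prod <- intersect(seeds, names(model$entities))
  sides <- lapply(entity_ids(model, "reaction"), function(rid) {
    s <- gsmtrace:::reaction_sides(model, rid)
    lhs <- vapply(s$reactants, `[[`, character(1), "id")
    rhs <- vapply(s$products, `[[`, character(1), "id")
    dirs <- list(list(lhs, rhs))
    if (reaction_direction(model, rid) == "REVERSIBLE")
      dirs <- c(dirs, list(list(rhs, lhs)))
    dirs
  })
  repeat {
    changed <- FALSE
    for (rdirs in sides) for (d in rdirs) {
      if (all(d[[1]] %in% prod)) {
        new <- setdiff(d[[2]], prod)
        if (length(new)) { prod <- c(prod, new); changed <- TRUE }
      }
    }
    if (!changed) break
  }
  sort(prod)
}

combn_sets <- function(x, k) {
  if (k == 0) return(list(character(0)))
  if (k > length(x)) return(list())
  utils::combn(x, k, simplify = FALSE)
}

# Exhaustive minimal-cardinality completions, checked with the naive oracle.
brute_min_completions <- function(draft, database, seeds, targets, max_k = 3) {
  cands <- sort(setdiff(entity_ids(database, "reaction"),
                        entity_ids(draft, "reaction")))
  for (k in 0:max_k) {
    sols <- Filter(function(set) {
      m <- apply_completion(draft, database, set)
      all(targets %in% oracle_scope(m, seeds))
    }, combn_sets(cands, k))
    if (length(sols)) return(lapply(sols, sort))
  }
  list()
}

# Exhaustive subset-minimal unblocking compound sets (empty when there is
# nothing to unblock, matching the operation's contract).
brute_unblocking <- function(model, seeds, targets, max_k = 3) {
  if (all(targets %in% oracle_scope(model, seeds))) return(list())
  cands <- sort(setdiff(entity_ids(model, "compound"), seeds))
  sols <- list()
  for (k in seq_len(max_k)) {
    for (set in combn_sets(cands, k)) {
      if (any(vapply(sols, function(s) all(s %in% set), logical(1)))) next
      if (all(targets %in% oracle_scope(model, c(seeds, set))))
        sols <- c(sols, list(set))
    }
  }
  sols
}

# Linear chain c1 -r1-> c2 -r2-> c3 ... (irreversible).
chain_model <- function(compounds, reversible = FALSE) {
  m <- gsm_model("chain")
  for (cid in compounds) m <- add_entity(m, gsm_entity(cid, "compound"))
  for (i in seq_len(length(compounds) - 1)) {
    rid <- paste0("r", i)
    dirn <- if (reversible) "REVERSIBLE" else "LEFT-TO-RIGHT"
    m <- add_entity(m, gsm_entity(rid, "reaction", list(direction = dirn)))
    m <- add_relation(m, rid, "consumes", compounds[i])
    m <- add_relation(m, rid, "produces", compounds[i + 1])
  }
  m
}

# One irreversible reaction from its participant lists; entries may carry a
# coefficient as "id:coef" (default 1).
add_rxn <- function(m, rid, reactants, products, direction = "LEFT-TO-RIGHT") {
  m <- add_entity(m, gsm_entity(rid, "reaction", list(direction = direction)))
  side <- function(m, ids, rtype) {
    for (spec in ids) {
      hit <- regexpr(":[0-9.]+$", spec)
      cid <- if (hit > 0) substr(spec, 1, hit - 1) else spec
      coef <- if (hit > 0) substring(spec, hit + 1) else "1"
      if (!has_entity(m, cid)) m <- add_entity(m, gsm_entity(cid, "compound"))
      m <- add_relation(m, rid, rtype, cid, list(coefficient = coef))
    }
    m
  }
  m <- side(m, reactants, "consumes")
  side(m, products, "produces")
}

# Count attribute values across entities (for the RDF triple formula).
n_attr_values <- function(model)
  sum(vapply(model$entities, function(e) length(unlist(e$attributes)),
             integer(1)))

expect_model_equal <- function(a, b) expect_true(model_equal(a, b))
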