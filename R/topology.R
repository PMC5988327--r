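# Topological producibility over the bipartite reaction/compound graph.
#
# Semantics (network expansion): a reaction fires iff all its reactants are
# already producible; its products then become producible; iterate to the
# least fixpoint. Reversible reactions are treated as two directed reactions,
# each of which must satisfy its own reactant side (firing one direction does
# not grant the other, and a compound appearing on both sides of a reaction
# does not bootstrap itself). Stoichiometric coefficients are ignored
# throughout this file: producibility is presence/absence, deliberately
# weaker than flux-based feasibility.

# Directed reaction table: list of list(rid, dir, reactants, products).
directed_reactions <- function(model, rids = NULL) {
  if (is.null(rids)) rids <- entity_ids(model, "reaction")
  cons <- list(); prod <- list()
  for (r in model$relations) {
    if (r$rtype == "consumes") cons[[r$subject]] <- c(cons[[r$subject]], r$object)
    else if (r$rtype == "produces") prod[[r$subject]] <- c(prod[[r$subject]], r$object)
  }
  dirs <- list()
  for (rid in rids) {
    lhs <- unique(cons[[rid]]); rhs <- unique(prod[[rid]])
    dirs[[length(dirs) + 1L]] <- list(rid = rid, dir = "fwd",
                                      reactants = lhs, products = rhs)
    if (reaction_direction(model, rid) == "REVERSIBLE")
      dirs[[length(dirs) + 1L]] <- list(rid = rid, dir = "rev",
                                        reactants = rhs, products = lhs)
  }
  dirs
}

# Least-fixpoint expansion. Breadth-synchronous so that the layer of a
# compound is the first iteration at which any reaction produced it.
scope_kernel <- function(dirs, seeds) {
  producible <- unique(seeds)
  layer <- stats::setNames(rep(0L, length(producible)), producible)
  unfired <- rep(TRUE, length(dirs))
  f_rid <- character(0); f_dir <- character(0); f_layer <- integer(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fire <- which(unfired)[vapply(dirs[unfired], function(d)
      all(d$reactants %in% producible), logical(1))]
    if (length(fire) == 0L) break
    newc <- character(0)
    for (i in fire) {
      unfired[i] <- FALSE
      f_rid <- c(f_rid, dirs[[i]]$rid)
      f_dir <- c(f_dir, dirs[[i]]$dir)
      f_layer <- c(f_layer, iter)
      newc <- c(newc, dirs[[i]]$products)
    }
    newc <- setdiff(unique(newc), producible)
    if (length(newc)) {
      producible <- c(producible, newc)
      layer[newc] <- iter
    }
  }
  list(producible = producible, layer = layer,
       fired = data.frame(rid = f_rid, dir = f_dir, layer = f_layer,
                          stringsAsFactors = FALSE))
}

check_seeds <- function(model, seeds) {
  known <- vapply(seeds, function(s) {
    e <- model$entities[[s]]
    !is.null(e) && e$etype %in% c("compound", "class")
  }, logical(1))
  if (any(!known))
    warning(sprintf("ignoring unknown seed compound(s): %s",
                    paste(sort_c(seeds[!known]), collapse = ", ")),
            call. = FALSE)
  list(valid = unique(seeds[known]), unknown = sort_c(seeds[!known]))
}

#' Compute the producible scope from a seed set
#'
#' Network expansion from the growth medium: seeds are producible at layer 0;
#' a reaction whose reactants are all producible fires and makes its products
#' producible; iteration continues to the least fixpoint, which is
#' independent of firing order and reached in at most one iteration per
#' compound. Unknown seed ids are excluded with a warning and reported in the
#' result, not an error.
#'
#' @param model a `gsm_model`.
#' @param seeds character vector of seed compound ids (see
#'   [read_compound_list()] for the TSV form).
#' @return a `gsm_scope` object: `producible` (sorted ids), `layer` (named
#'   integer, first expansion iteration producing each compound; seeds are
#'   0), `fired` (sorted ids of reactions that activated), `fired_detail`
#'   (per directed firing: rid, dir, layer), `unknown_seeds`.
#' @export
compute_scope <- function(model, seeds) {
  cs <- check_seeds(model, seeds)
  res <- scope_kernel(directed_reactions(model), cs$valid)
  structure(list(
    producible = sort_c(res$producible),
    layer = res$layer,
    fired = sort_c(unique(res$fired$rid)),
    fired_detail = res$fired,
    seeds = sort_c(cs$valid),
    unknown_seeds = cs$unknown
  ), class = "gsm_scope")
}

#' @export
print.gsm_scope <- function(x, ...) {
  cat(sprintf("<gsm_scope> %d producible compounds from %d seeds; %d reactions fired (%d layers)\n",
              length(x$producible), length(x$seeds), length(x$fired),
              max(c(0L, x$layer))))
  invisible(x)
}

#' Detect unproducible targets
#'
#' @param model a `gsm_model`.
#' @param seeds seed compound ids.
#' @param targets target compound ids whose producibility is asserted.
#' @return sorted character vector of the targets not in the scope; its
#'   `reason` attribute distinguishes ids absent from the model (`"absent"`)
#'   from present-but-blocked ones (`"blocked"`).
#' @export
unproducible_targets <- function(model, seeds, targets) {
  if (length(targets) == 0)
    gsm_abort("target set must be non-empty", "gsm_invalid_targets")
  sc <- compute_scope(model, seeds)
  bad <- sort_c(setdiff(targets, sc$producible))
  reason <- vapply(bad, function(t)
    if (has_entity(model, t)) "blocked" else "absent", character(1))
  structure(bad, reason = reason)
}

#' Enumerate minimal unblocking compound sets
#'
#' Finds every subset-minimal set of non-seed compounds whose addition to the
#' seeds restores producibility of all targets — the candidate cofactors or
#' transported nutrients whose absence explains a blocked target. Results are
#' sorted by cardinality, then lexicographically.
#'
#' @param model a `gsm_model`.
#' @param seeds seed compound ids.
#' @param targets target compound ids.
#' @param max_size maximum set cardinality to explore.
#' @param max_combinations guard on the exhaustive enumeration size.
#' @return list of character vectors (each sorted). Attribute `exhausted` is
#'   TRUE when no solution exists within `max_size` although targets are
#'   blocked; attribute `already_producible` is TRUE when there was nothing
#'   to unblock (empty list).
#' @export
unblocking_compounds <- function(model, seeds, targets, max_size = 3,
                                 max_combinations = 2e5) {
  blocked <- unproducible_targets(model, seeds, targets)
  if (length(blocked) == 0)
    return(structure(list(), exhausted = FALSE, already_producible = TRUE))
  cs <- check_seeds(model, seeds)
  candidates <- sort_c(setdiff(entity_ids(model, "compound"), cs$valid))
  dirs <- directed_reactions(model)
  solves <- function(extra) {
    res <- scope_kernel(dirs, c(cs$valid, extra))
    all(targets %in% res$producible)
  }
  solutions <- list()
  contains_solution <- function(set)
    any(vapply(solutions, function(s) all(s %in% set), logical(1)))
  for (k in seq_len(min(max_size, length(candidates)))) {
    if (choose(length(candidates), k) > max_combinations)
      gsm_abort(sprintf(
        "enumeration of %d-subsets over %d candidates exceeds max_combinations",
        k, length(candidates)), "gsm_search_too_large")
    combos <- utils::combn(candidates, k, simplify = FALSE)
    for (set in combos) {
      if (contains_solution(set)) next
      if (solves(set)) solutions[[length(solutions) + 1L]] <- set
    }
  }
  ord <- order_c(lengths(solutions),
                 vapply(solutions, paste, character(1), collapse = "\r"))
  structure(solutions[ord], exhausted = length(solutions) == 0,
            already_producible = FALSE)
}

#' Extract one production path to a target
#'
#' Returns a witness sequence of reaction ids, ordered by scope layer (ties
#' broken lexicographically), such that replaying the reactions in order
#' produces the target with every reactant available when its reaction is
#' replayed. The witness is built backwards from the target, at each compound
#' choosing the lexicographically first reaction that fired at that
#' compound's layer.
#'
#' @param model a `gsm_model`.
#' @param seeds seed compound ids.
#' @param target a single compound id.
#' @return character vector of reaction ids (empty when the target is a
#'   seed). Raises a typed not-producible error otherwise.
#' @export
production_path <- function(model, seeds, target) {
  stopifnot(length(target) == 1)
  sc <- compute_scope(model, seeds)
  if (!target %in% sc$producible) {
    dirs <- directed_reactions(model)
    producers <- unique(unlist(lapply(dirs, function(d)
      if (target %in% d$products) d$reactants)))
    missing <- sort_c(setdiff(producers, sc$producible))
    gsm_abort(sprintf(
      "target '%s' is not producible from the seeds; first missing precursor layer: {%s}",
      target, paste(missing, collapse = ", ")), "gsm_not_producible")
  }
  if (sc$layer[[target]] == 0L) return(character(0))
  dirs <- directed_reactions(model)
  key <- vapply(dirs, function(d) paste(d$rid, d$dir), character(1))
  dirmap <- stats::setNames(dirs, key)
  fd <- sc$fired_detail
  fd_key <- paste(fd$rid, fd$dir)
  chosen <- character(0)       # keys of chosen directed firings
  visit <- function(cid) {
    lay <- sc$layer[[cid]]
    if (lay == 0L) return(invisible(NULL))
    cand <- which(fd$layer == lay & vapply(seq_len(nrow(fd)), function(i)
      cid %in% dirmap[[fd_key[i]]]$products, logical(1)))
    pick <- cand[order_c(fd$rid[cand], fd$dir[cand])][1]
    k <- fd_key[pick]
    if (k %in% chosen) return(invisible(NULL))
    chosen <<- c(chosen, k)
    for (r in dirmap[[k]]$reactants) visit(r)
    invisible(NULL)
  }
  visit(target)
  sel <- fd[fd_key %in% chosen, , drop = FALSE]
  sel <- sel[order_c(sel$layer, sel$rid), , drop = FALSE]
  unique(sel$rid)
}

#' Instantiate class reactions over a compound ontology
#'
#' Reference databases write some reactions against compound *classes*
#' (ontology nodes) rather than concrete compounds; such reactions can never
#' fire topologically when the network only produces an *instance* of the
#' class. This operation adds, for every reaction with at least one
#' class-typed participant that has direct `is_a` instances, variant
#' reactions substituting each class slot by each direct instance (cartesian
#' product across slots). Variant ids are the parent id plus `/`-joined
#' instance ids; variants carry an `instance-of` attribute naming the parent,
#' inherit its relations (with substitution) and are tagged
#' category=gap-filling, tool=class-instantiation. Originals are retained.
#'
#' @param database a `gsm_model` (typically the reference database).
#' @param ontology optional `gsm_model` providing the `is_a` relations;
#'   defaults to `database` itself.
#' @param max_variants combinatorial cap per reaction; a reaction whose
#'   cartesian product exceeds it is skipped and reported in the `skipped`
#'   attribute of the result.
#' @return the augmented model, with attribute `skipped` (character vector)
#'   and `variants` (ids of the added variants).
#' @export
instantiate_class_reactions <- function(database, ontology = NULL,
                                        max_variants = 64) {
  if (is.null(ontology)) ontology <- database
  inst_of <- list()   # class id -> sorted instance ids
  edges <- list()
  for (r in ontology$relations) {
    if (r$rtype != "is_a") next
    inst_of[[r$object]] <- c(inst_of[[r$object]], r$subject)
    edges[[r$subject]] <- c(edges[[r$subject]], r$object)
  }
  # acyclicity of the is_a graph
  state <- new.env(parent = emptyenv())
  visit <- function(n) {
    s <- state[[n]]
    if (identical(s, 1L)) gsm_abort(sprintf("is_a ontology has a cycle through '%s'", n),
                                    "gsm_cyclic_ontology")
    if (identical(s, 2L)) return(invisible(NULL))
    state[[n]] <- 1L
    for (p in edges[[n]]) visit(p)
    state[[n]] <- 2L
    invisible(NULL)
  }
  for (n in names(edges)) visit(n)
  inst_of <- lapply(inst_of, sort_c)

  out <- database
  skipped <- character(0)
  variants <- character(0)
  for (rid in entity_ids(database, "reaction")) {
    sides <- reaction_sides(database, rid)
    parts <- unique(vapply(c(sides$reactants, sides$products), `[[`,
                           character(1), "id"))
    slots <- sort_c(parts[parts %in% names(inst_of)])
    if (length(slots) == 0) next
    n_var <- prod(lengths(inst_of[slots]))
    if (n_var > max_variants) {
      skipped <- c(skipped, rid)
      next
    }
    grid <- expand.grid(inst_of[slots], stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(nrow(grid))) {
      assign_ <- stats::setNames(as.character(grid[i, ]), slots)
      vid <- paste(c(rid, unname(assign_)), collapse = "/")
      subst <- function(id) if (id %in% slots) unname(assign_[[id]]) else id
      e <- database$entities[[rid]]
      vattrs <- union_attributes(e$attributes, list(`instance-of` = rid))
      out <- add_entity(out, gsm_entity(vid, "reaction", vattrs),
                        gsm_tag(vid, "gap-filling", "class-instantiation", rid))
      for (r in database$relations) {
        if (r$subject != rid) next
        if (r$rtype %in% c("consumes", "produces"))
          out <- add_relation(out, vid, r$rtype, subst(r$object), r$attributes)
        else if (r$rtype == "is_in_pathway")
          out <- add_relation(out, vid, r$rtype, r$object, r$attributes)
      }
      variants <- c(variants, vid)
    }
  }
  structure(out, skipped = sort_c(skipped), variants = sort_c(variants))
}

#' Topological gap-filling against a reaction database
#'
#' Searches for cardinality-minimal sets of database reactions whose addition
#' to the draft makes every target producible from the seeds. The search is
#' iterative deepening over cardinality: candidates (database reactions
#' absent from the draft) are first pruned to those on some backward path
#' from a target; each cardinality level is enumerated exhaustively while the
#' number of combinations stays below `exhaustive_limit`, above which a
#' greedy set-cover fallback returns one solution explicitly marked
#' heuristic (minimality then not guaranteed beyond single-removal pruning).
#'
#' @param draft,database `gsm_model` objects. Database reactions whose id
#'   already occurs in the draft are ignored as candidates.
#' @param seeds,targets compound id vectors.
#' @param max_size largest completion cardinality to consider.
#' @param enumerate when TRUE, return all minimal-cardinality solutions plus
#'   their union and intersection; otherwise the lexicographically first.
#' @param exhaustive_limit combination-count threshold for exact search.
#' @return a `gsm_completion` object: `solutions` (list of sorted reaction-id
#'   vectors; a single empty vector when targets are already producible),
#'   `size`, `union`, `intersection`, `heuristic`, `enumerate`.
#'   Raises a typed infeasible error (listing the still-blocked targets) when
#'   even the full database cannot restore producibility within the network.
#' @export
gapfill <- function(draft, database, seeds, targets, max_size = 10,
                    enumerate = FALSE, exhaustive_limit = 2e4) {
  if (length(targets) == 0)
    gsm_abort("target set must be non-empty", "gsm_invalid_targets")
  cs <- check_seeds(draft, seeds)
  seeds_ok <- unique(c(cs$valid,
                       intersect(seeds, entity_ids(database, c("compound", "class")))))
  draft_rids <- entity_ids(draft, "reaction")
  cand_rids <- sort_c(setdiff(entity_ids(database, "reaction"), draft_rids))
  dirs_draft <- directed_reactions(draft)
  dirs_db <- directed_reactions(database, cand_rids)

  completion <- function(solutions, heuristic = FALSE) {
    solutions <- lapply(solutions, sort_c)
    ord <- order_c(vapply(solutions, paste, character(1), collapse = "\r"))
    solutions <- solutions[ord]
    structure(list(
      solutions = solutions,
      size = if (length(solutions)) length(solutions[[1]]) else NA_integer_,
      union = sort_c(unique(unlist(solutions))),
      intersection = if (length(solutions)) sort_c(Reduce(intersect, solutions))
                     else character(0),
      heuristic = heuristic, enumerate = enumerate,
      targets = sort_c(targets), n_candidates = length(cand_rids)
    ), class = "gsm_completion")
  }

  base_scope <- scope_kernel(dirs_draft, seeds_ok)
  if (all(targets %in% base_scope$producible))
    return(completion(list(character(0))))

  # backward pruning: keep candidates on some backward path from a target
  all_dirs <- c(dirs_draft, dirs_db)
  needed <- unique(targets)
  repeat {
    add <- character(0)
    relevant <- logical(length(all_dirs))
    for (i in seq_along(all_dirs)) {
      if (any(all_dirs[[i]]$products %in% needed)) {
        relevant[i] <- TRUE
        add <- c(add, all_dirs[[i]]$reactants)
      }
    }
    new_needed <- unique(c(needed, add))
    if (length(new_needed) == length(needed)) break
    needed <- new_needed
  }
  relevant_rids <- unique(vapply(all_dirs[relevant], `[[`, character(1), "rid"))
  cand_rids <- intersect(cand_rids, relevant_rids)
  dirs_db <- dirs_db[vapply(dirs_db, function(d) d$rid %in% cand_rids, logical(1))]
  db_by_rid <- split(dirs_db, vapply(dirs_db, `[[`, character(1), "rid"))

  scope_with <- function(x) {
    extra <- unlist(db_by_rid[x], recursive = FALSE, use.names = FALSE)
    scope_kernel(c(dirs_draft, extra), seeds_ok)
  }
  solves <- function(x) all(targets %in% scope_with(x)$producible)

  if (!solves(cand_rids)) {
    still <- sort_c(setdiff(targets, scope_with(cand_rids)$producible))
    gsm_abort(sprintf(
      "targets unreachable even with the full database: %s",
      paste(still, collapse = ", ")), "gsm_infeasible")
  }

  for (k in seq_len(min(max_size, length(cand_rids)))) {
    if (choose(length(cand_rids), k) > exhaustive_limit) {
      # greedy set-cover fallback, then single-removal pruning
      x <- character(0)
      uncovered <- function(x) setdiff(targets, scope_with(x)$producible)
      while (length(u <- uncovered(x)) > 0) {
        gains <- vapply(setdiff(cand_rids, x), function(r) {
          res <- scope_with(c(x, r))
          sum(targets %in% res$producible) * 1e6 + length(res$producible)
        }, numeric(1))
        best <- names(gains)[gains == max(gains)]
        pick <- sort_c(best)[1]
        if (pick %in% x) break
        x <- c(x, pick)
      }
      for (r in rev(sort_c(x)))
        if (solves(setdiff(x, r))) x <- setdiff(x, r)
      warning("gap-filling used the greedy heuristic; minimality not guaranteed",
              call. = FALSE)
      return(completion(list(x), heuristic = TRUE))
    }
    combos <- utils::combn(cand_rids, k, simplify = FALSE)
    sols <- Filter(solves, combos)
    if (length(sols)) {
      if (!enumerate) sols <- sols[1]
      return(completion(sols))
    }
  }
  gsm_abort(sprintf(
    "no completion of size <= %d found (%d candidates); raise max_size",
    max_size, length(cand_rids)), "gsm_exhausted_bound")
}

#' @export
print.gsm_completion <- function(x, ...) {
  if (length(x$solutions) == 1 && length(x$solutions[[1]]) == 0) {
    cat("<gsm_completion> targets already producible; empty completion\n")
    return(invisible(x))
  }
  cat(sprintf("<gsm_completion> %d minimal solution(s) of size %d%s\n",
              length(x$solutions), x$size,
              if (x$heuristic) " [heuristic, minimality not guaranteed]" else ""))
  if (x$enumerate)
    cat(sprintf("  union: %d reactions; intersection: %d reactions\n",
                length(x$union), length(x$intersection)))
  for (s in x$solutions[seq_len(min(5, length(x$solutions)))])
    cat("  -", paste(s, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a completion to a draft model
#'
#' Copies the chosen database reactions (participants, relations, inherited
#' attributes) into the draft and tags them category=gap-filling.
#'
#' @param draft,database `gsm_model` objects.
#' @param reaction_ids completion reaction ids (from [gapfill()]).
#' @param tool,source,step provenance stamped on the added entities.
#' @return the augmented draft.
#' @export
apply_completion <- function(draft, database, reaction_ids,
                             tool = "topological-gapfill", source = "",
                             step = 0L) {
  for (rid in sort_c(reaction_ids)) {
    e <- database$entities[[rid]]
    if (is.null(e))
      gsm_abort(sprintf("completion reaction '%s' not in database", rid),
                "gsm_integrity_error")
    draft <- add_entity(draft, e, gsm_tag(rid, "gap-filling", tool, source, step))
    for (r in database$relations) {
      if (r$subject != rid) next
      obj <- database$entities[[r$object]]
      if (!has_entity(draft, obj$id)) {
        draft <- add_entity(draft, obj,
                            gsm_tag(obj$id, "gap-filling", tool, source, step))
      }
      draft <- add_relation(draft, rid, r$rtype, r$object, r$attributes)
    }
  }
  draft
}

#' Read a seed/target compound list
#'
#' One compound id per line; blank lines and `#` comments ignored.
#' @param path TSV/text file.
#' @return character vector of ids.
#' @export
read_compound_list <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
}
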