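# Matrix / mapping / RDF interop around the core store.

#' Export the stoichiometric matrix as TSV
#'
#' Rows are compounds, columns reactions, both in lexicographic order so the
#' export is deterministic. Entries are signed stoichiometric coefficients
#' (reactants negative, products positive; a compound on both sides nets).
#'
#' @param model a `gsm_model` with at least one reaction.
#' @param path output TSV.
#' @return the matrix, invisibly.
#' @export
export_matrix <- function(model, path) {
  reactions <- entity_ids(model, "reaction")
  if (length(reactions) == 0)
    gsm_abort("model has no reactions to export", "gsm_empty_model")
  compounds <- entity_ids(model, c("compound", "class"))
  mat <- matrix(0, nrow = length(compounds), ncol = length(reactions),
                dimnames = list(compounds, reactions))
  for (r in model$relations) {
    if (!r$rtype %in% c("consumes", "produces")) next
    coef <- as.numeric(r$attributes[["coefficient"]][1])
    sign <- if (r$rtype == "consumes") -1 else 1
    mat[r$object, r$subject] <- mat[r$object, r$subject] + sign * coef
  }
  header <- paste(c("compound", reactions), collapse = "\t")
  body <- vapply(seq_along(compounds), function(i)
    paste(c(compounds[i], format(mat[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(mat)
}

#' Read an identifier-mapping dictionary
#'
#' A MetaNetX-style TSV with header `foreign_id`, `reference_id`, `scope`
#' (scope is `reaction` or `compound`). Within a scope no foreign id may map
#' to two different reference ids, reference ids must be non-empty, and
#' transitive chains (a reference id that is itself a foreign id of the same
#' scope) are an input error — this keeps [map_identifiers()] single-pass and
#' idempotent.
#'
#' @param path TSV file.
#' @param name,version provenance of the dictionary.
#' @return a `gsm_mapping` object.
#' @export
read_mapping_table <- function(path, name = basename(path), version = "") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  need <- c("foreign_id", "reference_id", "scope")
  if (!all(need %in% names(df)))
    gsm_abort(sprintf("mapping table must have columns %s",
                      paste(need, collapse = ", ")), "gsm_parse_error")
  gsm_mapping(df[need], name = name, version = version)
}

#' @param table data frame with columns foreign_id, reference_id, scope.
#' @rdname read_mapping_table
#' @export
gsm_mapping <- function(table, name = "dictionary", version = "") {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (any(!nzchar(table$reference_id)))
    gsm_abort("mapping reference ids must be non-empty", "gsm_invalid_mapping")
  if (any(!table$scope %in% c("reaction", "compound")))
    gsm_abort("mapping scope must be 'reaction' or 'compound'", "gsm_invalid_mapping")
  for (sc in unique(table$scope)) {
    sub <- table[table$scope == sc, ]
    dup <- unique(sub$foreign_id[duplicated(sub$foreign_id)])
    for (d in dup)
      if (length(unique(sub$reference_id[sub$foreign_id == d])) > 1)
        gsm_abort(sprintf("foreign id '%s' maps to two reference ids in scope %s",
                          d, sc), "gsm_invalid_mapping")
    chained <- intersect(sub$reference_id, sub$foreign_id)
    chained <- setdiff(chained, sub$foreign_id[sub$foreign_id == sub$reference_id])
    if (length(chained))
      gsm_abort(sprintf("transitive mapping chains via: %s",
                        paste(sort_c(chained), collapse = ", ")),
                "gsm_invalid_mapping")
  }
  structure(list(table = unique(table), name = name, version = version),
            class = "gsm_mapping")
}

#' Rewrite model identifiers against a reference dictionary
#'
#' Every entity id with a dictionary entry (compounds/classes under the
#' `compound` scope, reactions under `reaction`) is rewritten, together with
#' all relation endpoints and tag references; rewritten entities gain an
#' `xrefs` attribute value recording the foreign id. When two entities of
#' compatible type collapse onto one reference id they are merged (attributes
#' and tag sets unioned); an incompatible collapse (different entity types)
#' raises a collision error. Applying the same table twice is a no-op the
#' second time.
#'
#' @param model a `gsm_model`.
#' @param table a `gsm_mapping`.
#' @return a list with elements `model` (rewritten) and `report`
#'   (a `gsm_mapping_report`: mapped counts, unmapped ids and collisions per
#'   scope, satisfying mapped + unmapped = ids encountered).
#' @export
map_identifiers <- function(model, table) {
  stopifnot(inherits(table, "gsm_mapping"))
  maps <- list(
    compound = with(subset(table$table, table$table$scope == "compound"),
                    stats::setNames(reference_id, foreign_id)),
    reaction = with(subset(table$table, table$table$scope == "reaction"),
                    stats::setNames(reference_id, foreign_id)))
  scope_of <- function(etype) switch(etype,
    compound = "compound", class = "compound", reaction = "reaction", NA_character_)
  rename <- stats::setNames(character(0), character(0))
  mapped <- c(compound = 0L, reaction = 0L)
  unmapped <- list(compound = character(0), reaction = character(0))
  merged_into <- character(0)
  for (id in entity_ids(model)) {
    sc <- scope_of(model$entities[[id]]$etype)
    if (is.na(sc)) next
    new <- unname(maps[[sc]][id])
    if (!is.na(new) && new != id) {
      rename[id] <- new
      mapped[sc] <- mapped[sc] + 1L
    } else {
      unmapped[[sc]] <- c(unmapped[[sc]], id)
    }
  }
  # collision detection: two old ids landing on one new id, or landing on an
  # untouched existing id
  new_id_of <- function(id) if (id %in% names(rename)) unname(rename[id]) else id
  final_ids <- vapply(names(model$entities), new_id_of, character(1))
  for (nid in unique(final_ids[duplicated(final_ids)])) {
    olds <- names(model$entities)[final_ids == nid]
    types <- vapply(olds, function(o) model$entities[[o]]$etype, character(1))
    if (length(unique(types)) > 1)
      gsm_abort(sprintf(
        "mapping collides entities of incompatible types onto '%s': %s",
        nid, paste(sort_c(olds), collapse = ", ")), "gsm_mapping_collision")
    merged_into <- c(merged_into, nid)
  }
  out <- gsm_model(model$meta$model_id, model$meta$ref_db, model$meta$ref_version)
  for (id in names(model$entities)) {
    e <- model$entities[[id]]
    nid <- new_id_of(id)
    attrs <- e$attributes
    if (nid != id) attrs <- union_attributes(attrs, list(xrefs = id))
    out <- add_entity(out, gsm_entity(nid, e$etype, attrs))
  }
  for (r in model$relations)
    out <- add_relation(out, new_id_of(r$subject), r$rtype, new_id_of(r$object),
                        r$attributes)
  if (nrow(model$tags))
    for (i in seq_len(nrow(model$tags))) {
      t <- model$tags[i, ]
      t$entity <- new_id_of(t$entity)
      out <- add_tag(out, t)
    }
  report <- structure(list(
    mapped = mapped,
    unmapped = lapply(unmapped, sort_c),
    collisions = sort_c(unique(merged_into)),
    dictionary = table$name), class = "gsm_mapping_report")
  list(model = out, report = report)
}

#' @export
print.gsm_mapping_report <- function(x, ...) {
  cat(sprintf("Identifier mapping against '%s'\n", x$dictionary))
  for (sc in names(x$mapped))
    cat(sprintf("  %-9s mapped %d, unmapped %d\n", sc, x$mapped[[sc]],
                length(x$unmapped[[sc]])))
  if (length(x$collisions))
    cat("  merged onto:", paste(x$collisions, collapse = ", "), "\n")
  invisible(x)
}

# ---- RDF ------------------------------------------------------------------

ttl_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

entity_iri <- function(base, id)
  paste0("<", base, "entity/", utils::URLencode(id, reserved = TRUE), ">")

#' Export a model as RDF Turtle
#'
#' Emits one triple per relation (entity IRI, relation-type predicate, entity
#' IRI), one triple per entity attribute value (literal object) and one
#' provenance node per source tag carrying exactly five predicates
#' (taggedEntity, category, tool, source, step; the free-text comment is not
#' exported). The total triple count is therefore
#' `|relations| + sum(attribute values) + 5 * |tags|`. One triple per line,
#' so downstream tools (and tests) can recount them. IRIs are minted under
#' `base`.
#'
#' @param model a valid `gsm_model`.
#' @param path output Turtle file.
#' @param base IRI namespace for minted resources.
#' @return the number of triples written, invisibly.
#' @export
export_rdf <- function(model, path, base = "http://example.org/gsm/") {
  validate_model(model)
  lines <- c(sprintf("@prefix rel: <%srelation/> .", base),
             sprintf("@prefix attr: <%sattribute/> .", base),
             sprintf("@prefix prov: <%sprovenance/> .", base),
             "")
  n <- 0L
  for (id in entity_ids(model)) {
    e <- model$entities[[id]]
    for (k in sort_c(names(e$attributes)))
      for (v in e$attributes[[k]]) {
        lines <- c(lines, sprintf("%s attr:%s %s .", entity_iri(base, id),
                                  gsub("[^A-Za-z0-9_-]", "_", k), ttl_literal(v)))
        n <- n + 1L
      }
  }
  if (length(model$relations)) {
    keys <- vapply(model$relations, function(r)
      paste(r$subject, r$rtype, r$object, sep = "\r"), character(1))
    for (i in order_c(keys)) {
      r <- model$relations[[i]]
      lines <- c(lines, sprintf("%s rel:%s %s .", entity_iri(base, r$subject),
                                r$rtype, entity_iri(base, r$object)))
      n <- n + 1L
    }
  }
  if (nrow(model$tags)) {
    t <- model$tags[order_c(model$tags$entity, model$tags$category,
                            model$tags$tool, model$tags$source, model$tags$step), ,
                    drop = FALSE]
    for (i in seq_len(nrow(t))) {
      node <- sprintf("<%stag/%d>", base, i)
      lines <- c(lines,
                 sprintf("%s prov:taggedEntity %s .", node, entity_iri(base, t$entity[i])),
                 sprintf("%s prov:category %s .", node, ttl_literal(t$category[i])),
                 sprintf("%s prov:tool %s .", node, ttl_literal(t$tool[i])),
                 sprintf("%s prov:source %s .", node, ttl_literal(t$source[i])),
                 sprintf("%s prov:step %d .", node, t$step[i]))
      n <- n + 5L
    }
  }
  writeLines(lines, path)
  invisible(n)
}
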