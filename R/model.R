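#' @keywords internal
"_PACKAGE"

# Closed vocabularies of the store. Reconstruction categories mirror the
# stages of an a-la-carte GSM pipeline; entity and relation types span the
# bipartite reaction/compound graph plus genes, pathways, proteins and
# ontology classes.
GSM_ETYPES <- c("reaction", "compound", "gene", "pathway", "protein", "class")
GSM_RTYPES <- c("consumes", "produces", "is_in_pathway", "is_linked_to",
                "catalyzes", "has_xref", "is_a")
GSM_CATEGORIES <- c("annotation", "orthology", "gap-filling", "manual")

gsm_abort <- function(msg, class) {
  stop(structure(class = c(class, "gsm_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Create an empty provenance-tracked metabolic model
#'
#' The container behind every operation in the package: an id-indexed set of
#' typed entities (reactions, compounds, genes, pathways, proteins, ontology
#' classes), typed relations between them (consumption/production with
#' stoichiometry, pathway membership, gene links, ontology `is_a` edges), and
#' per-entity source tags recording which reconstruction category, tool and
#' source introduced each entity at which pipeline step.
#'
#' @param model_id short identifier for the model.
#' @param ref_db name of the main reference database the identifiers come
#'   from (e.g. `"metacyc"`, `"bigg"`). Merging two models declared against
#'   different reference databases is refused until identifiers are mapped.
#' @param ref_version free-text version of the reference database.
#' @return an object of class `gsm_model`.
#' @seealso [add_entity()], [add_relation()], [merge_models()], [read_flat()]
#' @export
#' @examples
#' m <- gsm_model("demo")
#' m <- add_entity(m, gsm_entity("GTP", "compound"))
gsm_model <- function(model_id = "model", ref_db = "", ref_version = "") {
  structure(list(
    entities = structure(list(), names = character(0)),
    relations = list(),
    rel_keys = character(0),  # parallel (subject\r rtype\r object) keys
    tags = empty_tags(),
    log = list(),
    meta = list(model_id = model_id, ref_db = ref_db, ref_version = ref_version)
  ), class = "gsm_model")
}

empty_tags <- function() {
  data.frame(entity = character(0), category = character(0),
             tool = character(0), source = character(0),
             step = integer(0), comment = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a typed entity
#'
#' Attribute keys are case-insensitive: they are normalized to lower case on
#' construction, and each key holds an ordered list of text values (a
#' multimap), e.g. several `xrefs` or `ec-number` values. Common keys:
#' `common-name`, `ec-number`, `formula`, `charge`, `direction`, `xrefs`,
#' `boundary`.
#'
#' @param id unique identifier; case-preserved, surrounding whitespace
#'   stripped. May contain characters illegal in SBML (dots, slashes): those
#'   are only escaped at SBML import/export, never in the store.
#' @param etype one of `r paste(GSM_ETYPES, collapse = ", ")`.
#' @param attributes named list; each element is coerced to a character
#'   vector of values.
#' @return a `gsm_entity` list.
#' @export
gsm_entity <- function(id, etype, attributes = list()) {
  id <- trimws(id)
  if (!nzchar(id)) gsm_abort("entity id must be non-empty", "gsm_invalid_entity")
  if (!etype %in% GSM_ETYPES)
    gsm_abort(sprintf("unknown entity type '%s'", etype), "gsm_invalid_entity")
  structure(list(id = id, etype = etype,
                 attributes = normalize_attributes(attributes)),
            class = "gsm_entity")
}

normalize_attributes <- function(attributes) {
  if (length(attributes) == 0) return(structure(list(), names = character(0)))
  keys <- tolower(trimws(names(attributes)))
  if (any(!nzchar(keys))) gsm_abort("attribute keys must be named", "gsm_invalid_entity")
  out <- list()
  for (i in seq_along(attributes)) {
    v <- as.character(attributes[[i]])
    out[[keys[i]]] <- c(out[[keys[i]]], v)
  }
  out
}

#' Construct a source tag (process metadata)
#'
#' A source tag records why an entity is in the model: the reconstruction
#' `category` (annotation, orthology, gap-filling or manual), the `tool` that
#' produced it, the `source` it came from (template species, database,
#' literature reference), a free-text comment, and the pipeline `step` index.
#' An entity accumulates one tag per origin; tags are never overwritten.
#'
#' @param entity id of the tagged entity.
#' @param category one of `r paste(GSM_CATEGORIES, collapse = ", ")`.
#' @param tool,source,comment free text (may be empty).
#' @param step non-negative integer pipeline step index.
#' @return a one-row data frame.
#' @export
gsm_tag <- function(entity, category, tool = "", source = "", step = 0L,
                    comment = "") {
  if (!category %in% GSM_CATEGORIES)
    gsm_abort(sprintf("unknown tag category '%s' (expected one of %s)",
                      category, paste(GSM_CATEGORIES, collapse = ", ")),
              "gsm_invalid_tag")
  step <- as.integer(step)
  if (is.na(step) || step < 0L)
    gsm_abort("tag step must be a non-negative integer", "gsm_invalid_tag")
  data.frame(entity = entity, category = category, tool = tool,
             source = source, step = step, comment = comment,
             stringsAsFactors = FALSE)
}

#' Add an entity (with optional provenance tag) to a model
#'
#' Re-adding an existing id with the same entity type is legal and unions the
#' attribute value lists (new values appended, duplicates dropped per key),
#' so provenance accumulates instead of overwriting. Re-adding with a
#' different type raises a typed conflict error naming both types.
#'
#' @param model a `gsm_model`.
#' @param entity a [gsm_entity()].
#' @param tag optional [gsm_tag()] for this entity; its `entity` field is
#'   filled in from the entity id.
#' @return the updated model.
#' @export
add_entity <- function(model, entity, tag = NULL) {
  stopifnot(inherits(model, "gsm_model"), inherits(entity, "gsm_entity"))
  existing <- model$entities[[entity$id]]
  if (is.null(existing)) {
    model$entities[[entity$id]] <- entity
  } else {
    if (existing$etype != entity$etype)
      gsm_abort(sprintf(
        "entity '%s' already present with type '%s'; cannot re-add as '%s'",
        entity$id, existing$etype, entity$etype), "gsm_type_conflict")
    existing$attributes <- union_attributes(existing$attributes, entity$attributes)
    model$entities[[entity$id]] <- existing
  }
  if (!is.null(tag)) {
    tag$entity <- entity$id
    model <- add_tag(model, tag)
  }
  model
}

# Union of two attribute multimaps: value lists are concatenated in order,
# duplicates within a key dropped (first occurrence wins). Never overwrites.
union_attributes <- function(a, b) {
  for (k in names(b)) a[[k]] <- unique(c(a[[k]], b[[k]]))
  a
}

#' Add a typed relation between two existing entities
#'
#' Relations are deduplicated by the `(subject, rtype, object)` triple; adding
#' a duplicate unions its attributes. `consumes`/`produces` relations carry a
#' positive stoichiometric `coefficient` attribute (default 1) and optionally
#' a `compartment`; `is_a` must point at a `class` entity.
#'
#' @param model a `gsm_model`.
#' @param subject,object entity ids already present in the model.
#' @param rtype one of `r paste(GSM_RTYPES, collapse = ", ")`.
#' @param attributes named list of relation attributes.
#' @return the updated model.
#' @export
add_relation <- function(model, subject, rtype, object, attributes = list()) {
  stopifnot(inherits(model, "gsm_model"))
  if (!rtype %in% GSM_RTYPES)
    gsm_abort(sprintf("unknown relation type '%s'", rtype), "gsm_invalid_relation")
  for (e in c(subject, object))
    if (is.null(model$entities[[e]]))
      gsm_abort(sprintf("relation endpoint '%s' does not resolve to an entity", e),
                "gsm_integrity_error")
  attributes <- normalize_attributes(attributes)
  if (rtype %in% c("consumes", "produces")) {
    if (is.null(attributes[["coefficient"]])) attributes[["coefficient"]] <- "1"
    coef <- suppressWarnings(as.numeric(attributes[["coefficient"]][1]))
    if (is.na(coef) || coef <= 0)
      gsm_abort(sprintf("stoichiometric coefficient of %s %s %s must be > 0",
                        subject, rtype, object), "gsm_invalid_relation")
  }
  if (rtype == "is_a" && model$entities[[object]]$etype != "class")
    gsm_abort(sprintf("is_a object '%s' is not a class entity", object),
              "gsm_invalid_relation")
  idx <- relation_index(model, subject, rtype, object)
  if (is.na(idx)) {
    model$relations[[length(model$relations) + 1L]] <-
      list(subject = subject, rtype = rtype, object = object,
           attributes = attributes)
    model$rel_keys <- c(model$rel_keys,
                        paste(subject, rtype, object, sep = "\r"))
  } else {
    model$relations[[idx]]$attributes <-
      union_attributes(model$relations[[idx]]$attributes, attributes)
  }
  model
}

relation_index <- function(model, subject, rtype, object) {
  match(paste(subject, rtype, object, sep = "\r"), model$rel_keys)
}

#' Attach a source tag to an existing entity
#'
#' Tags are unique by `(entity, category, tool, source, step)`; re-adding an
#' existing tag is a no-op (the first comment is kept).
#'
#' @param model a `gsm_model`.
#' @param tag a [gsm_tag()].
#' @return the updated model.
#' @export
add_tag <- function(model, tag) {
  stopifnot(inherits(model, "gsm_model"), is.data.frame(tag))
  if (is.null(model$entities[[tag$entity]]))
    gsm_abort(sprintf("tag references unknown entity '%s'", tag$entity),
              "gsm_integrity_error")
  key <- function(t) paste(t$entity, t$category, t$tool, t$source, t$step, sep = "\r")
  if (nrow(model$tags) == 0L ||
      !key(tag) %in% apply_tag_keys(model$tags)) {
    model$tags <- rbind(model$tags, tag)
    rownames(model$tags) <- NULL
  }
  model
}

apply_tag_keys <- function(tags) {
  paste(tags$entity, tags$category, tags$tool, tags$source, tags$step, sep = "\r")
}

#' @export
#' @rdname entity_ids
has_entity <- function(model, id) !is.null(model$entities[[id]])

#' List entity ids, optionally restricted to one type
#'
#' @param model a `gsm_model`.
#' @param etype optional entity type filter.
#' @param id an entity id.
#' @return `entity_ids`: a sorted character vector. `has_entity`: a logical.
#'   `get_entity`: the `gsm_entity`, or NULL.
#' @export
entity_ids <- function(model, etype = NULL) {
  ids <- names(model$entities)
  if (!is.null(etype)) {
    keep <- vapply(model$entities, function(e) e$etype %in% etype, logical(1))
    ids <- ids[keep]
  }
  sort_c(ids)
}

#' @export
#' @rdname entity_ids
get_entity <- function(model, id) model$entities[[id]]

# Locale-independent lexicographic sort (C collation) so every enumeration
# order in the package is reproducible across machines.
sort_c <- function(x) {
  if (length(x) == 0) return(character(0))
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

# First value of an entity attribute, or default.
entity_attr1 <- function(model, id, key, default = NA_character_) {
  v <- model$entities[[id]]$attributes[[key]]
  if (is.null(v) || length(v) == 0) default else v[1]
}

#' Reaction direction
#'
#' Read from the `direction` attribute; absent means `REVERSIBLE` (the SBML
#' default).
#' @param model a `gsm_model`.
#' @param rid reaction id.
#' @return `"LEFT-TO-RIGHT"` or `"REVERSIBLE"`.
#' @export
reaction_direction <- function(model, rid) {
  d <- entity_attr1(model, rid, "direction", "REVERSIBLE")
  if (!d %in% c("LEFT-TO-RIGHT", "REVERSIBLE")) "REVERSIBLE" else d
}

# Participants of one reaction as lists of (id, coefficient).
reaction_sides <- function(model, rid) {
  reactants <- list(); products <- list()
  for (r in model$relations) {
    if (r$subject != rid) next
    if (r$rtype == "consumes")
      reactants[[length(reactants) + 1L]] <-
        list(id = r$object, coef = as.numeric(r$attributes[["coefficient"]][1]))
    else if (r$rtype == "produces")
      products[[length(products) + 1L]] <-
        list(id = r$object, coef = as.numeric(r$attributes[["coefficient"]][1]))
  }
  list(reactants = reactants, products = products)
}

#' Validate model invariants
#'
#' Checks referential integrity (relation endpoints and tag entities exist),
#' positive stoichiometric coefficients, and that every reaction has at least
#' one reactant and one product unless flagged `boundary`/`exchange`.
#'
#' @param model a `gsm_model`.
#' @return invisibly TRUE; aborts with a typed integrity error otherwise.
#' @export
validate_model <- function(model) {
  ids <- names(model$entities)
  for (r in model$relations) {
    for (e in c(r$subject, r$object))
      if (!e %in% ids)
        gsm_abort(sprintf("dangling relation endpoint '%s'", e),
                  "gsm_integrity_error")
  }
  if (nrow(model$tags) > 0) {
    bad <- setdiff(model$tags$entity, ids)
    if (length(bad))
      gsm_abort(sprintf("tags reference unknown entities: %s",
                        paste(bad, collapse = ", ")), "gsm_integrity_error")
  }
  for (rid in entity_ids(model, "reaction")) {
    if (identical(entity_attr1(model, rid, "boundary"), "true") ||
        identical(entity_attr1(model, rid, "exchange"), "true")) next
    sides <- reaction_sides(model, rid)
    if (length(sides$reactants) == 0L || length(sides$products) == 0L)
      gsm_abort(sprintf(
        "reaction '%s' lacks reactants or products and is not flagged exchange",
        rid), "gsm_integrity_error")
  }
  invisible(TRUE)
}

#' Structural model equality
#'
#' Two models are equal when they hold the same entities (id, type and
#' attribute multimaps, value order preserved), the same relation set and the
#' same tag set; storage order is irrelevant.
#'
#' @param a,b `gsm_model` objects.
#' @return logical.
#' @export
model_equal <- function(a, b) {
  if (!setequal(names(a$entities), names(b$entities))) return(FALSE)
  for (id in names(a$entities)) {
    ea <- a$entities[[id]]; eb <- b$entities[[id]]
    if (ea$etype != eb$etype) return(FALSE)
    if (!identical(ea$attributes[sort_c(names(ea$attributes))],
                   eb$attributes[sort_c(names(eb$attributes))])) return(FALSE)
  }
  rel_key <- function(m) sort_c(vapply(m$relations, function(r)
    paste(r$subject, r$rtype, r$object,
          serialize_attrs(r$attributes), sep = "\r"), character(1)))
  if (!identical(rel_key(a), rel_key(b))) return(FALSE)
  tag_key <- function(m) sort_c(paste(m$tags$entity, m$tags$category, m$tags$tool,
                                      m$tags$source, m$tags$step, m$tags$comment,
                                      sep = "\r"))
  identical(tag_key(a), tag_key(b))
}

serialize_attrs <- function(attrs) {
  keys <- sort_c(names(attrs))
  paste(vapply(keys, function(k) paste0(k, "=", paste(attrs[[k]], collapse = "|")),
               character(1)), collapse = ";")
}

#' Merge a model into a base model with provenance stamping
#'
#' Entity sets are unioned by id (attribute value lists unioned, never
#' overwritten, so conflicting values such as two directions are both kept
#' and can be flagged in reports); relations are unioned and deduplicated by
#' `(subject, rtype, object)`; every entity of `addition` gains one source
#' tag with the given category/tool/source/step, and tags already on `base`
#' are untouched. Both models must be declared against the same reference
#' namespace — map identifiers first otherwise (see [map_identifiers()]).
#'
#' @param base,addition `gsm_model` objects.
#' @param category reconstruction category to stamp on every added entity.
#' @param tool,source provenance of the addition (e.g. tool `"pantograph"`,
#'   source `"a-thaliana"`).
#' @param step pipeline step index.
#' @return the merged `gsm_model`.
#' @export
merge_models <- function(base, addition, category, tool = "", source = "",
                         step = 0L) {
  stopifnot(inherits(base, "gsm_model"), inherits(addition, "gsm_model"))
  if (nzchar(base$meta$ref_db) && nzchar(addition$meta$ref_db) &&
      base$meta$ref_db != addition$meta$ref_db)
    gsm_abort(sprintf(
      "reference namespace mismatch ('%s' vs '%s'): run map_identifiers() on the addition first",
      base$meta$ref_db, addition$meta$ref_db), "gsm_namespace_error")
  out <- base
  for (id in names(addition$entities))
    out <- add_entity(out, addition$entities[[id]])
  for (r in addition$relations)
    out <- add_relation(out, r$subject, r$rtype, r$object, r$attributes)
  if (nrow(addition$tags) > 0)
    for (i in seq_len(nrow(addition$tags))) out <- add_tag(out, addition$tags[i, ])
  for (id in sort_c(names(addition$entities)))
    out <- add_tag(out, gsm_tag(id, category, tool, source, step))
  out
}

#' @export
print.gsm_model <- function(x, ...) {
  counts <- table(factor(vapply(x$entities, `[[`, character(1), "etype"),
                         levels = GSM_ETYPES))
  cat(sprintf("<gsm_model '%s'>", x$meta$model_id))
  if (nzchar(x$meta$ref_db)) cat(sprintf(" [ref: %s]", x$meta$ref_db))
  cat("\n")
  cat(" ", paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), "\n")
  cat(sprintf("  relations: %d, tags: %d\n", length(x$relations), nrow(x$tags)))
  invisible(x)
}

#' @export
summary.gsm_model <- function(object, ...) {
  etypes <- vapply(object$entities, `[[`, character(1), "etype")
  out <- list(
    model_id = object$meta$model_id,
    ref_db = object$meta$ref_db,
    counts = table(factor(etypes, levels = GSM_ETYPES)),
    relations = length(object$relations),
    tags = nrow(object$tags),
    categories = if (nrow(object$tags)) table(object$tags$category) else table(character(0))
  )
  class(out) <- "summary.gsm_model"
  out
}

#' @export
print.summary.gsm_model <- function(x, ...) {
  cat(sprintf("Model '%s' (reference: %s)\n", x$model_id,
              if (nzchar(x$ref_db)) x$ref_db else "<unset>"))
  for (n in names(x$counts)) cat(sprintf("  %-10s %d\n", n, x$counts[[n]]))
  cat(sprintf("  relations  %d\n  tags       %d\n", x$relations, x$tags))
  if (length(x$categories))
    cat("  tag categories:",
        paste(sprintf("%s=%d", names(x$categories), x$categories), collapse = ", "),
        "\n")
  invisible(x)
}
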