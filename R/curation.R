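# Assisted, replayable manual curation. Forms are flat tab-separated blocks
# (not interactive prompts) so that curation is diffable, reviewable and
# replayable when the upstream pipeline is re-run on new inputs.

FORM_OPS <- c("add_reaction", "add_compound", "modify_entity", "delete_entity")

#' Construct a curation form
#'
#' A form is one manual model edit with its mandatory audit trail: a
#' free-text `justification` and a `source` (typically a literature
#' reference). `add_reaction` payloads must name at least one reactant and
#' one product (`"id:coefficient"` comma lists).
#'
#' @param op one of `r paste(FORM_OPS, collapse = ", ")`.
#' @param payload named list/character: `id`, plus for reactions `reactants`,
#'   `products`, optional `direction`, `genes`, `pathway`; any other key
#'   becomes an entity attribute.
#' @param justification,source mandatory non-empty text.
#' @param author,timestamp optional audit fields.
#' @return a `gsm_form`.
#' @export
curation_form <- function(op, payload, justification, source,
                          author = "", timestamp = "") {
  form <- structure(list(op = op, payload = as.list(payload),
                         justification = justification, source = source,
                         author = author, timestamp = timestamp),
                    class = "gsm_form")
  validate_form(form)
  form
}

validate_form <- function(form) {
  if (!form$op %in% FORM_OPS)
    gsm_abort(sprintf("unknown curation op '%s'", form$op), "gsm_validation_error")
  if (!nzchar(trimws(form$justification %||% "")))
    gsm_abort("curation form requires a non-empty justification",
              "gsm_validation_error")
  if (!nzchar(trimws(form$source %||% "")))
    gsm_abort("curation form requires a non-empty source", "gsm_validation_error")
  if (is.null(form$payload$id) || !nzchar(form$payload$id))
    gsm_abort("curation form payload requires an id", "gsm_validation_error")
  if (form$op == "add_reaction") {
    for (side in c("reactants", "products"))
      if (length(parse_participants(form$payload[[side]])) == 0)
        gsm_abort(sprintf("add_reaction requires at least one of %s", side),
                  "gsm_validation_error")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "A:1,B:2.5" -> list(list(id="A", coef="1"), ...); coefficient defaults to 1
parse_participants <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(list())
  out <- list()
  for (part in trimws(strsplit(spec, ",", fixed = TRUE)[[1]])) {
    if (!nzchar(part)) next
    colon <- regexpr(":[0-9.]+$", part)
    if (colon > 0) {
      out[[length(out) + 1L]] <- list(id = substr(part, 1, colon - 1),
                                      coef = substring(part, colon + 1))
    } else out[[length(out) + 1L]] <- list(id = part, coef = "1")
  }
  out
}

#' Read curation forms from a flat file
#'
#' One form per block, blocks separated by blank lines. Each block starts
#' with an `op:` line followed by `key<TAB>value` lines.
#'
#' @param path forms file.
#' @return list of `gsm_form` objects.
#' @export
read_forms <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  forms <- list()
  block <- list(); op <- NULL
  flush <- function() {
    if (is.null(op)) return(invisible(NULL))
    meta <- c("justification", "source", "author", "timestamp")
    forms[[length(forms) + 1L]] <<- curation_form(
      op, block[setdiff(names(block), meta)],
      justification = block$justification %||% "",
      source = block$source %||% "",
      author = block$author %||% "", timestamp = block$timestamp %||% "")
    block <<- list(); op <<- NULL
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) { flush(); next }
    if (grepl("^op\\s*:", line)) {
      flush()
      op <- trimws(sub("^op\\s*:", "", line))
    } else {
      f <- split_tsv(line)
      if (length(f) < 2 || is.null(op))
        gsm_abort(sprintf("line %d: expected 'key<TAB>value' inside a form block", i),
                  "gsm_parse_error")
      block[[trimws(f[1])]] <- f[2]
    }
  }
  flush()
  forms
}

#' Apply one curation form to a model
#'
#' Every entity touched by the form gains a source tag
#' `(manual, curation-form, form$source, comment = form$justification)`, and
#' the form is appended to the model's curation log, so the whole manual
#' history can be replayed on a regenerated base (see [replay_log()]).
#'
#' @param model a `gsm_model`.
#' @param form a [curation_form()].
#' @param step pipeline step index stamped on the tags.
#' @return the updated model.
#' @export
apply_form <- function(model, form, step = 0L) {
  validate_form(form)
  p <- form$payload
  id <- p$id
  tag_for <- function(e) gsm_tag(e, "manual", "curation-form", form$source,
                                 step, form$justification)
  reserved <- c("id", "reactants", "products", "direction", "genes", "pathway")
  extra_attrs <- p[setdiff(names(p), reserved)]
  if (form$op == "add_reaction") {
    attrs <- c(list(direction = p$direction %||% "REVERSIBLE"), extra_attrs)
    model <- add_entity(model, gsm_entity(id, "reaction", attrs), tag_for(id))
    for (side in list(c("reactants", "consumes"), c("products", "produces"))) {
      for (part in parse_participants(p[[side[1]]])) {
        if (!has_entity(model, part$id))
          model <- add_entity(model, gsm_entity(part$id, "compound"),
                              tag_for(part$id))
        model <- add_relation(model, id, side[2], part$id,
                              list(coefficient = part$coef))
      }
    }
    if (!is.null(p$genes) && nzchar(p$genes)) {
      for (g in trimws(strsplit(p$genes, ",", fixed = TRUE)[[1]])) {
        if (!has_entity(model, g))
          model <- add_entity(model, gsm_entity(g, "gene"), tag_for(g))
        model <- add_relation(model, g, "is_linked_to", id)
      }
    }
    if (!is.null(p$pathway) && nzchar(p$pathway)) {
      for (pw in trimws(strsplit(p$pathway, ",", fixed = TRUE)[[1]])) {
        if (!has_entity(model, pw))
          model <- add_entity(model, gsm_entity(pw, "pathway"), tag_for(pw))
        model <- add_relation(model, id, "is_in_pathway", pw)
      }
    }
  } else if (form$op == "add_compound") {
    model <- add_entity(model, gsm_entity(id, "compound", extra_attrs), tag_for(id))
  } else if (form$op == "modify_entity") {
    if (!has_entity(model, id))
      gsm_abort(sprintf("modify_entity: no entity '%s'", id), "gsm_not_found")
    e <- model$entities[[id]]
    for (k in names(extra_attrs))
      e$attributes[[tolower(k)]] <- strsplit(extra_attrs[[k]], ",", fixed = TRUE)[[1]]
    if (!is.null(p$direction)) e$attributes[["direction"]] <- p$direction
    model$entities[[id]] <- e
    model <- add_tag(model, tag_for(id))
  } else if (form$op == "delete_entity") {
    if (!has_entity(model, id))
      gsm_abort(sprintf("delete_entity: no entity '%s'", id), "gsm_not_found")
    model$entities[[id]] <- NULL
    keep <- vapply(model$relations, function(r)
      r$subject != id && r$object != id, logical(1))
    model$relations <- model$relations[keep]
    model$rel_keys <- model$rel_keys[keep]
    model$tags <- model$tags[model$tags$entity != id, , drop = FALSE]
    rownames(model$tags) <- NULL
  }
  model$log[[length(model$log) + 1L]] <- form
  model
}

#' Replay a curation log on a (possibly regenerated) base model
#'
#' Forms are applied in order. A form whose target no longer exists in the
#' base — legitimate after upstream regeneration, e.g. a new genome assembly
#' — is skipped with a report entry, never a fatal error. Replay on the
#' original base reproduces the curated model exactly.
#'
#' @param model the base `gsm_model`.
#' @param log list of `gsm_form` objects (e.g. a previous `model$log` or
#'   [read_forms()] output).
#' @param step step index stamped on the manual tags.
#' @return list with `model` and `skipped` (data frame: form index, op, id,
#'   reason).
#' @export
replay_log <- function(model, log, step = 0L) {
  skipped <- data.frame(index = integer(0), op = character(0),
                        id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_along(log)) {
    form <- log[[i]]
    result <- tryCatch(apply_form(model, form, step = step),
                       gsm_not_found = function(e) e,
                       gsm_type_conflict = function(e) e)
    if (inherits(result, "condition")) {
      skipped <- rbind(skipped, data.frame(
        index = i, op = form$op, id = form$payload$id %||% "",
        reason = conditionMessage(result), stringsAsFactors = FALSE))
    } else model <- result
  }
  list(model = model, skipped = skipped)
}

# ---- diff -----------------------------------------------------------------

DIFF_CATEGORIES <- c(gene = "genes", reaction = "reactions",
                     compound = "compounds", pathway = "pathways",
                     protein = "proteins", class = "classes")

#' Compare two models
#'
#' Reports, per entity category (genes, reactions, compounds, pathways, plus
#' proteins and ontology classes), the ids added, removed, and — for ids
#' common to both models — changed, with field-level deltas covering
#' attribute values and outgoing relations. `diff_models(a, b)$added` equals
#' `diff_models(b, a)$removed` by construction.
#'
#' @param a,b `gsm_model` objects (e.g. two versions of one GSM).
#' @return a `gsm_diff` object with per-category `added`, `removed`,
#'   `changed` (named list of delta descriptions) and a `summary` count
#'   data frame.
#' @export
diff_models <- function(a, b) {
  out <- list()
  for (et in names(DIFF_CATEGORIES)) {
    ia <- entity_ids(a, et); ib <- entity_ids(b, et)
    added <- sort_c(setdiff(ib, ia))
    removed <- sort_c(setdiff(ia, ib))
    changed <- list()
    for (id in sort_c(intersect(ia, ib))) {
      deltas <- entity_deltas(a, b, id)
      if (length(deltas)) changed[[id]] <- deltas
    }
    out[[DIFF_CATEGORIES[[et]]]] <-
      list(added = added, removed = removed, changed = changed)
  }
  summary <- do.call(rbind, lapply(names(out), function(cat) data.frame(
    category = cat, added = length(out[[cat]]$added),
    removed = length(out[[cat]]$removed), changed = length(out[[cat]]$changed),
    stringsAsFactors = FALSE)))
  structure(c(out, list(summary = summary)), class = "gsm_diff")
}

entity_deltas <- function(a, b, id) {
  ea <- a$entities[[id]]; eb <- b$entities[[id]]
  deltas <- character(0)
  for (k in sort_c(union(names(ea$attributes), names(eb$attributes)))) {
    va <- ea$attributes[[k]]; vb <- eb$attributes[[k]]
    if (!identical(va, vb))
      deltas <- c(deltas, sprintf("attribute %s: '%s' -> '%s'", k,
                                  paste(va, collapse = "|"),
                                  paste(vb, collapse = "|")))
  }
  rels <- function(m) sort_c(vapply(
    Filter(function(r) r$subject == id, m$relations),
    function(r) paste0(r$rtype, " ", r$object,
                       if (length(r$attributes[["coefficient"]]))
                         paste0(" x", r$attributes[["coefficient"]][1]) else ""),
    character(1)))
  ra <- rels(a); rb <- rels(b)
  for (x in setdiff(rb, ra)) deltas <- c(deltas, paste0("relation added: ", x))
  for (x in setdiff(ra, rb)) deltas <- c(deltas, paste0("relation removed: ", x))
  deltas
}

#' @export
print.gsm_diff <- function(x, ...) {
  cat("<gsm_diff>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a diff report as TSV
#'
#' @param diff a `gsm_diff`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_diff <- function(diff, path) {
  lines <- "category\tchange\tid\tdetail"
  for (cat in setdiff(names(diff), "summary")) {
    for (id in diff[[cat]]$added)
      lines <- c(lines, paste(cat, "added", id, "", sep = "\t"))
    for (id in diff[[cat]]$removed)
      lines <- c(lines, paste(cat, "removed", id, "", sep = "\t"))
    for (id in names(diff[[cat]]$changed))
      lines <- c(lines, paste(cat, "changed", id,
                              paste(diff[[cat]]$changed[[id]], collapse = "; "),
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
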