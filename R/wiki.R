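# Static wiki generation: one HTML page per entity plus index, category and
# pathway pages. Pages are plain hypertext regenerated from the model (never
# hand-edited); output is deterministic, so re-generation from an identical
# model is byte-identical and the site can be diffed between model versions.

DEFAULT_URL_TEMPLATES <- c(
  metacyc = "https://metacyc.org/META/NEW-IMAGE?object={id}",
  bigg = "http://bigg.ucsd.edu/search?query={id}",
  seed = "https://modelseed.org/biochem/compounds/{id}")

page_name <- function(kind, id) {
  if (!nzchar(id)) id <- "none"
  paste0(kind, "_", escape_sbml_id(id), ".html")
}

html_esc <- xml_esc

wiki_link <- function(kind, id, label = id)
  sprintf("<a href=\"%s\">%s</a>", page_name(kind, id), html_esc(label))

#' Generate a static wiki for a model
#'
#' Writes one page per entity (reaction pages list reactants and products
#' with coefficients, gene links, pathways, provenance tags and external
#' database links), one index page per entity type, one page per
#' reconstruction category/tool/source listing the entities it contributed,
#' and a pathway index sorted by completion rate when reference pathway
#' definitions are supplied. Every page carries the same navigation panel and
#' all internal links resolve within the generated directory.
#'
#' @param model a valid `gsm_model`.
#' @param outdir output directory (created; existing pages overwritten).
#' @param pathway_defs optional reference `gsm_model` for completion rates.
#' @param url_templates named character vector of external URL templates
#'   keyed by reference-database name, `{id}` substituted; defaults cover
#'   MetaCyc/BiGG/SEED. Links are emitted as configured even when
#'   unverifiable offline.
#' @return invisible character vector of files written.
#' @export
generate_wiki <- function(model, outdir, pathway_defs = NULL,
                          url_templates = DEFAULT_URL_TEMPLATES) {
  validate_model(model)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, title, body) {
    page <- c("<!DOCTYPE html>", "<html><head>",
              sprintf("<title>%s</title>", html_esc(title)),
              "<link rel=\"stylesheet\" href=\"style.css\"/>",
              "</head><body>", nav_panel(model),
              sprintf("<h1>%s</h1>", html_esc(title)), body,
              "</body></html>")
    f <- file.path(outdir, name)
    writeLines(page, f)
    files <<- c(files, f)
    invisible(NULL)
  }

  nav_panel <- function(model) {
    items <- c("<a href=\"index.html\">index</a>",
               vapply(GSM_ETYPES, function(et)
                 sprintf("<a href=\"index_%s.html\">%ss</a>", et, et), character(1)),
               "<a href=\"pathways.html\">pathway completion</a>",
               "<a href=\"provenance.html\">provenance</a>")
    paste0("<nav>", paste(items, collapse = " | "), "</nav>")
  }

  tag_rows <- function(id) {
    t <- model$tags[model$tags$entity == id, , drop = FALSE]
    if (nrow(t) == 0) return("<p>no provenance recorded</p>")
    t <- t[order_c(t$step, t$category, t$tool, t$source), , drop = FALSE]
    rows <- sprintf(
      "<tr><td><span class=\"badge badge-%s\">%s</span></td><td>%s</td><td>%s</td><td>%d</td><td>%s</td></tr>",
      gsub("[^a-z]", "", t$category), html_esc(t$category),
      vapply(seq_len(nrow(t)), function(i)
        wiki_link("prov_tool", t$tool[i], if (nzchar(t$tool[i])) t$tool[i] else "-"),
        character(1)),
      vapply(seq_len(nrow(t)), function(i)
        wiki_link("prov_source", t$source[i],
                  if (nzchar(t$source[i])) t$source[i] else "-"), character(1)),
      t$step, html_esc(t$comment))
    c("<table class=\"tags\"><tr><th>category</th><th>tool</th><th>source</th><th>step</th><th>comment</th></tr>",
      rows, "</table>")
  }

  xref_links <- function(id) {
    out <- character(0)
    db <- tolower(model$meta$ref_db)
    if (nzchar(db) && db %in% names(url_templates))
      out <- c(out, sprintf("<a href=\"%s\" class=\"external\">%s @ %s</a>",
                            html_esc(gsub("{id}", utils::URLencode(id, reserved = TRUE),
                                          url_templates[[db]], fixed = TRUE)),
                            html_esc(id), html_esc(db)))
    for (x in model$entities[[id]]$attributes[["xrefs"]] %||% character(0))
      out <- c(out, html_esc(x))
    if (length(out)) c("<p class=\"xrefs\">", paste(out, collapse = " | "), "</p>")
    else character(0)
  }

  attr_table <- function(id) {
    attrs <- model$entities[[id]]$attributes
    if (length(attrs) == 0) return(character(0))
    rows <- vapply(sort_c(names(attrs)), function(k)
      sprintf("<tr><td>%s</td><td>%s</td></tr>", html_esc(k),
              html_esc(paste(attrs[[k]], collapse = "; "))), character(1))
    c("<table class=\"attrs\">", rows, "</table>")
  }

  # --- per-entity pages ---
  rel_by_subject <- split(model$relations,
                          vapply(model$relations, `[[`, character(1), "subject"))
  rel_by_object <- split(model$relations,
                         vapply(model$relations, `[[`, character(1), "object"))
  for (id in entity_ids(model)) {
    e <- model$entities[[id]]
    body <- character(0)
    if (e$etype == "reaction") {
      sides <- reaction_sides(model, id)
      fmt_side <- function(side) paste(vapply(
        side[order_c(vapply(side, `[[`, character(1), "id"))],
        function(p) {
          ety <- model$entities[[p$id]]$etype
          paste0(if (p$coef != 1) paste0(p$coef, " ") else "",
                 wiki_link(ety, p$id))
        }, character(1)), collapse = " + ")
      arrow <- if (reaction_direction(model, id) == "REVERSIBLE")
        "&harr;" else "&rarr;"
      body <- c(body, sprintf("<p class=\"equation\">%s %s %s</p>",
                              fmt_side(sides$reactants), arrow,
                              fmt_side(sides$products)))
      genes <- sort_c(unlist(lapply(rel_by_object[[id]], function(r)
        if (r$rtype == "is_linked_to") r$subject)))
      if (length(genes))
        body <- c(body, "<p>genes: ",
                  paste(vapply(genes, function(g) wiki_link("gene", g),
                               character(1)), collapse = ", "), "</p>")
      pwys <- sort_c(unlist(lapply(rel_by_subject[[id]], function(r)
        if (r$rtype == "is_in_pathway") r$object)))
      if (length(pwys))
        body <- c(body, "<p>pathways: ",
                  paste(vapply(pwys, function(p) wiki_link("pathway", p),
                               character(1)), collapse = ", "), "</p>")
    } else if (e$etype %in% c("compound", "class")) {
      consumers <- character(0); producers <- character(0)
      for (r in rel_by_object[[id]] %||% list()) {
        if (r$rtype == "consumes") consumers <- c(consumers, r$subject)
        if (r$rtype == "produces") producers <- c(producers, r$subject)
      }
      rlinks <- function(ids) paste(vapply(sort_c(unique(ids)), function(r)
        wiki_link("reaction", r), character(1)), collapse = ", ")
      if (length(producers))
        body <- c(body, sprintf("<p>produced by: %s</p>", rlinks(producers)))
      if (length(consumers))
        body <- c(body, sprintf("<p>consumed by: %s</p>", rlinks(consumers)))
      classes <- sort_c(unlist(lapply(rel_by_subject[[id]], function(r)
        if (r$rtype == "is_a") r$object)))
      if (length(classes))
        body <- c(body, sprintf("<p>instance of: %s</p>", paste(
          vapply(classes, function(cl) wiki_link("class", cl), character(1)),
          collapse = ", ")))
    } else if (e$etype == "pathway") {
      members <- sort_c(unlist(lapply(rel_by_object[[id]], function(r)
        if (r$rtype == "is_in_pathway") r$subject)))
      if (length(members)) {
        rows <- vapply(members, function(rid) {
          cats <- sort_c(unique(model$tags$category[model$tags$entity == rid]))
          badges <- paste(sprintf("<span class=\"badge badge-%s\">%s</span>",
                                  gsub("[^a-z]", "", cats), cats), collapse = " ")
          sprintf("<tr><td>%s</td><td>%s</td></tr>",
                  wiki_link("reaction", rid), badges)
        }, character(1))
        body <- c(body, sprintf("<p>%d member reactions</p>", length(members)),
                  "<table class=\"members\"><tr><th>reaction</th><th>provenance</th></tr>",
                  rows, "</table>")
      }
    } else if (e$etype == "gene") {
      rxns <- sort_c(unlist(lapply(rel_by_subject[[id]], function(r)
        if (r$rtype == "is_linked_to") r$object)))
      if (length(rxns))
        body <- c(body, "<p>linked reactions: ",
                  paste(vapply(rxns, function(r) wiki_link("reaction", r),
                               character(1)), collapse = ", "), "</p>")
    }
    body <- c(body, attr_table(id), xref_links(id),
              "<h2>Provenance</h2>", tag_rows(id))
    emit(page_name(e$etype, id), paste0(e$etype, ": ", id), body)
  }

  # --- index pages ---
  for (et in GSM_ETYPES) {
    ids <- entity_ids(model, et)
    body <- if (length(ids))
      c("<ul>", sprintf("<li>%s</li>",
                        vapply(ids, function(i) wiki_link(et, i), character(1))),
        "</ul>")
    else "<p>none</p>"
    emit(paste0("index_", et, ".html"), paste0(et, "s"), body)
  }

  # --- provenance category/tool/source pages ---
  prov_body <- character(0)
  for (key in c("category", "tool", "source")) {
    kind <- paste0("prov_", if (key == "category") "cat" else key)
    values <- sort_c(unique(model$tags[[key]]))
    prov_body <- c(prov_body, sprintf("<h2>by %s</h2>", key), "<ul>")
    for (v in values) {
      ents <- sort_c(unique(model$tags$entity[model$tags[[key]] == v]))
      label <- if (nzchar(v)) v else "(unspecified)"
      prov_body <- c(prov_body, sprintf("<li>%s (%d entities)</li>",
                                        wiki_link(kind, v, label), length(ents)))
      rows <- vapply(ents, function(id)
        sprintf("<li>%s</li>", wiki_link(model$entities[[id]]$etype, id)),
        character(1))
      emit(page_name(kind, v), sprintf("%s: %s", key, label),
           c(sprintf("<p>%d entities</p>", length(ents)), "<ul>", rows, "</ul>"))
    }
    prov_body <- c(prov_body, "</ul>")
  }
  emit("provenance.html", "Reconstruction provenance", prov_body)

  # --- pathway completion index ---
  pw_body <- character(0)
  defs <- if (!is.null(pathway_defs)) pathway_defs else model
  comp <- pathway_completeness(model, defs)
  if (nrow(comp$table)) {
    rows <- vapply(seq_len(nrow(comp$table)), function(i) sprintf(
      "<tr><td>%s</td><td>%d</td><td>%d</td><td>%.2f</td></tr>",
      if (has_entity(model, comp$table$pathway[i]))
        wiki_link("pathway", comp$table$pathway[i])
      else html_esc(comp$table$pathway[i]),
      comp$table$total[i], comp$table$present[i], comp$table$ratio[i]),
      character(1))
    pw_body <- c("<table class=\"completion\"><tr><th>pathway</th><th>defined</th><th>present</th><th>completion rate</th></tr>",
                 rows, "</table>")
  } else pw_body <- "<p>no pathways defined</p>"
  emit("pathways.html", "Pathway completion", pw_body)

  # --- main index ---
  counts <- table(factor(vapply(model$entities, `[[`, character(1), "etype"),
                         levels = GSM_ETYPES))
  emit("index.html", paste0("Model ", model$meta$model_id),
       c(sprintf("<p>reference database: %s</p>",
                 html_esc(if (nzchar(model$meta$ref_db)) model$meta$ref_db
                          else "(unset)")),
         "<ul>",
         sprintf("<li><a href=\"index_%s.html\">%ss</a>: %d</li>",
                 names(counts), names(counts), as.integer(counts)),
         "</ul>"))

  writeLines(c(
    "body { font-family: sans-serif; margin: 2em; }",
    "nav { border-bottom: 1px solid #999; padding-bottom: .5em; }",
    "table { border-collapse: collapse; } td, th { border: 1px solid #ccc; padding: .2em .6em; }",
    ".badge { padding: 0 .4em; border-radius: .4em; color: #fff; }",
    ".badge-annotation { background: #c90; }",
    ".badge-orthology { background: #390; }",
    ".badge-gapfilling { background: #36c; }",
    ".badge-manual { background: #933; }"),
    file.path(outdir, "style.css"))
  files <- c(files, file.path(outdir, "style.css"))
  invisible(sort(files))
}
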