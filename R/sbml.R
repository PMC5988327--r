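# SBML Level 2 / Level 3 (core + fbc) import and export, built on xml2.
#
# Identifier convention: SBML SIds only allow [A-Za-z0-9_] and may not start
# with a digit, while reference databases use ids containing '.', '/', '-'
# (e.g. MetaCyc instantiated reactions). At export every forbidden character
# (and a leading digit) is escaped as __<decimal codepoint>__ ("." becomes
# "__46__"); import reverses it. The escape is applied only at the SBML
# boundary, never inside the store. Species/reaction/gene SIds additionally
# carry the conventional M_/R_/G_ prefix, stripped at import.

escape_sbml_id <- function(id) {
  chars <- strsplit(id, "")[[1]]
  ok <- grepl("[A-Za-z0-9_]", chars)
  if (length(chars) && ok[1] && grepl("[0-9]", chars[1])) ok[1] <- FALSE
  chars[!ok] <- vapply(chars[!ok],
                       function(ch) sprintf("__%d__", utf8ToInt(ch)), character(1))
  out <- paste(chars, collapse = "")
  if (unescape_sbml_id(out) != id)
    gsm_abort(sprintf("id '%s' cannot be escaped reversibly (contains a literal __<n>__ sequence)",
                      id), "gsm_unescapable_id")
  out
}

unescape_sbml_id <- function(id) {
  m <- gregexpr("__([0-9]+)__", id)
  regmatches(id, m) <- lapply(regmatches(id, m), function(hits)
    vapply(hits, function(h)
      intToUtf8(as.integer(sub("^__([0-9]+)__$", "\\1", h))), character(1)))
  id
}

strip_prefix <- function(id, prefix) {
  ifelse(startsWith(id, prefix), substring(id, nchar(prefix) + 1L), id)
}

xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

SBML_NS_L3 <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_NS_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# ---- export ---------------------------------------------------------------

note_lines_for_tags <- function(model, id) {
  t <- model$tags[model$tags$entity == id, , drop = FALSE]
  if (nrow(t) == 0) return(character(0))
  t <- t[order_c(t$category, t$tool, t$source, t$step), , drop = FALSE]
  esc <- function(x) gsub("|", "%7C", x, fixed = TRUE)
  sprintf("PROVENANCE: %s|%s|%s|%d|%s",
          esc(t$category), esc(t$tool), esc(t$source), t$step, esc(t$comment))
}

notes_block <- function(lines, indent) {
  if (length(lines) == 0) return(character(0))
  pad <- strrep(" ", indent)
  c(paste0(pad, "<notes>"),
    paste0(pad, "  <body xmlns=\"http://www.w3.org/1999/xhtml\">"),
    paste0(pad, "    <p>", xml_esc(lines), "</p>"),
    paste0(pad, "  </body>"),
    paste0(pad, "</notes>"))
}

#' Write a model as SBML
#'
#' Level 3 version 1 core is the default; gene associations are serialized
#' with the fbc version 2 package (plus a `GENE_ASSOCIATION` note when the
#' raw boolean rule is known). Level 2 version 4 uses notes-based
#' `GENE_ASSOCIATION`/`FORMULA`/`CHARGE` conventions. Source tags are
#' serialized as `PROVENANCE: category|tool|source|step|comment` note lines;
#' pathway membership as `SUBSYSTEM:` note lines. Ids are escaped as
#' described in the package identifier convention; an id that cannot be
#' escaped reversibly raises an error naming it.
#'
#' @param model a valid `gsm_model`.
#' @param path output file.
#' @param level 2 or 3.
#' @return `path` invisibly.
#' @export
write_sbml <- function(model, path, level = 3) {
  validate_model(model)
  if (!level %in% c(2, 3))
    gsm_abort(sprintf("unsupported SBML level %s", level), "gsm_unsupported_level")
  compounds <- entity_ids(model, c("compound", "class"))
  reactions <- entity_ids(model, "reaction")
  genes <- entity_ids(model, "gene")
  use_fbc <- level == 3

  header <- if (level == 3) {
    sprintf(paste0("<sbml xmlns=\"%s\" level=\"3\" version=\"1\"",
                   " xmlns:fbc=\"%s\" fbc:required=\"false\">"),
            SBML_NS_L3, SBML_NS_FBC)
  } else {
    "<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" level=\"2\" version=\"4\">"
  }
  model_attrs <- sprintf(" id=\"%s\" name=\"%s\"",
                         escape_sbml_id(model$meta$model_id),
                         xml_esc(model$meta$model_id))
  if (use_fbc) model_attrs <- paste0(model_attrs, " fbc:strict=\"false\"")
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", header,
             paste0("  <model", model_attrs, ">"))
  meta_notes <- character(0)
  if (nzchar(model$meta$ref_db))
    meta_notes <- c(meta_notes, paste0("REF_DB: ", model$meta$ref_db))
  if (nzchar(model$meta$ref_version))
    meta_notes <- c(meta_notes, paste0("REF_VERSION: ", model$meta$ref_version))
  lines <- c(lines, notes_block(meta_notes, 4))
  lines <- c(lines,
             "    <listOfCompartments>",
             if (level == 3)
               "      <compartment id=\"c\" constant=\"true\"/>"
             else
               "      <compartment id=\"c\"/>",
             "    </listOfCompartments>")

  lines <- c(lines, "    <listOfSpecies>")
  for (cid in compounds) {
    e <- model$entities[[cid]]
    name <- entity_attr1(model, cid, "common-name", cid)
    boundary <- identical(entity_attr1(model, cid, "boundary"), "true")
    extra <- ""
    sp_notes <- character(0)
    formula <- entity_attr1(model, cid, "formula")
    charge <- entity_attr1(model, cid, "charge")
    if (use_fbc) {
      if (!is.na(formula) && grepl("^[A-Za-z0-9]+$", formula))
        extra <- paste0(extra, sprintf(" fbc:chemicalFormula=\"%s\"", formula))
      if (!is.na(charge) && !is.na(suppressWarnings(as.integer(charge))))
        extra <- paste0(extra, sprintf(" fbc:charge=\"%s\"", as.integer(charge)))
    } else {
      if (!is.na(formula)) sp_notes <- c(sp_notes, paste0("FORMULA: ", formula))
      if (!is.na(charge)) sp_notes <- c(sp_notes, paste0("CHARGE: ", charge))
    }
    if (e$etype == "class") sp_notes <- c(sp_notes, "SPECIES_CLASS: true")
    sp_notes <- c(sp_notes, note_lines_for_tags(model, cid))
    l3req <- if (level == 3)
      " hasOnlySubstanceUnits=\"false\" constant=\"false\"" else ""
    open <- sprintf(paste0("      <species id=\"M_%s\" name=\"%s\" compartment=\"c\"",
                           " boundaryCondition=\"%s\"%s%s"),
                    escape_sbml_id(cid), xml_esc(name),
                    if (boundary) "true" else "false", l3req, extra)
    if (length(sp_notes)) {
      lines <- c(lines, paste0(open, ">"), notes_block(sp_notes, 8),
                 "      </species>")
    } else lines <- c(lines, paste0(open, "/>"))
  }
  lines <- c(lines, "    </listOfSpecies>")

  if (use_fbc && length(genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>")
    for (g in genes)
      lines <- c(lines, sprintf(
        "      <fbc:geneProduct fbc:id=\"G_%s\" fbc:label=\"%s\"/>",
        escape_sbml_id(g), xml_esc(g)))
    lines <- c(lines, "    </fbc:listOfGeneProducts>")
  }

  lines <- c(lines, "    <listOfReactions>")
  for (rid in reactions) {
    sides <- reaction_sides(model, rid)
    reversible <- reaction_direction(model, rid) == "REVERSIBLE"
    rxn_genes <- sort_c(unlist(lapply(model$relations, function(r)
      if (r$rtype == "is_linked_to" && r$object == rid) r$subject)))
    pathways <- sort_c(unlist(lapply(model$relations, function(r)
      if (r$rtype == "is_in_pathway" && r$subject == rid) r$object)))
    r_notes <- character(0)
    rule <- entity_attr1(model, rid, "gene-rule")
    if (level == 2 || !is.na(rule)) {
      rule_txt <- if (!is.na(rule)) rule else paste(rxn_genes, collapse = " or ")
      if (nzchar(rule_txt))
        r_notes <- c(r_notes, paste0("GENE_ASSOCIATION: ", rule_txt))
    }
    if (length(pathways))
      r_notes <- c(r_notes, paste0("SUBSYSTEM: ", pathways))
    inst <- entity_attr1(model, rid, "instance-of")
    if (!is.na(inst)) r_notes <- c(r_notes, paste0("INSTANCE_OF: ", inst))
    r_notes <- c(r_notes, note_lines_for_tags(model, rid))
    l3rxn <- if (level == 3) " fast=\"false\"" else ""
    lines <- c(lines, sprintf(
      "      <reaction id=\"R_%s\" name=\"%s\" reversible=\"%s\"%s>",
      escape_sbml_id(rid), xml_esc(entity_attr1(model, rid, "common-name", rid)),
      if (reversible) "true" else "false", l3rxn))
    lines <- c(lines, notes_block(r_notes, 8))
    write_side <- function(side, tag) {
      if (length(side) == 0) return(character(0))
      ord <- order_c(vapply(side, `[[`, character(1), "id"))
      l3sr <- if (level == 3) " constant=\"true\"" else ""
      c(sprintf("        <%s>", tag),
        vapply(side[ord], function(p) sprintf(
          "          <speciesReference species=\"M_%s\" stoichiometry=\"%s\"%s/>",
          escape_sbml_id(p$id), format(p$coef, scientific = FALSE), l3sr),
          character(1)),
        sprintf("        </%s>", tag))
    }
    lines <- c(lines, write_side(sides$reactants, "listOfReactants"),
               write_side(sides$products, "listOfProducts"))
    if (use_fbc && length(rxn_genes)) {
      refs <- sprintf("            <fbc:geneProductRef fbc:geneProduct=\"G_%s\"/>",
                      vapply(rxn_genes, escape_sbml_id, character(1)))
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 if (length(refs) > 1) c("          <fbc:or>",
                                         paste0("  ", refs),
                                         "          </fbc:or>")
                 else sub("^    ", "", refs),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  xml2::read_xml(path)  # well-formedness check
  invisible(path)
}

# ---- import ---------------------------------------------------------------

node_attr <- function(node, key) {
  a <- xml2::xml_attrs(node)
  nm <- names(a)
  hit <- which(nm == key | sub("^[^:]+:", "", nm) == key)
  if (length(hit)) a[[hit[1]]] else NA_character_
}

note_paragraphs <- function(node) {
  ps <- xml2::xml_find_all(node, "./notes//p")
  if (length(ps) == 0) ps <- xml2::xml_find_all(node, "./notes")
  txt <- trimws(unlist(strsplit(xml2::xml_text(ps), "\n")))
  txt[nzchar(txt)]
}

# Parse provenance note lines into tags: multi-tag "PROVENANCE: a|b|c|d|e"
# lines, or the single-tag CATEGORY:/TOOL:/SOURCE:/STEP:/COMMENT: convention.
tags_from_notes <- function(notes, entity) {
  out <- empty_tags()
  unesc <- function(x) gsub("%7C", "|", x, fixed = TRUE)
  for (line in grep("^PROVENANCE\\s*:", notes, value = TRUE)) {
    f <- strsplit(sub("^PROVENANCE\\s*:\\s*", "", line), "|", fixed = TRUE)[[1]]
    f <- c(f, rep("", 5 - length(f)))
    step <- suppressWarnings(as.integer(f[4])); if (is.na(step)) step <- 0L
    out <- rbind(out, gsm_tag(entity, unesc(f[1]), unesc(f[2]), unesc(f[3]),
                              step, unesc(f[5])))
  }
  keyval <- function(key) {
    hit <- grep(paste0("^", key, "\\s*:"), notes, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^", key, "\\s*:\\s*"), "", hit[1])) else ""
  }
  cat <- keyval("CATEGORY")
  if (nzchar(cat) && cat %in% GSM_CATEGORIES) {
    step <- suppressWarnings(as.integer(keyval("STEP"))); if (is.na(step)) step <- 0L
    out <- rbind(out, gsm_tag(entity, cat, keyval("TOOL"), keyval("SOURCE"),
                              step, keyval("COMMENT")))
  }
  out
}

gene_tokens <- function(rule) {
  toks <- regmatches(rule, gregexpr("[^()\\s]+", rule))[[1]]
  unique(toks[!tolower(toks) %in% c("and", "or")])
}

#' Read an SBML file into a model
#'
#' Accepts SBML Level 2 and Level 3 core, with the fbc package if present.
#' Species become compound entities (those carrying a `SPECIES_CLASS: true`
#' note become ontology classes; `boundaryCondition="true"` sets the
#' `boundary` attribute, making them legal seeds). Reaction notes are scanned
#' for `GENE_ASSOCIATION` rules (Level 2 convention), `SUBSYSTEM` pathway
#' membership, `INSTANCE_OF` links and `PROVENANCE`/`CATEGORY`-style process
#' metadata, which become source tags. fbc gene-product associations are
#' flattened to gene→reaction links; the raw boolean rule, when given as a
#' note, is kept in the `gene-rule` reaction attribute.
#'
#' @param path SBML file.
#' @return a `gsm_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    gsm_abort(paste0("invalid XML: ", conditionMessage(e)), "gsm_parse_error"))
  level <- xml2::xml_attr(doc, "level")
  if (!level %in% c("2", "3"))
    gsm_abort(sprintf("unsupported SBML level '%s' (only 2 and 3)", level),
              "gsm_unsupported_level")
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, "./model")
  model_id <- xml2::xml_attr(mnode, "id")
  model <- gsm_model(if (is.na(model_id)) "model" else unescape_sbml_id(model_id))
  mnotes <- note_paragraphs(mnode)
  for (line in mnotes) {
    if (grepl("^REF_DB\\s*:", line))
      model$meta$ref_db <- trimws(sub("^REF_DB\\s*:", "", line))
    if (grepl("^REF_VERSION\\s*:", line))
      model$meta$ref_version <- trimws(sub("^REF_VERSION\\s*:", "", line))
  }

  gene_labels <- list()
  for (gp in xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")) {
    gid <- node_attr(gp, "id"); lab <- node_attr(gp, "label")
    gene_labels[[gid]] <- if (!is.na(lab) && nzchar(lab)) lab
      else unescape_sbml_id(strip_prefix(gid, "G_"))
  }

  pending_tags <- empty_tags()
  for (sp in xml2::xml_find_all(doc, ".//listOfSpecies/species")) {
    sid <- node_attr(sp, "id")
    cid <- unescape_sbml_id(strip_prefix(sid, "M_"))
    notes <- note_paragraphs(sp)
    attrs <- list()
    name <- node_attr(sp, "name")
    if (!is.na(name) && nzchar(name) && name != cid) attrs[["common-name"]] <- name
    comp <- node_attr(sp, "compartment")
    if (!is.na(comp) && nzchar(comp)) attrs[["compartment"]] <- comp
    if (identical(node_attr(sp, "boundaryCondition"), "true"))
      attrs[["boundary"]] <- "true"
    fml <- node_attr(sp, "chemicalFormula")
    if (is.na(fml)) {
      hit <- grep("^FORMULA\\s*:", notes, value = TRUE)
      if (length(hit)) fml <- trimws(sub("^FORMULA\\s*:", "", hit[1]))
    }
    if (!is.na(fml) && nzchar(fml)) attrs[["formula"]] <- fml
    chg <- node_attr(sp, "charge")
    if (is.na(chg)) {
      hit <- grep("^CHARGE\\s*:", notes, value = TRUE)
      if (length(hit)) chg <- trimws(sub("^CHARGE\\s*:", "", hit[1]))
    }
    if (!is.na(chg) && nzchar(chg)) attrs[["charge"]] <- chg
    etype <- if (any(grepl("^SPECIES_CLASS\\s*:\\s*true", notes))) "class" else "compound"
    model <- add_entity(model, gsm_entity(cid, etype, attrs))
    pending_tags <- rbind(pending_tags, tags_from_notes(notes, cid))
  }

  for (rx in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    rid <- unescape_sbml_id(strip_prefix(node_attr(rx, "id"), "R_"))
    notes <- note_paragraphs(rx)
    rev <- node_attr(rx, "reversible")
    direction <- if (identical(rev, "false")) "LEFT-TO-RIGHT" else "REVERSIBLE"
    attrs <- list(direction = direction)
    name <- node_attr(rx, "name")
    if (!is.na(name) && nzchar(name) && name != rid) attrs[["common-name"]] <- name
    rule_hit <- grep("^GENE_ASSOCIATION\\s*:", notes, value = TRUE)
    rule <- if (length(rule_hit))
      trimws(sub("^GENE_ASSOCIATION\\s*:", "", rule_hit[1])) else NA_character_
    if (!is.na(rule) && nzchar(rule)) attrs[["gene-rule"]] <- rule
    inst_hit <- grep("^INSTANCE_OF\\s*:", notes, value = TRUE)
    if (length(inst_hit))
      attrs[["instance-of"]] <- trimws(sub("^INSTANCE_OF\\s*:", "", inst_hit[1]))
    model <- add_entity(model, gsm_entity(rid, "reaction", attrs))
    for (side in list(c("listOfReactants", "consumes"),
                      c("listOfProducts", "produces"))) {
      refs <- xml2::xml_find_all(rx, sprintf("./%s/speciesReference", side[1]))
      for (ref in refs) {
        cid <- unescape_sbml_id(strip_prefix(node_attr(ref, "species"), "M_"))
        st <- node_attr(ref, "stoichiometry")
        coef <- if (is.na(st)) "1" else st
        if (!has_entity(model, cid))
          model <- add_entity(model, gsm_entity(cid, "compound"))
        model <- add_relation(model, rid, side[2], cid,
                              list(coefficient = coef))
      }
    }
    genes <- character(0)
    for (ref in xml2::xml_find_all(rx, ".//*[local-name()='geneProductRef']")) {
      gid <- node_attr(ref, "geneProduct")
      lab <- gene_labels[[gid]]
      genes <- c(genes, if (!is.null(lab)) lab
                 else unescape_sbml_id(strip_prefix(gid, "G_")))
    }
    if (!is.na(rule) && nzchar(rule)) genes <- c(genes, gene_tokens(rule))
    for (g in unique(genes)) {
      if (!has_entity(model, g)) model <- add_entity(model, gsm_entity(g, "gene"))
      model <- add_relation(model, g, "is_linked_to", rid)
    }
    for (line in grep("^SUBSYSTEM\\s*:", notes, value = TRUE)) {
      pwy <- trimws(sub("^SUBSYSTEM\\s*:", "", line))
      if (!nzchar(pwy)) next
      if (!has_entity(model, pwy)) model <- add_entity(model, gsm_entity(pwy, "pathway"))
      model <- add_relation(model, rid, "is_in_pathway", pwy)
    }
    pending_tags <- rbind(pending_tags, tags_from_notes(notes, rid))
  }

  if (nrow(pending_tags))
    for (i in seq_len(nrow(pending_tags)))
      if (has_entity(model, pending_tags$entity[i]))
        model <- add_tag(model, pending_tags[i, ])
  model
}
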