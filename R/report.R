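# Reporting: pathway completeness rates, provenance set algebra, quality
# checks (gene-association ratio, mass/charge balance).

#' Pathway completeness report
#'
#' For every pathway defined in the reference (`is_in_pathway` relations in
#' `pathway_defs`), counts how many of its member reactions are present in
#' the model and reports the completion rate. A defined reaction also counts
#' as present when the model holds an instantiated variant of it (a reaction
#' whose `instance-of` attribute names it), since databases write generic
#' class reactions that reconstructions legitimately carry in instantiated
#' form. Pathways defining zero reactions are excluded and reported.
#'
#' @param model the `gsm_model` under evaluation.
#' @param pathway_defs a `gsm_model` whose `is_in_pathway` relations define
#'   the reference pathways.
#' @return a `gsm_completeness` object: `table` (pathway, total, present,
#'   ratio; sorted by decreasing ratio then id), `missing` (named list of
#'   missing reaction ids per pathway), `excluded` (empty pathways).
#' @export
pathway_completeness <- function(model, pathway_defs) {
  members <- list()
  for (r in pathway_defs$relations)
    if (r$rtype == "is_in_pathway")
      members[[r$object]] <- unique(c(members[[r$object]], r$subject))
  pathways <- entity_ids(pathway_defs, "pathway")
  excluded <- sort_c(setdiff(pathways, names(members)))
  model_rids <- entity_ids(model, "reaction")
  instance_parents <- unique(unlist(lapply(model_rids, function(rid)
    model$entities[[rid]]$attributes[["instance-of"]])))
  rows <- list(); missing <- list()
  for (pwy in sort_c(names(members))) {
    defined <- sort_c(members[[pwy]])
    is_present <- defined %in% model_rids | defined %in% instance_parents
    rows[[pwy]] <- data.frame(pathway = pwy, total = length(defined),
                              present = sum(is_present),
                              ratio = sum(is_present) / length(defined),
                              stringsAsFactors = FALSE)
    missing[[pwy]] <- defined[!is_present]
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(pathway = character(0), total = integer(0),
                      present = integer(0), ratio = numeric(0))
  tab <- tab[order(-tab$ratio, tab$pathway, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, missing = missing, excluded = excluded),
            class = "gsm_completeness")
}

#' @export
print.gsm_completeness <- function(x, ...) {
  cat("<gsm_completeness>\n")
  tab <- x$table
  tab$ratio <- sprintf("%.2f", tab$ratio)
  print(tab, row.names = FALSE)
  if (length(x$excluded))
    cat("excluded (no defined reactions):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Provenance breakdown by reconstruction category, tool or source
#'
#' Exact set algebra over tagged entities: how many distinct entities each
#' tag group contributed, the pairwise overlap matrix between groups, the
#' exclusive counts (entities tagged by exactly one group) and the union.
#' Counts always publish overlaps explicitly — groups are not assumed
#' disjoint, since one entity is typically found by several methods.
#'
#' @param model a tagged `gsm_model`.
#' @param key `"category"`, `"tool"` or `"source"`.
#' @param etype optional entity-type filter (e.g. `"reaction"`).
#' @return a `gsm_breakdown`: `counts` (named), `overlap` (symmetric
#'   matrix), `exclusive` (named), `union` (distinct entities across groups).
#' @export
provenance_breakdown <- function(model, key = c("category", "tool", "source"),
                                 etype = NULL) {
  key <- match.arg(key)
  tags <- model$tags
  if (!is.null(etype)) {
    keep_ids <- entity_ids(model, etype)
    tags <- tags[tags$entity %in% keep_ids, , drop = FALSE]
  }
  groups <- sort_c(unique(tags[[key]]))
  sets <- lapply(groups, function(g) unique(tags$entity[tags[[key]] == g]))
  names(sets) <- groups
  counts <- vapply(sets, length, integer(1))
  overlap <- matrix(0L, length(groups), length(groups),
                    dimnames = list(groups, groups))
  for (i in seq_along(groups))
    for (j in seq_along(groups))
      overlap[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  all_entities <- unique(unlist(sets))
  n_groups_of <- vapply(all_entities, function(e)
    sum(vapply(sets, function(s) e %in% s, logical(1))), integer(1))
  exclusive <- vapply(groups, function(g)
    sum(all_entities[n_groups_of == 1L] %in% sets[[g]]), integer(1))
  structure(list(key = key, etype = etype, counts = counts, overlap = overlap,
                 exclusive = exclusive, union = length(all_entities),
                 sets = sets),
            class = "gsm_breakdown")
}

#' @export
print.gsm_breakdown <- function(x, ...) {
  cat(sprintf("<gsm_breakdown> by %s%s: %d distinct entities\n", x$key,
              if (!is.null(x$etype)) paste0(" (", x$etype, ")") else "", x$union))
  for (g in names(x$counts))
    cat(sprintf("  %-14s %5d total, %5d exclusive\n", g, x$counts[[g]],
                x$exclusive[[g]]))
  invisible(x)
}

# ---- quality --------------------------------------------------------------

KNOWN_ELEMENTS <- c("C", "H", "N", "O", "P", "S", "Na", "K", "Cl", "Mg", "Ca",
                    "Fe", "Zn", "Mn", "Cu", "Co", "Ni", "Se", "Mo", "I", "Br",
                    "F", "B", "Si", "As", "W", "Li")

#' Parse a Hill-notation chemical formula
#'
#' @param formula e.g. `"C6H12O6"`.
#' @return named numeric vector of element counts, or NULL when the formula
#'   is not a plain element-count string (polymer `n`, `R`-groups,
#'   parentheses, unknown element symbols) and balance is undetermined.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) return(NULL)
  counts <- numeric(0)
  for (tok in regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% KNOWN_ELEMENTS) return(NULL)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0) + n
  }
  counts
}

#' Model quality report
#'
#' Computes the percentage of (non-exchange) reactions with at least one gene
#' link, the mass-unbalanced reactions with per-element deltas (sum of
#' coefficient-weighted formula counts over products minus reactants; a zero
#' vector means balanced), the charge-unbalanced reactions, and entity
#' counts. A reaction with any participant lacking a parseable formula (or
#' charge) is reported `undetermined`, never silently `balanced`.
#'
#' @param model a `gsm_model`.
#' @param exclude_exchange drop boundary/exchange reactions from the
#'   gene-ratio denominator (default TRUE).
#' @return a `gsm_quality` object.
#' @export
quality_report <- function(model, exclude_exchange = TRUE) {
  rids <- entity_ids(model, "reaction")
  is_exchange <- vapply(rids, function(rid) {
    if (identical(entity_attr1(model, rid, "boundary"), "true") ||
        identical(entity_attr1(model, rid, "exchange"), "true")) return(TRUE)
    sides <- reaction_sides(model, rid)
    length(sides$reactants) == 0 || length(sides$products) == 0
  }, logical(1))
  considered <- if (exclude_exchange) rids[!is_exchange] else rids
  linked <- unique(unlist(lapply(model$relations, function(r)
    if (r$rtype == "is_linked_to") r$object)))
  n_linked <- sum(considered %in% linked)
  gene_ratio <- if (length(considered))
    round(100 * n_linked / length(considered), 1) else NA_real_

  mass_unbalanced <- list(); charge_unbalanced <- numeric(0)
  undetermined <- character(0)
  for (rid in rids) {
    sides <- reaction_sides(model, rid)
    parts <- c(lapply(sides$reactants, c, sign = -1),
               lapply(sides$products, c, sign = 1))
    if (length(parts) == 0) next
    delta <- numeric(0); ok_mass <- TRUE
    charge <- 0; ok_charge <- TRUE
    for (p in parts) {
      f <- parse_formula(entity_attr1(model, p$id, "formula"))
      if (is.null(f)) {
        ok_mass <- FALSE
        undetermined[rid] <- sprintf("formula of '%s': %s", p$id,
                                     entity_attr1(model, p$id, "formula", "<absent>"))
      } else {
        for (el in names(f))
          delta[el] <- (if (el %in% names(delta)) delta[el] else 0) +
            p$sign * p$coef * f[[el]]
      }
      ch <- suppressWarnings(as.numeric(entity_attr1(model, p$id, "charge")))
      if (is.na(ch)) ok_charge <- FALSE
      else charge <- charge + p$sign * p$coef * ch
    }
    if (ok_mass) {
      delta <- delta[abs(delta) > 1e-9]
      if (length(delta)) mass_unbalanced[[rid]] <- delta
    }
    if (ok_charge && abs(charge) > 1e-9) charge_unbalanced[rid] <- charge
  }
  structure(list(
    gene_ratio = gene_ratio,
    n_considered = length(considered), n_gene_linked = n_linked,
    mass_unbalanced = mass_unbalanced,
    charge_unbalanced = charge_unbalanced,
    undetermined = undetermined,
    counts = c(reactions = length(rids),
               compounds = length(entity_ids(model, "compound")),
               genes = length(entity_ids(model, "gene")),
               pathways = length(entity_ids(model, "pathway")))
  ), class = "gsm_quality")
}

#' @export
print.gsm_quality <- function(x, ...) {
  cat("<gsm_quality>\n")
  cat(sprintf("  gene-association ratio: %s%% (%d/%d reactions)\n",
              x$gene_ratio, x$n_gene_linked, x$n_considered))
  cat(sprintf("  mass-unbalanced: %d, charge-unbalanced: %d, undetermined: %d\n",
              length(x$mass_unbalanced), length(x$charge_unbalanced),
              length(x$undetermined)))
  cat("  counts:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write the report suite as TSV files
#'
#' Emits `completeness.tsv`, `breakdown_<key>.tsv` for the three provenance
#' keys, and `quality.tsv` under `outdir`.
#'
#' @param model a `gsm_model`.
#' @param outdir output directory (created if needed).
#' @param pathway_defs optional reference pathways for the completeness
#'   report.
#' @return invisible character vector of files written.
#' @export
write_reports <- function(model, outdir, pathway_defs = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(pathway_defs)) {
    comp <- pathway_completeness(model, pathway_defs)
    tab <- comp$table
    tab$missing <- vapply(tab$pathway, function(p)
      paste(comp$missing[[p]], collapse = ","), character(1))
    f <- file.path(outdir, "completeness.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  for (key in c("category", "tool", "source")) {
    b <- provenance_breakdown(model, key)
    df <- data.frame(group = names(b$counts), entities = unname(b$counts),
                     exclusive = unname(b$exclusive), stringsAsFactors = FALSE)
    f <- file.path(outdir, paste0("breakdown_", key, ".tsv"))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  q <- quality_report(model)
  f <- file.path(outdir, "quality.tsv")
  lines <- c("metric\tvalue",
             paste0("gene_association_ratio\t", q$gene_ratio),
             paste0("mass_unbalanced\t", length(q$mass_unbalanced)),
             paste0("charge_unbalanced\t", length(q$charge_unbalanced)),
             paste0("undetermined\t", length(q$undetermined)),
             paste0(names(q$counts), "\t", q$counts))
  writeLines(lines, f)
  written <- c(written, f)
  invisible(written)
}
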