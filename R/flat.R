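# Flat attribute-based text dialect: tab-separated, UTF-8, LF endings.
# Three sections introduced by header lines [entities], [relations], [tags]
# (an optional leading [meta] section carries the model id and reference
# database). Within values, the characters %, TAB, LF, ';' and '=' are
# percent-encoded so any text round-trips.

flat_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x <- gsub("\n", "%0A", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  gsub("=", "%3D", x, fixed = TRUE)
}

flat_unescape <- function(x) {
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%0A", "\n", x, fixed = TRUE)
  x <- gsub("%09", "\t", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

# strsplit drops trailing empty fields; pad back to tab-count + 1 so empty
# trailing columns (e.g. an empty tag comment) survive.
split_tsv <- function(line) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  n <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))) + 1L
  c(fields, rep("", n - length(fields)))
}

format_attr_field <- function(attrs) {
  keys <- sort_c(names(attrs))
  parts <- character(0)
  for (k in keys)
    parts <- c(parts, paste0(flat_escape(k), "=", flat_escape(attrs[[k]])))
  paste(parts, collapse = ";")
}

parse_attr_field <- function(field, lineno) {
  attrs <- structure(list(), names = character(0))
  if (!nzchar(field)) return(attrs)
  for (pair in strsplit(field, ";", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", pair, fixed = TRUE)
    if (eq < 0)
      gsm_abort(sprintf("line %d: attribute '%s' lacks '='", lineno, pair),
                "gsm_parse_error")
    k <- flat_unescape(substr(pair, 1, eq - 1))
    v <- flat_unescape(substr(pair, eq + 1, nchar(pair)))
    attrs[[k]] <- c(attrs[[k]], v)
  }
  attrs
}

#' Write a model in the flat attribute-based dialect
#'
#' Output is canonical: entities sorted by id, relations by
#' (subject, rtype, object), tags by all key fields — so writing, re-reading
#' and writing again is byte-identical, which makes flat files diffable and
#' pipeline reruns verifiable by checksum.
#'
#' @param model a valid `gsm_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flat <- function(model, path) {
  validate_model(model)
  lines <- c("[meta]",
             paste0("model_id\t", flat_escape(model$meta$model_id)),
             paste0("ref_db\t", flat_escape(model$meta$ref_db)),
             paste0("ref_version\t", flat_escape(model$meta$ref_version)),
             "[entities]")
  for (id in entity_ids(model)) {
    e <- model$entities[[id]]
    lines <- c(lines, paste(flat_escape(e$id), e$etype,
                            format_attr_field(e$attributes), sep = "\t"))
  }
  lines <- c(lines, "[relations]")
  if (length(model$relations)) {
    keys <- vapply(model$relations, function(r)
      paste(r$subject, r$rtype, r$object, sep = "\r"), character(1))
    for (i in order_c(keys)) {
      r <- model$relations[[i]]
      lines <- c(lines, paste(flat_escape(r$subject), r$rtype,
                              flat_escape(r$object),
                              format_attr_field(r$attributes), sep = "\t"))
    }
  }
  lines <- c(lines, "[tags]")
  if (nrow(model$tags)) {
    t <- model$tags[order_c(model$tags$entity, model$tags$category,
                            model$tags$tool, model$tags$source,
                            model$tags$step, model$tags$comment), , drop = FALSE]
    lines <- c(lines, paste(flat_escape(t$entity), flat_escape(t$category),
                            flat_escape(t$tool), flat_escape(t$source),
                            t$step, flat_escape(t$comment), sep = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a model from the flat attribute-based dialect
#'
#' Malformed lines raise a parse error carrying the line number; a relation
#' or tag referencing an id not declared in the `[entities]` section raises
#' an integrity error listing the id.
#'
#' @param path file to read.
#' @return a `gsm_model`.
#' @export
read_flat <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  model <- gsm_model()
  section <- ""
  pending_relations <- list()
  pending_tags <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line %in% c("[meta]", "[entities]", "[relations]", "[tags]")) {
      section <- line
      next
    }
    fields <- split_tsv(line)
    if (section == "[meta]") {
      if (length(fields) < 1)
        gsm_abort(sprintf("line %d: malformed meta line", i), "gsm_parse_error")
      val <- if (length(fields) >= 2) flat_unescape(fields[2]) else ""
      key <- fields[1]
      if (key %in% c("model_id", "ref_db", "ref_version"))
        model$meta[[key]] <- val
    } else if (section == "[entities]") {
      if (length(fields) < 2 || length(fields) > 3)
        gsm_abort(sprintf("line %d: entity line needs 2-3 tab-separated fields, got %d",
                          i, length(fields)), "gsm_parse_error")
      attrs <- parse_attr_field(if (length(fields) == 3) fields[3] else "", i)
      model <- add_entity(model, gsm_entity(flat_unescape(fields[1]), fields[2], attrs))
    } else if (section == "[relations]") {
      if (length(fields) < 3 || length(fields) > 4)
        gsm_abort(sprintf("line %d: relation line needs 3-4 fields, got %d",
                          i, length(fields)), "gsm_parse_error")
      pending_relations[[length(pending_relations) + 1L]] <- list(
        subject = flat_unescape(fields[1]), rtype = fields[2],
        object = flat_unescape(fields[3]),
        attributes = parse_attr_field(if (length(fields) == 4) fields[4] else "", i),
        lineno = i)
    } else if (section == "[tags]") {
      if (length(fields) != 6)
        gsm_abort(sprintf("line %d: tag line needs 6 fields, got %d",
                          i, length(fields)), "gsm_parse_error")
      pending_tags[[length(pending_tags) + 1L]] <- list(fields = fields, lineno = i)
    } else {
      gsm_abort(sprintf("line %d: content before any section header", i),
                "gsm_parse_error")
    }
  }
  for (r in pending_relations) {
    for (e in c(r$subject, r$object))
      if (!has_entity(model, e))
        gsm_abort(sprintf("line %d: relation endpoint '%s' not declared in [entities]",
                          r$lineno, e), "gsm_integrity_error")
    model <- add_relation(model, r$subject, r$rtype, r$object, r$attributes)
  }
  for (t in pending_tags) {
    f <- t$fields
    ent <- flat_unescape(f[1])
    if (!has_entity(model, ent))
      gsm_abort(sprintf("line %d: tag references unknown entity '%s'",
                        t$lineno, ent), "gsm_integrity_error")
    step <- suppressWarnings(as.integer(f[5]))
    if (is.na(step))
      gsm_abort(sprintf("line %d: tag step '%s' is not an integer", t$lineno, f[5]),
                "gsm_parse_error")
    model <- add_tag(model, gsm_tag(ent, flat_unescape(f[2]), flat_unescape(f[3]),
                                    flat_unescape(f[4]), step, flat_unescape(f[6])))
  }
  model
}
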