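# Config-driven orchestration with a replayable run log. The pipeline never
# invokes external reconstruction tools: their SBML/TSV outputs are declared
# as step inputs, and the workspace records how they were chained.

PIPELINE_OPS <- c("read_sbml", "read_flat", "merge", "map_identifiers",
                  "gapfill", "curate", "write_flat", "write_sbml",
                  "export_matrix", "export_rdf", "report", "wiki")

#' Read and validate a pipeline configuration
#'
#' YAML with global keys `model_id`, `reference_db`, `workspace` (paths in
#' steps resolve relative to it) and `steps`, an ordered list of step blocks.
#' Each step has an `op` drawn from the registered set
#' (`r paste(PIPELINE_OPS, collapse = ", ")`), its input paths/parameters,
#' and for model-mutating steps the provenance to stamp (`category`, `tool`,
#' `source`). Unknown operations are rejected here, before any execution.
#'
#' @param path YAML file, or a list already parsed.
#' @return a validated `gsm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  config$model_id <- config$model_id %||% "model"
  config$reference_db <- config$reference_db %||% ""
  config$workspace <- config$workspace %||%
    (if (is.character(path)) dirname(path) else ".")
  config$steps <- config$steps %||% list()
  for (i in seq_along(config$steps)) {
    op <- config$steps[[i]]$op
    if (is.null(op) || !op %in% PIPELINE_OPS)
      gsm_abort(sprintf("step %d: unknown operation '%s'", i,
                        op %||% "<missing>"), "gsm_config_error")
  }
  structure(config, class = "gsm_pipeline_config")
}

digest_file <- function(path)
  if (file.exists(path)) unname(tools::md5sum(path)) else NA_character_

#' Run a reconstruction pipeline
#'
#' Executes the configured steps in order on a fresh model. Every
#' model-mutating step stamps its source tags with the step index, and every
#' step appends a run-log record (operation, parameters, md5 digests of the
#' input files, entity/reaction-count deltas, timestamp). Re-running an
#' identical configuration on identical inputs yields an identical final
#' model and identical log deltas — only timestamps differ. A failing step
#' halts the run; the error carries the partial log and the model state
#' reached so far (fields `log` and `model` of the condition).
#'
#' @param config path to a YAML config or a [read_pipeline_config()] result.
#' @param workspace optional override of the config's workspace directory.
#' @return list with `model` (final `gsm_model`) and `log` (data frame).
#' @export
run_pipeline <- function(config, workspace = NULL) {
  if (!inherits(config, "gsm_pipeline_config"))
    config <- read_pipeline_config(config)
  ws <- workspace %||% config$workspace
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(ws, p)
  model <- gsm_model(config$model_id, config$reference_db)
  log <- data.frame(step = integer(0), op = character(0), params = character(0),
                    inputs = character(0), d_entities = integer(0),
                    d_reactions = integer(0), timestamp = character(0),
                    stringsAsFactors = FALSE)
  n_ent <- function(m) length(m$entities)
  n_rxn <- function(m) length(entity_ids(m, "reaction"))
  for (i in seq_along(config$steps)) {
    s <- config$steps[[i]]
    before <- c(n_ent(model), n_rxn(model))
    inputs <- character(0)
    param_str <- paste(vapply(setdiff(names(s), "op"), function(k)
      paste0(k, "=", paste(s[[k]], collapse = ",")), character(1)),
      collapse = " ")
    res <- tryCatch({
      if (s$op %in% c("read_sbml", "read_flat", "merge")) {
        p <- resolve(s$path)
        inputs <- p
        addition <- if (s$op == "read_flat" || grepl("\\.(flat|tsv|txt)$", p))
          read_flat(p) else read_sbml(p)
        addition$meta$ref_db <- s$namespace %||% model$meta$ref_db
        model <- merge_models(model, addition,
                              category = s$category %||% "annotation",
                              tool = s$tool %||% "", source = s$source %||% "",
                              step = i)
      } else if (s$op == "map_identifiers") {
        p <- resolve(s$table)
        inputs <- p
        model <- map_identifiers(model, read_mapping_table(p))$model
      } else if (s$op == "gapfill") {
        dbp <- resolve(s$database)
        inputs <- c(dbp, resolve(s$seeds), resolve(s$targets))
        db <- if (grepl("\\.(flat|tsv|txt)$", dbp)) read_flat(dbp) else read_sbml(dbp)
        seeds <- read_compound_list(resolve(s$seeds))
        targets <- read_compound_list(resolve(s$targets))
        comp <- gapfill(model, db, seeds, targets,
                        max_size = s$max_size %||% 10,
                        enumerate = isTRUE(s$enumerate))
        model <- apply_completion(model, db, comp$solutions[[1]],
                                  tool = s$tool %||% "topological-gapfill",
                                  source = s$source %||% basename(dbp), step = i)
      } else if (s$op == "curate") {
        p <- resolve(s$forms)
        inputs <- p
        for (form in read_forms(p)) model <- apply_form(model, form, step = i)
      } else if (s$op == "write_flat") {
        write_flat(model, resolve(s$path))
      } else if (s$op == "write_sbml") {
        write_sbml(model, resolve(s$path), level = s$level %||% 3)
      } else if (s$op == "export_matrix") {
        export_matrix(model, resolve(s$path))
      } else if (s$op == "export_rdf") {
        export_rdf(model, resolve(s$path))
      } else if (s$op == "report") {
        defs <- if (!is.null(s$pathways)) {
          dp <- resolve(s$pathways)
          inputs <- dp
          if (grepl("\\.(flat|tsv|txt)$", dp)) read_flat(dp) else read_sbml(dp)
        } else NULL
        write_reports(model, resolve(s$out %||% "reports"), defs)
      } else if (s$op == "wiki") {
        generate_wiki(model, resolve(s$out %||% "wiki"))
      }
      NULL
    }, gsm_error = function(e) e)
    if (inherits(res, "condition")) {
      cond <- structure(class = c("gsm_pipeline_error", "gsm_error", "error",
                                  "condition"),
                        list(message = sprintf("step %d (%s) failed: %s", i,
                                               s$op, conditionMessage(res)),
                             call = NULL, log = log, model = model))
      stop(cond)
    }
    after <- c(n_ent(model), n_rxn(model))
    log <- rbind(log, data.frame(
      step = i, op = s$op, params = param_str,
      inputs = paste(stats::na.omit(vapply(inputs, digest_file, character(1))),
                     collapse = ","),
      d_entities = after[1] - before[1], d_reactions = after[2] - before[2],
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      stringsAsFactors = FALSE))
  }
  rownames(log) <- NULL
  list(model = model, log = log)
}

#' Human-readable pipeline run summary
#'
#' @param log the run-log data frame from [run_pipeline()].
#' @return character vector: one line per step plus totals (printed when the
#'   result is not assigned).
#' @export
describe_run <- function(log) {
  lines <- "step  operation         delta-entities  delta-reactions"
  for (i in seq_len(nrow(log)))
    lines <- c(lines, sprintf("%4d  %-16s %+15d %+16d", log$step[i], log$op[i],
                              log$d_entities[i], log$d_reactions[i]))
  if (nrow(log))
    lines <- c(lines, sprintf("total %-16s %+15d %+16d", "",
                              sum(log$d_entities), sum(log$d_reactions)))
  structure(lines, class = "gsm_run_summary")
}

#' @export
print.gsm_run_summary <- function(x, ...) {
  cat(paste(x, collapse = "\n"), "\n")
  invisible(x)
}
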