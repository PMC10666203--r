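# Problem-specification dialect: a yaml index naming an XML model document
# plus four tab-separated tables (parameters, conditions, measurements,
# summary statistics), in the PEtab lineage. Tables are UTF-8, tab-separated,
# '.' decimal, unquoted cells, mandatory header row.

PARAMETER_COLUMNS <- c("parameter_id", "prior_kind", "prior_arg1",
                       "prior_arg2", "scale", "estimate", "nominal_value",
                       "target_path")
MEASUREMENT_COLUMNS <- c("observable_id", "condition_id", "time", "value")
STATISTIC_COLUMNS <- c("statistic_id", "function_id", "args",
                       "observable_ids")
PRIOR_KINDS <- c("uniform", "log10-uniform", "normal")

# Restricted path grammar: child steps, [@name='...'] predicates, and a final
# /@attr or /text() selector. A deliberate subset of XPath.
.pathStep <- "[A-Za-z_][A-Za-z0-9_.-]*(\\[@[A-Za-z_][A-Za-z0-9_.-]*='[^']*'\\])?"
.pathRegex <- paste0("^/?", .pathStep, "(/", .pathStep, ")*",
                     "/(@[A-Za-z_][A-Za-z0-9_.-]*|text\\(\\))$")

isValidTargetPath <- function(path) {
  is.character(path) & !is.na(path) & grepl(.pathRegex, path)
}

# Split a target path into the element-locating part and the final selector.
splitTargetPath <- function(path) {
  if (grepl("/text\\(\\)$", path)) {
    list(element = sub("/text\\(\\)$", "", path), kind = "text", attr = NA_character_)
  } else {
    attr <- sub(".*/@([A-Za-z_][A-Za-z0-9_.-]*)$", "\\1", path)
    list(element = sub("/@[A-Za-z_][A-Za-z0-9_.-]*$", "", path), kind = "attr",
         attr = attr)
  }
}

findTargetNode <- function(doc, path) {
  parts <- splitTargetPath(path)
  if (startsWith(parts$element, "/")) {
    xml2::xml_find_first(doc, parts$element)
  } else {
    xml2::xml_find_first(xml2::xml_root(doc), paste0("./", parts$element))
  }
}

resolvesInDocument <- function(doc, path) {
  if (!isValidTargetPath(path)) return(FALSE)
  !inherits(findTargetNode(doc, path), "xml_missing")
}

setTargetValue <- function(doc, path, value) {
  node <- findTargetNode(doc, path)
  if (inherits(node, "xml_missing"))
    stop("mapping error: target path does not resolve: ", path,
         call. = FALSE)
  parts <- splitTargetPath(path)
  if (parts$kind == "attr") {
    xml2::xml_set_attr(node, parts$attr, value)
  } else {
    xml2::xml_set_text(node, value)
  }
  invisible(doc)
}

readTargetValue <- function(doc, path) {
  node <- findTargetNode(doc, path)
  if (inherits(node, "xml_missing")) return(NA_character_)
  parts <- splitTargetPath(path)
  if (parts$kind == "attr") xml2::xml_attr(node, parts$attr) else
    xml2::xml_text(node)
}

# Numbers are written with as many digits as needed to round-trip exactly,
# preferring the shortest representation.
formatNumber <- function(x) {
  out <- as.character(x)
  bad <- !is.na(x) & (as.numeric(out) != x)
  if (any(bad)) out[bad] <- formatC(x[bad], digits = 17, format = "g")
  out[is.na(x)] <- ""
  out
}

readTsvTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  names(df) <- trimws(names(df))
  df
}

asNum <- function(x) suppressWarnings(as.numeric(x))

reportEntry <- function(severity, code, message) {
  data.frame(severity = severity, code = code, message = message,
             stringsAsFactors = FALSE)
}

emptyReport <- function() {
  data.frame(severity = character(), code = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Parse a problem bundle
#'
#' Reads the yaml index file (keys `model_file`, `parameter_file`,
#' `condition_file`, `measurement_file`, `statistic_file`, relative paths),
#' loads the XML model document and the four tab-separated tables, and
#' cross-links them into a [ProblemSpec-class]. Unknown columns are
#' preserved but ignored. Problems are collected and raised together in a
#' single classed condition (`problemParseError`) whose `report` field
#' holds one entry per defect; I/O errors name the path, schema errors name
#' table and column, link errors name both identifiers.
#'
#' @param indexPath path to the yaml index file.
#' @param strict if `TRUE` (default), dangling cross-references are fatal
#'   at parse time; with `FALSE` they are left for [validateProblem()] to
#'   report, which is what [validateBundle()] uses.
#' @return A [ProblemSpec-class].
#' @examples
#' bundle <- makeGaussianToy(file.path(tempdir(), "toy"))
#' prob <- parseProblem(bundle$index)
#' prob
#' @export
parseProblem <- function(indexPath, strict = TRUE) {
  issues <- emptyReport()
  if (!file.exists(indexPath)) {
    stop(problemCondition("problemIOError",
                          paste0("I/O error: missing file: ", indexPath),
                          reportEntry("error", "MISSING_FILE", indexPath)))
  }
  index <- yaml::read_yaml(indexPath)
  dir <- dirname(normalizePath(indexPath))
  need <- c("model_file", "parameter_file", "condition_file",
            "measurement_file", "statistic_file")
  missingKeys <- setdiff(need, names(index))
  if (length(missingKeys))
    stop(problemCondition("problemSchemaError",
                          paste0("schema error: index missing keys: ",
                                 paste(missingKeys, collapse = ", ")),
                          reportEntry("error", "MISSING_INDEX_KEY", missingKeys)))
  paths <- vapply(index[need], function(p) file.path(dir, p), character(1))
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop(problemCondition("problemIOError",
                          paste0("I/O error: missing file: ",
                                 paste(absent, collapse = ", ")),
                          reportEntry("error", "MISSING_FILE", absent)))

  model <- xml2::read_xml(paths[["model_file"]])
  tabs <- lapply(paths[need[-1]], readTsvTable)
  names(tabs) <- c("parameter_table", "condition_table",
                   "measurement_table", "statistic_table")

  required <- list(parameter_table = PARAMETER_COLUMNS,
                   condition_table = "condition_id",
                   measurement_table = MEASUREMENT_COLUMNS,
                   statistic_table = STATISTIC_COLUMNS)
  for (tb in names(required)) {
    miss <- setdiff(required[[tb]], names(tabs[[tb]]))
    if (length(miss))
      issues <- rbind(issues, reportEntry(
        "error", "MISSING_COLUMN", paste0(tb, ": ", miss)))
  }
  if (nrow(issues))
    stop(problemCondition("problemSchemaError",
                          paste0("schema error: ",
                                 paste(issues$message, collapse = "; ")),
                          issues))

  par <- tabs$parameter_table
  par$prior_arg1 <- asNum(par$prior_arg1)
  par$prior_arg2 <- asNum(par$prior_arg2)
  par$nominal_value <- asNum(par$nominal_value)
  par$estimate <- par$estimate %in% c("1", "true", "TRUE", "True")

  meas <- tabs$measurement_table
  meas$time <- asNum(meas$time)
  meas$value <- asNum(meas$value)
  if (!"data_ref" %in% names(meas)) meas$data_ref <- ""
  if (!"replicate_id" %in% names(meas)) meas$replicate_id <- ""

  prob <- new("ProblemSpec", model = model, parameters = par,
              conditions = tabs$condition_table, measurements = meas,
              statistics = tabs$statistic_table, directory = dir)

  if (strict) {
    rep <- validateProblem(prob)
    links <- rep[rep$code %in% c("DANGLING_CONDITION", "DANGLING_OBSERVABLE"), ,
                 drop = FALSE]
    if (nrow(links))
      stop(problemCondition("problemLinkError",
                            paste0("link error: ",
                                   paste(links$message, collapse = "; ")),
                            links))
  }
  prob
}

problemCondition <- function(class, message, report) {
  structure(class = c(class, "problemError", "error", "condition"),
            list(message = message, call = NULL, report = report))
}

#' Validate a parsed problem
#'
#' Checks every invariant of the problem dialect and returns a report
#' data.frame (`severity`, `code`, `message`) rather than raising: an empty
#' report means the problem is valid. The report is deterministic, ordered
#' by table and then row.
#'
#' Error codes: `DUPLICATE_PARAMETER_ID`, `PRIOR_KIND`, `PRIOR_BOUNDS`
#' (uniform kinds need arg1 < arg2), `PRIOR_POSITIVITY` (log10-uniform
#' needs arg1 > 0), `PATH_UNRESOLVED`, `DUPLICATE_CONDITION_ID`,
#' `DANGLING_CONDITION`, `MEASUREMENT_VALUE_XOR` (exactly one of
#' value/data_ref), `DATA_REF_MISSING`, `UNKNOWN_STATISTIC`,
#' `NO_ESTIMATED_PARAMETER`, `NO_MEASUREMENT`.
#'
#' @param p a [ProblemSpec-class].
#' @return data.frame with columns `severity`, `code`, `message`.
#' @export
validateProblem <- function(p) {
  rep <- emptyReport()
  par <- p@parameters

  dup <- unique(par$parameter_id[duplicated(par$parameter_id)])
  for (id in dup)
    rep <- rbind(rep, reportEntry("error", "DUPLICATE_PARAMETER_ID",
                                  paste0("parameter_table: duplicate id ", id)))
  for (i in seq_len(nrow(par))) {
    row <- par[i, ]
    if (row$estimate && !row$prior_kind %in% PRIOR_KINDS) {
      rep <- rbind(rep, reportEntry("error", "PRIOR_KIND",
        paste0("parameter_table row ", i, " (", row$parameter_id,
               "): unknown prior_kind '", row$prior_kind, "'")))
    } else if (row$estimate) {
      if (row$prior_kind %in% c("uniform", "log10-uniform") &&
          (is.na(row$prior_arg1) || is.na(row$prior_arg2) ||
           row$prior_arg1 >= row$prior_arg2))
        rep <- rbind(rep, reportEntry("error", "PRIOR_BOUNDS",
          paste0("parameter_table row ", i, " (", row$parameter_id,
                 "): uniform priors need prior_arg1 < prior_arg2")))
      if (row$prior_kind == "log10-uniform" &&
          !is.na(row$prior_arg1) && row$prior_arg1 <= 0)
        rep <- rbind(rep, reportEntry("error", "PRIOR_POSITIVITY",
          paste0("parameter_table row ", i, " (", row$parameter_id,
                 "): log10-uniform needs prior_arg1 > 0")))
      if (row$prior_kind == "normal" &&
          (is.na(row$prior_arg2) || row$prior_arg2 <= 0))
        rep <- rbind(rep, reportEntry("error", "PRIOR_BOUNDS",
          paste0("parameter_table row ", i, " (", row$parameter_id,
                 "): normal prior needs sd > 0")))
    }
    if (!row$estimate && is.na(row$nominal_value))
      rep <- rbind(rep, reportEntry("error", "MISSING_NOMINAL",
        paste0("parameter_table row ", i, " (", row$parameter_id,
               "): estimate=false rows need a nominal_value")))
    if (!isTRUE(row$scale %in% c("lin", "log10")))
      rep <- rbind(rep, reportEntry("error", "BAD_SCALE",
        paste0("parameter_table row ", i, " (", row$parameter_id,
               "): scale must be lin or log10")))
    if (!resolvesInDocument(p@model, row$target_path))
      rep <- rbind(rep, reportEntry("error", "PATH_UNRESOLVED",
        paste0("parameter_table row ", i, " (", row$parameter_id,
               "): target_path does not resolve: ", row$target_path)))
  }
  if (!any(par$estimate))
    rep <- rbind(rep, reportEntry("error", "NO_ESTIMATED_PARAMETER",
                                  "parameter_table: no estimated parameter"))

  con <- p@conditions
  dup <- unique(con$condition_id[duplicated(con$condition_id)])
  for (id in dup)
    rep <- rbind(rep, reportEntry("error", "DUPLICATE_CONDITION_ID",
                                  paste0("condition_table: duplicate id ", id)))
  overrideCols <- setdiff(names(con), "condition_id")
  for (cl in overrideCols) {
    if (!any(nzchar(con[[cl]]))) next
    if (!resolvesInDocument(p@model, cl))
      rep <- rbind(rep, reportEntry("error", "PATH_UNRESOLVED",
        paste0("condition_table: override path does not resolve: ", cl)))
  }

  meas <- p@measurements
  for (i in seq_len(nrow(meas))) {
    row <- meas[i, ]
    hasValue <- !is.na(row$value)
    hasRef <- nzchar(row$data_ref)
    if (hasValue == hasRef)
      rep <- rbind(rep, reportEntry("error", "MEASUREMENT_VALUE_XOR",
        paste0("measurement_table row ", i,
               ": exactly one of value/data_ref must be set")))
    if (hasRef && !is.na(p@directory) &&
        !file.exists(file.path(p@directory, row$data_ref)))
      rep <- rbind(rep, reportEntry("error", "DATA_REF_MISSING",
        paste0("measurement_table row ", i, ": data_ref file not found: ",
               row$data_ref)))
    if (!row$condition_id %in% con$condition_id)
      rep <- rbind(rep, reportEntry("error", "DANGLING_CONDITION",
        paste0("measurement_table row ", i, ": condition_id '",
               row$condition_id, "' not in condition table")))
    if (is.na(row$time) || row$time < 0)
      rep <- rbind(rep, reportEntry("error", "BAD_TIME",
        paste0("measurement_table row ", i, ": time must be a number >= 0")))
  }
  if (!nrow(meas))
    rep <- rbind(rep, reportEntry("error", "NO_MEASUREMENT",
                                  "measurement_table: no measurement"))

  stat <- p@statistics
  for (i in seq_len(nrow(stat))) {
    row <- stat[i, ]
    if (!row$function_id %in% names(statisticRegistry)) {
      rep <- rbind(rep, reportEntry("error", "UNKNOWN_STATISTIC",
        paste0("statistic_table row ", i, " (", row$statistic_id,
               "): unknown function_id '", row$function_id, "'")))
      next
    }
    argErr <- tryCatch({
      checkStatisticArgs(row$function_id, parseStatisticArgs(row$args))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(argErr))
      rep <- rbind(rep, reportEntry("error", "BAD_STATISTIC_ARGS",
        paste0("statistic_table row ", i, " (", row$statistic_id, "): ",
               argErr)))
  }
  rownames(rep) <- NULL
  rep
}

#' Validate a problem bundle on disk
#'
#' Convenience wrapper combining [parseProblem()] (non-strict) and
#' [validateProblem()]: parse-level defects (missing files, missing
#' columns) become report entries instead of errors, so every bundle in a
#' corpus yields a report.
#'
#' @param indexPath path to the yaml index file.
#' @return A validation report data.frame; empty iff the bundle is valid.
#' @export
validateBundle <- function(indexPath) {
  prob <- tryCatch(parseProblem(indexPath, strict = FALSE),
                   problemError = function(e) e)
  if (inherits(prob, "condition")) return(prob$report)
  validateProblem(prob)
}

#' Sampling space of the estimated parameters
#'
#' Bridges the parameter table to the sampler: one row per estimated
#' parameter, in table order, with prior bounds expressed on the declared
#' sampling scale (log10-uniform bounds are log10-transformed; normal
#' priors are unbounded).
#'
#' @param p a [ProblemSpec-class].
#' @return data.frame with columns `parameter_id`, `lower`, `upper`,
#'   `scale`.
#' @export
sampleSpace <- function(p) {
  par <- p@parameters[p@parameters$estimate, , drop = FALSE]
  lower <- upper <- numeric(nrow(par))
  for (i in seq_len(nrow(par))) {
    row <- par[i, ]
    if (row$prior_kind == "uniform") {
      lower[i] <- row$prior_arg1; upper[i] <- row$prior_arg2
    } else if (row$prior_kind == "log10-uniform") {
      lower[i] <- log10(row$prior_arg1); upper[i] <- log10(row$prior_arg2)
    } else {
      lower[i] <- -Inf; upper[i] <- Inf
    }
  }
  data.frame(parameter_id = par$parameter_id, lower = lower, upper = upper,
             scale = par$scale, stringsAsFactors = FALSE)
}

#' Map a parameter vector into the model document
#'
#' Returns a deep copy of the model document with (i) the condition's
#' overrides applied, then (ii) each estimated parameter's value written at
#' its target path. Values of log10-scaled parameters are back-transformed
#' (`10^theta`) before writing. The input document is never modified; the
#' operation is pure and deterministic.
#'
#' @param p a [ProblemSpec-class].
#' @param theta numeric vector on the sampling scale, one entry per
#'   estimated parameter (table order); may be named.
#' @param conditionId condition to apply (default: first condition).
#' @return An `xml2` document copy.
#' @export
mapParameters <- function(p, theta, conditionId = NULL) {
  par <- p@parameters[p@parameters$estimate, , drop = FALSE]
  if (length(theta) != nrow(par))
    stop("theta must have one entry per estimated parameter (",
         nrow(par), "), got ", length(theta))
  con <- p@conditions
  if (is.null(conditionId)) conditionId <- con$condition_id[1]
  if (!conditionId %in% con$condition_id)
    stop("unknown condition: ", conditionId)

  doc <- xml2::read_xml(charToRaw(as.character(p@model)))

  row <- con[match(conditionId, con$condition_id), , drop = FALSE]
  for (cl in setdiff(names(con), "condition_id")) {
    val <- row[[cl]]
    if (nzchar(val)) setTargetValue(doc, cl, val)
  }
  for (i in seq_len(nrow(par))) {
    value <- theta[[i]]
    if (par$scale[i] == "log10") value <- 10^value
    setTargetValue(doc, par$target_path[i], formatNumber(value))
  }
  doc
}

#' Write a problem bundle to disk
#'
#' Serialises a [ProblemSpec-class] back to the yaml + tsv + xml on-disk
#' layout. [parseProblem()] on the result reconstructs an equal problem
#' (table order and values preserved).
#'
#' @param p a [ProblemSpec-class].
#' @param dir output directory (created if needed).
#' @param indexName file name for the yaml index.
#' @return The path to the written index file, invisibly.
#' @export
writeProblem <- function(p, dir, indexName = "problem.yaml") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(model_file = "model.xml", parameter_file = "parameters.tsv",
             condition_file = "conditions.tsv",
             measurement_file = "measurements.tsv",
             statistic_file = "statistics.tsv")
  xml2::write_xml(p@model, file.path(dir, files[["model_file"]]))

  writeTab <- function(df, path, numeric = character()) {
    out <- df
    for (cl in intersect(numeric, names(out))) out[[cl]] <- formatNumber(out[[cl]])
    if ("estimate" %in% names(out)) out$estimate <- as.integer(out$estimate)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  writeTab(p@parameters, file.path(dir, files[["parameter_file"]]),
           numeric = c("prior_arg1", "prior_arg2", "nominal_value"))
  writeTab(p@conditions, file.path(dir, files[["condition_file"]]))
  writeTab(p@measurements, file.path(dir, files[["measurement_file"]]),
           numeric = c("time", "value"))
  writeTab(p@statistics, file.path(dir, files[["statistic_file"]]))

  # copy referenced data files alongside the tables
  refs <- unique(p@measurements$data_ref[nzchar(p@measurements$data_ref)])
  for (r in refs) {
    src <- file.path(p@directory, r)
    if (!is.na(p@directory) && file.exists(src) &&
        normalizePath(src, mustWork = FALSE) !=
        normalizePath(file.path(dir, r), mustWork = FALSE)) {
      dir.create(dirname(file.path(dir, r)), recursive = TRUE,
                 showWarnings = FALSE)
      file.copy(src, file.path(dir, r), overwrite = TRUE)
    }
  }
  idx <- file.path(dir, indexName)
  yaml::write_yaml(as.list(files), idx)
  invisible(idx)
}

#' Fingerprint of a problem bundle
#'
#' md5 digest of the canonically re-serialised bundle, recorded in every
#' [ResultStore-class] so results can be matched to the exact problem they
#' came from.
#'
#' @param p a [ProblemSpec-class].
#' @return A character md5 string.
#' @export
problemFingerprint <- function(p) {
  tmp <- file.path(tempdir(), paste0("fingerprint-", Sys.getpid()))
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  writeProblem(p, tmp)
  files <- sort(list.files(tmp, recursive = TRUE, full.names = TRUE))
  joined <- tempfile()
  on.exit(unlink(joined), add = TRUE)
  con <- file(joined, "wb")
  for (f in files) writeBin(readBin(f, "raw", file.size(f)), con)
  close(con)
  unname(tools::md5sum(joined))
}

# Equality helper used by round-trip tests and store fingerprints.
problemsEqual <- function(a, b) {
  eqTab <- function(x, y) {
    if (!identical(dim(x), dim(y)) || !identical(names(x), names(y)))
      return(FALSE)
    for (cl in names(x)) {
      xx <- x[[cl]]; yy <- y[[cl]]
      ok <- if (is.numeric(xx)) isTRUE(all.equal(xx, yy, tolerance = 0)) else
        identical(as.character(xx), as.character(yy))
      if (!ok) return(FALSE)
    }
    TRUE
  }
  identical(as.character(a@model), as.character(b@model)) &&
    eqTab(a@parameters, b@parameters) && eqTab(a@conditions, b@conditions) &&
    eqTab(a@measurements, b@measurements) && eqTab(a@statistics, b@statistics)
}

#' Read a gridded-array reference
#'
#' Loads a `data_ref` file (a CSV matrix, one 2-D array per file, row-major)
#' relative to the bundle directory.
#'
#' @param p a [ProblemSpec-class].
#' @param ref the `data_ref` string from the measurement table.
#' @return A numeric matrix.
#' @export
readGriddedArray <- function(p, ref) {
  path <- file.path(p@directory, ref)
  if (!file.exists(path)) stop("data_ref file not found: ", path)
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
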