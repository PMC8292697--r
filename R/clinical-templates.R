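# Discrete clinical templates across the radiotherapy workflow
# (consult -> simulation directive -> on-treatment -> end-of-treatment ->
# follow-up), with validation, derived-field calculation (NCCN risk),
# auto-population between templates, and narrative round-tripping.
#
# Schemas, vocabularies (AJCC, CTCAE, ...), the NCCN rule table and the
# field-flow map are versioned JSON configuration, not code.

.TEMPLATE_ORDER <- c("CONSULT", "SIM_DIRECTIVE", "OTV", "EOT", "FOLLOWUP")

rtqa_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "rtqa")
  if (!nzchar(p)) stop("missing packaged config file: ",
                       file.path(...))
  p
}

.schema_cache <- new.env(parent = emptyenv())

#' Load the template schema catalogue
#' @param path schema JSON (default: the packaged catalogue)
#' @param vocab_path vocabulary JSON (default: packaged)
#' @return list with `schemas` (keyed "SITE.TEMPLATE") and `vocabularies`
#' @export
load_template_catalogue <- function(path = rtqa_extdata("templates", "schemas.json"),
                                    vocab_path = rtqa_extdata("templates", "vocabularies.json")) {
  key <- paste(path, vocab_path, sep = "|")
  if (!is.null(.schema_cache[[key]])) return(.schema_cache[[key]])
  raw <- jsonlite::read_json(path)
  vocab <- jsonlite::read_json(vocab_path)
  schemas <- list()
  for (s in raw$schemas) {
    s$fields <- lapply(s$fields, function(f) f)
    names(s$fields) <- vapply(s$fields, function(f) f$name, character(1))
    if (anyDuplicated(names(s$fields)))
      rtqa_error("duplicate field names in schema", "rtqa_config_error")
    class(s) <- "rt_template_schema"
    schemas[[paste(s$disease_site, s$template_id, sep = ".")]] <- s
  }
  out <- list(schemas = schemas, vocabularies = vocab$vocabularies,
              version = raw$version)
  .schema_cache[[key]] <- out
  out
}

#' Fetch one template schema
#' @param disease_site "PROSTATE" or "LUNG"
#' @param template_id one of CONSULT, SIM_DIRECTIVE, OTV, EOT, FOLLOWUP
#' @param catalogue result of [load_template_catalogue()]
#' @return an `rt_template_schema`
#' @export
template_schema <- function(disease_site, template_id,
                            catalogue = load_template_catalogue()) {
  if (!template_id %in% .TEMPLATE_ORDER)
    rtqa_error(paste("unknown template_id:", template_id), "rtqa_config_error")
  s <- catalogue$schemas[[paste(disease_site, template_id, sep = ".")]]
  if (is.null(s))
    rtqa_error(paste("no schema for", disease_site, template_id),
               "rtqa_config_error")
  s
}

.vocab_values <- function(vocab_key, catalogue) {
  v <- catalogue$vocabularies[[vocab_key]]
  if (is.null(v)) rtqa_error(paste("unknown vocabulary:", vocab_key),
                             "rtqa_config_error")
  unlist(v$values)
}

.check_field_value <- function(f, value, catalogue) {
  # returns NULL if fine, else a message
  if (f$type %in% c("number", "integer")) {
    if (!is.numeric(value)) return(sprintf("%s must be numeric", f$name))
    if (f$type == "integer" && value != round(value))
      return(sprintf("%s must be an integer", f$name))
    if (!is.null(f$min) && value < f$min)
      return(sprintf("%s out of range (%.4g < %.4g)", f$name, value, f$min))
    if (!is.null(f$max) && value > f$max)
      return(sprintf("%s out of range (%.4g > %.4g)", f$name, value, f$max))
  } else if (f$type == "vocab") {
    vv <- .vocab_values(f$vocabulary, catalogue)
    if (!as.character(value) %in% vv)
      return(sprintf("%s not in vocabulary %s: %s", f$name, f$vocabulary,
                     as.character(value)))
  } else if (f$type == "boolean") {
    if (!is.logical(value)) return(sprintf("%s must be logical", f$name))
  } else if (f$type == "date") {
    if (is.na(suppressWarnings(as.Date(value))))
      return(sprintf("%s is not a valid date", f$name))
  }
  NULL
}

#' Validate one encounter of a record against its template schema
#'
#' Missing required fields and range/vocabulary violations are ERRORs;
#' missing optional fields and fields unknown to the schema are WARNINGs.
#' An empty result means the encounter is clean.
#'
#' @param record an `rt_patient_record`
#' @param schema an `rt_template_schema`
#' @param catalogue schema catalogue (for vocabularies)
#' @return data.frame(field, severity, message)
#' @export
validate_record <- function(record, schema,
                            catalogue = load_template_catalogue()) {
  if (!identical(record$disease_site, schema$disease_site))
    rtqa_error("record disease_site does not match schema", "rtqa_config_error")
  enc <- record$encounters[[schema$template_id]]
  issues <- list()
  add <- function(field, severity, message)
    issues[[length(issues) + 1L]] <<- data.frame(field = field,
                                                 severity = severity,
                                                 message = message)
  fields <- if (is.null(enc)) list() else enc$fields
  for (f in schema$fields) {
    v <- fields[[f$name]]
    if (is.null(v)) {
      if (isTRUE(f$required)) add(f$name, "ERROR",
                                  sprintf("required field %s missing", f$name))
      else add(f$name, "WARNING", sprintf("optional field %s missing", f$name))
      next
    }
    msg <- .check_field_value(f, v, catalogue)
    if (!is.null(msg)) add(f$name, "ERROR", msg)
  }
  for (nm in names(fields))
    if (!nm %in% names(schema$fields))
      add(nm, "WARNING", sprintf("field %s unknown to schema", nm))
  if (!length(issues))
    return(data.frame(field = character(), severity = character(),
                      message = character()))
  do.call(rbind, issues)
}

#' Validate every encounter of a record
#' @param record an `rt_patient_record`
#' @param catalogue schema catalogue
#' @return data.frame(template, field, severity, message)
#' @export
validate_patient_record <- function(record,
                                    catalogue = load_template_catalogue()) {
  out <- list()
  for (tid in names(record$encounters)) {
    schema <- template_schema(record$disease_site, tid, catalogue)
    iss <- validate_record(record, schema, catalogue)
    if (nrow(iss)) out[[tid]] <- cbind(template = tid, iss)
  }
  if (!length(out))
    return(data.frame(template = character(), field = character(),
                      severity = character(), message = character()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' NCCN risk group for clinically localized prostate cancer
#'
#' Three-tier rule, encoded as versioned configuration: LOW iff T <= T2a and
#' Gleason sum <= 6 and PSA < 10 ng/mL; HIGH iff T >= T3a or Gleason
#' sum >= 8 or PSA > 20 ng/mL; otherwise INTERMEDIATE.
#'
#' @param t_stage AJCC clinical T label (e.g. "T1c")
#' @param gleason_primary,gleason_secondary Gleason components (3-5)
#' @param psa PSA in ng/mL
#' @param config rule table (default: packaged)
#' @return "LOW", "INTERMEDIATE" or "HIGH"
#' @export
compute_nccn_risk <- function(t_stage, gleason_primary, gleason_secondary, psa,
                              config = jsonlite::read_json(
                                rtqa_extdata("nccn_risk.json"))) {
  t_order <- unlist(config$t_order)
  ti <- match(t_stage, t_order)
  if (is.na(ti)) rtqa_error(paste("unknown T stage label:", t_stage),
                            "rtqa_domain_error")
  if (gleason_primary < 3 || gleason_primary > 5 ||
      gleason_secondary < 3 || gleason_secondary > 5)
    rtqa_error("Gleason components must lie in 3-5", "rtqa_domain_error")
  if (psa < 0) rtqa_error("PSA must be >= 0", "rtqa_domain_error")
  gsum <- gleason_primary + gleason_secondary
  hi <- config$high
  if (ti >= match(hi$t_min, t_order) || gsum >= hi$gleason_sum_min ||
      psa > hi$psa_min_exclusive) return("HIGH")
  lo <- config$low
  if (ti <= match(lo$t_max, t_order) && gsum <= lo$gleason_sum_max &&
      psa < lo$psa_max_exclusive) return("LOW")
  "INTERMEDIATE"
}

#' Auto-populate a target template from earlier encounters
#'
#' Copies values along the declared field-flow map (e.g. consult staging
#' into the end-of-treatment summary), marking them AUTO_POPULATED. Fields
#' already ENTERED in the target are left alone; re-running with unchanged
#' sources is idempotent. Missing source fields leave the target absent and
#' record a warning on the returned object (attribute "warnings").
#'
#' @param record an `rt_patient_record`
#' @param target_template template_id to populate
#' @param flows flow map (default: packaged), rows with from/to
#'   "TEMPLATE.field" paths
#' @return the updated record (attribute "warnings" lists skipped flows)
#' @export
autopopulate <- function(record, target_template,
                         flows = jsonlite::read_json(rtqa_extdata("flowmaps.json"))$flows) {
  catalogue <- load_template_catalogue()
  warnings <- character()
  if (is.null(record$encounters[[target_template]]))
    record$encounters[[target_template]] <- list(date = NA_character_,
                                                 fields = list(),
                                                 provenance = list())
  for (fl in flows) {
    if (!is.null(fl$site) && !identical(fl$site, record$disease_site)) next
    from <- strsplit(fl$from, ".", fixed = TRUE)[[1]]
    to <- strsplit(fl$to, ".", fixed = TRUE)[[1]]
    if (to[1] != target_template) next
    src_schema <- template_schema(record$disease_site, from[1], catalogue)
    tgt_schema <- template_schema(record$disease_site, to[1], catalogue)
    if (!from[2] %in% names(src_schema$fields) ||
        !to[2] %in% names(tgt_schema$fields))
      rtqa_error(sprintf("flow %s -> %s references unknown fields",
                         fl$from, fl$to), "rtqa_config_error")
    src_enc <- record$encounters[[from[1]]]
    v <- if (is.null(src_enc)) NULL else src_enc$fields[[from[2]]]
    if (is.null(v)) {
      warnings <- c(warnings, sprintf("source %s absent; %s left empty",
                                      fl$from, fl$to))
      next
    }
    prov <- record$encounters[[to[1]]]$provenance[[to[2]]]
    if (identical(prov, "ENTERED")) next  # manual edits win
    record$encounters[[to[1]]]$fields[[to[2]]] <- v
    record$encounters[[to[1]]]$provenance[[to[2]]] <- "AUTO_POPULATED"
  }
  attr(record, "warnings") <- warnings
  record
}

.NOT_RECORDED <- "[not recorded]"

.format_field_value <- function(v) {
  if (is.logical(v)) return(if (v) "yes" else "no")
  if (is.numeric(v)) return(format(v, trim = TRUE, scientific = FALSE,
                                   digits = 15))
  as.character(v)
}

# resolve a placeholder against a record: "TEMPLATE.field" or plain "field"
# (searched in workflow order). Returns list(found=, value=) .
.resolve_placeholder <- function(record, ph) {
  if (grepl(".", ph, fixed = TRUE)) {
    parts <- strsplit(ph, ".", fixed = TRUE)[[1]]
    enc <- record$encounters[[parts[1]]]
    v <- if (is.null(enc)) NULL else enc$fields[[parts[2]]]
    return(list(found = !is.null(v), value = v))
  }
  for (tid in .TEMPLATE_ORDER) {
    enc <- record$encounters[[tid]]
    if (!is.null(enc) && !is.null(enc$fields[[ph]]))
      return(list(found = TRUE, value = enc$fields[[ph]]))
  }
  list(found = FALSE, value = NULL)
}

.placeholder_in_schema <- function(record, ph, catalogue) {
  strip <- function(tid, field) {
    s <- catalogue$schemas[[paste(record$disease_site, tid, sep = ".")]]
    !is.null(s) && field %in% names(s$fields)
  }
  if (grepl(".", ph, fixed = TRUE)) {
    parts <- strsplit(ph, ".", fixed = TRUE)[[1]]
    return(strip(parts[1], parts[2]))
  }
  any(vapply(.TEMPLATE_ORDER, function(tid) strip(tid, ph), logical(1)))
}

.split_boilerplate <- function(boilerplate) {
  # returns list(literals = chr k+1, placeholders = chr k)
  m <- gregexpr("\\{[A-Za-z0-9_.]+\\}", boilerplate)[[1]]
  if (m[1] == -1L) return(list(literals = boilerplate, placeholders = character()))
  starts <- as.integer(m); lens <- attr(m, "match.length")
  literals <- character(); placeholders <- character()
  pos <- 1L
  for (i in seq_along(starts)) {
    literals <- c(literals, substr(boilerplate, pos, starts[i] - 1L))
    placeholders <- c(placeholders,
                      substr(boilerplate, starts[i] + 1L,
                             starts[i] + lens[i] - 2L))
    pos <- starts[i] + lens[i]
  }
  literals <- c(literals, substr(boilerplate, pos, nchar(boilerplate)))
  list(literals = literals, placeholders = placeholders)
}

#' Render a narrative note from a record and a boilerplate template
#'
#' Placeholders are single-line `{field}` or `{TEMPLATE.field}` tokens.
#' Plain field names are resolved across encounters in workflow order.
#' Absent optional fields render the sentinel `[not recorded]`.
#'
#' @param record an `rt_patient_record`
#' @param boilerplate template text with placeholders
#' @return narrative text (deterministic in its inputs)
#' @export
render_narrative <- function(record, boilerplate) {
  catalogue <- load_template_catalogue()
  bp <- .split_boilerplate(boilerplate)
  out <- bp$literals[1]
  for (i in seq_along(bp$placeholders)) {
    ph <- bp$placeholders[i]
    if (!.placeholder_in_schema(record, ph, catalogue))
      rtqa_error(paste("placeholder names unknown schema field:", ph),
                 "rtqa_config_error")
    r <- .resolve_placeholder(record, ph)
    out <- paste0(out, if (r$found) .format_field_value(r$value) else .NOT_RECORDED,
                  bp$literals[i + 1])
  }
  out
}

#' Recover discrete fields from a narrative produced by a boilerplate
#'
#' Inverse of [render_narrative()]: literal chunks of the boilerplate are
#' matched in order and the text between them is returned per placeholder.
#' The `[not recorded]` sentinel maps back to an absent field. A narrative
#' that does not match the boilerplate skeleton raises a parse error naming
#' the character position.
#'
#' @param narrative narrative text
#' @param boilerplate the boilerplate it was rendered from
#' @param schema optional `rt_template_schema` (or catalogue-backed record
#'   site) used to coerce values back to their field types
#' @param record_site optional disease site for typed coercion of
#'   unqualified placeholders
#' @return named list of recovered values (character unless coerced)
#' @export
extract_discrete <- function(narrative, boilerplate, schema = NULL,
                             record_site = NULL) {
  bp <- .split_boilerplate(boilerplate)
  k <- length(bp$placeholders)
  pos <- 1L
  n <- nchar(narrative)
  lit <- bp$literals
  # first literal must anchor at position 1
  if (nchar(lit[1])) {
    if (substr(narrative, 1L, nchar(lit[1])) != lit[1])
      rtqa_error("narrative does not match boilerplate at position 1",
                 "rtqa_parse_error")
    pos <- 1L + nchar(lit[1])
  }
  values <- list()
  for (i in seq_len(k)) {
    nxt <- lit[i + 1]
    if (i == k && nchar(nxt)) {
      # final literal anchors at the end of the narrative, so a trailing
      # value may itself contain the literal (e.g. "8.3" before ".")
      end <- n - nchar(nxt)
      if (end < pos - 1L ||
          substr(narrative, end + 1L, n) != nxt)
        rtqa_error(sprintf("narrative does not match boilerplate at position %d (expected trailing \"%s\")",
                           pos, substr(nxt, 1, 20)), "rtqa_parse_error")
      raw_v <- substr(narrative, pos, end)
      pos <- n + 1L
    } else if (nchar(nxt)) {
      hit <- regexpr(nxt, substr(narrative, pos, n), fixed = TRUE)
      if (hit == -1L)
        rtqa_error(sprintf("narrative does not match boilerplate at position %d (expected \"%s\")",
                           pos, substr(nxt, 1, 20)), "rtqa_parse_error")
      end <- pos + as.integer(hit) - 2L
      raw_v <- substr(narrative, pos, end)
      pos <- end + 1L + nchar(nxt)
    } else {
      # trailing placeholder: consumes the rest
      raw_v <- substr(narrative, pos, n)
      pos <- n + 1L
    }
    if (!identical(raw_v, .NOT_RECORDED))
      values[[bp$placeholders[i]]] <- raw_v
  }
  if (pos != n + 1L)
    rtqa_error(sprintf("trailing narrative text at position %d", pos),
               "rtqa_parse_error")
  if (!is.null(schema) || !is.null(record_site))
    values <- .coerce_extracted(values, schema, record_site)
  values
}

.coerce_extracted <- function(values, schema, record_site) {
  catalogue <- load_template_catalogue()
  field_def <- function(ph) {
    if (grepl(".", ph, fixed = TRUE)) {
      parts <- strsplit(ph, ".", fixed = TRUE)[[1]]
      s <- catalogue$schemas[[paste(record_site, parts[1], sep = ".")]]
      return(if (is.null(s)) NULL else s$fields[[parts[2]]])
    }
    if (!is.null(schema) && ph %in% names(schema$fields))
      return(schema$fields[[ph]])
    if (!is.null(record_site)) {
      for (tid in .TEMPLATE_ORDER) {
        s <- catalogue$schemas[[paste(record_site, tid, sep = ".")]]
        if (!is.null(s) && ph %in% names(s$fields)) return(s$fields[[ph]])
      }
    }
    NULL
  }
  for (nm in names(values)) {
    f <- field_def(nm)
    if (is.null(f)) next
    v <- values[[nm]]
    values[[nm]] <- switch(f$type,
      number = as.numeric(v),
      integer = as.integer(v),
      boolean = identical(v, "yes"),
      vocab = {
        vv <- catalogue$vocabularies[[f$vocabulary]]$values
        if (all(vapply(vv, is.numeric, logical(1)))) as.integer(v) else v
      },
      v)
  }
  values
}
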