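# Clinical quality measures as declarative decision trees over flattened
# record / plan / constraint-report features. The engine is a pure
# interpreter: structural problems (cycles, dangling branches, unknown
# features) are all caught at load time; at evaluation time a predicate on
# a missing field (other than EXISTS) yields NOT_EVALUABLE, never a silent
# FAIL. NOT_APPLICABLE is an authored leaf, not an engine special case.

.CQM_OPS <- c("EQ", "NE", "LT", "LE", "GT", "GE", "IN", "EXISTS")
.CQM_LEAVES <- c("PASS", "FAIL", "NOT_APPLICABLE")

#' Load and structurally validate a CQM rule set
#'
#' Every measure's tree is checked before acceptance: all branch ids must
#' resolve, the tree must be acyclic, every path must end in a leaf, every
#' predicate field must appear in the declared feature dictionary (typos
#' are reported with the nearest known field), and every operator must be
#' known. Rejection lists every violation.
#'
#' @param path rule set JSON file
#' @return object of class `rt_cqm_ruleset`
#' @export
load_ruleset <- function(path) {
  raw <- jsonlite::read_json(path)
  features <- as.character(unlist(raw$feature_dictionary))
  problems <- character()
  measures <- list()
  for (m in raw$measures) {
    nodes <- m$nodes
    ids <- names(nodes)
    for (id in ids) {
      node <- nodes[[id]]
      if (!is.null(node$result)) {
        if (!node$result %in% .CQM_LEAVES)
          problems <- c(problems, sprintf("%s/%s: unknown leaf result %s",
                                          m$measure_id, id, node$result))
        next
      }
      if (is.null(node$field) || is.null(node$op) ||
          is.null(node$true) || is.null(node$false)) {
        problems <- c(problems, sprintf("%s/%s: decision node incomplete",
                                        m$measure_id, id))
        next
      }
      if (!node$op %in% .CQM_OPS)
        problems <- c(problems, sprintf("%s/%s: unknown op %s",
                                        m$measure_id, id, node$op))
      if (!node$field %in% features) {
        d <- utils::adist(node$field, features)
        nearest <- features[which.min(d)]
        problems <- c(problems, sprintf(
          "%s/%s: field \"%s\" not in feature dictionary (nearest: \"%s\")",
          m$measure_id, id, node$field, nearest))
      }
      for (br in c(node$true, node$false))
        if (!br %in% ids)
          problems <- c(problems, sprintf("%s/%s: branch \"%s\" does not resolve",
                                          m$measure_id, id, br))
    }
    if (is.null(m$root) || !m$root %in% ids)
      problems <- c(problems, sprintf("%s: root does not resolve", m$measure_id))
    # cycle check: DFS from every node
    state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
    visit <- function(id, path) {
      if (state[[id]] == 1L) {
        problems <<- c(problems, sprintf("%s: cycle through %s",
                                         m$measure_id,
                                         paste(c(path, id), collapse = " -> ")))
        return()
      }
      if (state[[id]] == 2L) return()
      state[[id]] <<- 1L
      node <- nodes[[id]]
      if (is.null(node$result)) {
        for (br in c(node$true, node$false))
          if (br %in% ids) visit(br, c(path, id))
      }
      state[[id]] <<- 2L
    }
    if (!is.null(m$root) && m$root %in% ids) visit(m$root, character())
    if (!is.null(m$category) && !m$category %in%
        c("EXPECTED", "ASPIRATIONAL", "SURVEILLANCE"))
      problems <- c(problems, sprintf("%s: unknown category %s",
                                      m$measure_id, m$category))
    measures[[m$measure_id]] <- m
  }
  if (length(problems))
    rtqa_error(paste0("invalid rule set:\n  ",
                      paste(problems, collapse = "\n  ")),
               "rtqa_ruleset_error")
  structure(list(ruleset_id = raw$ruleset_id, version = raw$version,
                 feature_dictionary = features, measures = measures),
            class = "rt_cqm_ruleset")
}

#' @export
print.rt_cqm_ruleset <- function(x, ...) {
  cat("<rt_cqm_ruleset>", x$ruleset_id %||% "?", "-", length(x$measures),
      "measures,", length(x$feature_dictionary), "features\n")
  invisible(x)
}

.cqm_predicate <- function(op, feature_value, literal) {
  lit <- unlist(literal)
  switch(op,
    EQ = isTRUE(all.equal(feature_value, lit, check.attributes = FALSE)) ||
         identical(as.character(feature_value), as.character(lit)),
    NE = !(isTRUE(all.equal(feature_value, lit, check.attributes = FALSE)) ||
           identical(as.character(feature_value), as.character(lit))),
    LT = as.numeric(feature_value) < as.numeric(lit),
    LE = as.numeric(feature_value) <= as.numeric(lit),
    GT = as.numeric(feature_value) > as.numeric(lit),
    GE = as.numeric(feature_value) >= as.numeric(lit),
    IN = as.character(feature_value) %in% as.character(lit),
    stop("unhandled op ", op))
}

#' Evaluate one measure tree over a flattened feature map
#'
#' Walks root-to-leaf applying predicates. A predicate on a missing field
#' (other than EXISTS) halts the walk with NOT_EVALUABLE and records the
#' field; EXISTS never fails on a missing field. The returned path trace
#' lists the visited node ids with each predicate outcome and replays to
#' the reported leaf.
#'
#' @param features named list: flattened feature map
#' @param measure one measure from a loaded [load_ruleset()] rule set
#' @return object of class `rt_measure_result`: measure_id, result
#'   (PASS/FAIL/NOT_APPLICABLE/NOT_EVALUABLE), score (1/0/NA), path_trace,
#'   missing_fields
#' @export
evaluate_measure <- function(features, measure) {
  id <- measure$root
  trace <- list()
  repeat {
    node <- measure$nodes[[id]]
    if (!is.null(node$result)) {
      res <- node$result
      score <- switch(res, PASS = 1L, FAIL = 0L, NA_integer_)
      trace[[length(trace) + 1L]] <- list(node = id, outcome = res)
      return(structure(list(measure_id = measure$measure_id, result = res,
                            score = score, path_trace = trace,
                            missing_fields = character()),
                       class = "rt_measure_result"))
    }
    have <- node$field %in% names(features) &&
            !is.null(features[[node$field]])
    if (node$op == "EXISTS") {
      out <- have
    } else if (!have) {
      trace[[length(trace) + 1L]] <- list(node = id, outcome = "MISSING")
      return(structure(list(measure_id = measure$measure_id,
                            result = "NOT_EVALUABLE", score = NA_integer_,
                            path_trace = trace,
                            missing_fields = node$field),
                       class = "rt_measure_result"))
    } else {
      out <- isTRUE(.cqm_predicate(node$op, features[[node$field]],
                                   node$value))
    }
    trace[[length(trace) + 1L]] <- list(node = id, outcome = out)
    id <- if (out) node$true else node$false
  }
}

#' @export
print.rt_measure_result <- function(x, ...) {
  cat(sprintf("<rt_measure_result> %s: %s (score %s)\n", x$measure_id,
              x$result, format(x$score)))
  invisible(x)
}

#' Flatten record, plan and constraint report into the CQM feature namespace
#'
#' Namespaces: `record.<field>` (encounter fields, later templates override
#' earlier ones on name collision within the record), `record.disease_site`,
#' `plan.prescription_dose`, `plan.fractions`, `plan.dose_per_fraction`,
#' `plan.technique`, `dvh.<structure>.<metric>.value` / `.status` and
#' `dvh.plan_status`. A collision between namespaces is a wiring error.
#'
#' @param record an `rt_patient_record` (or NULL)
#' @param plan an `rt_plan_summary` (or NULL)
#' @param constraint_report an `rt_constraint_report` (or NULL)
#' @return named list of features
#' @export
flatten_features <- function(record = NULL, plan = NULL,
                             constraint_report = NULL) {
  f <- list()
  put <- function(key, value) {
    if (!is.null(f[[key]]))
      rtqa_error(paste("feature namespace collision:", key),
                 "rtqa_wiring_error")
    f[[key]] <<- value
  }
  if (!is.null(record)) {
    put("record.disease_site", record$disease_site)
    for (tid in intersect(.TEMPLATE_ORDER, names(record$encounters))) {
      enc <- record$encounters[[tid]]
      for (nm in names(enc$fields))
        f[[paste0("record.", nm)]] <- enc$fields[[nm]]  # later wins
    }
  }
  if (!is.null(plan)) {
    put("plan.prescription_dose", plan$prescription_dose)
    put("plan.fractions", plan$fractions)
    if (!is.na(plan$prescription_dose) && !is.na(plan$fractions))
      put("plan.dose_per_fraction", plan$prescription_dose / plan$fractions)
    put("plan.technique", plan$technique)
  }
  if (!is.null(constraint_report)) {
    for (r in constraint_report$constraints) {
      key <- paste0("dvh.", r$structure, ".", r$metric)
      put(paste0(key, ".value"), r$value)
      put(paste0(key, ".status"), r$status)
    }
    put("dvh.plan_status", constraint_report$plan_status)
  }
  f
}

#' Score one patient against a rule set
#'
#' @param record an `rt_patient_record`
#' @param plan an `rt_plan_summary`
#' @param constraint_report an `rt_constraint_report`
#' @param ruleset an [load_ruleset()] result
#' @return object of class `rt_scorecard`: patient_key, results (one
#'   `rt_measure_result` per measure), summary counts by result and by
#'   category
#' @export
score_patient <- function(record, plan, constraint_report, ruleset) {
  features <- flatten_features(record, plan, constraint_report)
  results <- lapply(ruleset$measures, function(m)
    evaluate_measure(features, m))
  statuses <- vapply(results, function(r) r$result, character(1))
  by_result <- table(factor(statuses, levels = c("PASS", "FAIL",
                                                 "NOT_APPLICABLE",
                                                 "NOT_EVALUABLE")))
  cats <- vapply(ruleset$measures, function(m) m$category %||% "EXPECTED",
                 character(1))
  structure(list(patient_key = record$patient_key,
                 results = results,
                 summary = list(by_result = as.list(by_result),
                                by_category = as.list(table(cats)),
                                n_measures = length(results))),
            class = "rt_scorecard")
}

#' @export
print.rt_scorecard <- function(x, ...) {
  cat("<rt_scorecard>", x$patient_key, "\n")
  for (r in x$results)
    cat(sprintf("  %-12s %s\n", r$measure_id, r$result))
  invisible(x)
}

#' Replay a path trace against a measure tree
#'
#' Verification helper: follows the recorded predicate outcomes from the
#' root and returns the node id reached.
#'
#' @param measure the measure whose tree produced the trace
#' @param trace a `path_trace` from [evaluate_measure()]
#' @return the final node id
#' @export
replay_trace <- function(measure, trace) {
  id <- measure$root
  for (step in trace) {
    if (!identical(step$node, id))
      rtqa_error(sprintf("trace diverges: expected %s, trace has %s",
                         id, step$node), "rtqa_wiring_error")
    node <- measure$nodes[[id]]
    if (!is.null(node$result)) return(id)
    if (identical(step$outcome, "MISSING")) return(id)
    id <- if (isTRUE(step$outcome)) node$true else node$false
  }
  id
}
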