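# Dose-constraint grading: PASS / VARIATION / FAIL / NOT_EVALUABLE.
# Boundary equality satisfies a limit (<= / >= semantics). Constraint sets
# are editable JSON per disease site; no limits are hard-coded. The shipped
# example sets are illustrative placeholders, not protocol transcriptions.

#' Construct a dose constraint
#'
#' @param structure TG-263 structure name the constraint applies to
#' @param metric a metric string ("V70Gy", "D2%", "Dmean", ...) or
#'   [metric_spec()]
#' @param comparator "LE" or "GE"
#' @param pass_limit limit for full compliance
#' @param variation_limit limit for acceptable variation (NULL if none);
#'   must be weakly looser than `pass_limit` under the comparator
#' @param source_label provenance label (e.g. protocol name)
#' @return object of class `rt_dose_constraint`
#' @export
dose_constraint <- function(structure, metric, comparator = c("LE", "GE"),
                            pass_limit, variation_limit = NULL,
                            source_label = "") {
  comparator <- match.arg(comparator)
  metric_label <- if (is.character(metric)) metric else
    stop("metric must be a metric string")
  spec <- parse_metric(metric_label)
  if (!is.null(variation_limit)) {
    ok <- if (comparator == "LE") variation_limit >= pass_limit
          else variation_limit <= pass_limit
    if (!ok) rtqa_error("variation_limit must be weakly looser than pass_limit",
                        "rtqa_config_error")
  }
  structure(list(structure = structure, metric_label = metric_label,
                 metric = spec, comparator = comparator,
                 pass_limit = pass_limit, variation_limit = variation_limit,
                 source_label = source_label),
            class = "rt_dose_constraint")
}

#' Read a constraint set from JSON
#' @param path constraint set JSON
#' @return list of [dose_constraint()] objects
#' @export
read_constraint_set <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw$constraints, function(c_)
    dose_constraint(c_$structure, c_$metric, c_$comparator, c_$pass_limit,
                    c_$variation_limit, raw$source_label %||% ""))
}

#' Grade a measured value against pass/variation limits
#'
#' Pure comparator logic: PASS if the comparator holds against
#' `pass_limit` (boundary equality satisfies the limit), else VARIATION if
#' it holds against `variation_limit`, else FAIL.
#'
#' @param value measured metric value
#' @param comparator "LE" or "GE"
#' @param pass_limit,variation_limit limits (`variation_limit` may be NULL)
#' @return "PASS", "VARIATION" or "FAIL"
#' @export
grade_value <- function(value, comparator, pass_limit, variation_limit = NULL) {
  holds <- function(lim) if (comparator == "LE") value <= lim else value >= lim
  if (holds(pass_limit)) return("PASS")
  if (!is.null(variation_limit) && holds(variation_limit)) return("VARIATION")
  "FAIL"
}

#' Evaluate one constraint against a DVH curve
#'
#' @param curve an `rt_dvh` for the constraint's structure
#' @param constraint an [dose_constraint()]
#' @return list(value, status, reason)
#' @export
evaluate_constraint <- function(curve, constraint) {
  if (!identical(curve$structure_name, constraint$structure))
    rtqa_error(sprintf("curve is for %s but constraint targets %s",
                       curve$structure_name, constraint$structure),
               "rtqa_wiring_error")
  value <- tryCatch(as.numeric(evaluate_metric(curve, constraint$metric)),
                    rtqa_domain_error = function(e) e)
  if (inherits(value, "condition"))
    return(list(value = NA_real_, status = "NOT_EVALUABLE",
                reason = conditionMessage(value)))
  status <- grade_value(value, constraint$comparator, constraint$pass_limit,
                        constraint$variation_limit)
  list(value = value, status = status,
       reason = sprintf("%s(%s) = %.4g vs %s %s %.4g",
                        constraint$metric_label, constraint$structure, value,
                        constraint$comparator,
                        if (status == "PASS") "pass limit" else "limit",
                        constraint$pass_limit))
}

.constraint_report <- function(rows) {
  statuses <- vapply(rows, function(r) r$status, character(1))
  evaluable <- statuses[statuses != "NOT_EVALUABLE"]
  plan_status <- if (!length(evaluable)) "NOT_EVALUABLE"
    else if (any(evaluable == "FAIL")) "FAIL"
    else if (any(evaluable == "VARIATION")) "VARIATION"
    else "PASS"
  structure(list(constraints = rows, plan_status = plan_status),
            class = "rt_constraint_report")
}

#' Evaluate a constraint list against a set of DVH curves
#'
#' Constraints referencing structures with no curve are reported
#' NOT_EVALUABLE and never count toward the plan status, which is the worst
#' status over evaluable constraints (FAIL > VARIATION > PASS).
#'
#' @param curves named list of `rt_dvh` curves (names = structure names)
#' @param constraints list of [dose_constraint()] objects
#' @return object of class `rt_constraint_report`
#' @export
evaluate_plan <- function(curves, constraints) {
  nm <- names(curves)
  if (is.null(nm))
    nm <- vapply(curves, function(c_) c_$structure_name, character(1))
  rows <- lapply(constraints, function(con) {
    base <- list(structure = con$structure, metric = con$metric_label,
                 comparator = con$comparator, pass_limit = con$pass_limit,
                 variation_limit = con$variation_limit %||% NA_real_)
    i <- match(con$structure, nm)
    if (is.na(i)) {
      return(c(base, list(value = NA_real_, status = "NOT_EVALUABLE",
                          reason = sprintf("structure %s absent from plan",
                                           con$structure))))
    }
    c(base, evaluate_constraint(curves[[i]], con))
  })
  .constraint_report(rows)
}

#' @export
print.rt_constraint_report <- function(x, ...) {
  cat("<rt_constraint_report> plan status:", x$plan_status, "\n")
  for (r in x$constraints)
    cat(sprintf("  %-14s %-8s %-13s %s\n", r$structure, r$metric, r$status,
                if (is.na(r$value)) "" else sprintf("%.4g", r$value)))
  invisible(x)
}

#' Constraint report as a data frame
#' @param x an `rt_constraint_report`
#' @param ... unused
#' @return data.frame, one row per constraint
#' @export
as.data.frame.rt_constraint_report <- function(x, ...) {
  do.call(rbind, lapply(x$constraints, function(r)
    data.frame(structure = r$structure, metric = r$metric,
               comparator = r$comparator, pass_limit = r$pass_limit,
               variation_limit = r$variation_limit %||% NA_real_,
               value = r$value, status = r$status, reason = r$reason)))
}
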