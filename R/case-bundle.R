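# Case bundle: one JSON document holding the structure set, dose grid and
# plan summary of a case — the interchange format of the command-line tool.

#' Write / read a case bundle as JSON
#'
#' @param ss an [rt_structure_set()]
#' @param grid an [rt_dose_grid()] (or NULL)
#' @param plan an [rt_plan_summary()] (or NULL)
#' @param path file path
#' @return `path` invisibly / list(structure_set, dose_grid, plan)
#' @export
write_case_bundle <- function(ss, grid = NULL, plan = NULL, path) {
  doc <- list(
    format = "rtqa-case-bundle",
    version = "1",
    patient_id = ss$patient_id,
    frame_of_reference = ss$frame_of_reference,
    structures = lapply(ss$structures, function(s) list(
      name = s$name, roi_number = s$roi_number,
      nonstandard = s$nonstandard %||% NA,
      color = s$color,
      analytic_volume_mm3 = s$analytic_volume_mm3,
      contours = lapply(s$contours, function(m) as.numeric(t(m)))))
  )
  if (!is.null(grid)) doc$dose_grid <- list(
    origin = grid$origin, spacing = grid$spacing,
    z_offsets = grid$z_offsets, dim = dim(grid$values),
    values = as.numeric(grid$values), dose_units = grid$dose_units)
  if (!is.null(plan)) doc$plan <- list(
    prescription_dose = plan$prescription_dose, fractions = plan$fractions,
    target_name = plan$target_name, technique = plan$technique,
    plan_label = plan$plan_label, warnings = plan$warnings)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_case_bundle
#' @export
read_case_bundle <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, "rtqa-case-bundle"))
    rtqa_error("not an rtqa case bundle", "rtqa_format_error")
  structures <- lapply(doc$structures, function(s) {
    st <- rt_structure(s$name, s$roi_number,
                       lapply(s$contours, function(v)
                         matrix(unlist(v), ncol = 3, byrow = TRUE)),
                       color = unlist(s$color),
                       analytic_volume_mm3 = s$analytic_volume_mm3)
    if (!is.null(s$nonstandard) && !is.na(s$nonstandard))
      st$nonstandard <- s$nonstandard
    st
  })
  ss <- rt_structure_set(structures,
                         frame_of_reference = doc$frame_of_reference,
                         patient_id = doc$patient_id)
  grid <- if (!is.null(doc$dose_grid)) {
    dg <- doc$dose_grid
    rt_dose_grid(unlist(dg$origin), unlist(dg$spacing), unlist(dg$z_offsets),
                 array(unlist(dg$values), dim = unlist(dg$dim)),
                 dose_units = dg$dose_units,
                 frame_of_reference = doc$frame_of_reference)
  }
  plan <- if (!is.null(doc$plan)) {
    pl <- doc$plan
    rt_plan_summary(pl$prescription_dose %||% NA_real_,
                    pl$fractions %||% NA_integer_,
                    target_name = pl$target_name %||% NA_character_,
                    technique = pl$technique %||% NA_character_,
                    plan_label = pl$plan_label %||% "PLAN",
                    warnings = as.character(unlist(pl$warnings)))
  }
  list(structure_set = ss, dose_grid = grid, plan = plan)
}
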