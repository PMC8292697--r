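# DICOM-RT readers/writers mapping files onto the internal data model.
# All geometry is in the DICOM patient coordinate system, millimetres.
# Only axial, non-tilted grids (identity direction cosines) are supported.

rtqa_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rtqa_error")))
}

#' Structure: a named set of closed planar contours
#'
#' @param name structure label as stored in the file
#' @param roi_number integer ROI identifier, unique within a set
#' @param contours list of n x 3 numeric matrices (x, y, z in mm); each
#'   contour must have >= 3 points and constant z
#' @param color optional RGB integer triple
#' @param analytic_volume_mm3 optional known volume of the ideal solid the
#'   contours approximate (attached by the phantom generator)
#' @return object of class `rt_structure`
#' @export
rt_structure <- function(name, roi_number, contours, color = NULL,
                         analytic_volume_mm3 = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  roi_number <- as.integer(roi_number)
  contours <- lapply(contours, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) rtqa_error("contour must be n x 3", "rtqa_malformed_contour")
    if (nrow(m) < 3L)
      rtqa_error(sprintf("contour of ROI %d has < 3 points", roi_number),
                 "rtqa_malformed_contour")
    if (diff(range(m[, 3])) > 1e-6)
      rtqa_error(sprintf("contour of ROI %d has non-constant z", roi_number),
                 "rtqa_malformed_contour")
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  structure(list(name = name, roi_number = roi_number, contours = contours,
                 color = color, analytic_volume_mm3 = analytic_volume_mm3),
            class = "rt_structure")
}

#' Structure set: the geometry side of DVH computation
#'
#' @param structures list of [rt_structure()] objects with unique ROI numbers
#' @param frame_of_reference frame-of-reference UID
#' @param patient_id patient identifier string
#' @return object of class `rt_structure_set`
#' @export
rt_structure_set <- function(structures, frame_of_reference = rtqa_uid("FOR"),
                             patient_id = "PHANTOM") {
  rois <- vapply(structures, function(s) s$roi_number, integer(1))
  if (anyDuplicated(rois))
    rtqa_error("duplicate roi_number in structure set", "rtqa_malformed_contour")
  structure(list(structures = structures,
                 frame_of_reference = frame_of_reference,
                 patient_id = patient_id),
            class = "rt_structure_set")
}

#' @export
print.rt_structure_set <- function(x, ...) {
  cat("<rt_structure_set>", length(x$structures), "structures,",
      "patient", x$patient_id, "\n")
  for (s in x$structures)
    cat(sprintf("  [%d] %s: %d contours\n", s$roi_number, s$name,
                length(s$contours)))
  invisible(x)
}

#' Regular 3-D dose grid
#'
#' Voxel values are stored as an array with dim (nx, ny, nz); the value at
#' `values[ix, iy, iz]` sits at patient coordinates
#' `origin + ((ix-1)*dx, (iy-1)*dy, z_offsets[iz])`. `origin` is the centre
#' of the first voxel. The conventional (nz, ny, nx) shape is available via
#' `grid_shape()`.
#'
#' @param origin (x, y, z) mm of the first voxel centre
#' @param spacing (dx, dy) mm in-plane spacing
#' @param z_offsets strictly monotonic per-plane offsets (mm) relative to
#'   `origin[3]`
#' @param values numeric array, Gy, dim (nx, ny, nz), all values >= 0
#' @param dose_units "GY" or "RELATIVE"
#' @param frame_of_reference frame-of-reference UID
#' @return object of class `rt_dose_grid`
#' @export
rt_dose_grid <- function(origin, spacing, z_offsets, values,
                         dose_units = "GY",
                         frame_of_reference = rtqa_uid("FOR")) {
  if (length(z_offsets) > 1L && any(diff(z_offsets) <= 0))
    rtqa_error("z_offsets not strictly monotonic", "rtqa_malformed_dose")
  if (any(values < 0)) rtqa_error("negative dose values", "rtqa_malformed_dose")
  d <- dim(values)
  if (length(d) != 3L || d[3] != length(z_offsets))
    rtqa_error("values extent inconsistent with z_offsets", "rtqa_malformed_dose")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 z_offsets = as.numeric(z_offsets), values = values,
                 dose_units = dose_units,
                 frame_of_reference = frame_of_reference),
            class = "rt_dose_grid")
}

#' Grid shape in (nz, ny, nx) order
#' @param grid an [rt_dose_grid()]
#' @return integer vector (nz, ny, nx)
#' @export
grid_shape <- function(grid) rev(dim(grid$values))

#' Absolute z coordinates of the grid planes (mm)
#' @param grid an [rt_dose_grid()]
#' @return numeric vector of plane z positions
#' @export
grid_plane_z <- function(grid) grid$origin[3] + grid$z_offsets

#' @export
print.rt_dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rt_dose_grid> %d x %d x %d voxels, %.3g-%.3g %s\n",
              d[1], d[2], d[3], min(x$values), max(x$values), x$dose_units))
  invisible(x)
}

#' Plan summary: prescription-level facts consumed downstream
#'
#' @param prescription_dose prescribed dose in Gy (> 0), or NA if unknown
#' @param fractions planned fraction count (>= 1), or NA
#' @param target_name prescription target label
#' @param technique technique label (e.g. "VMAT")
#' @param plan_label plan name
#' @param warnings character vector of reader warnings
#' @return object of class `rt_plan_summary`
#' @export
rt_plan_summary <- function(prescription_dose, fractions,
                            target_name = NA_character_,
                            technique = NA_character_,
                            plan_label = "PLAN", warnings = character()) {
  if (!is.na(prescription_dose) && prescription_dose <= 0)
    rtqa_error("prescription_dose must be > 0", "rtqa_malformed_plan")
  if (!is.na(fractions) && fractions < 1)
    rtqa_error("fractions must be >= 1", "rtqa_malformed_plan")
  structure(list(prescription_dose = as.numeric(prescription_dose),
                 fractions = if (is.na(fractions)) NA_integer_ else as.integer(fractions),
                 target_name = target_name, technique = technique,
                 plan_label = plan_label, warnings = warnings),
            class = "rt_plan_summary")
}

#' @export
print.rt_plan_summary <- function(x, ...) {
  cat(sprintf("<rt_plan_summary> %s: %s Gy / %s fx\n", x$plan_label,
              format(x$prescription_dose), format(x$fractions)))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

.check_sop_class <- function(dcm, expected, what) {
  found <- dcm_get(dcm, "SOPClassUID")
  if (!identical(found, .SOP_CLASS[[expected]]))
    rtqa_error(sprintf("%s: expected %s storage class, found %s", what,
                       expected, if (is.null(found)) "none" else found),
               "rtqa_format_error")
}

#' Read an RT Structure Set file
#'
#' @param path DICOM RTSTRUCT file
#' @return an [rt_structure_set()]
#' @export
read_structure_set <- function(path) {
  dcm <- dcm_read(path)
  .check_sop_class(dcm, "RTSTRUCT", path)
  roi_seq <- dcm_get(dcm, "StructureSetROISequence")
  con_seq <- dcm_get(dcm, "ROIContourSequence")
  if (is.null(roi_seq)) rtqa_error("missing StructureSetROISequence", "rtqa_format_error")
  names_by_roi <- list()
  for (item in roi_seq) {
    roi <- dcm_get(item, "ROINumber")
    names_by_roi[[as.character(roi)]] <- dcm_get(item, "ROIName")
  }
  structures <- list()
  for (item in con_seq) {
    roi <- dcm_get(item, "ReferencedROINumber")
    color <- dcm_get(item, "ROIDisplayColor")
    contours <- lapply(dcm_get(item, "ContourSequence"), function(cit) {
      pts <- dcm_get(cit, "ContourData")
      if (length(pts) %% 3L != 0L)
        rtqa_error(sprintf("ROI %d: contour coordinate count %d not a multiple of 3",
                           roi, length(pts)), "rtqa_malformed_contour")
      matrix(pts, ncol = 3L, byrow = TRUE)
    })
    nm <- names_by_roi[[as.character(roi)]]
    if (is.null(nm)) rtqa_error(sprintf("ROI %d has contours but no ROI entry", roi),
                                "rtqa_format_error")
    structures[[length(structures) + 1L]] <-
      rt_structure(nm, roi, contours, color = color)
  }
  if (length(structures) != length(roi_seq))
    rtqa_error(sprintf("structure count mismatch: %d ROI entries, %d contour sets",
                       length(roi_seq), length(structures)), "rtqa_format_error")
  rt_structure_set(structures,
                   frame_of_reference = dcm_get(dcm, "FrameOfReferenceUID"),
                   patient_id = dcm_get(dcm, "PatientID"))
}

#' Write an RT Structure Set file
#' @param ss an [rt_structure_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure_set <- function(ss, path) {
  roi_items <- lapply(ss$structures, function(s) list(
    dcm_el("ROINumber", s$roi_number),
    dcm_el("ReferencedFrameOfReferenceUID", ss$frame_of_reference),
    dcm_el("ROIName", s$name)
  ))
  con_items <- lapply(ss$structures, function(s) {
    cs <- lapply(s$contours, function(m) list(
      dcm_el("ContourGeometricType", "CLOSED_PLANAR"),
      dcm_el("NumberOfContourPoints", nrow(m)),
      dcm_el("ContourData", as.numeric(t(m)))
    ))
    item <- list(dcm_el("ContourSequence", cs),
                 dcm_el("ReferencedROINumber", s$roi_number))
    if (!is.null(s$color)) item <- c(list(dcm_el("ROIDisplayColor", s$color)), item)
    item
  })
  sop_uid <- rtqa_uid("RTSTRUCT", ss$patient_id, ss$frame_of_reference,
                      vapply(ss$structures, function(s) s$name, character(1)))
  ds <- list(
    dcm_el("SOPClassUID", .SOP_CLASS[["RTSTRUCT"]]),
    dcm_el("SOPInstanceUID", sop_uid),
    dcm_el("Modality", "RTSTRUCT"),
    dcm_el("PatientName", ss$patient_id),
    dcm_el("PatientID", ss$patient_id),
    dcm_el("StudyInstanceUID", rtqa_uid("STUDY", ss$patient_id)),
    dcm_el("SeriesInstanceUID", rtqa_uid("SERIES", sop_uid)),
    dcm_el("FrameOfReferenceUID", ss$frame_of_reference),
    dcm_el("StructureSetLabel", "rtqa"),
    dcm_el("StructureSetROISequence", roi_items),
    dcm_el("ROIContourSequence", con_items)
  )
  dcm_write(ds, path)
}

#' Read an RT Dose file
#'
#' Stored integer voxels are multiplied by DoseGridScaling. RELATIVE dose
#' units are converted to Gy using `prescription_dose` when supplied,
#' otherwise an error is raised (all downstream metrics are absolute dose).
#'
#' @param path DICOM RTDOSE file
#' @param prescription_dose optional prescription in Gy, used only to scale
#'   RELATIVE-unit grids
#' @return an [rt_dose_grid()]
#' @export
read_dose_grid <- function(path, prescription_dose = NULL) {
  dcm <- dcm_read(path)
  .check_sop_class(dcm, "RTDOSE", path)
  iop <- dcm_get(dcm, "ImageOrientationPatient")
  if (!is.null(iop) && max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-9)
    rtqa_error("only axial, non-tilted dose grids are supported",
               "rtqa_unsupported_orientation")
  offsets <- dcm_get(dcm, "GridFrameOffsetVector")
  if (is.null(offsets))
    rtqa_error("missing GridFrameOffsetVector", "rtqa_malformed_dose")
  if (length(offsets) > 1L && any(diff(offsets) <= 0))
    rtqa_error("GridFrameOffsetVector not strictly monotonic", "rtqa_malformed_dose")
  rows <- dcm_get(dcm, "Rows"); cols <- dcm_get(dcm, "Columns")
  nframes <- dcm_get(dcm, "NumberOfFrames")
  scaling <- dcm_get(dcm, "DoseGridScaling")
  if (is.null(scaling)) rtqa_error("missing DoseGridScaling", "rtqa_malformed_dose")
  pd <- dcm_get(dcm, "PixelData")
  bits <- dcm_get(dcm, "BitsAllocated")
  if (!identical(bits, 32L)) rtqa_error("only 32-bit dose grids supported",
                                        "rtqa_malformed_dose")
  stored <- readBin(pd, "integer", n = length(pd) / 4L, size = 4L,
                    endian = "little")
  if (length(stored) != rows * cols * nframes)
    rtqa_error("PixelData extent inconsistent with Rows/Columns/NumberOfFrames",
               "rtqa_malformed_dose")
  values <- array(stored * scaling, dim = c(cols, rows, nframes))
  units <- dcm_get(dcm, "DoseUnits")
  if (identical(units, "RELATIVE")) {
    if (is.null(prescription_dose))
      rtqa_error("RELATIVE dose units require a prescription dose to scale",
                 "rtqa_malformed_dose")
    values <- values / 100 * prescription_dose
    units <- "GY"
  }
  ps <- dcm_get(dcm, "PixelSpacing")  # (row spacing = dy, column spacing = dx)
  ipp <- dcm_get(dcm, "ImagePositionPatient")
  rt_dose_grid(origin = ipp, spacing = c(ps[2], ps[1]), z_offsets = offsets,
               values = values, dose_units = units,
               frame_of_reference = dcm_get(dcm, "FrameOfReferenceUID"))
}

#' Write an RT Dose file
#'
#' Doses are quantized to `scaling` Gy per stored integer unit; the
#' quantization error is at most `scaling / 2` per voxel.
#'
#' @param grid an [rt_dose_grid()]
#' @param path output path
#' @param scaling dose-grid scaling factor (Gy per stored unit)
#' @param patient_id patient identifier written to the file
#' @return `path`, invisibly
#' @export
write_dose_grid <- function(grid, path, scaling = 1e-4, patient_id = "PHANTOM") {
  d <- dim(grid$values)
  stored <- as.integer(round(as.vector(grid$values) / scaling))
  if (any(stored < 0) || any(as.numeric(stored) > 2^31 - 1))
    rtqa_error("dose values out of storable range at this scaling",
               "rtqa_malformed_dose")
  sop_uid <- rtqa_uid("RTDOSE", patient_id, grid$frame_of_reference,
                      format(d), format(grid$origin))
  ds <- list(
    dcm_el("SOPClassUID", .SOP_CLASS[["RTDOSE"]]),
    dcm_el("SOPInstanceUID", sop_uid),
    dcm_el("Modality", "RTDOSE"),
    dcm_el("PatientName", patient_id),
    dcm_el("PatientID", patient_id),
    dcm_el("StudyInstanceUID", rtqa_uid("STUDY", patient_id)),
    dcm_el("SeriesInstanceUID", rtqa_uid("SERIES", sop_uid)),
    dcm_el("ImagePositionPatient", grid$origin),
    dcm_el("ImageOrientationPatient", c(1, 0, 0, 0, 1, 0)),
    dcm_el("FrameOfReferenceUID", grid$frame_of_reference),
    dcm_el("SamplesPerPixel", 1L),
    dcm_el("PhotometricInterpretation", "MONOCHROME2"),
    dcm_el("NumberOfFrames", d[3]),
    dcm_el("Rows", d[2]),
    dcm_el("Columns", d[1]),
    dcm_el("PixelSpacing", c(grid$spacing[2], grid$spacing[1])),
    dcm_el("BitsAllocated", 32L),
    dcm_el("BitsStored", 32L),
    dcm_el("HighBit", 31L),
    dcm_el("PixelRepresentation", 0L),
    dcm_el("DoseUnits", grid$dose_units),
    dcm_el("DoseType", "PHYSICAL"),
    dcm_el("DoseSummationType", "PLAN"),
    dcm_el("GridFrameOffsetVector", grid$z_offsets),
    dcm_el("DoseGridScaling", scaling),
    dcm_el("PixelData", writeBin(stored, raw(), size = 4L, endian = "little"))
  )
  dcm_write(ds, path)
}

#' Read an RT Plan file
#'
#' A plan with no derivable prescription dose yields a summary with NA dose
#' and a recorded warning rather than an error.
#'
#' @param path DICOM RTPLAN file
#' @return an [rt_plan_summary()]
#' @export
read_plan <- function(path) {
  dcm <- dcm_read(path)
  .check_sop_class(dcm, "RTPLAN", path)
  warnings <- character()
  dose <- NA_real_; target <- NA_character_
  drs <- dcm_get(dcm, "DoseReferenceSequence")
  if (!is.null(drs) && length(drs) >= 1L) {
    dose_v <- dcm_get(drs[[1]], "TargetPrescriptionDose")
    if (!is.null(dose_v)) dose <- dose_v
    tn <- dcm_get(drs[[1]], "DoseReferenceDescription")
    if (!is.null(tn)) target <- tn
  }
  if (is.na(dose)) warnings <- c(warnings, "no prescription dose derivable")
  fx <- NA_integer_
  fgs <- dcm_get(dcm, "FractionGroupSequence")
  if (!is.null(fgs) && length(fgs) >= 1L) {
    fx_v <- dcm_get(fgs[[1]], "NumberOfFractionsPlanned")
    if (!is.null(fx_v)) fx <- fx_v
  }
  if (is.na(fx)) warnings <- c(warnings, "no fraction count present")
  technique <- dcm_get(dcm, "RTPlanDescription")
  label <- dcm_get(dcm, "RTPlanLabel")
  rt_plan_summary(dose, fx, target_name = target,
                  technique = if (is.null(technique)) NA_character_ else technique,
                  plan_label = if (is.null(label)) "PLAN" else label,
                  warnings = warnings)
}

#' Write an RT Plan file
#' @param plan an [rt_plan_summary()]
#' @param path output path
#' @param patient_id patient identifier written to the file
#' @param frame_of_reference frame-of-reference UID
#' @return `path`, invisibly
#' @export
write_plan <- function(plan, path, patient_id = "PHANTOM",
                       frame_of_reference = rtqa_uid("FOR")) {
  sop_uid <- rtqa_uid("RTPLAN", patient_id, plan$plan_label,
                      format(plan$prescription_dose))
  ds <- list(
    dcm_el("SOPClassUID", .SOP_CLASS[["RTPLAN"]]),
    dcm_el("SOPInstanceUID", sop_uid),
    dcm_el("Modality", "RTPLAN"),
    dcm_el("PatientName", patient_id),
    dcm_el("PatientID", patient_id),
    dcm_el("StudyInstanceUID", rtqa_uid("STUDY", patient_id)),
    dcm_el("SeriesInstanceUID", rtqa_uid("SERIES", sop_uid)),
    dcm_el("FrameOfReferenceUID", frame_of_reference),
    dcm_el("RTPlanLabel", plan$plan_label)
  )
  if (!is.na(plan$technique))
    ds <- c(ds, list(dcm_el("RTPlanDescription", plan$technique)))
  if (!is.na(plan$prescription_dose)) {
    dr <- list(dcm_el("TargetPrescriptionDose", plan$prescription_dose))
    if (!is.na(plan$target_name))
      dr <- c(list(dcm_el("DoseReferenceDescription", plan$target_name)), dr)
    ds <- c(ds, list(dcm_el("DoseReferenceSequence", list(dr))))
  }
  if (!is.na(plan$fractions))
    ds <- c(ds, list(dcm_el("FractionGroupSequence", list(list(
      dcm_el("NumberOfFractionsPlanned", plan$fractions))))))
  dcm_write(ds, path)
}
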