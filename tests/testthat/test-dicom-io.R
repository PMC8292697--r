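# DICOM-RT round trips and malformed-input handling.

test_that("structure set round trip preserves names, counts and coordinates", {
  b <- make_structure(phantom_spec("BOX", c(0, 0, 0), c(20, 20, 20), 2),
                      "Bladder", 1L)
  r <- make_structure(phantom_spec("SPHERE", c(5, 0, 0), 8, 2), "rect", 2L)
  ss <- rt_structure_set(list(b, r), frame_of_reference = FOR_UID,
                         patient_id = "P001")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_structure_set(ss, path)
  got <- read_structure_set(path)

  expect_length(got$structures, 2L)
  expect_identical(vapply(got$structures, function(s) s$name, character(1)),
                   c("Bladder", "rect"))
  expect_identical(got$frame_of_reference, FOR_UID)
  expect_identical(got$patient_id, "P001")
  for (i in 1:2) {
    expect_length(got$structures[[i]]$contours, length(ss$structures[[i]]$contours))
    for (j in seq_along(ss$structures[[i]]$contours))
      expect_equal(got$structures[[i]]$contours[[j]],
                   ss$structures[[i]]$contours[[j]], tolerance = 1e-8)
  }
})

test_that("readers reject the wrong storage class, naming what they found", {
  g <- small_grid(shape = c(10, 10, 5))
  dose_path <- withr::local_tempfile(fileext = ".dcm")
  write_dose_grid(g, dose_path)
  expect_error(read_structure_set(dose_path), class = "rtqa_format_error")
  expect_error(read_structure_set(dose_path), "RTSTRUCT")
  expect_error(read_dose_grid(dose_path), NA)
  expect_error(read_plan(dose_path), class = "rtqa_format_error")
})

test_that("a contour with a non-multiple-of-3 coordinate count is rejected with its ROI", {
  b <- make_structure(phantom_spec("BOX", c(0, 0, 0), c(10, 10, 10), 2),
                      "Bladder", 7L)
  ss <- rt_structure_set(list(b), frame_of_reference = FOR_UID)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_structure_set(ss, path)
  dcm <- dcm_read(path)
  # truncate one ContourData value in place
  for (i in seq_along(dcm$elements)) {
    if (dcm$elements[[i]]$name == "ROIContourSequence") {
      item <- dcm$elements[[i]]$value[[1]]
      for (j in seq_along(item)) {
        if (item[[j]]$name == "ContourSequence") {
          cd <- item[[j]]$value[[1]]
          for (k in seq_along(cd)) {
            if (cd[[k]]$name == "ContourData")
              cd[[k]]$value <- cd[[k]]$value[-1]
          }
          item[[j]]$value[[1]] <- cd
        }
      }
      dcm$elements[[i]]$value[[1]] <- item
    }
  }
  path2 <- withr::local_tempfile(fileext = ".dcm")
  dcm_write(dcm$elements, path2)
  err <- expect_error(read_structure_set(path2),
                      class = "rtqa_malformed_contour")
  expect_match(conditionMessage(err), "ROI 7")
})

test_that("dose grids round trip through scaling and reject bad offsets", {
  g <- small_grid(dose_field_spec("UNIFORM", level = 20),
                  origin = c(0, 0, 0), shape = c(10, 10, 5))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dose_grid(g, path, scaling = 0.01)
  got <- read_dose_grid(path)
  expect_true(max(abs(got$values - 20)) < 1e-9)
  expect_identical(dim(got$values), c(10L, 10L, 5L))
  expect_equal(got$z_offsets, 0:4)

  # stored-value scaling arithmetic: 15000 * 0.001 = 15 Gy
  g15 <- small_grid(dose_field_spec("UNIFORM", level = 15),
                    origin = c(0, 0, 0), shape = c(4, 4, 2))
  p15 <- withr::local_tempfile(fileext = ".dcm")
  write_dose_grid(g15, p15, scaling = 0.001)
  expect_true(max(abs(read_dose_grid(p15)$values - 15)) < 1e-12)

  # non-monotonic frame offsets
  dcm <- dcm_read(path)
  els <- rtqa:::dcm_set(dcm$elements, "GridFrameOffsetVector", c(0, 3, 2, 4, 5))
  p2 <- withr::local_tempfile(fileext = ".dcm")
  dcm_write(els, p2)
  expect_error(read_dose_grid(p2), class = "rtqa_malformed_dose")

  # missing frame offsets
  els3 <- rtqa:::dcm_remove(dcm$elements, "GridFrameOffsetVector")
  p3 <- withr::local_tempfile(fileext = ".dcm")
  dcm_write(els3, p3)
  expect_error(read_dose_grid(p3), class = "rtqa_malformed_dose")
})

test_that("tilted dose grids raise an unsupported-orientation error", {
  g <- small_grid(shape = c(6, 6, 3))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dose_grid(g, path)
  dcm <- dcm_read(path)
  els <- rtqa:::dcm_set(dcm$elements, "ImageOrientationPatient",
                        c(0.999, 0.045, 0, -0.045, 0.999, 0))
  p2 <- withr::local_tempfile(fileext = ".dcm")
  dcm_write(els, p2)
  expect_error(read_dose_grid(p2), class = "rtqa_unsupported_orientation")
})

test_that("RELATIVE dose units convert through the prescription or fail", {
  g <- small_grid(dose_field_spec("UNIFORM", level = 100),
                  origin = c(0, 0, 0), shape = c(4, 4, 2))
  g$dose_units <- "RELATIVE"
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dose_grid(g, path, scaling = 0.01)
  expect_error(read_dose_grid(path), class = "rtqa_malformed_dose")
  got <- read_dose_grid(path, prescription_dose = 78)
  expect_true(max(abs(got$values - 78)) < 1e-9)
  expect_identical(got$dose_units, "GY")
})

test_that("plan round trip preserves prescription; absent fields become NA with warnings", {
  p <- rt_plan_summary(60, 30, target_name = "PTV", technique = "VMAT",
                       plan_label = "PLAN1")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_plan(p, path)
  got <- read_plan(path)
  expect_equal(got$prescription_dose, 60)
  expect_identical(got$fractions, 30L)
  expect_identical(got$target_name, "PTV")
  expect_length(got$warnings, 0L)

  # dose per fraction derivable downstream
  p78 <- rt_plan_summary(78, 39)
  path78 <- withr::local_tempfile(fileext = ".dcm")
  write_plan(p78, path78)
  got78 <- read_plan(path78)
  expect_equal(got78$prescription_dose / got78$fractions, 2.0)

  # plan lacking fraction count: NA + recorded warning, no error
  nofx <- rt_plan_summary(60, NA)
  path2 <- withr::local_tempfile(fileext = ".dcm")
  write_plan(nofx, path2)
  got2 <- read_plan(path2)
  expect_true(is.na(got2$fractions))
  expect_match(got2$warnings, "fraction", all = FALSE)

  # plan lacking prescription: NA dose + warning
  norx <- rt_plan_summary(NA, 30)
  path3 <- withr::local_tempfile(fileext = ".dcm")
  write_plan(norx, path3)
  got3 <- read_plan(path3)
  expect_true(is.na(got3$prescription_dose))
  expect_match(got3$warnings, "prescription", all = FALSE)
})

test_that("no ROI is silently dropped: contours without a ROI entry raise", {
  b <- make_structure(phantom_spec("BOX", c(0, 0, 0), c(10, 10, 10), 2),
                      "Bladder", 1L)
  ss <- rt_structure_set(list(b), frame_of_reference = FOR_UID)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_structure_set(ss, path)
  dcm <- dcm_read(path)
  # point the contour set at a ROI number that has no StructureSetROI entry
  for (i in seq_along(dcm$elements)) {
    if (dcm$elements[[i]]$name == "ROIContourSequence") {
      item <- dcm$elements[[i]]$value[[1]]
      for (j in seq_along(item))
        if (item[[j]]$name == "ReferencedROINumber") item[[j]]$value <- 99L
      dcm$elements[[i]]$value[[1]] <- item
    }
  }
  p2 <- withr::local_tempfile(fileext = ".dcm")
  dcm_write(dcm$elements, p2)
  expect_error(read_structure_set(p2), class = "rtqa_format_error")
})

test_that("case bundles round trip structures, grid and plan through JSON", {
  ss <- rt_structure_set(list(make_structure(
    phantom_spec("SPHERE", c(1, -2, 0), 6, 2), "GTV", 1L)),
    frame_of_reference = FOR_UID, patient_id = "PB1")
  g <- small_grid(dose_field_spec("LINEAR_X", gradient = 0.2, intercept = 5),
                  shape = c(8, 8, 4))
  plan <- rt_plan_summary(60, 30, target_name = "GTV", technique = "SBRT")
  path <- withr::local_tempfile(fileext = ".json")
  write_case_bundle(ss, g, plan, path)
  got <- read_case_bundle(path)
  expect_identical(got$structure_set$structures[[1]]$name, "GTV")
  expect_equal(got$structure_set$structures[[1]]$contours,
               ss$structures[[1]]$contours)
  expect_equal(got$dose_grid$values, g$values)
  expect_equal(got$dose_grid$z_offsets, g$z_offsets)
  expect_equal(got$plan$prescription_dose, 60)
  expect_identical(got$plan$fractions, 30L)
  not_bundle <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), not_bundle)
  expect_error(read_case_bundle(not_bundle), class = "rtqa_format_error")
})
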