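# Synthetic patient records: fill the full template chain (consult ->
# follow-up) with plausible, schema-conformant values drawn reproducibly
# from an explicit seed. These emulate discrete clinical capture for
# prostate and lung radiotherapy; they are NOT population-calibrated.

.FIRST_NAMES <- c("James", "Mary", "Robert", "Patricia", "John", "Jennifer",
                  "Michael", "Linda", "David", "Elizabeth", "William", "Susan")
.LAST_NAMES <- c("Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia",
                 "Miller", "Davis", "Rodriguez", "Martinez", "Wilson", "Lopez")
.COMORBIDITIES <- c("none", "hypertension", "type 2 diabetes",
                    "coronary artery disease", "COPD")

.new_encounter <- function(date, fields, provenance = NULL) {
  if (is.null(provenance))
    provenance <- stats::setNames(as.list(rep("ENTERED", length(fields))),
                                  names(fields))
  list(date = as.character(date), fields = fields, provenance = provenance)
}

#' Generate a synthetic patient record
#'
#' Fills the full template chain for one disease site with plausible values
#' drawn reproducibly from `seed`. `overrides` force named fields (matched
#' against the site's schemas; unknown names raise an error); derived fields
#' (the NCCN risk group) are recomputed after overrides unless themselves
#' overridden.
#'
#' @param disease_site "PROSTATE" or "LUNG"
#' @param seed integer seed; identical seeds give identical records
#' @param overrides named list of field values to force
#' @return object of class `rt_patient_record`
#' @export
make_patient_record <- function(disease_site = c("PROSTATE", "LUNG"),
                                seed = 1L, overrides = list()) {
  disease_site <- match.arg(disease_site)
  with_rtqa_rng(derive_seed(seed, paste0("record/", disease_site)), {
    first <- sample(.FIRST_NAMES, 1); last <- sample(.LAST_NAMES, 1)
    identity <- list(
      name = paste(first, last),
      mrn = sprintf("MRN%07d", sample.int(9999999L, 1)),
      dob = as.character(as.Date("1935-01-01") + sample.int(11000L, 1)),
      address = sprintf("%d Oak Street, Springfield", sample.int(999L, 1)),
      phone = sprintf("555-%04d", sample.int(9999L, 1))
    )
    d0 <- as.Date("2020-01-01") + sample.int(365L, 1)
    enc <- list()
    if (disease_site == "PROSTATE") {
      t_stage <- sample(c("T1c", "T2a", "T2b", "T2c", "T3a"), 1,
                        prob = c(.40, .20, .15, .15, .10))
      gp <- sample(3:5, 1, prob = c(.5, .4, .1))
      gs <- sample(3:5, 1, prob = c(.4, .5, .1))
      psa <- round(min(200, max(0.1, stats::rlnorm(1, log(9), 0.7))), 1)
      consult <- list(
        age = round(stats::runif(1, 55, 85)),
        ecog = sample(0:2, 1, prob = c(.6, .3, .1)),
        t_stage = t_stage, n_stage = "N0", m_stage = "M0",
        gleason_primary = gp, gleason_secondary = gs, psa = psa,
        risk_group = NA_character_,  # derived below
        treatment_intent = sample(c("CURATIVE", "PALLIATIVE"), 1, prob = c(.95, .05)),
        hormone_therapy = NA,        # depends on risk, set below
        comorbidity = sample(.COMORBIDITIES, 1)
      )
      rx <- sample(list(c(78, 39), c(70, 28), c(60, 20)), 1)[[1]]
      sim <- list(target_name = "PTV",
                  prescription_dose_gy = rx[1], fractions = as.integer(rx[2]),
                  technique = sample(c("VMAT", "IMRT"), 1, prob = c(.7, .3)),
                  immobilization = "vac-lok with knee sponge")
      otv <- list(otv_week = sample(2:7, 1),
                  gu_toxicity_grade = sample(0:2, 1, prob = c(.5, .4, .1)),
                  gi_toxicity_grade = sample(0:2, 1, prob = c(.6, .3, .1)))
      completed <- stats::runif(1) < 0.95
      fx_done <- if (completed) sim$fractions else sim$fractions - sample(1:3, 1)
      eot <- list(total_dose_delivered_gy = round(sim$prescription_dose_gy *
                                                   fx_done / sim$fractions, 1),
                  fractions_delivered = as.integer(fx_done),
                  treatment_completed = completed,
                  eot_gu_toxicity_grade = sample(0:3, 1, prob = c(.4, .4, .15, .05)),
                  eot_gi_toxicity_grade = sample(0:3, 1, prob = c(.5, .35, .1, .05)))
      fup <- list(months_since_rt = 3,
                  fu_psa = round(stats::runif(1, 0.05, 2.0), 2),
                  recurrence = stats::runif(1) < 0.05,
                  late_gi_toxicity_grade = sample(0:1, 1, prob = c(.85, .15)))
    } else {
      consult <- list(
        age = round(stats::runif(1, 55, 88)),
        ecog = sample(0:3, 1, prob = c(.3, .4, .2, .1)),
        t_stage = sample(c("T1a", "T1b", "T1c", "T2a", "T2b", "T3", "T4"), 1,
                         prob = c(.1, .2, .15, .2, .15, .12, .08)),
        n_stage = sample(c("N0", "N1", "N2", "N3"), 1, prob = c(.45, .2, .25, .1)),
        m_stage = "M0",
        histology = sample(c("ADENOCARCINOMA", "SQUAMOUS", "SMALL_CELL",
                             "NSCLC_NOS"), 1, prob = c(.45, .3, .15, .1)),
        smoking_status = sample(c("CURRENT", "FORMER", "NEVER"), 1,
                                prob = c(.35, .5, .15)),
        fev1_pct = round(stats::runif(1, 40, 110)),
        treatment_intent = sample(c("CURATIVE", "PALLIATIVE"), 1, prob = c(.8, .2)),
        comorbidity = sample(.COMORBIDITIES, 1)
      )
      sbrt <- stats::runif(1) < 0.3
      rx <- if (sbrt) c(54, 3) else sample(list(c(60, 30), c(66, 33)), 1)[[1]]
      sim <- list(target_name = "PTV",
                  prescription_dose_gy = rx[1], fractions = as.integer(rx[2]),
                  technique = if (sbrt) "SBRT" else sample(c("VMAT", "IMRT"), 1),
                  motion_management = if (sbrt) "4DCT_ITV" else
                    sample(c("NONE", "4DCT_ITV", "GATING"), 1, prob = c(.5, .4, .1)))
      otv <- list(otv_week = sample(1:6, 1),
                  esophagitis_grade = sample(0:2, 1, prob = c(.5, .35, .15)),
                  dyspnea_grade = sample(0:2, 1, prob = c(.6, .3, .1)),
                  weight_loss_pct = round(stats::runif(1, 0, 8), 1))
      completed <- stats::runif(1) < 0.93
      fx_done <- if (completed) sim$fractions else max(1L, sim$fractions - sample(1:4, 1))
      eot <- list(total_dose_delivered_gy = round(sim$prescription_dose_gy *
                                                   fx_done / sim$fractions, 1),
                  fractions_delivered = as.integer(fx_done),
                  treatment_completed = completed,
                  eot_esophagitis_grade = sample(0:3, 1, prob = c(.4, .4, .15, .05)))
      fup <- list(months_since_rt = 3,
                  pneumonitis_grade = sample(0:2, 1, prob = c(.75, .2, .05)),
                  recurrence = stats::runif(1) < 0.12)
    }
    enc$CONSULT <- .new_encounter(d0, consult)
    enc$SIM_DIRECTIVE <- .new_encounter(d0 + 14, sim)
    # prescription fields come across from the planning system
    for (nm in c("target_name", "prescription_dose_gy", "fractions", "technique"))
      enc$SIM_DIRECTIVE$provenance[[nm]] <- "IMPORTED"
    enc$OTV <- .new_encounter(d0 + 28, otv)
    enc$EOT <- .new_encounter(d0 + 80, eot)
    enc$FOLLOWUP <- .new_encounter(d0 + 170, fup)

    record <- structure(list(
      patient_key = sprintf("PT-%s-%05d", substr(disease_site, 1, 2),
                            sample.int(99999L, 1)),
      disease_site = disease_site,
      identity = identity,
      encounters = enc), class = "rt_patient_record")

    record <- .apply_overrides(record, overrides)

    if (disease_site == "PROSTATE") {
      cf <- record$encounters$CONSULT$fields
      if (!"risk_group" %in% names(overrides)) {
        record$encounters$CONSULT$fields$risk_group <-
          compute_nccn_risk(cf$t_stage, cf$gleason_primary,
                            cf$gleason_secondary, cf$psa)
        record$encounters$CONSULT$provenance$risk_group <- "AUTO_CALCULATED"
      }
      if (!"hormone_therapy" %in% names(overrides)) {
        risk <- record$encounters$CONSULT$fields$risk_group
        p <- switch(risk, HIGH = .9, INTERMEDIATE = .4, LOW = .05)
        record$encounters$CONSULT$fields$hormone_therapy <- stats::runif(1) < p
      }
    }
    record <- autopopulate(record, "EOT")
    attr(record, "warnings") <- NULL
    record
  })
}

.apply_overrides <- function(record, overrides) {
  if (!length(overrides)) return(record)
  catalogue <- load_template_catalogue()
  for (nm in names(overrides)) {
    placed <- FALSE
    for (tid in .TEMPLATE_ORDER) {
      schema <- catalogue$schemas[[paste(record$disease_site, tid, sep = ".")]]
      if (!is.null(schema) && nm %in% names(schema$fields)) {
        record$encounters[[tid]]$fields[[nm]] <- overrides[[nm]]
        record$encounters[[tid]]$provenance[[nm]] <- "ENTERED"
        placed <- TRUE
        break
      }
    }
    if (!placed)
      rtqa_error(paste("override of unknown field:", nm), "rtqa_unknown_field")
  }
  record
}

#' @export
print.rt_patient_record <- function(x, ...) {
  cat(sprintf("<rt_patient_record> %s (%s), %d encounters\n", x$patient_key,
              x$disease_site, length(x$encounters)))
  invisible(x)
}

#' Write / read a patient record as JSON
#' @param record an `rt_patient_record`
#' @param path file path
#' @return `path` invisibly / the record
#' @export
write_patient_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_patient_record
#' @export
read_patient_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$encounters <- lapply(x$encounters, function(e) {
    e$fields <- lapply(e$fields, function(v) {
      if (is.list(v)) unlist(v) else v
    })
    e
  })
  structure(x, class = "rt_patient_record")
}

#' Generate a reproducible synthetic cohort
#'
#' Patients are assigned to practices round-robin. Each entry carries the
#' record, a plan summary taken from the simulation directive, a synthetic
#' constraint report (metric values sampled around the packaged constraint
#' limits and graded with the real comparator logic), and the flattened
#' feature map used by the CQM engine.
#'
#' @param n number of patients (>= 1)
#' @param sites character vector of practice labels
#' @param seed integer seed
#' @param disease_site "PROSTATE" or "LUNG"
#' @return list of entries: record, plan, constraint_report, practice, features
#' @export
make_cohort <- function(n, sites = c("practice_A", "practice_B"), seed = 1L,
                        disease_site = "PROSTATE") {
  stopifnot(n >= 1)
  constraints <- read_constraint_set(rtqa_extdata(
    "constraints", paste0(tolower(disease_site), ".json")))
  lapply(seq_len(n), function(i) {
    rec_seed <- derive_seed(seed, paste0("cohort/", i))
    record <- make_patient_record(disease_site, seed = rec_seed)
    sim <- record$encounters$SIM_DIRECTIVE$fields
    plan <- rt_plan_summary(sim$prescription_dose_gy, sim$fractions,
                            target_name = sim$target_name,
                            technique = sim$technique,
                            plan_label = paste0("PLAN-", record$patient_key))
    report <- with_rtqa_rng(derive_seed(rec_seed, "dvh"), {
      .synthetic_constraint_report(constraints)
    })
    entry <- list(record = record, plan = plan, constraint_report = report,
                  practice = sites[((i - 1L) %% length(sites)) + 1L])
    entry$features <- flatten_features(record, plan, report)
    entry
  })
}

# sample a measured value near each constraint's limits and grade it with
# the production comparator; roughly 85% pass / 10% variation / 5% fail
.synthetic_constraint_report <- function(constraints) {
  rows <- lapply(constraints, function(con) {
    u <- stats::runif(1)
    pl <- con$pass_limit
    vl <- if (is.null(con$variation_limit)) con$pass_limit else con$variation_limit
    value <- if (con$comparator == "LE") {
      if (u < .85) pl * stats::runif(1, 0.4, 1.0)
      else if (u < .95 && vl > pl) stats::runif(1, pl, vl)
      else vl * stats::runif(1, 1.02, 1.3)
    } else {
      if (u < .85) pl * stats::runif(1, 1.0, 1.1)
      else if (u < .95 && vl < pl) stats::runif(1, vl, pl)
      else vl * stats::runif(1, 0.7, 0.98)
    }
    st <- grade_value(value, con$comparator, con$pass_limit, con$variation_limit)
    list(structure = con$structure, metric = con$metric_label,
         comparator = con$comparator, pass_limit = con$pass_limit,
         variation_limit = vl, value = value, status = st,
         reason = sprintf("%s = %.4g vs %s limit %.4g", con$metric_label,
                          value, con$comparator, con$pass_limit))
  })
  .constraint_report(rows)
}
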