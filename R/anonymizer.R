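# De-identification with consistent keyed pseudonymization, uniform
# per-patient date shifting (intervals preserved), DICOM UID remapping that
# keeps the RTSTRUCT/RTDOSE/RTPLAN triplet internally consistent, and
# integrity sealing via a cryptographic digest over a canonical
# serialization. Identifier handling fails closed: an identity field the
# policy does not cover is an error, never silently kept.

#' Read an anonymization policy
#'
#' The policy maps record identity fields and DICOM attributes to actions
#' (REMOVE, REPLACE_DUMMY, HASH_PSEUDONYM, KEEP, SHIFT_DATE). Loading
#' verifies that every mandatory identifier category is covered and that
#' no identifier is mapped to KEEP.
#'
#' @param path policy JSON (default: the packaged policy)
#' @return object of class `rt_anon_policy`
#' @export
read_anonymization_policy <- function(path = rtqa_extdata("anonymization",
                                                          "policy_default.json")) {
  p <- jsonlite::read_json(path)
  mandatory <- as.character(unlist(p$mandatory_identifiers))
  for (f in mandatory) {
    act <- p$record_fields[[f]]
    if (is.null(act))
      rtqa_error(paste("policy does not cover mandatory identifier:", f),
                 "rtqa_policy_error")
    if (identical(act, "KEEP"))
      rtqa_error(paste("policy maps identifier to KEEP:", f),
                 "rtqa_policy_error")
  }
  structure(list(record_fields = p$record_fields,
                 dicom_tags = p$dicom_tags,
                 uid_root = p$uid_root %||% "2.25",
                 date_shift_range = p$date_shift_range %||% 90L,
                 mandatory_identifiers = mandatory),
            class = "rt_anon_policy")
}

#' Create an anonymization map
#'
#' Holds the secret key for the keyed one-way pseudonym/UID derivation,
#' plus the accumulated original -> pseudonym pairs and per-patient date
#' offsets, so re-anonymizing the same inputs reproduces the same outputs.
#'
#' @param key secret key material (keep out of exported data)
#' @return object of class `rt_anon_map` (an environment)
#' @export
new_anonymization_map <- function(key) {
  e <- new.env(parent = emptyenv())
  e$key <- key
  e$pseudonyms <- list()
  e$date_offsets <- list()
  class(e) <- "rt_anon_map"
  e
}

.keyed_hash <- function(map, ...) {
  digest::hmac(map$key, paste(c(...), collapse = "|"), algo = "sha256")
}

.pseudonym_for <- function(map, original) {
  k <- as.character(original)
  if (is.null(map$pseudonyms[[k]])) {
    p <- paste0("ANON-", toupper(substr(.keyed_hash(map, "pseudonym", k), 1, 12)))
    map$pseudonyms[[k]] <- p
  }
  map$pseudonyms[[k]]
}

.date_offset_for <- function(map, patient_key, range_days) {
  k <- as.character(patient_key)
  if (is.null(map$date_offsets[[k]])) {
    h <- .keyed_hash(map, "dateshift", k)
    span <- 2L * as.integer(range_days) + 1L
    map$date_offsets[[k]] <- (strtoi(substr(h, 1, 7), 16L) %% span) -
      as.integer(range_days)
  }
  map$date_offsets[[k]]
}

.shift_date <- function(s, offset) {
  d <- suppressWarnings(as.Date(s))
  if (is.na(d)) return(s)
  as.character(d + offset)
}

#' De-identify a patient record
#'
#' Identity fields are actioned per policy; the patient key is replaced by
#' a keyed pseudonym; every date in the record (encounter dates and
#' date-typed fields) is shifted by one consistent per-patient offset so
#' all intervals are preserved. A field in the identity block that the
#' policy does not cover raises an unhandled-identifier error.
#'
#' @param record an `rt_patient_record`
#' @param policy an [read_anonymization_policy()] result
#' @param map an [new_anonymization_map()]; updated in place
#' @return list(record = de-identified record, map = map)
#' @export
anonymize_record <- function(record, policy, map) {
  offset <- .date_offset_for(map, record$patient_key, policy$date_shift_range)
  out <- record
  for (f in names(record$identity)) {
    act <- policy$record_fields[[f]]
    if (is.null(act))
      rtqa_error(paste("identity field not covered by policy:", f),
                 "rtqa_unhandled_identifier")
    out$identity[[f]] <- switch(act,
      REMOVE = NULL,
      REPLACE_DUMMY = "REDACTED",
      HASH_PSEUDONYM = .pseudonym_for(map, record$identity[[f]]),
      SHIFT_DATE = .shift_date(record$identity[[f]], offset),
      KEEP = record$identity[[f]],
      rtqa_error(paste("unknown policy action:", act), "rtqa_policy_error"))
  }
  out$patient_key <- .pseudonym_for(map, record$patient_key)
  for (tid in names(out$encounters)) {
    if (!is.null(out$encounters[[tid]]$date))
      out$encounters[[tid]]$date <- .shift_date(out$encounters[[tid]]$date,
                                                offset)
  }
  list(record = out, map = map)
}

# UI-VR attributes that identify the dataset lineage and must be remapped;
# class UIDs (which identify *what* the object is) are left alone.
.UID_KEEP <- c("SOPClassUID", "MediaStorageSOPClassUID", "TransferSyntaxUID",
               "ImplementationClassUID", "ReferencedSOPClassUID")

.anon_uid <- function(map, uid, uid_root) {
  k <- as.character(uid)
  cache_key <- paste0("uid:", k)
  if (is.null(map$pseudonyms[[cache_key]])) {
    h <- .keyed_hash(map, "uid", k)
    a <- strtoi(substr(h, 1, 7), 16L)
    b <- strtoi(substr(h, 8, 14), 16L)
    d <- strtoi(substr(h, 15, 21), 16L)
    map$pseudonyms[[cache_key]] <- paste(uid_root, a, b, d, sep = ".")
  }
  map$pseudonyms[[cache_key]]
}

.anonymize_elements <- function(els, policy, map, patient_key, offset) {
  out <- list()
  for (e in els) {
    act <- policy$dicom_tags[[e$name]]
    if (!is.null(act)) {
      if (identical(act, "REMOVE")) next
      e$value <- switch(act,
        REPLACE_DUMMY = "ANON",
        HASH_PSEUDONYM = .pseudonym_for(map, e$value),
        SHIFT_DATE = {
          d <- as.Date(e$value, format = "%Y%m%d")
          if (is.na(d)) e$value else format(d + offset, "%Y%m%d")
        },
        KEEP = e$value,
        rtqa_error(paste("unknown policy action:", act), "rtqa_policy_error"))
    } else if (e$vr == "UI" && !e$name %in% .UID_KEEP) {
      e$value <- vapply(e$value, function(u)
        .anon_uid(map, u, policy$uid_root), character(1), USE.NAMES = FALSE)
    } else if (e$vr == "SQ") {
      e$value <- lapply(e$value, .anonymize_elements, policy = policy,
                        map = map, patient_key = patient_key, offset = offset)
    }
    out[[length(out) + 1L]] <- e
  }
  out
}

#' De-identify a DICOM dataset
#'
#' Identifying attributes are actioned per policy; every instance/frame
#' UID (all UI elements except storage-class UIDs) is remapped through a
#' deterministic keyed derivation under the policy's `uid_root`, so the
#' RTSTRUCT/RTDOSE/RTPLAN triplet processed with one map keeps its
#' cross-references (frame of reference, referenced SOP instances) valid.
#'
#' @param dcm an `rtqa_dicom` dataset from [dcm_read()]
#' @param policy an [read_anonymization_policy()] result
#' @param map an [new_anonymization_map()]; updated in place
#' @return the de-identified `rtqa_dicom` dataset
#' @export
anonymize_dicom <- function(dcm, policy, map) {
  pid <- dcm_get(dcm, "PatientID") %||% "UNKNOWN"
  offset <- .date_offset_for(map, pid, policy$date_shift_range)
  dcm$elements <- .anonymize_elements(dcm$elements, policy, map, pid, offset)
  dcm$path <- NULL
  dcm
}

# ---- integrity sealing -----------------------------------------------------

.audit_env <- new.env(parent = emptyenv())
.audit_env$log <- list()

.audit <- function(event, detail) {
  .audit_env$log[[length(.audit_env$log) + 1L]] <-
    list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         event = event, detail = detail)
}

#' Read (or clear) the audit trail
#' @param clear if TRUE, empty the trail after reading
#' @return list of audit entries (time, event, detail)
#' @export
audit_trail <- function(clear = FALSE) {
  out <- .audit_env$log
  if (clear) .audit_env$log <- list()
  out
}

# canonical serialization: keys sorted recursively, fixed numeric format
.canonical_json <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v))) v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = NA, null = "null")
}

#' Seal a payload with a cryptographic digest
#'
#' The digest is computed over a canonical, key-sorted JSON serialization
#' so logically identical payloads always produce identical digests.
#'
#' @param payload an R object (list/record/report) to seal
#' @param algorithm digest algorithm (default sha256)
#' @return object of class `rt_integrity_envelope`: digest hex + algorithm
#' @export
seal <- function(payload, algorithm = "sha256") {
  structure(list(algorithm = algorithm,
                 digest = digest::digest(.canonical_json(payload),
                                         algo = algorithm, serialize = FALSE)),
            class = "rt_integrity_envelope")
}

#' Verify a sealed payload
#'
#' Returns TRUE iff the recomputed digest matches the envelope. A failed
#' verification appends an entry to the audit trail and returns FALSE
#' (with a "reason" attribute); the caller's contract is to reject the
#' payload, not to process it.
#'
#' @param payload the payload to check
#' @param envelope the [seal()] envelope
#' @return logical; FALSE carries a "reason" attribute
#' @export
verify_seal <- function(payload, envelope) {
  if (!envelope$algorithm %in% c("sha256", "sha512", "md5")) {
    .audit("integrity_failure", paste("unknown algorithm", envelope$algorithm))
    return(structure(FALSE, reason = paste("unknown algorithm:",
                                           envelope$algorithm)))
  }
  actual <- digest::digest(.canonical_json(payload),
                           algo = envelope$algorithm, serialize = FALSE)
  if (!identical(actual, envelope$digest)) {
    .audit("integrity_failure",
           sprintf("digest mismatch (%s): payload rejected", envelope$algorithm))
    return(structure(FALSE, reason = "digest mismatch"))
  }
  TRUE
}
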