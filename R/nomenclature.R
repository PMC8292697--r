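# TG-263 nomenclature standardization: exact/synonym lookup on normalized
# labels, plus ranked fuzzy suggestions (normalized Levenshtein similarity)
# for human confirmation. Suggestions are never auto-applied below score
# 1.0; applying a mapping is a separate, explicit act.

.LATERALITY_TOKENS <- c("lt" = "l", "left" = "l", "l" = "l",
                        "rt" = "r", "right" = "r", "r" = "r")

#' Normalize a raw structure label for matching
#'
#' Lowercases, collapses non-alphanumeric runs to single spaces, strips
#' leading/trailing separators, and canonicalizes laterality tokens
#' ("lt"/"left"/"l" -> "l"; "rt"/"right"/"r" -> "r").
#'
#' @param raw raw label text
#' @return normalized label (empty input normalizes to empty)
#' @export
normalize_label <- function(raw) {
  vapply(raw, function(s) {
    s <- tolower(s)
    s <- gsub("[^a-z0-9]+", " ", s)
    s <- trimws(s)
    if (!nzchar(s)) return("")
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    lat <- .LATERALITY_TOKENS[toks]
    toks <- ifelse(is.na(lat), toks, lat)
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a TG-263 lexicon from JSON
#'
#' Entries carry a canonical `tg263_name`, a synonym list and a category
#' (TARGET or OAR). Canonical names must be unique and no normalized
#' synonym may map to two canonicals.
#'
#' @param path lexicon JSON (default: the packaged starter lexicon)
#' @return object of class `rt_lexicon`
#' @export
read_lexicon <- function(path = rtqa_extdata("lexicon_tg263.json")) {
  raw <- jsonlite::read_json(path)
  entries <- lapply(raw$entries, function(e)
    list(tg263_name = e$tg263_name,
         synonyms = as.character(unlist(e$synonyms)),
         category = e$category))
  canon <- vapply(entries, function(e) e$tg263_name, character(1))
  if (anyDuplicated(canon))
    rtqa_error("duplicate canonical names in lexicon", "rtqa_config_error")
  syn_map <- list()
  for (e in entries) {
    for (s in normalize_label(c(e$tg263_name, e$synonyms))) {
      if (!is.null(syn_map[[s]]) && syn_map[[s]] != e$tg263_name)
        rtqa_error(sprintf("synonym \"%s\" maps to both %s and %s", s,
                           syn_map[[s]], e$tg263_name), "rtqa_config_error")
      syn_map[[s]] <- e$tg263_name
    }
  }
  structure(list(entries = entries, version = raw$version),
            class = "rt_lexicon")
}

#' @export
print.rt_lexicon <- function(x, ...) {
  cat("<rt_lexicon>", length(x$entries), "entries, version",
      x$version %||% "?", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalized Levenshtein similarity: 1 - d / max(nchar)
.label_similarity <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) return(1)
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(nchar(a), nchar(b))
}

#' Suggest TG-263 names for a raw structure label
#'
#' Exact matches against canonical names and synonym matches (both on
#' normalized labels) come first with score 1.0. Otherwise the top-`k`
#' fuzzy candidates by normalized Levenshtein similarity are returned,
#' all with score >= `threshold`, in descending score with alphabetical
#' tie-break.
#'
#' @param raw raw structure label
#' @param lexicon an [read_lexicon()] result
#' @param k maximum number of fuzzy suggestions
#' @param threshold minimum similarity in \[0, 1\]
#' @return data.frame(tg263_name, score, match_kind)
#' @export
suggest_tg263 <- function(raw, lexicon, k = 5L, threshold = 0.70) {
  stopifnot(k >= 1L, threshold >= 0, threshold <= 1)
  if (!length(lexicon$entries))
    rtqa_error("empty lexicon", "rtqa_config_error")
  nraw <- normalize_label(raw)
  out <- data.frame(tg263_name = character(), score = numeric(),
                    match_kind = character())
  for (e in lexicon$entries) {
    if (normalize_label(e$tg263_name) == nraw)
      out <- rbind(out, data.frame(tg263_name = e$tg263_name, score = 1,
                                   match_kind = "EXACT"))
    else if (nraw %in% normalize_label(e$synonyms))
      out <- rbind(out, data.frame(tg263_name = e$tg263_name, score = 1,
                                   match_kind = "SYNONYM"))
  }
  if (nrow(out)) {
    out <- out[order(out$match_kind, out$tg263_name), , drop = FALSE]  # EXACT < SYNONYM
    rownames(out) <- NULL
    return(out)
  }
  cand <- do.call(rbind, lapply(lexicon$entries, function(e) {
    s <- max(.label_similarity(nraw, normalize_label(e$tg263_name)),
             vapply(normalize_label(e$synonyms),
                    function(x) .label_similarity(nraw, x), numeric(1),
                    USE.NAMES = FALSE), 0)
    data.frame(tg263_name = e$tg263_name, score = s, match_kind = "FUZZY")
  }))
  cand <- cand[cand$score >= threshold, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$tg263_name), , drop = FALSE]
  cand <- utils::head(cand, k)
  rownames(cand) <- NULL
  cand
}

#' Apply a confirmed raw-name -> TG-263 mapping to a structure set
#'
#' Structures named in `mapping` are renamed; unmapped structures are
#' retained and flagged nonstandard. Two raw names mapping to one canonical
#' is a conflict (merges are not supported), and the post-rename name set
#' must be unique.
#'
#' @param ss an [rt_structure_set()]
#' @param mapping named character vector / list, raw name -> TG-263 name
#' @return the renamed structure set; each structure gains a `nonstandard`
#'   flag
#' @export
apply_mapping <- function(ss, mapping) {
  mapping <- unlist(mapping)
  raw_names <- vapply(ss$structures, function(s) s$name, character(1))
  missing <- setdiff(names(mapping), raw_names)
  if (length(missing))
    rtqa_error(paste("mapped raw names not present in structure set:",
                     paste(missing, collapse = ", ")), "rtqa_mapping_error")
  dup <- mapping[duplicated(mapping) | duplicated(mapping, fromLast = TRUE)]
  if (length(dup))
    rtqa_error(sprintf("mapping conflict: raw names {%s} all map to %s",
                       paste(names(mapping)[mapping %in% dup], collapse = ", "),
                       paste(unique(dup), collapse = ", ")),
               "rtqa_mapping_conflict")
  new_names <- raw_names
  for (i in seq_along(ss$structures)) {
    nm <- raw_names[i]
    if (nm %in% names(mapping)) {
      ss$structures[[i]]$name <- unname(mapping[[nm]])
      ss$structures[[i]]$nonstandard <- FALSE
      new_names[i] <- mapping[[nm]]
    } else {
      ss$structures[[i]]$nonstandard <- TRUE
    }
  }
  if (anyDuplicated(new_names))
    rtqa_error(paste("structure names not unique after mapping:",
                     paste(new_names[duplicated(new_names)], collapse = ", ")),
               "rtqa_mapping_conflict")
  ss
}
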