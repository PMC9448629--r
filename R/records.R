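#' Construct a clinical record
#'
#' A record is one patient's tokenized diagnosis-and-treatment episode:
#' deduplicated symptom tokens, a primary constitution from the fixed 9-label
#' set, optional secondary constitutions, and regimen / disease / drug tokens.
#'
#' @param record_id Non-empty string, unique within a corpus.
#' @param symptoms Character vector of symptom tokens.
#' @param primary_constitution One label from [constitution_labels].
#' @param secondary_constitutions Character vector of labels (may be empty);
#'   must not contain the primary constitution.
#' @param regimen,diseases,drugs Character vectors of tokens (may be empty).
#' @return An object of class `tcm_record`.
#' @examples
#' medical_record("R1", c("easy fatigue", "pale face"), "QDC",
#'                regimen = "warm diet")
#' @export
medical_record <- function(record_id, symptoms, primary_constitution,
                           secondary_constitutions = character(),
                           regimen = character(),
                           diseases = character(),
                           drugs = character()) {
  record_id <- trimws(as.character(record_id))
  if (length(record_id) != 1L || !nzchar(record_id))
    stop("record_id must be a single non-empty string", call. = FALSE)
  primary <- validate_tokens(primary_constitution, "constitution",
                             "primary_constitution")
  if (length(primary) != 1L)
    stop("exactly one primary constitution required", call. = FALSE)
  secondary <- validate_tokens(secondary_constitutions, "constitution",
                               "secondary_constitutions")
  if (primary %in% secondary)
    stop("primary constitution must not appear in secondary_constitutions",
         call. = FALSE)
  rec <- list(
    record_id = record_id,
    symptoms = validate_tokens(symptoms, "symptom"),
    primary_constitution = primary,
    secondary_constitutions = secondary,
    regimen = validate_tokens(regimen, "regimen"),
    diseases = validate_tokens(diseases, "disease"),
    drugs = validate_tokens(drugs, "drug")
  )
  class(rec) <- "tcm_record"
  rec
}

#' @export
print.tcm_record <- function(x, ...) {
  cat("<tcm_record ", x$record_id, "> ", x$primary_constitution, "; ",
      length(x$symptoms), " symptom(s); ", length(x$regimen),
      " regimen item(s)\n", sep = "")
  invisible(x)
}

record_fields <- c("record_id", "symptoms", "primary_constitution",
                   "secondary_constitutions", "regimen", "diseases", "drugs")
multi_fields <- setdiff(record_fields,
                        c("record_id", "primary_constitution"))

validate_corpus <- function(records) {
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(ids))
    stop("duplicate record_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  invisible(records)
}

as_chr <- function(x) {
  if (is.null(x) || (is.list(x) && !length(x))) character(0)
  else as.character(unlist(x, use.names = FALSE))
}

record_from_list <- function(x) {
  medical_record(
    record_id = as_chr(x$record_id),
    symptoms = as_chr(x$symptoms),
    primary_constitution = as_chr(x$primary_constitution),
    secondary_constitutions = as_chr(x$secondary_constitutions),
    regimen = as_chr(x$regimen),
    diseases = as_chr(x$diseases),
    drugs = as_chr(x$drugs)
  )
}

#' Read and write clinical-record corpora
#'
#' JSONL is the canonical serialization: one JSON object per line with fields
#' `record_id`, `symptoms[]`, `primary_constitution`,
#' `secondary_constitutions[]`, `regimen[]`, `diseases[]`, `drugs[]`. The CSV
#' dialect uses the same columns with multi-valued cells joined by `"|"`.
#' Order is preserved; a write-then-read round trip is the identity on
#' validated records.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `read_records()`: a list of [medical_record()] objects, in file
#'   order. `write_records()`: `path`, invisibly.
#' @export
read_records <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      tryCatch(
        record_from_list(jsonlite::fromJSON(lines[[i]],
                                            simplifyVector = TRUE)),
        error = function(e) {
          stop("malformed record at line ", i, " of ", path, ": ",
               conditionMessage(e), call. = FALSE)
        })
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    missing <- setdiff(record_fields, names(df))
    if (length(missing))
      stop("CSV is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    lapply(seq_len(nrow(df)), function(i) {
      row <- lapply(df[i, record_fields, drop = FALSE], as.character)
      for (f in multi_fields) {
        row[[f]] <- if (nzchar(row[[f]]))
          strsplit(row[[f]], "|", fixed = TRUE)[[1]] else character(0)
      }
      tryCatch(record_from_list(row), error = function(e) {
        stop("malformed record at row ", i, " of ", path, ": ",
             conditionMessage(e), call. = FALSE)
      })
    })
  }
  validate_corpus(records)
  records
}

#' @rdname read_records
#' @param records List of [medical_record()] objects.
#' @export
write_records <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  validate_corpus(records)
  if (format == "jsonl") {
    # scalar fields stay scalar, multi-valued fields stay arrays
    lines <- vapply(records, function(r) {
      x <- unclass(r)
      as.character(jsonlite::toJSON(
        c(list(record_id = jsonlite::unbox(x$record_id)),
          list(symptoms = x$symptoms,
               primary_constitution = jsonlite::unbox(x$primary_constitution),
               secondary_constitutions = x$secondary_constitutions,
               regimen = x$regimen, diseases = x$diseases, drugs = x$drugs))))
    }, character(1))
    writeLines(lines, path)
  } else {
    df <- data.frame(
      record_id = vapply(records, `[[`, character(1), "record_id"),
      stringsAsFactors = FALSE
    )
    df$symptoms <- vapply(records, function(r)
      paste(r$symptoms, collapse = "|"), character(1))
    df$primary_constitution <- vapply(records, `[[`, character(1),
                                      "primary_constitution")
    for (f in setdiff(multi_fields, "symptoms"))
      df[[f]] <- vapply(records, function(r)
        paste(r[[f]], collapse = "|"), character(1))
    df <- df[, record_fields, drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Project records onto transactions
#'
#' Each record yields exactly one transaction (an item set of qualified
#' `"role:token"` items); duplicate records yield duplicate transactions, so
#' the corpus is a multiset and identical records count multiply toward
#' support.
#'
#' @param records List of [medical_record()] objects.
#' @param projection `"symptom_constitution"` (symptoms plus the primary
#'   constitution; the stage-1 classification view), `"constitution_regimen"`
#'   (primary constitution plus regimen items; the stage-1 recommendation
#'   view), or `"full"` (union of all item sets).
#' @param include_secondary Include secondary constitution labels as items
#'   (default `FALSE`; their participation in mining is configurable because
#'   it is not fixed by the record model).
#' @return List of character vectors (one transaction per record, in order).
#' @export
to_transactions <- function(records,
                            projection = c("symptom_constitution",
                                           "constitution_regimen", "full"),
                            include_secondary = FALSE) {
  projection <- match.arg(projection)
  lapply(records, function(r) {
    cons <- tcm_item(r$primary_constitution, "constitution")
    if (include_secondary && length(r$secondary_constitutions))
      cons <- c(cons, tcm_item(r$secondary_constitutions, "constitution"))
    items <- switch(projection,
      symptom_constitution = c(tcm_item(r$symptoms, "symptom"), cons),
      constitution_regimen = c(cons, tcm_item(r$regimen, "regimen")),
      full = c(tcm_item(r$symptoms, "symptom"), cons,
               tcm_item(r$regimen, "regimen"),
               tcm_item(r$diseases, "disease"),
               tcm_item(r$drugs, "drug"))
    )
    unique(items)
  })
}
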