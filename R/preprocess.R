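#' Default stop-word list
#'
#' Ships with the package as a plain-text fixture (one word per line):
#' articles, pronouns, auxiliary verbs, prepositions and conjunctions that
#' carry no diagnostic signal and would otherwise inflate the item vocabulary.
#'
#' @return Character vector of lower-case stop words.
#' @export
default_stoplist <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "tcmrules",
                      mustWork = TRUE)
  words <- readLines(path, warn = FALSE)
  tolower(trimws(words[nzchar(trimws(words))]))
}

#' Remove stop words from a token sequence
#'
#' Case-insensitive filtering that preserves the order of the surviving
#' tokens. Applied to symptom tokens only in the pipeline; label items are a
#' controlled vocabulary and are never filtered.
#'
#' @param tokens Character vector.
#' @param stoplist Character vector of stop words (default the shipped list).
#' @return `tokens` without the stop words, original order kept.
#' @examples
#' remove_stopwords(c("this", "fatigue", "and"))
#' @export
remove_stopwords <- function(tokens, stoplist = default_stoplist()) {
  if (!length(tokens)) return(character(0))
  tokens[!(tolower(tokens) %in% tolower(stoplist))]
}

#' Profile symptoms across the nine constitutions
#'
#' For every distinct symptom token, counts the records of each constitution
#' that contain it. Discriminability is `max(counts) / sum(counts)`: 1 when a
#' symptom is exclusive to one constitution, `1/9` when spread evenly over all
#' nine. Low-discriminability symptoms are the "shared symptom" noise that
#' degrades constitution recognition.
#'
#' @param records List of [medical_record()] objects.
#' @return Data frame with columns `symptom`, one count column per label in
#'   [constitution_labels], `total` and `discriminability`.
#' @export
profile_symptoms <- function(records) {
  labs <- constitution_labels
  empty <- data.frame(symptom = character(0), stringsAsFactors = FALSE)
  for (l in labs) empty[[l]] <- integer(0)
  empty$total <- integer(0)
  empty$discriminability <- numeric(0)
  if (!length(records)) return(empty)
  sym <- unlist(lapply(records, `[[`, "symptoms"), use.names = FALSE)
  con <- rep(vapply(records, `[[`, character(1), "primary_constitution"),
             vapply(records, function(r) length(r$symptoms), integer(1)))
  if (!length(sym)) return(empty)
  tab <- table(factor(sym), factor(con, levels = labs))
  out <- data.frame(symptom = rownames(tab), stringsAsFactors = FALSE)
  for (l in labs) out[[l]] <- as.integer(tab[, l])
  counts <- as.matrix(tab)
  out$total <- as.integer(rowSums(counts))
  out$discriminability <- ifelse(out$total > 0,
                                 apply(counts, 1, max) / out$total, NA_real_)
  rownames(out) <- NULL
  out[order(out$symptom, method = "radix"), , drop = FALSE]
}

#' Remove cross-constitution shared symptoms
#'
#' Deletes from every record the symptoms that occur at least
#' `min_occurrences` times corpus-wide yet discriminate poorly between
#' constitutions (discriminability below `min_discriminability`). A symptom
#' seen evenly in two constitutions ("pale red tongue" in both BC and QDC
#' records) has discriminability 0.5 and is removed at the default threshold;
#' a symptom exclusive to one constitution has discriminability 1 and is
#' always retained. Records themselves are never deleted, so the operation is
#' idempotent and conserves the record count.
#'
#' @param records List of [medical_record()] objects.
#' @param min_discriminability Threshold in `(0, 1]`; symptoms strictly below
#'   it are removed. Default 0.8.
#' @param min_occurrences Minimum corpus-wide occurrence count (>= 1) for a
#'   symptom to be eligible for removal; rarer symptoms are left alone.
#'   Default 2.
#' @return List with `records` (filtered corpus, same length and order) and
#'   `removed` (the [profile_symptoms()] rows of the deleted symptoms).
#' @export
remove_shared_symptoms <- function(records, min_discriminability = 0.8,
                                   min_occurrences = 2) {
  if (!is.numeric(min_discriminability) || length(min_discriminability) != 1 ||
      min_discriminability <= 0 || min_discriminability > 1)
    stop("min_discriminability must be a single value in (0, 1]",
         call. = FALSE)
  if (!is.numeric(min_occurrences) || min_occurrences < 1)
    stop("min_occurrences must be >= 1", call. = FALSE)
  prof <- profile_symptoms(records)
  drop <- prof$total >= min_occurrences &
    prof$discriminability < min_discriminability
  removed <- prof[drop, , drop = FALSE]
  if (nrow(removed)) {
    bad <- removed$symptom
    records <- lapply(records, function(r) {
      r$symptoms <- setdiff(r$symptoms, bad)
      r
    })
  }
  list(records = records, removed = removed)
}

#' Preprocess a corpus for training
#'
#' Text stage: stop words are removed from the symptom tokens of every
#' record. Noise stage: shared symptoms are removed with
#' [remove_shared_symptoms()]. Record count and order are conserved.
#'
#' @inheritParams remove_shared_symptoms
#' @param stoplist Stop-word vector; `NULL` disables the text stage.
#' @return List with `records` and `removed` (as in
#'   [remove_shared_symptoms()]).
#' @export
preprocess_records <- function(records, stoplist = default_stoplist(),
                               min_discriminability = 0.8,
                               min_occurrences = 2) {
  if (!is.null(stoplist)) {
    records <- lapply(records, function(r) {
      r$symptoms <- remove_stopwords(r$symptoms, stoplist)
      r
    })
  }
  remove_shared_symptoms(records, min_discriminability, min_occurrences)
}
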