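#' Train the two-stage rule base
#'
#' Stage 1 of the procedure: preprocess the corpus (stop-word and
#' shared-symptom removal), project it twice — symptoms + constitution, and
#' constitution + regimen — and mine each projection with the partitioned
#' FP-growth miner. Association rules are then generated and filtered to the
#' two shapes the classifier consumes: symptom-only antecedents with a single
#' constitution consequent (`stage1_sc`), and a single-constitution antecedent
#' with a single regimen consequent (`stage1_cr`). All thresholds and
#' preprocessing settings are recorded on the rule base for provenance.
#'
#' @param records List of [medical_record()] objects (non-empty).
#' @param min_support_count Global minimum support count (default 20, the
#'   judging-standard floor of distinct symptom items per constitution).
#' @param min_confidence Minimum rule confidence (default 0.6).
#' @param stoplist Stop words for preprocessing (`NULL` disables).
#' @inheritParams remove_shared_symptoms
#' @inheritParams mine_parallel
#' @param include_secondary Include secondary constitutions in transactions.
#' @return Object of class `tcm_rulebase`: `stage1_sc`, `stage1_cr`
#'   (both [generate_rules()] outputs), `removed_symptoms`, `params`,
#'   `vocabulary`, `vocabulary_hash`.
#' @export
tcm_train <- function(records, min_support_count = 20, min_confidence = 0.6,
                      stoplist = default_stoplist(),
                      min_discriminability = 0.8, min_occurrences = 2,
                      n_shards = 1L, n_groups = 9L,
                      executor = c("serial", "multicore"),
                      include_secondary = FALSE) {
  executor <- match.arg(executor)
  if (!length(records)) stop("empty corpus", call. = FALSE)
  validate_corpus(records)
  prep <- preprocess_records(records, stoplist, min_discriminability,
                             min_occurrences)
  t_sc <- to_transactions(prep$records, "symptom_constitution",
                          include_secondary = include_secondary)
  t_cr <- to_transactions(prep$records, "constitution_regimen",
                          include_secondary = include_secondary)
  fi_sc <- mine_parallel(t_sc, min_support_count, n_shards, n_groups,
                         executor)
  fi_cr <- mine_parallel(t_cr, min_support_count, n_shards, n_groups,
                         executor)
  rules_sc <- generate_rules(fi_sc, min_confidence,
                             consequent_role = "constitution")
  rules_sc <- rules_sc[rules_sc$n_consequent == 1L &
                         vapply(key_items(rules_sc$antecedent), function(it)
                           all(item_role(it) == "symptom"), logical(1)), ,
                       drop = FALSE]
  rules_cr <- generate_rules(fi_cr, min_confidence,
                             consequent_role = "regimen")
  rules_cr <- rules_cr[rules_cr$n_consequent == 1L &
                         rules_cr$n_antecedent == 1L &
                         item_role(rules_cr$antecedent) == "constitution", ,
                       drop = FALSE]
  rownames(rules_sc) <- rownames(rules_cr) <- NULL
  if (!nrow(rules_sc))
    warning("no symptom -> constitution rules cleared the thresholds",
            call. = FALSE)
  if (!nrow(rules_cr))
    warning("no constitution -> regimen rules cleared the thresholds",
            call. = FALSE)
  vocab <- sort(unique(unlist(t_sc, use.names = FALSE)), method = "radix")
  rb <- list(
    stage1_sc = rules_sc,
    stage1_cr = rules_cr,
    removed_symptoms = prep$removed,
    params = list(min_support_count = min_support_count,
                  min_confidence = min_confidence,
                  min_discriminability = min_discriminability,
                  min_occurrences = min_occurrences,
                  n_shards = as.integer(n_shards),
                  n_groups = as.integer(n_groups),
                  executor = executor,
                  include_secondary = include_secondary,
                  stopwords = length(stoplist),
                  n_records = length(records)),
    vocabulary = vocab,
    vocabulary_hash = fnv1a_hash(vocab)
  )
  class(rb) <- "tcm_rulebase"
  rb
}

#' @export
print.tcm_rulebase <- function(x, ...) {
  cat("<tcm_rulebase>\n",
      "  symptom -> constitution rules: ", nrow(x$stage1_sc), "\n",
      "  constitution -> regimen rules: ", nrow(x$stage1_cr), "\n",
      "  min support ", x$params$min_support_count,
      ", min confidence ", x$params$min_confidence,
      ", trained on ", x$params$n_records, " record(s)\n", sep = "")
  invisible(x)
}

# antecedent-key -> rule-row index, built lazily and cached on the rule base
sc_rule_index <- function(rulebase) {
  idx <- attr(rulebase$stage1_sc, "antecedent_index")
  if (is.null(idx)) idx <- split(seq_len(nrow(rulebase$stage1_sc)),
                                 rulebase$stage1_sc$antecedent)
  idx
}

#' Classify a symptom set into constitutions
#'
#' Scores every constitution by summing the confidences of the stage-1
#' symptom rules whose antecedent is contained in the presented symptom set
#' (`method = "confidence_sum"`, the default; `"max_confidence"` and
#' `"support_weighted"` are variants). The score is monotone: presenting more
#' symptoms can only add matching rules. The top-scoring constitution is the
#' primary prediction; every constitution scoring at least
#' `multi_label_fraction` of the top score forms the predicted set, since a
#' patient may belong to several constitutions at once. Ties break by label
#' order for determinism.
#'
#' @param symptoms Character vector of symptom tokens (raw tokens or
#'   `"symptom:..."` items).
#' @param rulebase A trained [tcm_train()] rule base.
#' @param multi_label_fraction Multi-label cutoff as a fraction of the top
#'   score (default 0.5).
#' @param method Scoring variant.
#' @return Object of class `tcm_prediction`: `scores` (data frame
#'   `constitution`, `score`, non-increasing), `top` (single label or
#'   `NA` when nothing matched) and `predicted` (character vector, possibly
#'   empty).
#' @export
tcm_classify <- function(symptoms, rulebase, multi_label_fraction = 0.5,
                         method = c("confidence_sum", "max_confidence",
                                    "support_weighted")) {
  method <- match.arg(method)
  symptoms <- unique(ifelse(grepl("^symptom:", symptoms), symptoms,
                            tcm_item(symptoms, "symptom")))
  rules <- rulebase$stage1_sc
  idx <- sc_rule_index(rulebase)
  max_ant <- if (nrow(rules)) max(rules$n_antecedent) else 0L
  hit <- integer(0)
  if (length(symptoms) && max_ant > 0L) {
    # look up every subset of the symptom set no larger than the widest
    # antecedent; rules are indexed by antecedent key
    s <- sort(symptoms, method = "radix")
    sizes <- seq_len(min(max_ant, length(s)))
    keys <- unlist(lapply(sizes, function(k) {
      if (k == 1L) s
      else utils::combn(s, k, FUN = paste, collapse = "|")
    }), use.names = FALSE)
    hit <- unlist(idx[intersect(keys, names(idx))], use.names = FALSE)
  }
  labs <- constitution_labels
  score <- stats::setNames(numeric(length(labs)), labs)
  if (length(hit)) {
    matched <- rules[hit, , drop = FALSE]
    cons <- item_token(matched$consequent)
    w <- switch(method,
      confidence_sum = matched$confidence,
      max_confidence = matched$confidence,
      support_weighted = matched$confidence * matched$support_fraction)
    agg <- if (method == "max_confidence")
      tapply(w, cons, max) else tapply(w, cons, sum)
    score[names(agg)] <- agg
  }
  ord <- order(-score, labs, method = "radix")
  scores <- data.frame(constitution = labs[ord], score = unname(score[ord]),
                       stringsAsFactors = FALSE)
  top <- if (scores$score[1L] > 0) scores$constitution[1L] else NA_character_
  predicted <- if (is.na(top)) character(0) else
    scores$constitution[scores$score > 0 &
                          scores$score >= multi_label_fraction *
                          scores$score[1L]]
  structure(list(scores = scores, top = top, predicted = predicted),
            class = "tcm_prediction")
}

#' @export
print.tcm_prediction <- function(x, ...) {
  if (is.na(x$top)) {
    cat("<tcm_prediction> no rule matched\n")
  } else {
    cat("<tcm_prediction> top: ", x$top, "; predicted set: {",
        paste(x$predicted, collapse = ", "), "}\n", sep = "")
    print.data.frame(x$scores[x$scores$score > 0, , drop = FALSE],
                     digits = 4)
  }
  invisible(x)
}

#' Predict constitutions for a corpus
#'
#' Top-1 classification of each record's symptoms.
#'
#' @param object A `tcm_rulebase`.
#' @param records List of [medical_record()] objects.
#' @param ... Passed to [tcm_classify()].
#' @return Data frame `record_id`, `predicted` (NA when nothing matched),
#'   `score`, `truth` (the recorded primary constitution).
#' @export
predict.tcm_rulebase <- function(object, records, ...) {
  attr(object$stage1_sc, "antecedent_index") <- sc_rule_index(object)
  preds <- lapply(records, function(r)
    tcm_classify(r$symptoms, object, ...))
  data.frame(
    record_id = vapply(records, `[[`, character(1), "record_id"),
    predicted = vapply(preds, `[[`, character(1), "top"),
    score = vapply(preds, function(p) p$scores$score[1L], numeric(1)),
    truth = vapply(records, `[[`, character(1), "primary_constitution"),
    stringsAsFactors = FALSE
  )
}

#' Link the two rule stages
#'
#' Cross-joins the symptom -> constitution rules with the constitution ->
#' regimen rules on the shared constitution; the chain score is the product
#' of the two confidences, an upper bound on the confidence of the implied
#' symptoms -> regimen rule under the chaining route.
#'
#' @param rulebase A trained `tcm_rulebase`.
#' @return Data frame `symptoms` (antecedent key), `constitution`,
#'   `regimen_item`, `sc_confidence`, `cr_confidence`, `chain_score`; empty
#'   join allowed.
#' @export
tcm_link <- function(rulebase) {
  sc <- rulebase$stage1_sc
  cr <- rulebase$stage1_cr
  out <- data.frame(symptoms = character(0), constitution = character(0),
                    regimen_item = character(0), sc_confidence = numeric(0),
                    cr_confidence = numeric(0), chain_score = numeric(0),
                    stringsAsFactors = FALSE)
  if (!nrow(sc) || !nrow(cr)) return(out)
  sc_con <- item_token(sc$consequent)
  cr_con <- item_token(cr$antecedent)
  pieces <- lapply(intersect(unique(sc_con), unique(cr_con)), function(con) {
    a <- sc[sc_con == con, , drop = FALSE]
    b <- cr[cr_con == con, , drop = FALSE]
    grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(symptoms = a$antecedent[grid$i],
               constitution = con,
               regimen_item = item_token(b$consequent[grid$j]),
               sc_confidence = a$confidence[grid$i],
               cr_confidence = b$confidence[grid$j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(out[0, 1:5]), pieces))
  out$chain_score <- out$sc_confidence * out$cr_confidence
  out <- out[order(-out$chain_score, out$symptoms, out$regimen_item,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recommend regimens for a constitution
#'
#' Returns the constitution's regimen rules sorted by confidence then support
#' (descending, token order as final tie-break), truncated to `top_k`.
#'
#' @param constitution A label from [constitution_labels].
#' @param rulebase A trained `tcm_rulebase`.
#' @param top_k Maximum number of regimen items (default 5; 0 gives an empty
#'   result).
#' @return Data frame `regimen`, `confidence`, `support_count`.
#' @export
tcm_recommend <- function(constitution, rulebase, top_k = 5L) {
  constitution <- validate_tokens(constitution, "constitution")
  if (length(constitution) != 1L)
    stop("exactly one constitution label required", call. = FALSE)
  if (!is.numeric(top_k) || top_k < 0)
    stop("top_k must be a non-negative integer", call. = FALSE)
  cr <- rulebase$stage1_cr
  sel <- cr[item_token(cr$antecedent) == constitution, , drop = FALSE]
  sel <- sel[order(-sel$confidence, -sel$support_count, sel$consequent,
                   method = "radix"), , drop = FALSE]
  sel <- utils::head(sel, as.integer(top_k))
  data.frame(regimen = item_token(sel$consequent),
             confidence = sel$confidence,
             support_count = sel$support_count,
             stringsAsFactors = FALSE)
}

#' Serialize and restore a rule base
#'
#' A rule base round-trips through a single JSON document holding both rule
#' tables, all training parameters and the vocabulary hash.
#'
#' @param rulebase A `tcm_rulebase`.
#' @param path JSON file path.
#' @return `write_rulebase()`: `path` invisibly; `read_rulebase()`: the
#'   restored `tcm_rulebase`.
#' @export
write_rulebase <- function(rulebase, path) {
  doc <- list(
    format = "tcm_rulebase/1",
    params = rulebase$params,
    vocabulary = rulebase$vocabulary,
    vocabulary_hash = rulebase$vocabulary_hash,
    removed_symptoms = rulebase$removed_symptoms,
    stage1_sc = as.data.frame(rulebase$stage1_sc),
    stage1_cr = as.data.frame(rulebase$stage1_cr)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_rulebase
#' @export
read_rulebase <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$format) || !identical(doc$format, "tcm_rulebase/1"))
    stop("not a serialized rule base: ", path, call. = FALSE)
  as_rules <- function(x) {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    if (!nrow(df))
      df <- data.frame(antecedent = character(0), consequent = character(0),
                       n_antecedent = integer(0), n_consequent = integer(0),
                       support_count = integer(0), confidence = numeric(0),
                       support_fraction = numeric(0), lift = numeric(0),
                       stringsAsFactors = FALSE)
    class(df) <- c("tcm_rules", "data.frame")
    df
  }
  rb <- list(
    stage1_sc = as_rules(doc$stage1_sc),
    stage1_cr = as_rules(doc$stage1_cr),
    removed_symptoms = as.data.frame(doc$removed_symptoms,
                                     stringsAsFactors = FALSE),
    params = doc$params,
    vocabulary = as.character(doc$vocabulary),
    vocabulary_hash = doc$vocabulary_hash
  )
  class(rb) <- "tcm_rulebase"
  rb
}
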