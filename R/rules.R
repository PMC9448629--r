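#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2 and every non-empty proper split
#' into antecedent and consequent, emits the rule when
#' `confidence = support(antecedent + consequent) / support(antecedent)`
#' reaches `min_confidence`. The itemset collection must be downward-closed
#' (as the miners produce): a missing antecedent support is an error, never a
#' silent skip. Lift is computed and reported but never used for filtering.
#'
#' @param itemsets An `fp_itemsets` data frame from [fp_growth()] or
#'   [mine_parallel()].
#' @param min_confidence Minimum confidence in `[0, 1]` (default 0.6).
#' @param consequent_role Optional role from [item_roles]; when set, only
#'   rules whose consequent items all carry that role are emitted.
#' @param n_transactions Corpus size for support fractions and lift; defaults
#'   to the attribute carried by `itemsets`.
#' @return Object of class `tcm_rules` (a data frame): `antecedent` and
#'   `consequent` (itemset keys, items joined by `"|"`), `n_antecedent`,
#'   `n_consequent`, `support_count`, `support_fraction`, `confidence`,
#'   `lift`. Sorted by confidence, then support, descending.
#' @examples
#' db <- list(c("A", "B"), c("B", "C"), c("A", "B", "C"))
#' generate_rules(fp_growth(db, 2), min_confidence = 0.5)
#' @export
generate_rules <- function(itemsets, min_confidence = 0.6,
                           consequent_role = NULL, n_transactions = NULL) {
  if (!is.numeric(min_confidence) || length(min_confidence) != 1 ||
      min_confidence < 0 || min_confidence > 1)
    stop("min_confidence must be a single value in [0, 1]", call. = FALSE)
  if (!is.null(consequent_role))
    consequent_role <- match.arg(consequent_role, item_roles)
  if (is.null(n_transactions))
    n_transactions <- attr(itemsets, "n_transactions")
  support <- stats::setNames(itemsets$support, itemsets$key)
  big <- itemsets[itemsets$size >= 2L, , drop = FALSE]
  ant <- con <- character(0)
  n_a <- n_c <- sup <- conf <- numeric(0)
  out <- vector("list", nrow(big))
  for (r in seq_len(nrow(big))) {
    items <- key_items(big$key[r])[[1L]]
    m <- length(items)
    s_full <- big$support[r]
    masks <- seq_len(2^m - 2L)
    bits <- bitwShiftL(1L, 0:(m - 1L))
    a_keys <- c_keys <- character(length(masks))
    a_n <- c_n <- integer(length(masks))
    for (j in seq_along(masks)) {
      sel <- bitwAnd(masks[j], bits) != 0L
      a_keys[j] <- itemset_key(items[sel])
      c_keys[j] <- itemset_key(items[!sel])
      a_n[j] <- sum(sel)
      c_n[j] <- m - a_n[j]
    }
    s_ant <- unname(support[a_keys])
    if (anyNA(s_ant))
      stop("downward closure violated: missing support for antecedent(s) ",
           paste(a_keys[is.na(s_ant)], collapse = "; "), call. = FALSE)
    cf <- s_full / s_ant
    keep <- cf >= min_confidence
    if (!is.null(consequent_role)) {
      role_ok <- vapply(key_items(c_keys), function(it)
        all(item_role(it) == consequent_role), logical(1))
      keep <- keep & role_ok
    }
    if (any(keep))
      out[[r]] <- data.frame(antecedent = a_keys[keep],
                             consequent = c_keys[keep],
                             n_antecedent = a_n[keep],
                             n_consequent = c_n[keep],
                             support_count = s_full,
                             confidence = cf[keep],
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  rules <- if (length(out)) do.call(rbind, out) else
    data.frame(antecedent = character(0), consequent = character(0),
               n_antecedent = integer(0), n_consequent = integer(0),
               support_count = integer(0), confidence = numeric(0),
               stringsAsFactors = FALSE)
  rules$support_fraction <- if (length(n_transactions) && n_transactions > 0)
    rules$support_count / n_transactions else NA_real_
  s_con <- unname(support[rules$consequent])
  rules$lift <- if (length(n_transactions) && n_transactions > 0)
    rules$confidence / (s_con / n_transactions) else NA_real_
  rules <- rules[order(-rules$confidence, -rules$support_count,
                       rules$antecedent, rules$consequent,
                       method = "radix"), , drop = FALSE]
  rownames(rules) <- NULL
  attr(rules, "min_confidence") <- min_confidence
  attr(rules, "n_transactions") <- n_transactions
  class(rules) <- c("tcm_rules", "data.frame")
  rules
}

#' @export
print.tcm_rules <- function(x, ...) {
  cat("<tcm_rules> ", nrow(x), " rule(s) at min confidence ",
      attr(x, "min_confidence"), "\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 10L), digits = 4)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

#' Export rules as CSV
#'
#' @param rules A `tcm_rules` data frame.
#' @param path Output file path.
#' @export
write_rules <- function(rules, path) {
  utils::write.csv(as.data.frame(rules), path, row.names = FALSE)
  invisible(path)
}
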