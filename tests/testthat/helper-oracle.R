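# Independent brute-force oracle: enumerate every subset of every
# transaction and tally exact supports. Deliberately shares no code with the
# FP-growth implementations it is used to check.
brute_force_itemsets <- function(transactions, min_support_count) {
  tally <- new.env(parent = emptyenv())
  for (t in transactions) {
    items <- sort(unique(as.character(t)), method = "radix")
    m <- length(items)
    if (!m) next
    for (k in seq_len(m)) {
      keys <- if (k == 1L) items else
        utils::combn(items, k, FUN = paste, collapse = "|")
      for (key in keys) {
        cur <- tally[[key]]
        tally[[key]] <- if (is.null(cur)) 1L else cur + 1L
      }
    }
  }
  keys <- ls(tally, sorted = FALSE)
  sups <- vapply(keys, function(k) tally[[k]], integer(1), USE.NAMES = FALSE)
  keep <- sups >= min_support_count
  out <- data.frame(key = keys[keep], support = sups[keep],
                    stringsAsFactors = FALSE)
  out[order(out$key, method = "radix"), , drop = FALSE]
}

# random small transaction database over single-letter items
random_db <- function(n_items = 8, n_trans = 30) {
  universe <- LETTERS[seq_len(sample.int(n_items, 1))]
  n <- sample.int(n_trans, 1)
  lapply(seq_len(n), function(i) {
    sample(universe, sample.int(length(universe), 1))
  })
}

# normalize an fp_itemsets / decode_local / oracle result for comparison
canon_sets <- function(x) {
  sup <- if (is.null(x$support)) x$count else x$support
  df <- data.frame(key = x$key, support = as.integer(sup),
                   stringsAsFactors = FALSE)
  df <- df[order(df$key, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}
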