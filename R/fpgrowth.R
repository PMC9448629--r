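#' Build the frequent-item list (F-list)
#'
#' First database scan of FP-growth: tally every item, drop the items below
#' the minimum support count, and order the survivors by descending support.
#' Equal counts are broken by ascending token order (C locale) so the ordering
#' is deterministic across runs and shard counts.
#'
#' @param transactions List of character vectors (item sets). Duplicate items
#'   within a transaction are ignored (set semantics); duplicate transactions
#'   count multiply (multiset semantics across the corpus).
#' @param min_support_count Absolute minimum support count, >= 1.
#' @param weights Optional per-transaction integer weights (used internally
#'   for conditional pattern bases; default 1 each).
#' @return Data frame with columns `item` and `count`, rows in F-list order.
#' @examples
#' db <- list(c("A", "B"), c("B", "C"), c("A", "B", "C"))
#' build_flist(db, 2)
#' @export
build_flist <- function(transactions, min_support_count, weights = NULL) {
  if (!is.numeric(min_support_count) || min_support_count < 1)
    stop("min_support_count must be >= 1", call. = FALSE)
  empty <- data.frame(item = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(transactions)) return(empty)
  transactions <- lapply(transactions, unique)
  if (is.null(weights)) weights <- rep(1L, length(transactions))
  items <- unlist(transactions, use.names = FALSE)
  if (!length(items)) return(empty)
  w <- rep(weights, lengths(transactions))
  tal <- rowsum(w, items)
  counts <- tal[, 1L]
  nm <- rownames(tal)
  keep <- counts >= min_support_count
  counts <- counts[keep]
  nm <- nm[keep]
  ord <- order(-counts, nm, method = "radix")
  data.frame(item = nm[ord], count = as.integer(counts[ord]),
             stringsAsFactors = FALSE)
}

# --- FP-tree (reference implementation, environment-backed) ----------------

new_fptree <- function(items) {
  tree <- new.env(parent = emptyenv())
  tree$items <- items
  tree$rank <- stats::setNames(seq_along(items), items)
  tree$parent <- 0L          # node 1 is the root
  tree$item <- 0L            # item code, 0 = root marker
  tree$count <- 0L
  tree$n_nodes <- 1L
  tree$children <- new.env(hash = TRUE, parent = emptyenv())
  tree$header <- stats::setNames(vector("list", length(items)), items)
  class(tree) <- "fp_tree"
  tree
}

insert_path <- function(tree, codes, w) {
  cur <- 1L
  for (code in codes) {
    key <- paste0(cur, ".", code)
    nid <- tree$children[[key]]
    if (is.null(nid)) {
      nid <- tree$n_nodes + 1L
      tree$n_nodes <- nid
      tree$parent[nid] <- cur
      tree$item[nid] <- code
      tree$count[nid] <- w
      tree$children[[key]] <- nid
      it <- tree$items[code]
      tree$header[[it]] <- c(tree$header[[it]], nid)
    } else {
      tree$count[nid] <- tree$count[nid] + w
    }
    cur <- nid
  }
}

#' Build an FP-tree
#'
#' Second database scan: each transaction is filtered to F-list items, sorted
#' in F-list order (most frequent first) and inserted as a path from the root,
#' accumulating counts on shared prefixes. The header table links, per item,
#' every tree node carrying that item; the counts along each item's chain sum
#' to the item's F-list support.
#'
#' @inheritParams build_flist
#' @param flist F-list from [build_flist()] on the same transactions.
#' @return An `fp_tree` object (environment). Inspect with `as.data.frame()`.
#' @export
build_fptree <- function(transactions, flist, weights = NULL) {
  tree <- new_fptree(flist$item)
  if (is.null(weights)) weights <- rep(1L, length(transactions))
  for (i in seq_along(transactions)) {
    codes <- tree$rank[unique(transactions[[i]])]
    codes <- sort(codes[!is.na(codes)])
    if (length(codes)) insert_path(tree, unname(codes), weights[i])
  }
  tree
}

#' @export
as.data.frame.fp_tree <- function(x, ...) {
  n <- x$n_nodes
  data.frame(
    node = seq_len(n),
    item = c(NA_character_, x$items[x$item[-1L]])[seq_len(n)],
    count = x$count[seq_len(n)],
    parent = x$parent[seq_len(n)],
    stringsAsFactors = FALSE
  )
}

#' @export
print.fp_tree <- function(x, ...) {
  cat("<fp_tree> ", x$n_nodes - 1L, " node(s), ",
      length(x$items), " item(s) in header\n", sep = "")
  invisible(x)
}

#' Conditional pattern base of a suffix item
#'
#' One entry per node on the item's header chain: the root-to-parent prefix
#' path, with the count of the suffix node itself (the prefix counts are
#' re-based on the suffix, which is what makes the conditional database
#' correct when an item sits on several branches).
#'
#' @param tree An `fp_tree`.
#' @param item Item present in the tree header.
#' @return List of `list(items = <character prefix>, count = <int>)`.
#' @export
conditional_pattern_base <- function(tree, item) {
  nodes <- tree$header[[item]]
  if (is.null(nodes) || !length(nodes))
    stop("item not present in tree header: ", item, call. = FALSE)
  lapply(nodes, function(nid) {
    path <- integer(0)
    cur <- tree$parent[nid]
    while (cur > 1L) {
      path <- c(tree$item[cur], path)
      cur <- tree$parent[cur]
    }
    list(items = tree$items[path], count = tree$count[nid])
  })
}

# TRUE iff every node has at most one child (tree is one root path)
is_single_path <- function(tree) {
  n <- tree$n_nodes
  if (n <= 2L) return(TRUE)
  all(tree$parent[2:n] == 1:(n - 1L))
}

# frequent itemset container: data.frame(key, support, size) + metadata
fp_itemsets <- function(keys, supports, n_transactions, min_support_count) {
  ord <- order(keys, method = "radix")
  out <- data.frame(key = keys[ord], support = as.integer(supports[ord]),
                    stringsAsFactors = FALSE)
  out$size <- lengths(key_items(out$key))
  attr(out, "n_transactions") <- as.integer(n_transactions)
  attr(out, "min_support_count") <- as.integer(min_support_count)
  class(out) <- c("fp_itemsets", "data.frame")
  out
}

#' @export
print.fp_itemsets <- function(x, ...) {
  cat("<fp_itemsets> ", nrow(x), " itemset(s) at min support ",
      attr(x, "min_support_count"), " over ", attr(x, "n_transactions"),
      " transaction(s)\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

#' Mine frequent itemsets with FP-growth
#'
#' Reference single-machine miner: builds the F-list and FP-tree, then
#' recurses over conditional pattern bases, least-frequent header item first.
#' When a (conditional) tree degenerates to a single path, all sub-combinations
#' of the path are enumerated directly. Returns exactly the itemsets whose
#' support reaches `min_support_count`, each with its exact support.
#'
#' @inheritParams build_flist
#' @return An `fp_itemsets` data frame: `key` (items sorted and joined by
#'   `"|"`), `support`, `size`.
#' @examples
#' db <- list(c("A", "B"), c("B", "C"), c("A", "B", "C"))
#' fp_growth(db, 2)
#' @export
fp_growth <- function(transactions, min_support_count) {
  if (!is.numeric(min_support_count) || min_support_count < 1)
    stop("min_support_count must be >= 1", call. = FALSE)
  transactions <- lapply(transactions, function(t) unique(as.character(t)))
  acc <- new.env(parent = emptyenv())
  acc$keys <- vector("list", 0L)
  acc$sups <- vector("list", 0L)
  mine_rec(transactions, NULL, as.integer(min_support_count),
           character(0), acc)
  keys <- unlist(acc$keys, use.names = FALSE)
  sups <- unlist(acc$sups, use.names = FALSE)
  if (is.null(keys)) keys <- character(0)
  if (is.null(sups)) sups <- integer(0)
  fp_itemsets(keys, sups, length(transactions), min_support_count)
}

emit_sets <- function(acc, keys, sups) {
  acc$keys[[length(acc$keys) + 1L]] <- keys
  acc$sups[[length(acc$sups) + 1L]] <- sups
}

mine_rec <- function(transactions, weights, min_support, suffix, acc) {
  fl <- build_flist(transactions, min_support, weights)
  if (!nrow(fl)) return(invisible())
  tree <- build_fptree(transactions, fl, weights)
  # the subset shortcut is only worthwhile (and safe to allocate) on short paths
  if (is_single_path(tree) && tree$n_nodes <= 17L) {
    n <- tree$n_nodes
    if (n == 1L) return(invisible())
    path_items <- tree$items[tree$item[2:n]]
    path_counts <- tree$count[2:n]
    d <- n - 1L
    keys <- character(2^d - 1L)
    sups <- integer(2^d - 1L)
    for (mask in seq_len(2^d - 1L)) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) != 0L)
      keys[mask] <- itemset_key(c(path_items[sel], suffix))
      sups[mask] <- path_counts[max(sel)]
    }
    emit_sets(acc, keys, sups)
    return(invisible())
  }
  for (i in rev(seq_len(nrow(fl)))) {
    it <- fl$item[i]
    emit_sets(acc, itemset_key(c(it, suffix)), fl$count[i])
    cpb <- conditional_pattern_base(tree, it)
    cond_trans <- lapply(cpb, `[[`, "items")
    cond_w <- vapply(cpb, `[[`, integer(1), "count")
    keep <- lengths(cond_trans) > 0L
    if (any(keep))
      mine_rec(cond_trans[keep], cond_w[keep], min_support,
               c(it, suffix), acc)
  }
  invisible()
}

#' Export frequent itemsets as CSV
#'
#' Two columns: `items` (tokens joined by `"|"`, sorted) and `support`.
#'
#' @param itemsets An `fp_itemsets` object.
#' @param path Output file path.
#' @export
write_itemsets <- function(itemsets, path) {
  utils::write.csv(
    data.frame(items = itemsets$key, support = itemsets$support,
               stringsAsFactors = FALSE),
    path, row.names = FALSE)
  invisible(path)
}
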