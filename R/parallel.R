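#' Shard a transaction corpus horizontally
#'
#' Contiguous split in input order (no shuffling, for reproducibility); shard
#' sizes differ by at most one, larger shards first. Empty shards are allowed
#' when `n_shards` exceeds the corpus size. The shards partition the corpus:
#' disjoint, in order, multiplicities preserved.
#'
#' @param transactions List of character item vectors.
#' @param n_shards Positive integer.
#' @return List of shards; each shard is `list(shard_id, transactions)`.
#' @export
shard_transactions <- function(transactions, n_shards) {
  if (!is.numeric(n_shards) || length(n_shards) != 1 || n_shards < 1)
    stop("n_shards must be a positive integer", call. = FALSE)
  n_shards <- as.integer(n_shards)
  n <- length(transactions)
  base <- n %/% n_shards
  extra <- n %% n_shards
  sizes <- rep(base, n_shards) + c(rep(1L, extra), rep(0L, n_shards - extra))
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  lapply(seq_len(n_shards), function(i) {
    idx <- if (sizes[i] > 0) seq(starts[i], stops[i]) else integer(0)
    list(shard_id = i - 1L, transactions = transactions[idx])
  })
}

#' Global F-list from shards
#'
#' Sums per-shard item tallies, thresholds at the global minimum support and
#' orders as [build_flist()] does. By construction this equals `build_flist()`
#' on the unsharded corpus for any shard count.
#'
#' @param shards List of shards from [shard_transactions()].
#' @inheritParams build_flist
#' @return F-list data frame (`item`, `count`).
#' @export
global_flist <- function(shards, min_support_count) {
  build_flist(unlist(lapply(shards, `[[`, "transactions"), recursive = FALSE),
              min_support_count)
}

#' Balanced grouping of F-list items
#'
#' Round-robin by F-list rank: the item at 0-based rank `r` goes to group
#' `r %% n_groups`, so group sizes differ by at most one and the grouping is
#' deterministic. Group-filtered mining tasks then partition the itemset space
#' by the group of each itemset's rightmost (least frequent) item.
#'
#' @param flist F-list data frame.
#' @param n_groups Positive integer; default 9, one group per constitution.
#' @return Object of class `fp_groups`: `n_groups` and `mapping` (named
#'   integer vector, item -> 0-based group id).
#' @export
assign_groups <- function(flist, n_groups = 9L) {
  if (!is.numeric(n_groups) || length(n_groups) != 1 || n_groups < 1)
    stop("n_groups must be a positive integer", call. = FALSE)
  n_groups <- as.integer(n_groups)
  mapping <- if (nrow(flist))
    stats::setNames((seq_len(nrow(flist)) - 1L) %% n_groups, flist$item)
  else stats::setNames(integer(0), character(0))
  structure(list(n_groups = n_groups, mapping = mapping),
            class = "fp_groups")
}

encode_transactions <- function(transactions, flist) {
  rank <- stats::setNames(seq_len(nrow(flist)), flist$item)
  lapply(transactions, function(t) {
    codes <- rank[unique(t)]
    as.integer(sort(codes[!is.na(codes)]))
  })
}

#' Mine one shard locally
#'
#' Builds and mines a local FP-tree over the shard's transactions, restricted
#' to global F-list items and sorted in global F-list order. Local supports
#' are kept unthresholded (local minimum support 1) so that merging local
#' counts and thresholding globally is exact. With a `group` filter, only the
#' itemsets whose rightmost (least frequent, highest F-list rank) item belongs
#' to that group are mined; the union over all groups equals the unfiltered
#' result.
#'
#' @param shard A shard from [shard_transactions()].
#' @param flist Global F-list (computed before any local mining).
#' @param groups [assign_groups()] result; required when `group` is set.
#' @param group Optional 0-based group id to mine, or `NULL` for all itemsets.
#' @param min_local_support Local support floor (default 1; the merge step is
#'   only exact at 1).
#' @return Object of class `fp_local`: `shard_id`, `group`, `flist` and
#'   `itemsets` (a data.table with F-list-coded `key` and local `count`).
#'   Decode for inspection with [decode_local()].
#' @export
mine_shard <- function(shard, flist, groups = NULL, group = NULL,
                       min_local_support = 1L) {
  codes <- encode_transactions(shard$transactions, flist)
  use_filter <- !is.null(group)
  allowed <- integer(0)
  if (use_filter) {
    if (is.null(groups))
      stop("groups assignment required when group filter is set",
           call. = FALSE)
    allowed <- which(unname(groups$mapping) == as.integer(group))
  }
  res <- cpp_fpgrowth(codes, nrow(flist), as.integer(min_local_support),
                      as.integer(allowed), use_filter)
  structure(
    list(shard_id = shard$shard_id,
         group = if (use_filter) as.integer(group) else NA_integer_,
         flist = flist,
         itemsets = data.table::data.table(iset = res$key, count = res$count)),
    class = "fp_local")
}

#' @export
print.fp_local <- function(x, ...) {
  cat("<fp_local> shard ", x$shard_id,
      if (!is.na(x$group)) paste0(", group ", x$group) else "",
      ": ", nrow(x$itemsets), " local itemset(s)\n", sep = "")
  invisible(x)
}

decode_code_keys <- function(keys, flist) {
  vapply(strsplit(keys, "|", fixed = TRUE),
         function(cs) itemset_key(flist$item[as.integer(cs)]),
         character(1))
}

#' Decode a local mining result to item tokens
#'
#' @param local An `fp_local` object.
#' @return Data frame with `key` (item strings) and `count`.
#' @export
decode_local <- function(local) {
  data.frame(key = decode_code_keys(local$itemsets$iset, local$flist),
             count = local$itemsets$count, stringsAsFactors = FALSE)
}

#' Merge local results into global frequent itemsets
#'
#' Sums each itemset's local counts across shards, then keeps the itemsets
#' whose global count reaches the minimum support, with their exact global
#' support. Errors if the same (shard, group) task is present twice
#' (inconsistent shard coverage would double-count).
#'
#' @param local_results List of `fp_local` objects covering all shards.
#' @inheritParams build_flist
#' @param n_transactions Total corpus size (carried onto the result).
#' @return An `fp_itemsets` data frame.
#' @export
merge_local_results <- function(local_results, min_support_count,
                                n_transactions) {
  if (!length(local_results))
    stop("no local results to merge", call. = FALSE)
  tasks <- vapply(local_results, function(l)
    paste0(l$shard_id, "/", l$group), character(1))
  if (anyDuplicated(tasks))
    stop("inconsistent shard coverage: duplicated (shard, group) task(s): ",
         paste(unique(tasks[duplicated(tasks)]), collapse = ", "),
         call. = FALSE)
  flist <- local_results[[1L]]$flist
  for (l in local_results[-1L])
    if (!identical(l$flist$item, flist$item))
      stop("local results were mined against different F-lists",
           call. = FALSE)
  count <- NULL  # data.table NSE
  dt <- data.table::rbindlist(lapply(local_results, `[[`, "itemsets"))
  if (!nrow(dt))
    return(fp_itemsets(character(0), integer(0), n_transactions,
                       min_support_count))
  glob <- dt[, list(support = sum(count)), by = "iset"]
  glob <- glob[glob$support >= min_support_count, ]
  fp_itemsets(decode_code_keys(glob$iset, flist), glob$support,
              n_transactions, min_support_count)
}

#' Partitioned FP-growth mining
#'
#' The full shard-and-merge miner: horizontal sharding, one global F-list
#' (communicated once), per-(shard, group) local FP-tree mining with no
#' further communication, and a merge that sums local counts and applies the
#' global threshold. The result — itemsets and supports — is identical for
#' every shard count, group count and executor, and equals [fp_growth()] on
#' the unsharded corpus.
#'
#' @inheritParams build_flist
#' @param n_shards Number of horizontal shards (default 1).
#' @param n_groups Number of balanced item groups (default 9); `1` disables
#'   group filtering.
#' @param executor `"serial"` (reference) or `"multicore"`
#'   (`parallel::mclapply`, forked worker processes; falls back to serial
#'   scheduling where forking is unavailable).
#' @param mc_cores Worker count for the multicore executor (default 2).
#' @return An `fp_itemsets` data frame.
#' @examples
#' db <- list(c("A", "B"), c("B", "C"), c("A", "B", "C"))
#' mine_parallel(db, 2, n_shards = 2, n_groups = 2)
#' @export
mine_parallel <- function(transactions, min_support_count, n_shards = 1L,
                          n_groups = 9L,
                          executor = c("serial", "multicore"),
                          mc_cores = 2L) {
  executor <- match.arg(executor)
  if (!is.numeric(min_support_count) || min_support_count < 1)
    stop("min_support_count must be >= 1", call. = FALSE)
  shards <- shard_transactions(transactions, n_shards)
  gfl <- global_flist(shards, min_support_count)
  if (!nrow(gfl))
    return(fp_itemsets(character(0), integer(0), length(transactions),
                       min_support_count))
  groups <- assign_groups(gfl, n_groups)
  tasks <- expand.grid(shard = seq_along(shards),
                       group = seq_len(groups$n_groups) - 1L)
  run_task <- function(i) {
    g <- if (groups$n_groups > 1L) tasks$group[i] else NULL
    mine_shard(shards[[tasks$shard[i]]], gfl, groups, group = g)
  }
  idx <- seq_len(if (groups$n_groups > 1L) nrow(tasks)
                 else length(shards))
  locals <- if (executor == "serial") {
    lapply(idx, run_task)
  } else {
    res <- parallel::mclapply(idx, run_task,
                              mc.cores = max(1L, as.integer(mc_cores)))
    bad <- vapply(res, inherits, logical(1), "try-error")
    if (any(bad))
      stop("multicore task failed: ",
           conditionMessage(attr(res[[which(bad)[1L]]], "condition")),
           call. = FALSE)
    res
  }
  merge_local_results(locals, min_support_count, length(transactions))
}
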