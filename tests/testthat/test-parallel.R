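test_that("sharding is a balanced contiguous partition", {
  trans <- as.list(letters[1:10])
  sh <- shard_transactions(trans, 3)
  expect_equal(vapply(sh, function(s) length(s$transactions), integer(1)),
               c(4L, 3L, 3L))
  expect_equal(vapply(sh, `[[`, integer(1), "shard_id"), 0:2)
  # concatenation restores the corpus in order
  expect_identical(unlist(lapply(sh, `[[`, "transactions"),
                          recursive = FALSE), trans)
  expect_identical(shard_transactions(trans, 1)[[1]]$transactions, trans)
  # more shards than transactions: empty shards allowed
  sh2 <- shard_transactions(trans[1:2], 5)
  expect_length(sh2, 5)
  expect_equal(sum(lengths(lapply(sh2, `[[`, "transactions"))), 2)
  expect_error(shard_transactions(trans, 0), "positive")
})

test_that("global F-list equals the unsharded F-list for any shard count", {
  set.seed(31)
  for (i in 1:10) {
    db <- random_db()
    ms <- sample.int(4, 1)
    ref <- build_flist(db, ms)
    for (k in c(1, 2, 4))
      expect_equal(global_flist(shard_transactions(db, k), ms), ref)
  }
  expect_equal(nrow(global_flist(shard_transactions(list(), 3), 1)), 0)
})

test_that("balanced grouping is round-robin by rank and balanced within 1", {
  fl <- data.frame(item = letters[1:9], count = 9:1)
  ga <- assign_groups(fl, 9)
  expect_equal(unname(ga$mapping), 0:8)           # bijection
  ga10 <- assign_groups(rbind(fl, data.frame(item = "j", count = 1)), 9)
  expect_equal(sum(ga10$mapping == 0), 2)         # pigeonhole
  expect_true(all(table(ga10$mapping) %in% 1:2))
  set.seed(5)
  for (i in 1:10) {
    n <- sample.int(40, 1)
    g <- sample.int(9, 1)
    ga <- assign_groups(data.frame(item = as.character(seq_len(n)),
                                   count = rep(1, n)), g)
    sizes <- tabulate(ga$mapping + 1L, nbins = g)
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("mine_shard on the whole corpus equals support-1 fp_growth over F-list items", {
  set.seed(41)
  for (i in 1:10) {
    db <- random_db()
    fl <- build_flist(db, 2)
    if (!nrow(fl)) next
    local <- mine_shard(list(shard_id = 0L, transactions = db), fl)
    got <- canon_sets(decode_local(local))
    # oracle: all itemsets over F-list items, any support
    ref <- brute_force_itemsets(lapply(db, intersect, fl$item), 1)
    expect_equal(got, canon_sets(ref), info = paste("db", i))
  }
  empty <- mine_shard(list(shard_id = 0L, transactions = list()),
                      build_flist(toy_db(), 2))
  expect_equal(nrow(empty$itemsets), 0)
})

test_that("group-filtered tasks partition the itemset space", {
  set.seed(51)
  for (i in 1:8) {
    db <- random_db()
    fl <- build_flist(db, 1)
    ga <- assign_groups(fl, 9)
    sh <- list(shard_id = 0L, transactions = db)
    unfiltered <- canon_sets(decode_local(mine_shard(sh, fl)))
    parts <- lapply(0:8, function(g)
      decode_local(mine_shard(sh, fl, ga, group = g)))
    combined <- do.call(rbind, parts)
    # disjoint union: no itemset appears in two groups
    expect_false(anyDuplicated(combined$key) > 0)
    expect_equal(canon_sets(combined), unfiltered, info = paste("db", i))
  }
})

test_that("merge sums local counts and enforces task coverage", {
  db <- toy_db()
  fl <- build_flist(db, 2)
  sh <- shard_transactions(db, 2)
  locals <- lapply(sh, mine_shard, flist = fl)
  merged <- merge_local_results(locals, 2, length(db))
  expect_equal(canon_sets(merged), toy_expected())
  # single shard: pass-through thresholding
  one <- merge_local_results(list(mine_shard(
    list(shard_id = 0L, transactions = db), fl)), 2, length(db))
  expect_equal(canon_sets(one), toy_expected())
  # merge conservation: global support = sum of local supports
  decs <- lapply(locals, decode_local)
  for (j in seq_len(nrow(merged))) {
    locs <- vapply(decs, function(d) {
      v <- d$count[d$key == merged$key[j]]
      if (length(v)) v else 0L
    }, integer(1))
    expect_true(all(locs <= merged$support[j]))
    expect_equal(sum(locs), merged$support[j])
  }
  expect_error(merge_local_results(c(locals, locals[1]), 2, 3),
               "inconsistent shard coverage")
})

test_that("mine_parallel is invariant to shards, groups and executor", {
  expect_equal(canon_sets(mine_parallel(toy_db(), 2)), toy_expected())
  set.seed(61)
  for (i in 1:10) {
    db <- random_db()
    ms <- sample.int(4, 1)
    ref <- canon_sets(fp_growth(db, ms))
    for (k in c(1, 2, 4, 8)) {
      for (g in c(1, 9)) {
        expect_equal(
          canon_sets(mine_parallel(db, ms, n_shards = k, n_groups = g)),
          ref, info = paste("db", i, "shards", k, "groups", g))
      }
    }
  }
  # degenerate configuration is bit-identical to fp_growth
  expect_identical(
    as.data.frame(mine_parallel(toy_db(), 2, n_shards = 1, n_groups = 1)),
    as.data.frame(fp_growth(toy_db(), 2)))
  # multicore executor agrees with serial
  db <- random_db()
  expect_equal(
    canon_sets(mine_parallel(db, 2, n_shards = 3, executor = "multicore")),
    canon_sets(mine_parallel(db, 2, n_shards = 3, executor = "serial")))
})
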