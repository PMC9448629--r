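test_that("F-list thresholds, orders and tie-breaks deterministically", {
  fl <- build_flist(toy_db(), 2)
  expect_equal(fl$item, c("B", "A", "C"))  # tie A/C broken by token order
  expect_equal(fl$count, c(3L, 2L, 2L))
  expect_equal(nrow(build_flist(list(), 1)), 0)
  expect_equal(nrow(build_flist(toy_db(), 4)), 0)
  expect_error(build_flist(toy_db(), 0), ">= 1")
})

test_that("FP-tree matches the hand-traced structure", {
  fl <- build_flist(toy_db(), 2)
  tree <- build_fptree(toy_db(), fl)
  df <- as.data.frame(tree)
  # root -> B(3); B -> A(2); A -> C(1); B -> C(1)
  # (nodes appear in insertion order: B, A, then C under B, then C under A)
  expect_equal(df$item, c(NA, "B", "A", "C", "C"))
  expect_equal(df$count, c(0, 3, 2, 1, 1))
  expect_equal(df$parent, c(0, 1, 2, 2, 3))
  # single transaction: one path, counts 1
  t1 <- build_fptree(list(c("A", "B")), build_flist(list(c("A", "B")), 1))
  expect_equal(as.data.frame(t1)$count, c(0, 1, 1))
  # nothing frequent: bare root
  t0 <- build_fptree(toy_db(), build_flist(toy_db(), 4))
  expect_equal(t0$n_nodes, 1L)
})

test_that("header chains conserve F-list supports", {
  for (seed in 1:5) {
    set.seed(seed)
    db <- random_db()
    fl <- build_flist(db, sample.int(3, 1))
    if (!nrow(fl)) next
    tree <- build_fptree(db, fl)
    for (i in seq_len(nrow(fl))) {
      nodes <- tree$header[[fl$item[i]]]
      expect_equal(sum(tree$count[nodes]), fl$count[i])
    }
  }
})

test_that("conditional pattern bases enumerate prefix paths with re-based counts", {
  fl <- build_flist(toy_db(), 2)
  tree <- build_fptree(toy_db(), fl)
  cpb <- conditional_pattern_base(tree, "C")
  got <- lapply(cpb, function(e) list(items = sort(e$items), count = e$count))
  expect_setequal(got, list(list(items = "B", count = 1L),
                            list(items = c("A", "B"), count = 1L)))
  # item with no ancestors: empty prefixes
  cpb_b <- conditional_pattern_base(tree, "B")
  expect_true(all(lengths(lapply(cpb_b, `[[`, "items")) == 0))
  expect_error(conditional_pattern_base(tree, "Z"), "not present")
})

test_that("fp_growth reproduces the worked example and the power-set case", {
  expect_equal(canon_sets(fp_growth(toy_db(), 2)), toy_expected())
  all7 <- fp_growth(list(c("A", "B", "C")), 1)
  expect_equal(nrow(all7), 7)
  expect_true(all(all7$support == 1))
  expect_equal(nrow(fp_growth(list(), 1)), 0)
})

test_that("fp_growth equals the brute-force oracle on random databases", {
  set.seed(1001)
  for (i in 1:40) {
    db <- random_db()
    ms <- sample.int(5, 1)
    expect_equal(canon_sets(fp_growth(db, ms)),
                 canon_sets(brute_force_itemsets(db, ms)),
                 info = paste("db", i, "min", ms))
  }
})

test_that("downward closure and anti-monotonicity hold on mined output", {
  set.seed(2002)
  for (i in 1:10) {
    db <- random_db()
    res <- fp_growth(db, 2)
    sup <- stats::setNames(res$support, res$key)
    for (r in seq_len(nrow(res))) {
      items <- strsplit(res$key[r], "|", fixed = TRUE)[[1]]
      if (length(items) < 2) next
      for (drop in seq_along(items)) {
        sub <- paste(items[-drop], collapse = "|")
        expect_false(is.na(sup[sub]))           # subset reported
        expect_gte(sup[[sub]], res$support[r])  # support anti-monotone
      }
    }
  }
})
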