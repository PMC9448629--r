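test_that("generator config validates its invariants", {
  expect_s3_class(generator_config(), "tcm_genconfig")
  expect_error(generator_config(n_records = -1), "n_records")
  expect_error(generator_config(prevalence = rep(0.2, 5)), "9 non-negative")
  expect_error(generator_config(prevalence = rep(0.2, 9)), "sum to 1")
  expect_error(generator_config(shared_symptom_rate = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(symptoms_per_record = c(5, 2)),
               "lo <= hi")
})

test_that("degenerate configurations behave as stated", {
  expect_length(simulate_records(generator_config(n_records = 0))$records, 0)
  prev <- c(1, rep(0, 8))
  sim <- simulate_records(generator_config(n_records = 40,
                                           prevalence = prev, seed = 2,
                                           label_noise_rate = 0))
  expect_true(all(vapply(sim$records, `[[`, character(1),
                         "primary_constitution") == "BC"))
})

test_that("generation is bit-identical for identical configs", {
  cfg <- preset_config("uniform", n_records = 150, seed = 33)
  s1 <- simulate_records(cfg)
  s2 <- simulate_records(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$planted_rules, s2$truth$planted_rules)
  s3 <- simulate_records(preset_config("uniform", n_records = 150,
                                       seed = 34))
  expect_false(identical(s1$records, s3$records))
})

test_that("class frequencies track the prevalence vector", {
  n <- 10000
  sim <- simulate_records(preset_config("uniform", n_records = n, seed = 5))
  labels <- vapply(sim$records, `[[`, character(1), "primary_constitution")
  # label noise redistributes mass symmetrically under uniform prevalence,
  # so expected frequency stays 1/9
  p <- 1 / 9
  se <- sqrt(p * (1 - p) / n)
  for (cl in constitution_labels)
    expect_lt(abs(mean(labels == cl) - p), 3 * se + 1e-9)
  # paper_like preset concentrates on the three stated classes
  sim3 <- simulate_records(preset_config("paper_like", n_records = 500,
                                         seed = 6))
  lab3 <- vapply(sim3$records, `[[`, character(1), "primary_constitution")
  expect_gt(mean(lab3 %in% c("BC", "DHC", "ISC")), 0.93)
})

test_that("ground truth is disjoint except for the shared pool", {
  truth <- gen_corpus(10, seed = 1)$truth
  expect_length(truth$typical_symptoms, 9)
  expect_true(all(lengths(truth$typical_symptoms) == 20))
  for (i in 1:8) for (j in (i + 1):9) {
    overlap <- intersect(truth$typical_symptoms[[i]],
                         truth$typical_symptoms[[j]])
    expect_length(overlap, 0)
  }
  expect_length(intersect(unlist(truth$typical_symptoms),
                          truth$shared_pool), 0)
  expect_true("pale red tongue" %in% truth$shared_pool)
})

test_that("plant_check agrees with a direct scan and flags thresholds", {
  sim <- gen_corpus(400, "noise_free", seed = 13)
  pc <- plant_check(sim$records, sim$truth, 20, 0.6)
  sc <- pc[pc$kind == "symptom_constitution", ]
  expect_true(all(sc$confidence == 1))              # noise-free world
  expect_true(all(pc[pc$kind == "constitution_regimen", ]$confidence == 1))
  # empirical support equals an independent tally for a sample of rules
  labels <- vapply(sim$records, `[[`, character(1), "primary_constitution")
  set.seed(14)
  for (i in sample.int(nrow(sc), 8)) {
    cnt <- sum(vapply(sim$records, function(r)
      sc$antecedent[i] %in% r$symptoms, logical(1)) &
        labels == sc$consequent[i])
    expect_equal(sc$support[i], cnt)
  }
  # an impossible threshold is flagged unrecoverable
  pc_hi <- plant_check(sim$records, sim$truth, 10000, 0.6)
  expect_true(all(!pc_hi$recoverable))
})

test_that("preprocessing removes exactly the designated shared pool", {
  sim <- gen_corpus(1500, "uniform", seed = 17)
  out <- preprocess_records(sim$records)
  expect_setequal(out$removed$symptom, sim$truth$shared_pool)
})
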