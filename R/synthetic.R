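# Typical-symptom vocabulary seeds, one set per constitution. Phrases that
# recur across constitutions in the clinical judging standards (e.g. "pale
# red tongue" for both BC and QDC) live in the designated shared pool below,
# keeping the per-class sets pairwise disjoint.
class_symptom_seeds <- list(
  BC   = c("thin white moss", "ruddy complexion", "dense and shiny hair",
           "energetic"),
  YADC = c("fat and tender tongue", "dark lips", "thin hair",
           "fat and soft muscle", "chilly"),
  YIDC = c("red tongue", "flushed face", "dry mouth and throat",
           "pulse breakdown", "hot hands and feet"),
  QDC  = c("weak pulse", "pale face", "easy fatigue"),
  QSC  = c("unstable introversion", "sensitive and anxious", "depressed",
           "insomniac"),
  PDC  = c("sticky mouth and greasy moss", "oily and sweaty skin",
           "somnolent", "fat and soft belly", "edema eyes"),
  DHC  = c("easily upset and irritable", "prone to acne"),
  BSC  = c("blue and purple lips", "rough and dark skin",
           "irritability and forgetfulness", "easy itchy and achy",
           "yellow hair"),
  ISC  = c("prone to be allergic", "poor immunity", "easy to urticaria",
           "easy to allergic rhinitis", "easy to asthma",
           "easy to skin desquamation")
)

# symptoms that occur across constitutions; injected as cross-class noise
shared_symptom_pool <- c("pale red tongue", "black eyes", "fat or thin",
                         "lethargic")

# stop-word contamination drawn from these high-frequency function words
stopword_pool <- c("this", "and", "or", "the", "he", "she", "it", "of")

#' Synthetic-corpus generator configuration
#'
#' Validates and freezes the stated world for [simulate_records()]. Defaults:
#' uniform prevalence over the nine constitutions; 20 typical symptoms per
#' constitution (seeded from the clinical judging-standard phrases, padded
#' with systematic `s_<class>_<k>` tokens); 3-8 symptoms per record; a 0.1
#' chance of one cross-constitution shared symptom; a 0.1 chance of one
#' stop-word token; 3 regimen items per constitution mapped deterministically
#' from the recorded label; a 0.05 chance the record is labeled with a
#' uniformly random other constitution.
#'
#' @param n_records Number of records (>= 0).
#' @param prevalence Length-9 probability vector over [constitution_labels]
#'   (non-negative, sums to 1 within 1e-9).
#' @param symptoms_per_constitution Distinct typical symptoms per class.
#' @param symptoms_per_record Integer range `c(lo, hi)` sampled uniformly.
#' @param shared_symptom_rate,stopword_rate,label_noise_rate Rates in
#'   `[0, 1]`.
#' @param regimen_items_per_constitution Regimen items per class map entry.
#' @param seed Integer seed; the corpus is a pure function of the config.
#' @return Object of class `tcm_genconfig`.
#' @export
generator_config <- function(n_records = 5000L,
                             prevalence = rep(1 / 9, 9),
                             symptoms_per_constitution = 20L,
                             symptoms_per_record = c(3L, 8L),
                             shared_symptom_rate = 0.1,
                             stopword_rate = 0.1,
                             regimen_items_per_constitution = 3L,
                             label_noise_rate = 0.05,
                             seed = 1L) {
  fail <- function(...) stop("invalid generator config: ", ...,
                             call. = FALSE)
  if (!is.numeric(n_records) || length(n_records) != 1 || n_records < 0)
    fail("n_records must be a single non-negative integer")
  if (length(prevalence) != 9 || any(prevalence < 0))
    fail("prevalence must be 9 non-negative values")
  if (abs(sum(prevalence) - 1) > 1e-9)
    fail("prevalence must sum to 1 (got ", sum(prevalence), ")")
  if (!is.numeric(symptoms_per_constitution) || symptoms_per_constitution < 1)
    fail("symptoms_per_constitution must be >= 1")
  if (length(symptoms_per_record) != 2 ||
      symptoms_per_record[1] < 1 ||
      symptoms_per_record[2] < symptoms_per_record[1])
    fail("symptoms_per_record must be c(lo, hi) with 1 <= lo <= hi")
  for (r in c(shared_symptom_rate = shared_symptom_rate,
              stopword_rate = stopword_rate,
              label_noise_rate = label_noise_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1)
      fail("rates must lie in [0, 1]")
  }
  if (!is.numeric(regimen_items_per_constitution) ||
      regimen_items_per_constitution < 1)
    fail("regimen_items_per_constitution must be >= 1")
  cfg <- list(n_records = as.integer(n_records),
              prevalence = stats::setNames(as.numeric(prevalence),
                                           constitution_labels),
              symptoms_per_constitution =
                as.integer(symptoms_per_constitution),
              symptoms_per_record = as.integer(symptoms_per_record),
              shared_symptom_rate = shared_symptom_rate,
              stopword_rate = stopword_rate,
              regimen_items_per_constitution =
                as.integer(regimen_items_per_constitution),
              label_noise_rate = label_noise_rate,
              seed = as.integer(seed))
  class(cfg) <- "tcm_genconfig"
  cfg
}

#' Preset generator configurations
#'
#' `"uniform"` (the default world), `"noise_free"` (all contamination rates
#' zero: shared symptoms, stop words and label noise off) and `"paper_like"`
#' (prevalence concentrated on BC / DHC / ISC in ratio 42.3 : 31.3 : 26.2,
#' renormalized; an analogy for a clinic population dominated by three
#' constitutions, not a reconstruction of any real cohort).
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [generator_config()] (e.g. `n_records`,
#'   `seed`).
#' @return A `tcm_genconfig`.
#' @export
preset_config <- function(preset = c("uniform", "noise_free", "paper_like"),
                          ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    uniform = list(),
    noise_free = list(shared_symptom_rate = 0, stopword_rate = 0,
                      label_noise_rate = 0),
    paper_like = {
      p <- c(42.3, 31.3, 26.2) / sum(c(42.3, 31.3, 26.2))
      prev <- stats::setNames(numeric(9), constitution_labels)
      prev[c("BC", "DHC", "ISC")] <- p
      list(prevalence = unname(prev))
    })
  do.call(generator_config, utils::modifyList(base, list(...)))
}

build_ground_truth <- function(cfg) {
  typical <- lapply(constitution_labels, function(cl) {
    seeds <- setdiff(class_symptom_seeds[[cl]], shared_symptom_pool)
    k <- cfg$symptoms_per_constitution
    if (length(seeds) >= k) return(seeds[seq_len(k)])
    pad <- sprintf("s_%s_%02d", tolower(cl),
                   seq_len(k - length(seeds)) + length(seeds))
    c(seeds, pad)
  })
  names(typical) <- constitution_labels
  regimen_map <- lapply(constitution_labels, function(cl) {
    items <- sprintf("r_%s_%d", tolower(cl),
                     seq_len(cfg$regimen_items_per_constitution))
    if (cl == "PDC") items[1] <- "eliminate phlegm and remove dampness"
    items
  })
  names(regimen_map) <- constitution_labels
  planted <- do.call(rbind, lapply(constitution_labels, function(cl) {
    rbind(
      # symptoms are class-exclusive, so a record containing the symptom is
      # labeled with the class unless its label was flipped by noise
      data.frame(antecedent = typical[[cl]], consequent = cl,
                 kind = "symptom_constitution",
                 design_confidence = 1 - cfg$label_noise_rate,
                 stringsAsFactors = FALSE)[cfg$prevalence[[cl]] > 0, ],
      data.frame(antecedent = cl, consequent = regimen_map[[cl]],
                 kind = "constitution_regimen", design_confidence = 1,
                 stringsAsFactors = FALSE)
    )
  }))
  rownames(planted) <- NULL
  structure(list(typical_symptoms = typical,
                 shared_pool = shared_symptom_pool,
                 regimen_map = regimen_map,
                 planted_rules = planted,
                 config = cfg),
            class = "tcm_truth")
}

#' Generate a synthetic clinical-record corpus
#'
#' Draws each record's constitution from the prevalence vector, its symptoms
#' from that constitution's typical set (pairwise disjoint across classes
#' except for the designated shared pool), then contaminates it: one shared
#' symptom with probability `shared_symptom_rate`, one stop-word token with
#' probability `stopword_rate`, and a uniformly random *other* recorded label
#' with probability `label_noise_rate`. The regimen is the deterministic map
#' entry of the *recorded* label (treatment follows the clinician's
#' assessment). Fully reproducible: identical configs give bit-identical
#' corpora.
#'
#' @param config A [generator_config()].
#' @return List with `records` (list of [medical_record()]) and `truth`
#'   (class `tcm_truth`: typical symptom sets, shared pool, regimen map and
#'   the planted rule list with design confidences).
#' @export
simulate_records <- function(config) {
  if (!inherits(config, "tcm_genconfig"))
    stop("config must come from generator_config()", call. = FALSE)
  truth <- build_ground_truth(config)
  n <- config$n_records
  records <- if (n == 0) list() else with_seed(config$seed, {
    true_class <- sample(constitution_labels, n, replace = TRUE,
                         prob = config$prevalence)
    n_sym <- sample(seq(config$symptoms_per_record[1],
                        config$symptoms_per_record[2]),
                    n, replace = TRUE)
    add_shared <- stats::runif(n) < config$shared_symptom_rate
    shared_pick <- sample(truth$shared_pool, n, replace = TRUE)
    add_stop <- stats::runif(n) < config$stopword_rate
    stop_pick <- sample(stopword_pool, n, replace = TRUE)
    relabel <- stats::runif(n) < config$label_noise_rate
    lapply(seq_len(n), function(i) {
      cl <- true_class[i]
      sym <- sample(truth$typical_symptoms[[cl]],
                    min(n_sym[i], length(truth$typical_symptoms[[cl]])))
      if (add_shared[i]) sym <- c(sym, shared_pick[i])
      if (add_stop[i]) sym <- c(sym, stop_pick[i])
      label <- if (relabel[i])
        sample(setdiff(constitution_labels, cl), 1L) else cl
      medical_record(
        record_id = sprintf("R%06d", i),
        symptoms = sym,
        primary_constitution = label,
        regimen = truth$regimen_map[[label]]
      )
    })
  })
  list(records = records, truth = truth)
}

#' Check planted rules against a corpus
#'
#' Independent brute-force tally (no FP-growth involved): for every planted
#' rule, counts its empirical support and confidence in the corpus and flags
#' whether each clears the given thresholds. Used to calibrate what a
#' mining run can possibly recover.
#'
#' @param records Generated records.
#' @param truth The matching `tcm_truth`.
#' @inheritParams tcm_train
#' @return Data frame: planted rule columns plus `support`,
#'   `antecedent_support`, `confidence`, `clears_support`,
#'   `clears_confidence`, `recoverable`.
#' @export
plant_check <- function(records, truth, min_support_count = 20,
                        min_confidence = 0.6) {
  labels <- vapply(records, `[[`, character(1), "primary_constitution")
  pr <- truth$planted_rules
  res <- lapply(seq_len(nrow(pr)), function(i) {
    if (pr$kind[i] == "symptom_constitution") {
      has_ant <- vapply(records, function(r)
        pr$antecedent[i] %in% r$symptoms, logical(1))
      both <- sum(has_ant & labels == pr$consequent[i])
    } else {
      has_ant <- labels == pr$antecedent[i]
      both <- sum(has_ant & vapply(records, function(r)
        pr$consequent[i] %in% r$regimen, logical(1)))
    }
    c(support = both, antecedent_support = sum(has_ant))
  })
  res <- do.call(rbind, res)
  out <- cbind(pr, as.data.frame(res))
  out$confidence <- ifelse(out$antecedent_support > 0,
                           out$support / out$antecedent_support, NA_real_)
  out$clears_support <- out$support >= min_support_count
  out$clears_confidence <- !is.na(out$confidence) &
    out$confidence >= min_confidence
  out$recoverable <- out$clears_support & out$clears_confidence
  out
}
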