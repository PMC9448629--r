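# the worked 3-transaction database used throughout the mining tests
toy_db <- function() list(c("A", "B"), c("B", "C"), c("A", "B", "C"))

toy_expected <- function() {
  data.frame(key = c("A", "A|B", "B", "B|C", "C"),
             support = c(2L, 2L, 3L, 2L, 2L),
             stringsAsFactors = FALSE)
}

# small hand-built record corpus: 2 BC + 2 QDC + 1 PDC, with "pale red
# tongue" planted evenly in the BC and QDC records
shared_symptom_corpus <- function() {
  list(
    medical_record("b1", c("ruddy complexion", "energetic",
                           "pale red tongue"), "BC",
                   regimen = "balanced diet"),
    medical_record("b2", c("ruddy complexion", "pale red tongue"), "BC",
                   regimen = "balanced diet"),
    medical_record("q1", c("easy fatigue", "pale red tongue"), "QDC",
                   regimen = "tonify qi"),
    medical_record("q2", c("easy fatigue", "weak pulse",
                           "pale red tongue"), "QDC",
                   regimen = "tonify qi"),
    medical_record("p1", c("somnolent", "edema eyes"), "PDC",
                   regimen = "eliminate phlegm and remove dampness")
  )
}

# deterministic synthetic corpus via the generator presets
gen_corpus <- function(n = 600, preset = "noise_free", seed = 42, ...) {
  simulate_records(preset_config(preset, n_records = n, seed = seed, ...))
}
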