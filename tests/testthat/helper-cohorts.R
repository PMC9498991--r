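# Shared fixtures, built in code.

noiseless_params <- function(...) {
  ground_truth_params(noise_scale = 0, ...)
}

# a tiny hand-written cohort data.frame (3 lines, one per phenotype class)
tiny_records <- function() {
  rbind(
    as.data.frame(simulate_record(0, "wildtype_like", noiseless_params(),
                                  id = "WT0"), stringsAsFactors = FALSE),
    as.data.frame(simulate_record(3, "wildtype_like", noiseless_params(),
                                  id = "WT3"), stringsAsFactors = FALSE),
    as.data.frame(simulate_record(5, "atm_homozygous", noiseless_params(),
                                  id = "AT5"), stringsAsFactors = FALSE)
  )
}

tiny_cohort_csv <- function(path = tempfile(fileext = ".csv")) {
  write_cohort_csv(cohort(tiny_records()), path)
  path
}

# latent law values used all over the tests
law_sf2 <- function(g) 61.55 - 11.72 * g
law_patm <- function(g) 41.72 - 6.78 * g
law_mn <- function(sf2) -log(sf2 / 62.2) / 0.107
law_h2ax <- function(sf2) -log(sf2 / 62.56) / 0.216
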