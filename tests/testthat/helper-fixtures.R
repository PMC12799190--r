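# shared fixtures and helpers for the suite

quiet_fit <- function(spec, data, mcmc = mcmc_profile("test"), seed = 1) {
  suppressWarnings(fit_model(spec, data, mcmc, seed = seed))
}

# small config for generator-driven tests
test_config <- function(...) {
  sim_config(n_participants = 12, n_sessions = 2, session_length = 300,
             seed = 424242, ...)
}

# toy fixation log builder: categories at given start times, 0.3 s events
toy_fixations <- function(starts, categories,
                          objects = paste0(categories, "_001")) {
  data.frame(start = starts, end = starts + 0.3,
             duration = 0.3, object_id = objects, category = categories,
             stringsAsFactors = FALSE)
}

# plug-in (maximum-likelihood) entropy of a count vector, in bits: the
# independent oracle for the large-sample limit of the corrected estimator
plugin_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}
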