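# Shared fixtures, generated in code and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small fast canvas for unit tests that only need plausible smear content
small_smear_params <- function(height = 160L, width = 160L, wbc_count = 1L) {
  smear_synth_params(height = height, width = width, wbc_count = wbc_count,
                     rbc_count_mean = 6, rbc_radius_mean = 12,
                     rbc_radius_sd = 1.5,
                     normal_radius_mean = 14, normal_radius_sd = 1.5,
                     blast_radius_mean = 22, blast_radius_sd = 2.5)
}

default_dataset_200 <- function() {
  cached("ds200", generate_dataset(100, seed = 0))
}

handcrafted_fit_200 <- function() {
  cached("fit200", {
    ds <- default_dataset_200()
    leukodiag(ds$manifest, samples = ds$samples,
              config = run_config(mode = "handcrafted", classifier = "ffnn",
                                  seed = 0,
                                  mlp = train_config(max_epochs = 300L)))
  })
}

hybrid_fit_200 <- function() {
  cached("hybrid200", {
    ds <- default_dataset_200()
    leukodiag(ds$manifest, samples = ds$samples,
              config = run_config(mode = "hybrid_cnn_svm", seed = 0))
  })
}
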