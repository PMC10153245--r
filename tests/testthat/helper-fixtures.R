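# Shared heavy fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

# classifier trained on a simulator-labelled cohort (the reconstruction of
# the "generic training set")
fixture_model <- function() {
  if (is.null(.fixtures$model)) {
    cfg <- run_config()
    tr <- generate_cohort(synthetic_spec(n_genomes = 5,
                                         genome_len_mode = 1e6,
                                         genome_len_spread = 2e5,
                                         seed = 2024))
    td <- build_training_data(tr, cfg)
    .fixtures$model <- train_classifier(td$metrics, td$labels,
                                        n_trees = cfg$randomforest_trees,
                                        seed = 7)
    .fixtures$training_data <- td
  }
  .fixtures$model
}

fixture_training_data <- function() {
  fixture_model()
  .fixtures$training_data
}

# small sequence-level cohort for detector tests
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(
      synthetic_spec(n_genomes = 4, genome_len_mode = 6e5,
                     genome_len_spread = 1e5, seed = 99))
  }
  .fixtures$cohort
}

fixture_detect <- function() {
  if (is.null(.fixtures$regions)) {
    co <- fixture_cohort()
    model <- fixture_model()
    cfg <- run_config()
    .fixtures$regions <- dplyr::bind_rows(
      lapply(co$genomes, function(g) detect(g, model, co$marker_set, cfg)))
  }
  .fixtures$regions
}
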