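# Heavy packaged-model objects are shared across test files within one
# session (helpers are sourced once per test run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

packaged_model <- function() cached("model", ecoli_trp_model())

packaged_gt <- function() cached("gt", make_ground_truth(packaged_model(),
                                                         seed = 42))

packaged_dataset <- function() cached("dataset",
  generate_perturbation_dataset(packaged_gt(), seed = 3))

packaged_fva <- function() cached("fva",
  loopless_fva(packaged_model(), reference_rates()))

toy_gt <- function() cached("toy_gt", make_ground_truth(toy_branched_model(),
                                                        seed = 7))
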