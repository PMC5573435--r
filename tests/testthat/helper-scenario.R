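# The staged synthetic scenario used by the acceptance tests:
# 5 species, order-3 Markov composition (Dirichlet concentration 1),
# 10 reference + 2 validation genomes per species, 50 kb each, 2%
# within-species divergence, 400 bp fragments; ensemble k = 6..10,
# omega = 32, voting threshold 5. These are the package defaults
# (synthetic_spec()); the heavier runs are cached per test session.

scenario_run <- function(name, spec) {
  fixture(name, function() {
    ds <- make_dataset(spec)
    ens <- train_ensemble(ds$reference_fragments, kset = 6:10, omega = 32)
    truth <- ds$validation_fragments[, c("id", "label")]
    vote <- classify_vote(ens, ds$validation_fragments, threshold = 5)
    full <- classify_fragments(ens, ds$validation_fragments,
                               reference = ds$reference_genomes,
                               threshold = 5)
    list(ds = ds, ens = ens, truth = truth, vote = vote, full = full,
         vote_report = staged_report(vote, truth),
         full_report = staged_report(full, truth))
  })
}

scenario_staged <- function() {
  scenario_run("scenario_staged", synthetic_spec(seed = 1))
}

scenario_clean <- function() {
  scenario_run("scenario_clean",
               synthetic_spec(divergence = 0, error_rate = 0, seed = 1))
}

scenario_uniform <- function() {
  scenario_run("scenario_uniform",
               synthetic_spec(concentration = Inf, seed = 1))
}

stage_value <- function(report, stage, column) {
  report[[column]][report$stage == stage]
}
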