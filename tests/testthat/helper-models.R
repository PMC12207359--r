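# Shared synthetic study suite and trained models, built once per test
# session and reused by the property and acceptance tests.
#
# Study conditions: 13 tasks of 300 reactions-worth of synthetic
# features (48 sparse binary + 3 condition columns), 65/35 class
# imbalance, moderate between-task shift and label noise; 8 training,
# 2 validation and 3 test tasks.  Meta-training episodes use support 64
# / query 32 in batches of five tasks (a scaled-down version of the
# 512/64 protocol the trainers default to).

.fixtures <- new.env(parent = emptyenv())

acceptance_spec <- function() {
  synthetic_spec(n_tasks = 13, n_per_task = 300, dim = 48,
                 task_shift_scale = 0.5, noise_scale = 0.5,
                 positive_prevalence = 0.65, feature_on_rate = 0.1,
                 seed = 101)
}

acceptance_suite <- function() {
  if (is.null(.fixtures$suite)) {
    suite <- generate_tasks(acceptance_spec())
    .fixtures$suite <- list(suite = suite,
                            split = suite_split(suite, 8, 2, 3))
  }
  .fixtures$suite
}

acceptance_config <- function(n_iters, seed) {
  meta_config(support_size = 64, query_size = 32, task_batch = 5,
              n_iters = n_iters, outer_lr = 0.01, inner_steps = 25,
              inner_lr = 0.1, eval_every = 25, hidden = 24,
              latent_dim = 8, seed = seed)
}

trained_models <- function() {
  if (is.null(.fixtures$models)) {
    fx <- acceptance_suite()
    X <- fx$suite$X
    y <- fx$suite$y
    sp <- fx$split
    .fixtures$models <- list(
      dkt = train_dkt(X, y, sp$train, sp$valid,
                      acceptance_config(150, seed = 211)),
      adkf = train_adkf(X, y, sp$train, sp$valid,
                        acceptance_config(80, seed = 212)),
      adkf_prior = train_adkf_prior(X, y, sp$train, sp$valid,
                                    acceptance_config(60, seed = 213)),
      protonet = train_protonet(X, y, sp$train, sp$valid,
                                acceptance_config(200, seed = 214)))
  }
  .fixtures$models
}

# A tiny suite for fast unit tests of the trainers.
tiny_suite <- function(seed = 7) {
  suite <- generate_tasks(synthetic_spec(n_tasks = 5, n_per_task = 90,
                                         dim = 16, seed = seed))
  list(suite = suite, split = suite_split(suite, 3, 1, 1))
}

tiny_config <- function(n_iters = 5, seed = 9) {
  meta_config(support_size = 30, query_size = 15, task_batch = 3,
              n_iters = n_iters, inner_steps = 10, eval_every = n_iters,
              hidden = 8, latent_dim = 4, seed = seed)
}
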