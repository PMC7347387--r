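# The end-to-end synthetic study and the initialization-robustness
# protocol are expensive; they are computed once per test run and shared
# by the acceptance blocks that assert on different aspects of the same
# results.

acceptance_study <- function() {
  memo("acceptance_study", {
    run_synthetic_study(duration_s = 100, seed = 1, jackknife_n = 5,
                        train_stride = 6,
                        config = study_config(1, max_epochs = 10))
  })
}

robustness_runs <- function() {
  memo("robustness_runs", {
    lapply(c(linear = "linear", gain_adaptive = "gain_adaptive"),
           function(kind) {
             ds <- make_dataset(synthetic_neuron(kind), 100,
                                seed = 7 + match(kind, c("linear",
                                                         "gain_adaptive")))
             initialization_robustness(ds,
                                       config = study_config(seed = 7,
                                                             max_epochs = 6),
                                       n_init = 4, train_stride = 6)
           })
  })
}
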