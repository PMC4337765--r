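# Small configurations used across unit tests. The full study conditions
# (4096 steps, 100+ flights) live in test-acceptance.R; unit tests use
# shorter flights to stay fast while exercising the same code paths.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_steps = 512L, seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
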