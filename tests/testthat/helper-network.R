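# miniature sizes shared across tests: 36-neuron ring keeps every dynamical
# regime of the 120-neuron default (kernels and gains are size-invariant)
mini_ring <- 36
mini_alb <- 108

# short conflict-scenery learning run used by several tests
mini_run <- function(seed = 1, duration = 90, tests = list(test_spec(label = "conflict")),
                     ...) {
  scn <- scenery_conflict(mini_ring)
  proto <- hd_protocol(list(list(scenery = scn, duration = duration,
                                 tests = tests)),
                       seed = seed, test_revs = 1, name = "mini")
  run_protocol(proto, n_dirs = mini_ring, n_alb = mini_alb, ...)
}
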