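# Shared fixtures: representative states and a reduced-stiffness parameter
# set used where the default calibration's slow constants are irrelevant.

mid_state <- function(h2s = 0) {
  model_state(psii_g = 0.5, psii_e = 0.3, psii_d = 0.2,
              oec_a = 0.6, oec_ox = 0.25, oec_i = 0.15,
              pq_red = 0.4, et_red = 0.35, nadph = 0.45,
              h2s = h2s, o2 = 10)
}

# random valid states under a fixed seed, for property-style loops
random_states <- function(n, seed = 42, h2s_max = 100) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ps <- as.numeric(stats::rmultinom(1, 1000, c(1, 1, 1))) / 1000
    oe <- as.numeric(stats::rmultinom(1, 1000, c(1, 1, 1))) / 1000
    model_state(psii_g = ps[1], psii_e = ps[2], psii_d = ps[3],
                oec_a = oe[1], oec_ox = oe[2], oec_i = oe[3],
                pq_red = stats::runif(1), et_red = stats::runif(1),
                nadph = stats::runif(1),
                h2s = stats::runif(1, 0, h2s_max),
                o2 = stats::runif(1, 0, 300))
  })
}
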