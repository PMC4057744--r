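# shared test helpers

# reduced swarm budget for test-suite speed; the 1-D k search converges in
# far fewer iterations than the production default
test_control <- function() {
  gm_control(n_particles = 20L, t_max = 120L, stall = 25L)
}

# small alignment used across io tests
toy_alignment <- function() {
  gm_alignment(c(human = "M-KTW", mouse = "MAKTW", frog = "MAQSW"))
}

random_residues <- function(n) {
  sample(rownames(aa_properties), n, replace = TRUE)
}
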