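# Shared fixtures: built once per test run.

truth_params <- her_truth_parameters()
truth_free <- her_free_values(truth_params)

# tiny noiseless dataset on the parental line, used by estimation tests
tiny_parental_data <- local({
  des <- her_design_small("parental")
  her_synthesize(des, truth_params, cv = 0, seed = 7)
})

# a random nonnegative state vector with reproducible contents
random_state <- function(seed, scale = 1e4) {
  set.seed(seed)
  setNames(runif(51) * scale, her_state_names())
}

# parameters with every biochemical rate and synthesis switched off;
# trafficking exit rates must stay positive, so kinetic silence is
# asserted on surface-only states
silent_params <- function() {
  her_parameters(
    ku = setNames(rep(0, 20), names(her_free_values(truth_params))[1:20]),
    binding = list(kon1s = 0, koff1s = 0, kon1e = 0, koff1e = 0,
                   kon3s = 0, koff3s = 0, kon3e = 0, koff3e = 0),
    kc = c(s = 0, e = 0),
    trafficking = list(her1 = c(kt = 0, ke = 0, kx = 0.15, f = 0.5),
                       her23 = c(kt = 0, ke = 0, kx = 0.15, f = 0.85))
  )
}
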