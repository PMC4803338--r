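# One shared default model for the whole suite: the settled resting state is
# cached on the object, so every test that simulates from rest reuses it.
shared_model <- build_neuron_model()

# and a shared passive twin for the linear-cable oracles
shared_passive <- build_neuron_model(passive_only = TRUE)

t0_std <- 10

std_step <- function(t0 = t0_std) protocol(step_current(onset = t0))

run_step_with_inh <- function(model, g_nS, loc_um = 90, onset = 2,
                              t0 = t0_std, path = "apical", dur = 40) {
  p <- protocol(step_current(onset = t0),
                inhibitory_synapse(site_um(loc_um, path), g_nS,
                                   onsets = t0 + onset))
  simulate_protocol(model, p, simulation_spec(duration = dur))
}
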