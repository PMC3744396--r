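# Example run configuration for vasosim.R / run_experiment().
# Omitted keys fall back to the standard single-cell parameter tables.
experiment: fig3_freq_response
seed: 1
secretion:
  r_max: 1000000
spiking:
  I_re: 600
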