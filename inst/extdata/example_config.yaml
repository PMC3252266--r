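# Example run configuration for load_run_config() / the affsim CLI.
# Every key mirrors a constructor argument; omitted sections use defaults.
model:
  tau_reach: 2
  log_prec:
    salience: 4
schedule:
  preset: paper_default
world:
  tau_arm: 4
  tau_sal: 2
sim:
  n_bins: 128
  seed: 1
lesions:
  salience_sensory: 3.2
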