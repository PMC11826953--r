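# Example run configuration for read_run_config() / scripts/compsleep_cli.R.
# All generator fields are optional; omitted ones keep package defaults.
input: simulate
seed: 20240131
delta: 0.06
level: 0.95
generator:
  n_participants: 500
  planted_effects:
    - focal: protein
      mode: add
      delta: 0.06
      outcome: tst_h
      target: 0.27
    - focal: monounsaturated
      mode: add
      delta: 0.06
      outcome: sl_min
      target: 4.64
    - focal: polyunsaturated
      mode: add
      delta: 0.06
      outcome: sl_min
      target: -4.72
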