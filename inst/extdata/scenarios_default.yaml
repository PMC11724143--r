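# Default treatment scenarios: untreated reference, irbesartan monotherapy
# with full persistence, and irbesartan + amlodipine dual therapy at full
# and at 50% 1-year persistence (constant discontinuation hazard).
engine:
  n_sample: 100000
  horizon_days: 3650
  step_days: 1
  iterations: 10
  master_seed: 1
  common_random_numbers: true
risk_model:
  rrr_per_5mmhg: 0.10
scenarios:
  - name: untreated
    drugs: []
    p1: 1.0
  - name: irbesartan_mono_p100
    drugs: ["irbesartan 150"]
    p1: 1.0
  - name: irbesartan_amlodipine_p100
    drugs: ["irbesartan 150", "amlodipine 5"]
    p1: 1.0
  - name: irbesartan_amlodipine_p50
    drugs: ["irbesartan 150", "amlodipine 5"]
    p1: 0.5
subgroups: ["ascvd", "diabetes"]
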