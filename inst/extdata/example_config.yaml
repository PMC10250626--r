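# Example pipeline configuration. Entries override default_config();
# anything omitted keeps its default. The seed is mandatory.
seed: 42
n_persons: 20000
incidence:
  decline_rate: 0.015
  bump_height: 1.3
obesity:
  prevalence:
    M: 0.25
    F: 0.25
  rr_incidence: 3.0
  rr_mortality: 1.5
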