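# Demo pipeline configuration: all three resuspension scenarios,
# shortened series for a quick run.
seed: 1
scenarios: [active, filtered, AOA]
t_max_hr: 24
n_injections: 8
noise_cv: 0.05
stages: [simulate, drift, quantify, screen]
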